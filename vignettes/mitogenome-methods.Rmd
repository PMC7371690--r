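---
title: "Methods: comparative mitogenome characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenome characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocompare)
```

This vignette documents the statistics `mitocompare` computes, the
conventions and defaults behind them, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## Coordinates and the circular gene ledger

All coordinates are 1-based and fully inclusive on the heavy (H) strand,
exactly as mitogenome annotation tables are printed. A feature with
`start > end` wraps the circular origin; its length is
`(L − start + 1) + end` for a genome of length `L`. Internally the
adjacency ledger works in *unrolled* coordinates (a wrapping feature ends
at `end + L`), which makes the gap arithmetic uniform even when a gene
overlap itself straddles the origin — a case random layouts do produce.

For consecutive features $a \rightarrow b$ the ledger records
$\mathrm{gap} = \mathrm{start}(b) - \mathrm{end}(a) - 1$: positive values
are intergenic spacers, negative values overlaps, zero means abutting. The
last feature closes the circle back to the first, so a table of $n$
features yields exactly $n$ ledger entries and the conservation law
$\sum \mathrm{gap} + \sum \mathrm{length} = L$ holds identically; the test
suite checks it on 1,000 random layouts.

Two conventions required a decision:

* **Counting regions.** Published spacer/overlap tallies count *non-zero*
  gaps only; abutting genes (gap 0) belong to neither count. The summary
  adopts this, which is what makes the gaur table come out at 14 spacer
  regions and 7 overlap locations (two 1-bp overlaps count as distinct
  locations).
* **PCG fraction.** The protein-coding fraction of the genome uses the
  genomic *union* of PCG positions (overlapping positions counted once):
  the gaur PCGs sum to 11,404 bp but carry 65 bp of mutual overlap, and
  only the union (11,339 bp, 69.37%) is consistent with the fraction as
  conventionally reported. `pcg_fraction = "sum"` gives the alternative.
* **Containment.** A feature fully contained in its predecessor (absent in
  bovids, possible in corrupt input) is skipped from the ledger with a
  warning rather than producing a negative gap larger than the feature.

Completeness (13 PCG + 22 tRNA + 2 rRNA + 1 control region) is a warning
by default and an error under `strict = TRUE`: partial tables are
legitimate inputs for slicing and composition work.

## Composition and strand skews

Skews are the classical strand-asymmetry measures
$\mathrm{AT}_{skew} = (A - T)/(A + T)$,
$\mathrm{GC}_{skew} = (G - C)/(G + C)$, computed from counts or
percentages interchangeably (they are scale-invariant). Gaps and N bases
are excluded from the effective length; a zero denominator (e.g. a
sequence with no G or C) yields skew 0 plus an explicit flag rather than
`NaN`, so downstream tables stay numeric.

Per-gene and per-class profiles use the *coding strand*: an L-strand gene
is profiled on its reverse complement. This matches how gene-level skews
are conventionally reported — the single L-strand PCG (nad6) then shows
sign-flipped skews relative to the H-strand genes. The PCG class profile
concatenates coding sequences, counting overlap positions once per gene
occurrence (the natural convention for codon-linked analyses);
`pcg_union = TRUE` switches to the genomic union.

A note on reproducing printed skews: recomputing a skew from *rounded*
percentages can differ from the value computed from raw counts in the
third decimal (for the gaur composition, −0.318 from the printed
percentages vs −0.319 printed). Tests on this quantity therefore use a
0.0015 tolerance.

## Codon usage and RSCU

Codons are read in frame from position 1 of each PCG's coding sequence.
Vertebrate mitochondrial PCGs often end in an incomplete stop (T or TA,
completed to UAA by polyadenylation); the trailing 1–2 nt are dropped, and
a terminal complete stop codon is excluded by default
(`include_stops = TRUE` flips this, the conventions differ across tools
and the choice only shifts stop-codon counts).

RSCU is $k \cdot X_i / \sum_{family} X$ with $k$ the synonymous-family
size, families derived from the genetic code in use — by default NCBI
translation table 2, where AGA/AGG are stops (so arginine has $k = 4$),
ATA is Met and TGA is Trp. A family with zero total count reports RSCU 0
for all members plus a `zero_family` flag instead of `NaN`. Codon labels
are reported in both DNA and RNA alphabets.

## Control-region motifs

`scan_motifs()` reports **all** occurrences including overlapping ones
(e.g. TACAT twice in "TACATACAT"); published descriptions rarely state an
overlap convention, and counting all occurrences is the conservative
superset. `terminal_polyc()` is the maximal C-suffix of the region. Both
operate on any sequence window, defaulting to the annotated control
region.

## Distances, divergence and AMOVA

Pairwise substitution counts skip sites where either sequence carries a
gap or N (pairwise deletion; `complete_deletion` drops such columns
globally first, matching the stricter convention of some GUI tools —
published analyses rarely state which was used). Transitions are A↔G and
C↔T; K2P is $d = -\tfrac12 \ln\!\big((1-2P-Q)\sqrt{1-2Q}\big)$ with $P,Q$
the transition/transversion proportions; outside its domain the distance
is reported as `Inf` with a warning rather than an error, so distance
matrices for saturated pairs remain inspectable.

"Genetic divergence" between two groups is the mean of all between-group
pairwise distances; the model is selectable (p-distance by default, which
is the weakest assumption when the source analysis does not name one).

AMOVA uses the standard one-level estimators from pairwise *squared*
substitution counts $d^2_{ij}$ (the default haplotype distance of the
classical implementations):

$$SSD_{total} = \frac{1}{N}\sum_{i<j} d^2_{ij}, \qquad
  SSD_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d^2_{ij}, \qquad
  SSD_{among} = SSD_{total} - SSD_{within}$$

with $\sigma^2_w = SSD_{within}/(N-G)$,
$\sigma^2_a = (SSD_{among}/(G-1) - \sigma^2_w)/\bar n$,
$\bar n = (N - \sum_g n_g^2/N)/(G-1)$, and
$\Phi_{ST} = \sigma^2_a/(\sigma^2_a + \sigma^2_w)$. A negative
among-group component is reported as-is with a flag (standard AMOVA
behavior). The permutation p-value counts the observed labeling as one
permutation: $p = (1 + \#\{\Phi^{perm} \ge \Phi^{obs}\})/(1 + B)$, which
is the exact-test convention and keeps $p > 0$. Groups of size 1 are
allowed with a warning — the design the package emulates (4 + 1 + 1
haplotypes) has them — but the within-group variance then rests entirely
on the multi-member groups, and the permutation null is coarse (few
distinct labelings), so p-values bottom out well above $1/B$.

## Trees

Neighbor joining is the Saitou–Nei agglomeration with the usual
Q-criterion, branch-length and reduction formulas. Two numerical choices:
ties in Q are broken by the lexicographically smallest pair of subtree
labels (making output deterministic on degenerate, e.g. equidistant,
matrices), and negative branch lengths — which NJ can produce on
non-additive input — are clamped to zero, as the common GUI tools do. On
additive matrices the generating tree is recovered exactly (topology and
lengths to 1e-9; tested on 4–6 taxa).

Fitch small-parsimony scoring uses bitmask state sets; gaps/N are fully
ambiguous tips. The input tree is rerooted at a tip and binarized first,
which leaves the score invariant for the binary-unrooted trees the
package produces. `mp_search()` enumerates all unrooted topologies (via
`phangorn::allTrees`) and scores them with the package's own Fitch
implementation; it refuses above 9 taxa (135,135 topologies) and points
to NJ. All tied optima are returned, ordered lexicographically by their
Newick strings.

Bootstrap support resamples alignment columns with replacement and
reports, for each internal bipartition of the point-estimate tree, the
percentage of replicate trees containing it. 100 replicates is the
default at desk scale (the classical recommendation of several thousand
is configurable but rarely informative for the handful of taxa this
package targets). Bayesian inference is deliberately out of scope; the
topological questions the package answers (clade membership of gaur-like,
mithun-like and outgroup lineages) are served by NJ/MP, and published
comparisons report the MP topology as identical to the Bayesian one for
this system.

## The synthetic-data generator

`sim_config()` defaults encode the study conditions the comparative
stages assume: a 16,345 bp circular genome at base composition A 0.335,
T 0.272, C 0.259, G 0.134 over the published gaur gene order; three
haplotype groups of 4 + 1 + 1 with ~33 pairwise substitutions within the
first group and group ancestors 0/304/634 substitutions from the base;
three planted copies each of TACAT and ATGTA ("multiple copies" is the
only published statement; three is a realistic bovid control-region
count) and a 13 nt terminal poly-C.

Haplotypes are built by placing substitutions at uniformly sampled sites:
each group ancestor receives its between-group count from the base, each
haplotype roughly half the within-group target from its ancestor
(alternating ceiling/floor, so mixed pairs differ by exactly the target).
In `"exact"` mode all substituted sites are globally disjoint — realized
pairwise counts are then exact sums of private-site counts with no
back-mutation, and the generator reports them from its own bookkeeping so
tests can compare against an independent tally. In `"poisson"` mode the
counts are Poisson draws at the same means, for statistical
(parameter-recovery) tests.

What the generator does **not** emulate: indels and alignment error (the
real genomes are length-identical, so comparisons are substitution-only),
rate heterogeneity across sites, transition/transversion bias, codon
bias, and selection. Consequences worth stating: exact-mode mutations are
almost all singletons, so within-group structure is star-like
(parsimony-uninformative within groups) — bootstrap tests therefore use
designs with ≥2 haplotypes per group, where shared ancestor sites create
internal edges. Passing tests show the *estimators* are correct under the
generator's idealized model, not that real mitogenome alignments satisfy
that model.

Coding constraints (an ATG start, a complete TAA or incomplete T/TA stop
matching each gene's length mod 3, no internal stops) are planted by
iterative repair: overlapping PCGs — e.g. the 40 bp atp8–atp6 overlap,
and the antiparallel nad5–nad6 overlap — can undo each other's fixes, so
passes repeat until stable (bounded at 40, with a warning if not
converged; in practice the default template converges in a few passes).
Planted motif counts are made exact by scrubbing accidental occurrences
outside the planted windows (a ~900 bp random region would otherwise
contain roughly one accidental copy of each 5-mer).

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed (`sim_config()`, AMOVA
permutations, bootstrap), and identical seeds give byte-identical outputs
— the report bundle written by `full_report()` is compared
file-for-file in the tests. The suite runs at desk scale: 1,000 random
gene layouts for the conservation law, 20 Poisson-mode simulations of the
4+1+1 design for AMOVA recovery (within ±5 percentage points of the
exact-placement generating value), exhaustive Fitch enumeration on
5-taxon alignments, and NJ recovery on 4–6-taxon additive matrices; the
full run takes well under a minute on one core.

## Known limitations

* The GenBank reader is deliberately minimal (LOCUS length, the feature
  keys gene/CDS/tRNA/rRNA/D-loop/misc_feature with one- or two-segment
  locations, `/gene`/`/product`, ORIGIN). It is not a general flat-file
  parser.
* AMOVA is one-level (haplotypes within groups); hierarchical designs are
  out of scope.
* `mp_search()` is exhaustive and limited to 9 taxa by design; larger
  problems should use NJ (or a dedicated phylogenetics package).
* Distances treat ambiguity codes other than N as invalid characters;
  alignments carrying IUPAC codes must be cleaned first.
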