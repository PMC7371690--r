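# Stage 3: codon extraction from protein-coding genes and relative
# synonymous codon usage (RSCU) under the vertebrate mitochondrial code.
# RSCU_i = k * X_i / sum(X over the codon's synonymous family), where k is
# the family size; 1 means no bias within the family.

#' A genetic code table
#'
#' Wraps [Biostrings::getGeneticCode()]. The default is NCBI translation
#' table 2 (vertebrate mitochondrial): AGA/AGG are stops, ATA codes Met and
#' TGA codes Trp.
#'
#' @param id Translation-table identifier accepted by
#'   [Biostrings::getGeneticCode()], e.g. `"1"` (standard) or `"2"`.
#' @return List with `id`, `table` (named character: codon -> one-letter
#'   amino acid, `*` for stop), `start_codons`, `stop_codons` and `families`
#'   (sense codons split by encoded amino acid).
#' @export
genetic_code <- function(id = "2") {
  tab <- Biostrings::getGeneticCode(id, full.search = TRUE)
  starts <- names(tab)[tab == "M"]
  alt <- attr(tab, "alt_init_codons")
  starts <- union(starts, alt)
  stops <- names(tab)[tab == "*"]
  sense <- tab[tab != "*"]
  list(
    id = id,
    table = as.character(tab) |> setNames(names(tab)),
    start_codons = starts,
    stop_codons = stops,
    families = split(names(sense), as.character(sense))
  )
}

#' Extract in-frame codon counts from the protein-coding genes
#'
#' Each PCG is sliced on its coding strand and read in frame from its first
#' position; a trailing 1-2 nt incomplete stop is dropped and a terminal
#' complete stop codon is excluded by default. Counts are pooled over all
#' PCGs.
#'
#' @param genome A [mito_genome()].
#' @param gene_table Gene table (only `feature_class == "PCG"` rows used).
#' @param code Genetic code id (default vertebrate mitochondrial).
#' @param include_stops Keep terminal complete stop codons in the counts?
#'
#' @return Tibble `codon`, `count` over the 64 codons (zeros included).
#' @export
extract_codons <- function(genome, gene_table, code = "2",
                           include_stops = FALSE) {
  gc <- genetic_code(code)
  pcg <- filter(as_tibble(gene_table), .data$feature_class == "PCG")
  counts <- setNames(integer(64), names(gc$table))
  for (i in seq_len(nrow(pcg))) {
    cds <- slice_sequence(genome, pcg$start[i], pcg$end[i], pcg$strand[i])
    n_full <- nchar(cds) %/% 3L
    if (n_full == 0L) next
    codons <- substring(cds, seq.int(1L, by = 3L, length.out = n_full),
                        seq.int(3L, by = 3L, length.out = n_full))
    if (!include_stops && codons[n_full] %in% gc$stop_codons) {
      codons <- codons[-n_full]
    }
    codons <- codons[codons %in% names(counts)]   # skip codons with N
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  tibble(codon = names(counts), count = unname(counts))
}

#' Relative synonymous codon usage
#'
#' For each sense codon, `rscu = k * count / family_total` where `k` is the
#' number of synonymous codons encoding the same amino acid. Stop codons are
#' excluded. A family whose total count is zero gets RSCU 0 for all members,
#' flagged in `zero_family`.
#'
#' @param codon_counts Tibble `codon`, `count` (e.g. from
#'   [extract_codons()]), or a named vector of counts.
#' @param code Genetic code id.
#'
#' @return Tibble `codon`, `codon_rna`, `amino_acid`, `count`, `family_size`,
#'   `rscu`, `zero_family`, sorted by amino acid then codon.
#' @examples
#' rscu(c(GCA = 2, GCC = 2, GCG = 2, GCT = 2))
#' @export
rscu <- function(codon_counts, code = "2") {
  if (!is.data.frame(codon_counts)) {
    codon_counts <- tibble(codon = names(codon_counts),
                           count = as.numeric(codon_counts))
  }
  gc <- genetic_code(code)
  sense <- names(gc$table)[gc$table != "*"]
  cnt <- setNames(numeric(length(sense)), sense)
  present <- intersect(codon_counts$codon, sense)
  cnt[present] <- codon_counts$count[match(present, codon_counts$codon)]
  out <- purrr::map_dfr(names(gc$families), function(aa) {
    fam <- sort(gc$families[[aa]])
    k <- length(fam)
    total <- sum(cnt[fam])
    tibble(
      codon = fam,
      codon_rna = chartr("T", "U", fam),
      amino_acid = aa,
      count = unname(cnt[fam]),
      family_size = k,
      rscu = if (total > 0) k * unname(cnt[fam]) / total else rep(0, k),
      zero_family = total == 0
    )
  })
  arrange(out, .data$amino_acid, .data$codon)
}

#' Amino-acid usage from codon counts
#'
#' Totals codon counts by encoded amino acid (so e.g. both leucine families,
#' CUN and UUA/UUG, pool into Leu under the vertebrate mitochondrial code)
#' and ranks amino acids by abundance.
#'
#' @inheritParams rscu
#' @return Tibble `amino_acid`, `count`, `rank`, most abundant first.
#' @export
aa_usage <- function(codon_counts, code = "2") {
  r <- rscu(codon_counts, code)
  out <- summarise(group_by(r, .data$amino_acid), count = sum(.data$count),
                   .groups = "drop")
  out <- arrange(out, dplyr::desc(.data$count), .data$amino_acid)
  mutate(out, rank = dplyr::row_number())
}

#' RSCU bar chart by amino-acid family
#'
#' @param rscu_table Output of [rscu()].
#' @return A ggplot object with stacked per-codon RSCU bars per amino acid.
#' @export
plot_rscu <- function(rscu_table) {
  ggplot2::ggplot(rscu_table,
                  ggplot2::aes(x = .data$amino_acid, y = .data$rscu,
                               fill = .data$codon_rna)) +
    ggplot2::geom_col(color = "grey30", linewidth = 0.1) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = "amino acid", y = "RSCU") +
    ggplot2::theme_minimal()
}
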