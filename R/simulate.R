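# Synthetic mitogenome generator. Emulates the study design the comparative
# stages assume: a ~16.3 kb circular genome at bovid base composition, the
# published gaur gene order (or a random non-pathological layout), planted
# control-region motifs and poly-C terminus, and grouped haplotype sets
# with configured within-/between-group substitution counts.

#' Simulation configuration
#'
#' Defaults are the study conditions: a 16,345 bp genome at the gaur base
#' composition (A 33.5%, T 27.2%, C 25.9%, G 13.4%), the published gene
#' order, three groups of 4 + 1 + 1 haplotypes whose group ancestors sit
#' 0 / 304 / 634 substitutions from the base genome, ~33 pairwise
#' substitutions within a group, three copies each of the TACAT/ATGTA
#' control-region motifs and a 13 nt terminal poly-C.
#'
#' @param seed Integer seed; recorded in all generator outputs.
#' @param genome_length Genome length in bp (must be 16345 with the
#'   `"bovid"` template, which uses the published coordinates).
#' @param gene_order `"bovid"` or `"random"` (a random
#'   non-overlapping layout; its genome length is emergent).
#' @param base_comp Named A/T/C/G probabilities summing to 1.
#' @param groups Named integer vector: haplotypes per group.
#' @param within_group_diffs Target pairwise substitution count within a
#'   group (scalar or one per group).
#' @param between_group_diffs Substitutions between each group's ancestor
#'   and the base genome (one per group; group 0 means the base itself).
#' @param motif_counts Named counts of motifs to plant in the control region.
#' @param polyc_length Terminal poly-C length to plant.
#' @param coding_constraints Give PCGs an ATG start, a complete or
#'   incomplete stop, and no internal stops?
#' @param mutation_mode `"exact"` (planted counts realized exactly on
#'   globally disjoint sites) or `"poisson"` (counts drawn Poisson at the
#'   configured means).
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 16345L,
                       gene_order = c("bovid", "random"),
                       base_comp = c(A = 0.335, T = 0.272, C = 0.259, G = 0.134),
                       groups = c(indian = 4L, cambodian = 1L, malayan = 1L),
                       within_group_diffs = 33,
                       between_group_diffs = c(indian = 0, cambodian = 304,
                                               malayan = 634),
                       motif_counts = c(TACAT = 3L, ATGTA = 3L),
                       polyc_length = 13L,
                       coding_constraints = TRUE,
                       mutation_mode = c("exact", "poisson")) {
  gene_order <- match.arg(gene_order)
  mutation_mode <- match.arg(mutation_mode)
  if (abs(sum(base_comp) - 1) > 1e-6) {
    abort("base composition must sum to 1", class = "mito_error_config")
  }
  if (any(within_group_diffs < 0) || any(between_group_diffs < 0)) {
    abort("substitution targets must be non-negative",
          class = "mito_error_config")
  }
  if (length(between_group_diffs) != length(groups)) {
    abort("between_group_diffs must have one entry per group",
          class = "mito_error_config")
  }
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    gene_order = gene_order, base_comp = base_comp[c("A", "T", "C", "G")],
    groups = groups,
    within_group_diffs = rep_len(within_group_diffs, length(groups)),
    between_group_diffs = between_group_diffs,
    motif_counts = motif_counts, polyc_length = as.integer(polyc_length),
    coding_constraints = coding_constraints, mutation_mode = mutation_mode
  ), class = "sim_config")
}

#' Random non-pathological gene layout
#'
#' Lays the full 37-gene + control-region complement around a circle with
#' random feature lengths, random inter-feature gaps and a random rotation
#' (so one feature can wrap the origin). With `allow_overlap = TRUE`,
#' adjacent features may overlap by a few bases (never by enough for
#' containment). The genome length is emergent from the layout.
#'
#' @param seed Integer seed.
#' @param allow_overlap Permit small negative gaps between neighbors?
#' @return Gene-table tibble with attribute `genome_length`.
#' @export
random_gene_table <- function(seed = 1L, allow_overlap = FALSE) {
  set.seed(seed)
  vocab <- mito_feature_vocabulary()
  layout <- bind_rows(
    tibble(name = vocab$PCG, feature_class = "PCG",
           length = 3L * sample(80:500, 13, replace = TRUE)),
    tibble(name = vocab$tRNA, feature_class = "tRNA",
           length = sample(60:75, 22, replace = TRUE)),
    tibble(name = vocab$rRNA, feature_class = "rRNA",
           length = sample(900:1600, 2, replace = TRUE)),
    tibble(name = vocab$control, feature_class = "control",
           length = sample(800:1000, 1))
  )
  layout <- layout[sample.int(nrow(layout)), ]
  layout$strand <- sample(c("H", "L"), nrow(layout), replace = TRUE,
                        prob = c(0.75, 0.25))
  n <- nrow(layout)
  gaps <- sample(0:25, n, replace = TRUE)
  if (allow_overlap) {
    flip <- sample.int(n, size = ceiling(n / 5))
    for (i in flip) {
      nxt <- if (i == n) 1L else i + 1L
      max_ov <- min(layout$length[i], layout$length[nxt]) - 1L
      gaps[i] <- -sample.int(min(30L, max_ov), 1L)
    }
  }
  L <- sum(layout$length) + sum(gaps)
  offset <- sample.int(L, 1L)
  starts <- (cumsum(c(0L, head(layout$length + gaps, -1L))) + offset - 1L) %% L + 1L
  ends <- (starts + layout$length - 2L) %% L + 1L
  out <- tibble(name = layout$name, strand = layout$strand,
                start = as.integer(starts), end = as.integer(ends),
                feature_class = layout$feature_class,
                anticodon = NA_character_)
  out <- arrange(out, .data$start)
  attr(out, "genome_length") <- as.integer(L)
  attr(out, "gaps") <- gaps      # in layout order, for bookkeeping tests
  attr(out, "seed") <- as.integer(seed)
  out
}

# Replace characters at (possibly wrapping) feature positions on the coding
# strand; `chars` is the genome as a character vector.
write_coding <- function(chars, start, end, strand, cds_chars, L) {
  pos <- feature_positions(start, end, L)
  if (strand == "L") {
    comp <- chartr("ACGTN", "TGCAN", paste(rev(cds_chars), collapse = ""))
    chars[pos] <- strsplit(comp, "")[[1]]
  } else {
    chars[pos] <- cds_chars
  }
  chars
}

read_coding <- function(chars, start, end, strand, L) {
  pos <- feature_positions(start, end, L)
  s <- chars[pos]
  if (strand == "L") strsplit(chartr("ACGTN", "TGCAN",
                                     paste(rev(s), collapse = "")), "")[[1]]
  else s
}

# Iteratively repair PCGs until all have an initiator start, a complete or
# incomplete stop, and no internal stops. Overlapping PCGs can undo each
# other's repairs, hence the passes.
plant_coding <- function(chars, gene_table, L, code = "2", max_pass = 40L) {
  gc <- genetic_code(code)
  sense <- names(gc$table)[gc$table != "*"]
  pcg <- filter(gene_table, .data$feature_class == "PCG")
  for (pass in seq_len(max_pass)) {
    edited <- FALSE
    for (i in seq_len(nrow(pcg))) {
      cds <- read_coding(chars, pcg$start[i], pcg$end[i], pcg$strand[i], L)
      n <- length(cds)
      rem <- n %% 3L
      if (paste(cds[1:3], collapse = "") != "ATG") {
        cds[1:3] <- c("A", "T", "G"); edited <- TRUE
      }
      if (rem == 1L) {
        if (cds[n] != "T") { cds[n] <- "T"; edited <- TRUE }
      } else if (rem == 2L) {
        if (!identical(cds[c(n - 1L, n)], c("T", "A"))) {
          cds[c(n - 1L, n)] <- c("T", "A"); edited <- TRUE
        }
      } else {
        if (!(paste(cds[c(n - 2L, n - 1L, n)], collapse = "") %in%
              gc$stop_codons)) {
          cds[c(n - 2L, n - 1L, n)] <- c("T", "A", "A"); edited <- TRUE
        }
      }
      n_full <- (n - rem) %/% 3L
      last_internal <- if (rem == 0L) n_full - 1L else n_full
      for (ci in seq.int(2L, length.out = max(0L, last_internal - 1L))) {
        at <- (ci - 1L) * 3L + 1L
        codon <- paste(cds[at:(at + 2L)], collapse = "")
        if (codon %in% gc$stop_codons) {
          cds[at:(at + 2L)] <- strsplit(sample(sense, 1L), "")[[1]]
          edited <- TRUE
        }
      }
      chars <- write_coding(chars, pcg$start[i], pcg$end[i], pcg$strand[i],
                            cds, L)
    }
    if (!edited) return(chars)
  }
  warn("coding-constraint planting did not converge; some PCGs may fail validation")
  chars
}

# Plant motif copies and the poly-C terminus in the control region, then
# scrub accidental extra occurrences so planted counts are exact.
plant_motifs <- function(chars, cr_start, cr_end, cr_strand, L, motif_counts,
                         polyc_length) {
  region <- read_coding(chars, cr_start, cr_end, cr_strand, L)
  n <- length(region)
  if (polyc_length > 0L) {
    region[seq.int(n - polyc_length + 1L, n)] <- "C"
  }
  if (polyc_length < n) region[n - polyc_length] <- "A"  # delimit the run
  motifs <- names(motif_counts)
  total <- sum(motif_counts)
  wmax <- max(nchar(motifs))
  usable <- n - polyc_length - 1L
  slots <- seq.int(1L, usable - wmax + 1L, by = wmax + 2L)
  if (length(slots) < total) {
    abort("control region too short for the requested motif copies",
          class = "mito_error_config")
  }
  chosen <- sort(sample(slots, total))
  lab <- rep(motifs, motif_counts)[sample.int(total)]
  planted <- logical(n)
  for (k in seq_len(total)) {
    w <- nchar(lab[k])
    idx <- seq.int(chosen[k], length.out = w)
    region[idx] <- strsplit(lab[k], "")[[1]]
    planted[idx] <- TRUE
  }
  # scrub accidental occurrences that are not the planted ones
  for (iter in 1:50) {
    extra <- FALSE
    for (m in motifs) {
      hits <- scan_motifs(paste(region, collapse = ""), m)$positions[[1]]
      for (h in hits) {
        idx <- seq.int(h, length.out = nchar(m))
        if (all(planted[idx])) next
        mutate_at <- idx[which(!planted[idx])[1]]
        region[mutate_at] <- sample(setdiff(c("A", "C", "G", "T"),
                                            region[mutate_at]), 1L)
        extra <- TRUE
      }
    }
    if (!extra) break
  }
  write_coding(chars, cr_start, cr_end, cr_strand, region, L)
}

#' Generate a synthetic annotated mitogenome
#'
#' Draws a circular genome i.i.d. from the configured base composition over
#' either the published gaur gene order or a random layout, then (by
#' default) plants coding constraints in the PCGs, the configured
#' control-region motif copies (exactly — accidental extra occurrences are
#' scrubbed) and the terminal poly-C stretch.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (a [mito_genome()]) and `gene_table`.
#' @export
generate_genome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  if (cfg$gene_order == "bovid") {
    gt <- gaur_gene_table()
    if (cfg$genome_length != attr(gt, "genome_length")) {
      abort("the bovid template fixes genome_length = 16345",
            class = "mito_error_config")
    }
  } else {
    gt <- random_gene_table(seed = cfg$seed, allow_overlap = FALSE)
  }
  L <- attr(gt, "genome_length")
  chars <- sample(names(cfg$base_comp), L, replace = TRUE,
                  prob = cfg$base_comp)
  if (cfg$coding_constraints) {
    chars <- plant_coding(chars, gt, L)
  }
  cr <- filter(gt, .data$feature_class == "control")
  if (nrow(cr) == 1L && (sum(cfg$motif_counts) > 0L || cfg$polyc_length > 0L)) {
    chars <- plant_motifs(chars, cr$start[1], cr$end[1], cr$strand[1], L,
                          cfg$motif_counts, cfg$polyc_length)
  }
  genome <- mito_genome(paste(chars, collapse = ""),
                        id = sprintf("sim_seed%d", cfg$seed))
  list(genome = genome, gene_table = gt)
}

#' Generate grouped haplotypes from a base genome
#'
#' One ancestral sequence per group is derived from the base genome by
#' substituting the configured number of sites; each haplotype is then
#' derived from its group ancestor by substituting about half the
#' within-group pairwise target, so two group members differ by
#' approximately (in `"exact"` mode, within one of) the target. All
#' substituted sites are globally disjoint in `"exact"` mode, so realized
#' pairwise counts are exact sums of private-site counts with no
#' back-mutation; in `"poisson"` mode per-derivation counts are Poisson
#' draws. Realized pairwise difference counts (computed from the generator's
#' own site bookkeeping, not from the alignment) are attached as attribute
#' `realized`.
#'
#' @param genome Base [mito_genome()] (e.g. from [generate_genome()]).
#' @param cfg A [sim_config()].
#' @return Alignment tibble (`id`, `sequence`, `group`) with attributes
#'   `realized` (pairwise difference-count matrix) and `config`.
#' @export
generate_haplotypes <- function(genome, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- genome$length
  if (any(cfg$between_group_diffs > L) || any(cfg$within_group_diffs > L)) {
    abort("requested substitution counts exceed the genome length",
          class = "mito_error_config")
  }
  set.seed(cfg$seed + 1L)
  exact <- cfg$mutation_mode == "exact"
  draw <- function(mean) {
    if (exact) as.integer(round(mean)) else stats::rpois(1L, mean)
  }
  g_labels <- names(cfg$groups)
  anc_n <- vapply(cfg$between_group_diffs[g_labels], draw, integer(1))
  hap_n <- list()
  for (g in seq_along(g_labels)) {
    w <- cfg$within_group_diffs[g]
    ns <- cfg$groups[g]
    per <- if (exact) {
      # alternate ceiling/floor of w/2 so mixed pairs differ by exactly w
      as.integer(ifelse(seq_len(ns) %% 2L == 1L, ceiling(w / 2), floor(w / 2)))
    } else {
      stats::rpois(ns, w / 2)
    }
    hap_n[[g_labels[g]]] <- per
  }
  total_sites <- sum(anc_n) + sum(unlist(hap_n))
  if (total_sites > L) {
    abort("requested substitutions exceed available sites",
          class = "mito_error_config")
  }
  pool <- if (exact) sample.int(L, total_sites) else NULL
  take <- local({
    used <- 0L
    function(k) {
      if (exact) {
        out <- pool[seq.int(used + 1L, length.out = k)]
        used <<- used + k
        out
      } else {
        sample.int(L, k)
      }
    }
  })
  base_chars <- strsplit(genome$sequence, "")[[1]]
  mutate_sites <- function(chars, sites) {
    for (s in sites) {
      chars[s] <- sample(setdiff(c("A", "C", "G", "T"), chars[s]), 1L)
    }
    chars
  }
  ids <- character(0); seqs <- character(0); grp <- character(0)
  site_maps <- list()   # per haplotype: named base at every touched site
  for (g in g_labels) {
    anc_sites <- take(anc_n[[g]])
    anc_chars <- mutate_sites(base_chars, anc_sites)
    for (h in seq_len(cfg$groups[[g]])) {
      hs <- take(hap_n[[g]][h])
      hap_chars <- mutate_sites(anc_chars, hs)
      id <- sprintf("%s_%d", g, h)
      ids <- c(ids, id); grp <- c(grp, g)
      seqs <- c(seqs, paste(hap_chars, collapse = ""))
      touched <- c(anc_sites, hs)
      site_maps[[id]] <- setNames(hap_chars[touched], touched)
    }
  }
  # realized pairwise counts from site bookkeeping alone
  n <- length(ids)
  realized <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      si <- site_maps[[i]]; sj <- site_maps[[j]]
      sites <- union(names(si), names(sj))
      bi <- ifelse(sites %in% names(si), si[sites],
                   base_chars[as.integer(sites)])
      bj <- ifelse(sites %in% names(sj), sj[sites],
                   base_chars[as.integer(sites)])
      realized[i, j] <- realized[j, i] <- sum(bi != bj)
    }
  }
  out <- alignment(ids, seqs, groups = grp)
  attr(out, "realized") <- realized
  attr(out, "config") <- cfg
  out
}
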