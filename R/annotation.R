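# Stage 1: the structural ledger of an annotated circular mitogenome —
# per-gene lengths, the intergenic-spacer/overlap ledger between consecutive
# genes, and the genome-wide structural summary.

#' Intergenic-spacer / overlap ledger of a circular gene table
#'
#' For each feature the gap to the *following* feature is reported:
#' positive values are intergenic spacers (bp), negative values overlaps
#' (bp), zero means the two genes abut. The final entry wraps from the last
#' feature back to the first through the circular origin, so the ledger has
#' exactly one entry per feature.
#'
#' @param gene_table Gene table (sorted by start; unsorted input is sorted
#'   with a warning). Features fully contained in their predecessor are
#'   skipped with a warning.
#' @param genome_length Genome length; default taken from the table.
#'
#' @return Tibble with columns `upstream`, `downstream`, `gap_bp`, `type`
#'   (`spacer`/`overlap`/`abutting`).
#' @examples
#' adjacency_ledger(gaur_gene_table())
#' @export
adjacency_ledger <- function(gene_table, genome_length = NULL) {
  genome_length <- genome_length %||% attr(gene_table, "genome_length") %||%
    max(gene_table$end)
  gt <- as_tibble(gene_table)
  if (is.unsorted(gt$start)) {
    warn("gene table not sorted by start; sorting")
    gt <- arrange(gt, .data$start)
  }
  # work in unrolled coordinates: a wrapping feature ends at end + L, which
  # makes the gap arithmetic uniform for features and overlaps that straddle
  # the origin
  uend <- gt$start + feature_length(gt$start, gt$end, genome_length) - 1L
  if (nrow(gt) > 1L) {
    keep <- rep(TRUE, nrow(gt))
    running <- uend[1]
    for (i in seq.int(2L, nrow(gt))) {
      if (uend[i] <= running) {
        keep[i] <- FALSE
        warn(paste0("feature '", gt$name[i],
                    "' is fully contained in its predecessor; skipped"))
      } else {
        running <- uend[i]
      }
    }
    gt <- gt[keep, ]
    uend <- uend[keep]
  }
  n <- nrow(gt)
  nxt <- c(seq_len(n)[-1], 1L)
  gap <- gt$start[nxt] - uend - 1L
  # circular closure: the last feature pairs with the first through the origin
  gap[n] <- gt$start[1] + genome_length - uend[n] - 1L
  if (any(abs(gap) > genome_length)) {
    abort("gap larger than the genome; corrupt coordinates",
          class = "mito_error_coordinate")
  }
  tibble(
    upstream = gt$name,
    downstream = gt$name[nxt],
    gap_bp = as.integer(gap),
    type = dplyr::case_when(gap > 0 ~ "spacer", gap < 0 ~ "overlap",
                            TRUE ~ "abutting")
  )
}

#' Structural summary of an annotated mitogenome
#'
#' Computes, from coordinates alone, the genome-wide structural statistics:
#' feature counts by class, strand tallies over the 37 genes (the control
#' region carries no strand assignment), per-class union lengths, the
#' protein-coding fraction of the genome, total/maximum intergenic spacer and
#' overlap with their counts (zero gaps, i.e. abutting genes, are not counted
#' as spacer regions or overlap locations), and the tRNA size range.
#'
#' @param gene_table Gene table.
#' @param genome_length Genome length; default from the table.
#' @param pcg_fraction One of `"union"` (overlapping positions counted once;
#'   default) or `"sum"` (sum of gene sizes).
#'
#' @return Object of class `mito_structure` (a list); see [glance.mito_structure()]
#'   for a one-row tibble version.
#' @examples
#' structural_summary(gaur_gene_table())
#' @export
structural_summary <- function(gene_table, genome_length = NULL,
                               pcg_fraction = c("union", "sum")) {
  pcg_fraction <- match.arg(pcg_fraction)
  genome_length <- genome_length %||% attr(gene_table, "genome_length") %||%
    max(gene_table$end)
  gt <- arrange(as_tibble(gene_table), .data$start)
  gt$length <- feature_length(gt$start, gt$end, genome_length)

  genes <- filter(gt, .data$feature_class != "control")
  class_counts <- table(factor(gt$feature_class,
                               levels = c("PCG", "tRNA", "rRNA", "control")))
  class_union <- vapply(c("PCG", "tRNA", "rRNA", "control"), function(cl) {
    union_length(filter(gt, .data$feature_class == cl), genome_length)
  }, integer(1))
  pcg <- filter(gt, .data$feature_class == "PCG")
  pcg_bp <- if (pcg_fraction == "union") class_union[["PCG"]] else sum(pcg$length)
  ledger <- suppressWarnings(adjacency_ledger(gt, genome_length))
  sp <- filter(ledger, .data$type == "spacer")
  ov <- filter(ledger, .data$type == "overlap")
  trna <- filter(gt, .data$feature_class == "tRNA")

  pair_of <- function(df, i) paste0(df$upstream[i], "-", df$downstream[i])
  structure(list(
    genome_length = genome_length,
    n_features = nrow(gt),
    n_pcg = unname(class_counts[["PCG"]]),
    n_trna = unname(class_counts[["tRNA"]]),
    n_rrna = unname(class_counts[["rRNA"]]),
    n_control = unname(class_counts[["control"]]),
    strand_h = sum(genes$strand == "H"),
    strand_l = sum(genes$strand == "L"),
    pcg_union_bp = unname(class_union[["PCG"]]),
    pcg_sum_bp = sum(pcg$length),
    trna_bp = unname(class_union[["tRNA"]]),
    rrna_bp = unname(class_union[["rRNA"]]),
    control_bp = unname(class_union[["control"]]),
    pcg_pct = round(100 * pcg_bp / genome_length, 2),
    igs_total_bp = sum(sp$gap_bp),
    igs_n = nrow(sp),
    igs_max_bp = if (nrow(sp)) max(sp$gap_bp) else 0L,
    igs_max_pair = if (nrow(sp)) pair_of(sp, which.max(sp$gap_bp)) else NA_character_,
    overlap_total_bp = sum(abs(ov$gap_bp)),
    overlap_n = nrow(ov),
    overlap_max_bp = if (nrow(ov)) max(abs(ov$gap_bp)) else 0L,
    overlap_max_pair = if (nrow(ov)) pair_of(ov, which.max(abs(ov$gap_bp))) else NA_character_,
    trna_min_bp = if (nrow(trna)) min(trna$length) else NA_integer_,
    trna_min_gene = if (nrow(trna)) trna$name[which.min(trna$length)] else NA_character_,
    trna_max_bp = if (nrow(trna)) max(trna$length) else NA_integer_,
    trna_max_gene = if (nrow(trna)) trna$name[which.max(trna$length)] else NA_character_,
    ledger = ledger
  ), class = "mito_structure")
}

#' @export
print.mito_structure <- function(x, ...) {
  cat(sprintf("<mito_structure> %s bp circular genome\n",
              format(x$genome_length, big.mark = ",")))
  cat(sprintf("  features: %d PCG, %d tRNA, %d rRNA, %d control (%d H / %d L)\n",
              x$n_pcg, x$n_trna, x$n_rrna, x$n_control, x$strand_h, x$strand_l))
  cat(sprintf("  PCG union %s bp (%.2f%% of genome); rRNA %s bp; tRNA %d-%d bp (%s-%s)\n",
              format(x$pcg_union_bp, big.mark = ","), x$pcg_pct,
              format(x$rrna_bp, big.mark = ","), x$trna_min_bp, x$trna_max_bp,
              x$trna_min_gene, x$trna_max_gene))
  cat(sprintf("  IGS: %d bp over %d regions (max %d bp, %s)\n",
              x$igs_total_bp, x$igs_n, x$igs_max_bp, x$igs_max_pair))
  cat(sprintf("  overlaps: %d bp at %d locations (max %d bp, %s)\n",
              x$overlap_total_bp, x$overlap_n, x$overlap_max_bp,
              x$overlap_max_pair))
  invisible(x)
}

#' One-row summary of a structural summary
#'
#' @param x A `mito_structure` object.
#' @param ... Unused.
#' @return One-row tibble of all scalar summary fields.
#' @method glance mito_structure
#' @export
glance.mito_structure <- function(x, ...) {
  as_tibble(x[setdiff(names(x), "ledger")])
}

#' Validate protein-coding genes against a genetic code
#'
#' For each annotated PCG, reports the start codon (and whether it is an
#' initiator under the chosen code), the terminal codon state — `complete`
#' stop, `incomplete_T`/`incomplete_TA` (completed to UAA by
#' polyadenylation), or `none` — and the number of internal stop codons in
#' frame. Problems are reported, not raised: annotation validation is a
#' screen, not a gate.
#'
#' @param genome A [mito_genome()].
#' @param gene_table Gene table with the PCGs to check.
#' @param code Genetic code id (default `"2"`, vertebrate mitochondrial).
#'
#' @return Tibble with one row per PCG: `name`, `length`, `start_codon`,
#'   `start_ok`, `terminal_state`, `internal_stops`, `ok`.
#' @export
validate_pcg <- function(genome, gene_table, code = "2") {
  gc <- genetic_code(code)
  pcg <- filter(as_tibble(gene_table), .data$feature_class == "PCG")
  purrr::map_dfr(seq_len(nrow(pcg)), function(i) {
    cds <- slice_sequence(genome, pcg$start[i], pcg$end[i], pcg$strand[i])
    n <- nchar(cds)
    if (n < 6L) {
      abort(paste0("PCG '", pcg$name[i], "' shorter than 6 nt"),
            class = "mito_error_validation")
    }
    rem <- n %% 3L
    start_codon <- substr(cds, 1L, 3L)
    terminal_state <- if (rem == 0L) {
      if (substr(cds, n - 2L, n) %in% gc$stop_codons) "complete" else "none"
    } else if (rem == 1L) {
      if (substr(cds, n, n) == "T") "incomplete_T" else "none"
    } else {
      if (substr(cds, n - 1L, n) == "TA") "incomplete_TA" else "none"
    }
    n_full <- (n - rem) %/% 3L
    last_internal <- if (rem == 0L && terminal_state == "complete") {
      n_full - 1L
    } else {
      n_full
    }
    internal <- if (last_internal >= 2L) {
      codons <- substring(cds, seq.int(4L, by = 3L, length.out = last_internal - 1L),
                          seq.int(6L, by = 3L, length.out = last_internal - 1L))
      sum(codons %in% gc$stop_codons)
    } else 0L
    tibble(
      name = pcg$name[i], length = n, start_codon = start_codon,
      start_ok = start_codon %in% gc$start_codons,
      terminal_state = terminal_state,
      internal_stops = as.integer(internal),
      ok = start_codon %in% gc$start_codons && terminal_state != "none" &&
        internal == 0L
    )
  })
}
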