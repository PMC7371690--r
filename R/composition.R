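# Stage 2: nucleotide composition, AT/GC content, and strand skews.
# AT skew = (A - T)/(A + T); GC skew = (G - C)/(G + C). Positive AT skew
# means an excess of adenine over thymine on the reported strand.

#' Nucleotide composition and skews of a sequence
#'
#' Counts A/C/G/T, computes per-base percentages, AT/GC content and AT/GC
#' skews. Gaps and N/ambiguity codes are excluded from the effective length.
#'
#' @param sequence Nucleotide string (case-insensitive; may contain `N`/`-`).
#' @param label Label for the profile row.
#'
#' @return One-row tibble: `label`, counts `a`,`c`,`g`,`t`, `n_effective`,
#'   `n_other`, percentages `pct_a..pct_t`, `at_content`, `gc_content`,
#'   `at_skew`, `gc_skew`, and `at_zero`/`gc_zero` flags marking
#'   zero-denominator skews (reported as 0).
#' @examples
#' composition("ATGC")
#' @export
composition <- function(sequence, label = "sequence") {
  sequence <- toupper(sequence)
  n_all <- nchar(sequence)
  if (n_all == 0L) {
    abort("empty sequence", class = "mito_error_sequence")
  }
  cnt <- vapply(c("A", "C", "G", "T"), function(b) {
    nchar(sequence) - nchar(gsub(b, "", sequence, fixed = TRUE))
  }, numeric(1))
  n_eff <- sum(cnt)
  if (n_eff == 0) {
    abort("sequence has no unambiguous A/C/G/T bases",
          class = "mito_error_sequence")
  }
  sk <- skews(cnt[["A"]], cnt[["T"]], cnt[["G"]], cnt[["C"]])
  tibble(
    label = label,
    a = cnt[["A"]], c = cnt[["C"]], g = cnt[["G"]], t = cnt[["T"]],
    n_effective = n_eff, n_other = n_all - n_eff,
    pct_a = 100 * cnt[["A"]] / n_eff, pct_c = 100 * cnt[["C"]] / n_eff,
    pct_g = 100 * cnt[["G"]] / n_eff, pct_t = 100 * cnt[["T"]] / n_eff,
    at_content = 100 * (cnt[["A"]] + cnt[["T"]]) / n_eff,
    gc_content = 100 * (cnt[["G"]] + cnt[["C"]]) / n_eff,
    at_skew = sk$at_skew, gc_skew = sk$gc_skew,
    at_zero = sk$at_zero, gc_zero = sk$gc_zero
  )
}

#' AT and GC skew
#'
#' `at_skew = (A - T)/(A + T)` and `gc_skew = (G - C)/(G + C)`. The inputs
#' may be raw counts or percentages — the skews are scale-invariant. A
#' zero denominator yields a skew of 0 with the corresponding flag set.
#'
#' @param a,t,g,c Base counts or percentages.
#' @return List with `at_skew`, `gc_skew`, `at_zero`, `gc_zero`.
#' @examples
#' skews(33.5, 27.2, 13.4, 25.9)
#' @export
skews <- function(a, t, g, c) {
  at_zero <- (a + t) == 0
  gc_zero <- (g + c) == 0
  list(
    at_skew = ifelse(at_zero, 0, (a - t) / (a + t)),
    gc_skew = ifelse(gc_zero, 0, (g - c) / (g + c)),
    at_zero = at_zero, gc_zero = gc_zero
  )
}

#' Composition profiles per feature class (and per gene)
#'
#' One composition row for the whole genome and one per feature class (PCG,
#' rRNA, tRNA, control region), optionally one per gene. L-strand features
#' are profiled on their coding (reverse-complemented) sequence, so a gene
#' like nad6 shows the sign-flipped skews expected of L-strand genes. The
#' PCG class profile concatenates coding sequences, counting overlap
#' positions once per gene occurrence (set `pcg_union = TRUE` for the
#' genomic-union alternative).
#'
#' @param genome A [mito_genome()].
#' @param gene_table Gene table.
#' @param per_gene Also emit one profile per feature?
#' @param pcg_union Profile the PCG class on the genomic union of PCG
#'   positions (H-strand) instead of concatenated coding sequences.
#'
#' @return Tibble of composition rows (see [composition()]) with a `scope`
#'   column (`genome`/`class`/`gene`).
#' @export
class_profiles <- function(genome, gene_table, per_gene = FALSE,
                           pcg_union = FALSE) {
  gt <- arrange(as_tibble(gene_table), .data$start)
  rows <- list(mutate(composition(genome$sequence, "genome"), scope = "genome"))
  class_seq <- function(cl) {
    feats <- filter(gt, .data$feature_class == cl)
    if (nrow(feats) == 0L) return(NULL)
    if (cl == "PCG" && pcg_union) {
      L <- genome$length
      covered <- logical(L)
      for (i in seq_len(nrow(feats))) {
        covered[feature_positions(feats$start[i], feats$end[i], L)] <- TRUE
      }
      return(paste(strsplit(genome$sequence, "")[[1]][covered], collapse = ""))
    }
    paste(purrr::map_chr(seq_len(nrow(feats)), function(i) {
      slice_sequence(genome, feats$start[i], feats$end[i], feats$strand[i])
    }), collapse = "")
  }
  for (cl in c("PCG", "rRNA", "tRNA", "control")) {
    s <- class_seq(cl)
    if (!is.null(s)) {
      rows[[length(rows) + 1L]] <- mutate(composition(s, cl), scope = "class")
    }
  }
  if (per_gene) {
    for (i in seq_len(nrow(gt))) {
      s <- slice_sequence(genome, gt$start[i], gt$end[i], gt$strand[i])
      rows[[length(rows) + 1L]] <-
        mutate(composition(s, gt$name[i]), scope = "gene")
    }
  }
  bind_rows(rows)
}

#' Bar chart of AT/GC content and skews across profiles
#'
#' @param profiles Output of [class_profiles()] (or rows of [composition()]).
#' @return A ggplot object: content percentages and skews, faceted.
#' @export
plot_composition <- function(profiles) {
  long <- tidyr::pivot_longer(
    profiles,
    cols = c("at_content", "gc_content", "at_skew", "gc_skew"),
    names_to = "metric", values_to = "value"
  )
  long$panel <- ifelse(long$metric %in% c("at_content", "gc_content"),
                       "content (%)", "skew")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
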