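# Stage 4: control-region motif detection. The bovid control region carries
# dispersed TACAT/ATGTA palindromic motifs (putative hairpin formers) and
# typically terminates in a poly-C stretch.

#' Scan a region for motif occurrences
#'
#' Finds all occurrences of each motif, *including overlapping ones*;
#' matching is case-insensitive and exact (no ambiguity codes).
#'
#' @param region Nucleotide string to scan.
#' @param motifs Character vector of motifs over `{A,C,G,T}` (default the
#'   control-region palindrome pair TACAT/ATGTA).
#'
#' @return Tibble with one row per motif: `motif`, `count`, `positions`
#'   (list column of 1-based offsets within the region).
#' @examples
#' scan_motifs("TACATACAT")  # TACAT at 1 and 5 (overlapping)
#' @export
scan_motifs <- function(region, motifs = c("TACAT", "ATGTA")) {
  region <- toupper(region)
  if (nchar(region) == 0L) {
    abort("empty region", class = "mito_error_sequence")
  }
  motifs <- toupper(motifs)
  if (any(grepl("[^ACGT]", motifs))) {
    abort("motifs must be over {A,C,G,T}", class = "mito_error_format")
  }
  purrr::map_dfr(motifs, function(m) {
    # lookahead makes gregexpr report overlapping occurrences
    hits <- gregexpr(paste0("(?=", m, ")"), region, perl = TRUE)[[1]]
    pos <- if (hits[1] == -1L) integer(0) else as.integer(hits)
    tibble(motif = m, count = length(pos), positions = list(pos))
  })
}

#' Length of the terminal poly-C stretch
#'
#' The maximal suffix of the region consisting solely of C; 0 when the
#' region does not end in C.
#'
#' @param region Nucleotide string.
#' @return Non-negative integer.
#' @examples
#' terminal_polyc("ATCCCCC")  # 5
#' @export
terminal_polyc <- function(region) {
  region <- toupper(region)
  if (nchar(region) == 0L) {
    abort("empty region", class = "mito_error_sequence")
  }
  m <- regmatches(region, regexpr("C*$", region))[[1]]
  nchar(m)
}

#' Motif report for the control region of an annotated genome
#'
#' Convenience wrapper: slices the `control_region` feature and runs
#' [scan_motifs()] and [terminal_polyc()] on it.
#'
#' @param genome A [mito_genome()].
#' @param gene_table Gene table containing a `control_region` feature.
#' @inheritParams scan_motifs
#' @return List with `motifs` (tibble) and `terminal_polyc` (integer).
#' @export
control_region_report <- function(genome, gene_table,
                                  motifs = c("TACAT", "ATGTA")) {
  cr <- filter(as_tibble(gene_table), .data$feature_class == "control")
  if (nrow(cr) != 1L) {
    abort("gene table must contain exactly one control region",
          class = "mito_error_format")
  }
  region <- slice_sequence(genome, cr$start[1], cr$end[1], cr$strand[1])
  list(motifs = scan_motifs(region, motifs),
       terminal_polyc = terminal_polyc(region))
}
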