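# Core types: circular mitogenome, gene features, and circular-coordinate
# arithmetic. Coordinates are 1-based and fully inclusive on the H strand;
# a feature with start > end wraps through the circular origin.

#' Controlled vocabulary of mitochondrial feature names
#'
#' The 13 protein-coding genes, 22 tRNAs, 2 rRNAs and the control region of a
#' vertebrate mitogenome, in the naming convention used throughout the
#' package (`nad1..nad6`, `nad4l`, `cox1..cox3`, `atp6`, `atp8`, `cob`,
#' `rrnS`, `rrnL`, `trnX`, `control_region`).
#'
#' @return Named list with character vectors `PCG`, `tRNA`, `rRNA`, `control`.
#' @export
mito_feature_vocabulary <- function() {
  list(
    PCG = c("nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6",
            "cox1", "cox2", "cox3", "atp6", "atp8", "cob"),
    tRNA = paste0("trn", c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                           "L1", "L2", "M", "N", "P", "Q", "R", "S1", "S2",
                           "T", "V", "W", "Y")),
    rRNA = c("rrnS", "rrnL"),
    control = "control_region"
  )
}

#' Create a circular mitochondrial genome object
#'
#' @param sequence Nucleotide string over `{A,C,G,T,N}` (case-insensitive).
#' @param id Sequence identifier.
#' @param circular Is the molecule circular? Default `TRUE`.
#'
#' @return An object of class `mito_genome`: a list with fields `id`,
#'   `sequence` (uppercased), `length` and `circular`.
#' @examples
#' g <- mito_genome("ATGCAT", id = "toy")
#' g$length
#' @export
mito_genome <- function(sequence, id = "genome", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) {
    abort("genome sequence must be non-empty", class = "mito_error_sequence")
  }
  if (grepl("[^ACGTN]", sequence)) {
    abort("genome sequence may only contain A, C, G, T, N",
          class = "mito_error_sequence")
  }
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence),
         circular = isTRUE(circular)),
    class = "mito_genome"
  )
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %s bp, %s\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Validate a gene table
#'
#' A gene table is a tibble with columns `name`, `strand` (`H`/`L`), `start`,
#' `end` (1-based, inclusive; `start > end` marks a feature wrapping the
#' circular origin), `feature_class` (`PCG`, `tRNA`, `rRNA`, `control`) and
#' optional `anticodon`. Checks coordinate sanity against the genome length
#' and, optionally, completeness of the canonical 37-gene + control-region
#' complement.
#'
#' @param gene_table Gene-table tibble.
#' @param genome_length Genome length in bp; defaults to `max(end)`.
#' @param strict If `TRUE`, completeness/vocabulary problems are errors
#'   rather than warnings.
#'
#' @return The validated gene table (sorted by `start`), invisibly usable in
#'   pipes, with attribute `genome_length`.
#' @export
validate_gene_table <- function(gene_table, genome_length = NULL,
                                strict = FALSE) {
  required <- c("name", "strand", "start", "end", "feature_class")
  missing_cols <- setdiff(required, names(gene_table))
  if (length(missing_cols) > 0L) {
    abort(paste0("gene table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mito_error_format")
  }
  gene_table <- as_tibble(gene_table)
  if (!"anticodon" %in% names(gene_table)) gene_table$anticodon <- NA_character_
  # max(end) except when a feature wraps the origin (start > end), whose
  # start then bounds the genome from below
  genome_length <- genome_length %||% max(gene_table$start, gene_table$end)
  bad <- gene_table$start < 1L | gene_table$end < 1L |
    gene_table$start > genome_length | gene_table$end > genome_length
  if (any(bad)) {
    abort(sprintf("feature coordinates outside [1, %d]: %s", genome_length,
                  paste(gene_table$name[bad], collapse = ", ")),
          class = "mito_error_coordinate")
  }
  if (!all(gene_table$strand %in% c("H", "L"))) {
    abort("strand must be 'H' or 'L'", class = "mito_error_format")
  }
  if (!all(gene_table$feature_class %in% c("PCG", "tRNA", "rRNA", "control"))) {
    abort("feature_class must be PCG, tRNA, rRNA or control",
          class = "mito_error_format")
  }
  vocab <- unlist(mito_feature_vocabulary(), use.names = FALSE)
  unknown <- setdiff(gene_table$name, vocab)
  if (length(unknown) > 0L) {
    msg <- paste0("feature name(s) outside vocabulary: ",
                  paste(unknown, collapse = ", "))
    if (strict) abort(msg, class = "mito_error_format") else warn(msg)
  }
  counts <- table(gene_table$feature_class)
  complete <- identical(as.integer(counts[c("PCG", "tRNA", "rRNA", "control")]),
                        c(13L, 22L, 2L, 1L))
  if (!complete) {
    msg <- "gene table is not a complete 13 PCG + 22 tRNA + 2 rRNA + control complement"
    if (strict) abort(msg, class = "mito_error_format") else warn(msg)
  }
  if (is.unsorted(gene_table$start)) {
    warn("gene table not sorted by start; sorting")
    gene_table <- arrange(gene_table, .data$start)
  }
  attr(gene_table, "genome_length") <- genome_length
  gene_table
}

#' The Indian gaur mitogenome gene table
#'
#' The packaged annotation of the 16,345 bp Indian gaur mitochondrial genome:
#' 13 protein-coding genes, 22 tRNAs, 2 rRNAs and the control region with
#' 1-based inclusive H-strand coordinates and tRNA anticodons. One tRNA-Phe
#' anticodon variant (AAA instead of GAA in one of the four sequenced
#' animals) exists; the table stores the majority anticodon GAA.
#'
#' @return Gene-table tibble (38 rows) with attribute `genome_length = 16345`.
#' @examples
#' gt <- gaur_gene_table()
#' nrow(gt)
#' @export
gaur_gene_table <- function() {
  path <- system.file("extdata", "gaur_gene_table.tsv",
                      package = "mitocompare", mustWork = TRUE)
  read_gene_table(path)
}

#' Length of a feature on a circular genome
#'
#' @param start,end 1-based inclusive coordinates; `start > end` wraps the
#'   origin.
#' @param genome_length Genome length L in bp.
#'
#' @return Integer vector of feature lengths: `end - start + 1` for plain
#'   features, `(L - start + 1) + end` for wrapping ones.
#' @examples
#' feature_length(7765, 7965, 16345)  # atp8: 201 bp
#' feature_length(16340, 5, 16345)    # wraps the origin: 11 bp
#' @export
feature_length <- function(start, end, genome_length) {
  start <- as.integer(start); end <- as.integer(end)
  genome_length <- as.integer(genome_length)
  if (any(start < 1L | end < 1L | start > genome_length | end > genome_length)) {
    abort("feature coordinates outside [1, genome_length]",
          class = "mito_error_coordinate")
  }
  ifelse(start <= end, end - start + 1L,
         (genome_length - start + 1L) + end)
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of sequences over `{A,C,G,T,N,-}`.
#' @return Reverse-complemented sequences (N and `-` map to themselves).
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Extract the coding-strand sequence of a feature
#'
#' Returns the H-strand substring for H-strand features and its reverse
#' complement for L-strand features; features wrapping the circular origin
#' concatenate the sequence tail and head.
#'
#' @param genome A [mito_genome()].
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"H"` or `"L"`.
#'
#' @return Nucleotide string.
#' @examples
#' g <- mito_genome("ATGCAT")
#' slice_sequence(g, 1, 3, "L")  # reverse complement of "ATG"
#' @export
slice_sequence <- function(genome, start, end, strand = "H") {
  stopifnot(inherits(genome, "mito_genome"))
  L <- genome$length
  if (start < 1L || end < 1L || start > L || end > L) {
    abort("slice coordinates outside [1, genome length]",
          class = "mito_error_coordinate")
  }
  if (start <= end) {
    s <- substr(genome$sequence, start, end)
  } else {
    if (!genome$circular) {
      abort("wrapping slice on a linear genome", class = "mito_error_coordinate")
    }
    s <- paste0(substr(genome$sequence, start, L),
                substr(genome$sequence, 1L, end))
  }
  if (strand == "L") reverse_complement(s) else s
}

# Positions covered by a (possibly wrapping) feature, as integer vector.
feature_positions <- function(start, end, genome_length) {
  if (start <= end) seq.int(start, end)
  else c(seq.int(start, genome_length), seq.int(1L, end))
}

#' Number of distinct genome positions covered by a set of features
#'
#' Overlapping positions are counted once; circularly aware.
#'
#' @param gene_table Gene table (or any tibble with `start`, `end`).
#' @param genome_length Genome length; defaults to the table's
#'   `genome_length` attribute, else `max(end)`.
#'
#' @return Non-negative integer; 0 for an empty table.
#' @examples
#' union_length(tibble::tibble(start = c(1, 5), end = c(10, 14)), 20)  # 14
#' @export
union_length <- function(gene_table, genome_length = NULL) {
  if (nrow(gene_table) == 0L) return(0L)
  genome_length <- genome_length %||% attr(gene_table, "genome_length") %||%
    max(gene_table$end)
  covered <- logical(genome_length)
  for (i in seq_len(nrow(gene_table))) {
    covered[feature_positions(gene_table$start[i], gene_table$end[i],
                              genome_length)] <- TRUE
  }
  sum(covered)
}
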