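# Readers/writers for the plain-text formats the pipeline touches:
# FASTA, gene-table TSV, a deliberately small subset of the GenBank flat
# file, and Newick (via ape).

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `sequence` (uppercased, concatenated across lines).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "mito_error_input")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !startsWith(lines[[1]], ">")) {
    abort("malformed FASTA: must start with a '>' header",
          class = "mito_error_format")
  }
  hdr <- startsWith(lines, ">")
  rec <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  # records with a header but no sequence lines are format errors
  if (length(seqs) != length(ids) || any(!nzchar(seqs))) {
    abort("malformed FASTA: record with empty sequence",
          class = "mito_error_format")
  }
  tibble(id = ids, sequence = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' Sequences are wrapped at 70 columns; `write_fasta()` then [read_fasta()]
#' round-trips ids and sequences byte-for-byte.
#'
#' @param records Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  if (nrow(records) == 0L) {
    abort("refusing to write an empty FASTA", class = "mito_error_format")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read / write a gene-table TSV
#'
#' The TSV contract: tab-separated, header row required, columns `name`,
#' `strand`, `start`, `end`, `feature_class`, `anticodon` (empty allowed).
#'
#' @param path File path.
#' @param genome_length Genome length; default `max(end)`.
#' @param strict Passed to [validate_gene_table()].
#' @return For `read_gene_table()`, a validated gene-table tibble.
#' @export
read_gene_table <- function(path, genome_length = NULL, strict = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "mito_error_input")
  }
  gt <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      name = readr::col_character(),
                      strand = readr::col_character(),
                      start = readr::col_integer(),
                      end = readr::col_integer(),
                      feature_class = readr::col_character(),
                      anticodon = readr::col_character()
                    )),
    error = function(e) abort(paste0("cannot parse gene table: ",
                                     conditionMessage(e)),
                              class = "mito_error_format")
  )
  if (nrow(gt) == 0L) {
    abort("empty gene table", class = "mito_error_format")
  }
  suppressWarnings(validate_gene_table(gt, genome_length, strict = strict))
}

#' @rdname read_gene_table
#' @param gene_table Gene table to serialize.
#' @export
write_gene_table <- function(gene_table, path) {
  cols <- c("name", "strand", "start", "end", "feature_class", "anticodon")
  gt <- as_tibble(gene_table)
  if (!"anticodon" %in% names(gt)) gt$anticodon <- NA_character_
  readr::write_tsv(gt[cols], path, progress = FALSE)
  invisible(path)
}

#' Read a minimal GenBank flat file
#'
#' Parses only what the pipeline needs from a GenBank record: the LOCUS
#' length, the `gene`/`CDS`/`tRNA`/`rRNA`/`D-loop`/`misc_feature` entries of
#' the FEATURES block with their `/gene` or `/product` qualifier, and the
#' ORIGIN sequence. `complement(a..b)` maps to strand L; a two-segment
#' `join(a..L,1..b)` maps to a feature wrapping the circular origin;
#' D-loop/misc_feature features are named `control_region`.
#'
#' @param path Path to a GenBank flat file.
#' @return List with elements `genome` (a [mito_genome()]) and `gene_table`.
#' @export
read_genbank_lite <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "mito_error_input")
  }
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) != 1L) {
    abort("GenBank-lite: missing LOCUS line", class = "mito_error_format")
  }
  locus_id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]
  declared_len <- as.integer(sub(".*?(\\d+)\\s+bp.*", "\\1", locus))
  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) != 1L) {
    abort("GenBank-lite: missing ORIGIN block", class = "mito_error_format")
  }
  seq_lines <- lines[(origin_at + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[0-9[:space:]]", "", paste(seq_lines, collapse = "")))
  if (!is.na(declared_len) && nchar(sequence) != declared_len) {
    abort(sprintf("GenBank-lite: LOCUS declares %d bp but ORIGIN holds %d",
                  declared_len, nchar(sequence)), class = "mito_error_format")
  }
  feat_at <- grep("^FEATURES", lines)
  if (length(feat_at) != 1L) {
    abort("GenBank-lite: missing FEATURES block", class = "mito_error_format")
  }
  block <- lines[(feat_at + 1L):(origin_at - 1L)]
  key_rx <- "^\\s{1,10}(\\S+)\\s+(.*)$"
  is_key <- grepl(key_rx, block) & !grepl("^\\s{12,}", block)
  keys <- sub(key_rx, "\\1", block[is_key])
  locs <- sub(key_rx, "\\2", block[is_key])
  idx <- which(is_key)
  keep <- keys %in% c("gene", "CDS", "tRNA", "rRNA", "D-loop", "misc_feature")
  out <- list()
  for (k in which(keep)) {
    key <- keys[k]; loc <- locs[k]
    qual_end <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
    quals <- block[seq.int(idx[k] + 1L, length.out = max(0L, qual_end - idx[k]))]
    strand <- if (grepl("complement", loc)) "L" else "H"
    loc <- gsub("complement\\(|join\\(|\\)|<|>", "", loc)
    parts <- strsplit(loc, ",")[[1]]
    coords <- do.call(rbind, lapply(parts, function(p) {
      as.integer(strsplit(p, "\\.\\.")[[1]])
    }))
    if (nrow(coords) == 1L) {
      start <- coords[1, 1]; end <- coords[1, 2]
    } else if (nrow(coords) == 2L && coords[2, 1] == 1L) {
      start <- coords[1, 1]; end <- coords[2, 2]   # two-segment origin wrap
    } else {
      warn(paste0("GenBank-lite: skipping unsupported join location: ", loc))
      next
    }
    gene_q <- grep('/(gene|product)="', quals, value = TRUE)
    name <- if (length(gene_q) > 0L) {
      sub('.*?/(?:gene|product)="([^"]*)".*', "\\1", gene_q[[1]])
    } else NA_character_
    fclass <- switch(key, CDS = "PCG", gene = "PCG", tRNA = "tRNA",
                     rRNA = "rRNA", "control")
    if (key %in% c("D-loop", "misc_feature")) name <- "control_region"
    out[[length(out) + 1L]] <- tibble(
      name = name, strand = strand, start = start, end = end,
      feature_class = fclass, anticodon = NA_character_
    )
  }
  gt <- bind_rows(out)
  # drop 'gene' rows duplicating a CDS/tRNA/rRNA at identical coordinates
  if (nrow(gt) > 0L) {
    gt <- dplyr::distinct(gt, .data$start, .data$end, .data$strand,
                          .keep_all = TRUE)
    gt <- arrange(gt, .data$start)
  }
  genome <- mito_genome(sequence, id = locus_id)
  if (nrow(gt) > 0L && any(gt$end > genome$length | gt$start > genome$length)) {
    abort("GenBank-lite: feature outside sequence",
          class = "mito_error_coordinate")
  }
  attr(gt, "genome_length") <- genome$length
  list(genome = genome, gene_table = gt)
}

#' Serialize / parse trees as Newick
#'
#' Thin wrappers over [ape::write.tree()] and [ape::read.tree()] that enforce
#' labeled tips.
#'
#' @param tree An [ape::phylo] tree.
#' @return For `write_newick()`, a Newick string.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (any(is.na(tree$tip.label)) || any(!nzchar(tree$tip.label))) {
    abort("all tips must be labeled", class = "mito_error_serialization")
  }
  ape::write.tree(tree)
}

#' @rdname write_newick
#' @param text Newick string.
#' @export
read_newick <- function(text) {
  ape::read.tree(text = text)
}

#' Assemble an alignment tibble
#'
#' An alignment is a tibble with columns `id`, `sequence` (equal-length
#' gapped nucleotide strings over `{A,C,G,T,N,-}`) and optionally `group`.
#'
#' @param ids Sequence identifiers.
#' @param sequences Aligned sequences.
#' @param groups Optional group labels (recycled against `ids`).
#' @return Alignment tibble.
#' @export
alignment <- function(ids, sequences, groups = NULL) {
  sequences <- toupper(sequences)
  if (length(unique(nchar(sequences))) > 1L) {
    abort("alignment rows must all have the same length",
          class = "mito_error_format")
  }
  if (any(grepl("\\.", sequences, fixed = FALSE))) {
    abort("'.' is not an accepted gap character; use '-'",
          class = "mito_error_format")
  }
  if (any(grepl("[^ACGTN-]", sequences))) {
    abort("alignment alphabet is {A,C,G,T,N,-}", class = "mito_error_format")
  }
  out <- tibble(id = ids, sequence = sequences)
  if (!is.null(groups)) {
    if (any(!nzchar(groups))) {
      abort("group labels must be non-empty", class = "mito_error_format")
    }
    out$group <- groups
  }
  out
}

# Alignment tibble -> character matrix (rows = sequences).
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}
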