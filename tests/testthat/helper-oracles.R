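# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by enumeration rather than calling package internals.

# position set of a (possibly wrapping) 1-based inclusive feature
oracle_positions <- function(start, end, L) {
  if (start <= end) start:end else c(start:L, 1:end)
}

oracle_feature_length <- function(start, end, L) {
  length(oracle_positions(start, end, L))
}

oracle_union_length <- function(starts, ends, L) {
  length(unique(unlist(mapply(oracle_positions, starts, ends,
                              MoreArgs = list(L = L), SIMPLIFY = FALSE))))
}

oracle_base_counts <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  vapply(c("A", "C", "G", "T"), function(b) sum(s == b), numeric(1))
}

# all occurrences of a motif by naive sliding window (overlaps included)
oracle_motif_positions <- function(region, motif) {
  region <- toupper(region); motif <- toupper(motif)
  n <- nchar(region); w <- nchar(motif)
  if (w > n) return(integer(0))
  which(vapply(seq_len(n - w + 1L),
               function(i) substr(region, i, i + w - 1L) == motif,
               logical(1)))
}

oracle_pairwise_diff <- function(s1, s2) {
  x <- strsplit(toupper(s1), "")[[1]]
  y <- strsplit(toupper(s2), "")[[1]]
  d <- 0L
  for (k in seq_along(x)) {
    if (x[k] %in% c("A", "C", "G", "T") && y[k] %in% c("A", "C", "G", "T") &&
        x[k] != y[k]) {
      d <- d + 1L
    }
  }
  d
}

# RSCU by direct looping over the code's synonymous families
oracle_rscu <- function(counts, code_table) {
  sense <- names(code_table)[code_table != "*"]
  out <- setNames(numeric(length(sense)), sense)
  for (aa in unique(code_table[sense])) {
    fam <- sense[code_table[sense] == aa]
    tot <- sum(counts[fam], na.rm = TRUE)
    for (cd in fam) {
      x <- if (cd %in% names(counts)) counts[[cd]] else 0
      out[cd] <- if (tot > 0) length(fam) * x / tot else 0
    }
  }
  out
}

# Fitch score by exhaustive enumeration of internal-node states (ACGT tips)
oracle_fitch <- function(aln, tree) {
  tr <- ape::unroot(tree)
  ntip <- length(tr$tip.label)
  m <- do.call(rbind, strsplit(aln$sequence[match(tr$tip.label, aln$id)], ""))
  states <- c("A", "C", "G", "T")
  n_int <- tr$Nnode
  grid <- as.matrix(expand.grid(rep(list(states), n_int),
                                stringsAsFactors = FALSE))
  total <- 0L
  for (site in seq_len(ncol(m))) {
    tip_states <- m[, site]
    best <- Inf
    for (r in seq_len(nrow(grid))) {
      st <- c(tip_states, grid[r, ])
      cost <- sum(st[tr$edge[, 1]] != st[tr$edge[, 2]])
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  total
}

random_alignment <- function(n_seq, n_site, seed, alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  alignment(paste0("s", seq_len(n_seq)),
            vapply(seq_len(n_seq), function(i) {
              paste(sample(alphabet, n_site, replace = TRUE), collapse = "")
            }, character(1)))
}

# a random tree with strictly positive branch lengths (additive input for NJ)
random_additive_tree <- function(n_tip, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tip, tip.label = paste0("t", seq_len(n_tip)))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 3)
  ape::unroot(tr)
}
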