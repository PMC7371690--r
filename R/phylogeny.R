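# Stage 6: distance and parsimony tree inference at desk scale —
# Saitou-Nei neighbor joining, Fitch small-parsimony scoring, exhaustive
# maximum-parsimony search for small taxon sets, and nonparametric
# bootstrap support. Trees are ape::phylo objects throughout.

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration: repeatedly join the pair minimizing the
#' Q-criterion `Q_ij = (n-2) d_ij - r_i - r_j` (with `r_i` the row sum),
#' assign branch lengths `v_i = d_ij/2 + (r_i - r_j)/(2(n-2))`, and reduce
#' the matrix with `d_uk = (d_ik + d_jk - d_ij)/2`. Ties in Q are broken by
#' the lexicographically smallest pair of subtree labels, so the result is
#' deterministic. Negative branch lengths (possible on non-additive input)
#' are clamped to zero. The output is unrooted, stored with a trifurcation.
#'
#' @param dm A [dist_matrix()] result, a `dist`, or a symmetric matrix with
#'   dimnames.
#' @return An unrooted [ape::phylo] tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "mito_dist")) dm$matrix else as.matrix(dm)
  n <- nrow(d)
  if (n < 3L) {
    abort("neighbor joining needs at least 3 taxa",
          class = "mito_error_inference")
  }
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  labels <- rownames(d)
  newick <- labels          # growing subtree strings
  rep_lab <- labels         # lexicographically smallest tip in each subtree
  fmt <- function(x) sprintf("%.12g", max(0, x))
  while (n > 3L) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      paste(sort(c(rep_lab[ij[1]], rep_lab[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    merged <- paste0("(", newick[i], ":", fmt(vi), ",",
                     newick[j], ":", fmt(vj), ")")
    duk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d_new <- rbind(cbind(d[keep, keep, drop = FALSE], duk[keep]),
                   c(duk[keep], 0))
    newick <- c(newick[keep], merged)
    rep_lab <- c(rep_lab[keep], min(rep_lab[c(i, j)]))
    rownames(d_new) <- colnames(d_new) <- rep_lab
    d <- d_new
    n <- n - 1L
  }
  va <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  vb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  vc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- paste0("(", newick[1], ":", fmt(va), ",", newick[2], ":", fmt(vb),
                ",", newick[3], ":", fmt(vc), ");")
  ape::read.tree(text = txt)
}

#' Fitch small-parsimony score of a tree on an alignment
#'
#' Sums over alignment sites the minimum number of substitutions required on
#' the tree (Fitch set intersection/union). Sites where a sequence carries a
#' gap/N are treated as fully ambiguous for that tip. The score is invariant
#' under re-rooting.
#'
#' @param aln Alignment tibble; must contain every tree tip id.
#' @param tree An [ape::phylo] tree (rooted or unrooted).
#' @return Non-negative integer.
#' @export
fitch_score <- function(aln, tree) {
  if (!all(tree$tip.label %in% aln$id)) {
    abort("tree tips must be a subset of alignment ids",
          class = "mito_error_input")
  }
  tr <- ape::unroot(tree)
  tr <- ape::root(tr, outgroup = tr$tip.label[1], resolve.root = TRUE)
  tr <- ape::multi2di(tr)
  tr <- ape::reorder.phylo(tr, "postorder")
  ntip <- length(tr$tip.label)
  m <- aln_matrix(aln[match(tr$tip.label, aln$id), ])
  code <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  bits <- matrix(15L, nrow = nrow(m), ncol = ncol(m))
  for (b in names(code)) bits[m == b] <- code[[b]]
  nsite <- ncol(m)
  S <- matrix(0L, max(tr$edge), nsite)
  S[seq_len(ntip), ] <- bits
  changes <- integer(nsite)
  for (p in unique(tr$edge[, 1])) {       # postorder: children before parents
    kids <- tr$edge[tr$edge[, 1] == p, 2]
    s <- S[kids[1], ]
    for (k in kids[-1]) {
      inter <- bitwAnd(s, S[k, ])
      zero <- inter == 0L
      changes <- changes + zero
      s <- ifelse(zero, bitwOr(s, S[k, ]), inter)
    }
    S[p, ] <- s
  }
  sum(changes)
}

#' Exhaustive maximum-parsimony search
#'
#' Enumerates every unrooted binary topology on the alignment's taxa and
#' returns the one(s) minimizing [fitch_score()]. Exhaustive enumeration is
#' only feasible for small taxon sets; above `max_taxa` the function refuses
#' and points to [nj_tree()].
#'
#' @param aln Alignment tibble (3 or more sequences).
#' @param max_taxa Refuse above this many taxa (default 9; 9 taxa already
#'   mean 135,135 topologies).
#'
#' @return List with `tree` (first optimal topology in lexicographic Newick
#'   order), `score`, and `optimal` (list of all tied optimal trees).
#' @export
mp_search <- function(aln, max_taxa = 9L) {
  n <- nrow(aln)
  if (n < 3L) {
    abort("parsimony search needs at least 3 taxa",
          class = "mito_error_inference")
  }
  if (n > max_taxa) {
    abort(sprintf("%d taxa exceed the exhaustive-search limit (%d); use nj_tree()",
                  n, max_taxa), class = "mito_error_inference")
  }
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = aln$id)
  scores <- vapply(trees, function(tr) fitch_score(aln, tr), numeric(1))
  best <- min(scores)
  opt <- trees[scores == best]
  ord <- order(vapply(opt, function(tr) ape::write.tree(tr), character(1)))
  opt <- opt[ord]
  list(tree = opt[[1]], score = as.integer(best), optimal = opt)
}

# Non-trivial bipartitions of an unrooted tree, canonicalized so the side
# not containing the alphabetically first tip is reported, as "a|b|c" keys.
tree_splits <- function(tree) {
  tr <- ape::unroot(tree)
  tips <- tr$tip.label
  ref <- sort(tips)[1]
  ntip <- length(tips)
  desc <- phangorn::Descendants(tr, type = "tips")
  keys <- character(0)
  nodes <- integer(0)
  for (e in seq_len(nrow(tr$edge))) {
    child <- tr$edge[e, 2]
    if (child <= ntip) next
    side <- tips[desc[[child]]]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > ntip - 2L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, child)
  }
  tibble(node = nodes, split = keys)
}

#' Bootstrap support for a tree
#'
#' Site-resampling bootstrap: alignment columns are resampled with
#' replacement `n_replicates` times, a tree is inferred from each replicate
#' with the chosen method, and the support of each internal bipartition of
#' the point-estimate tree is the percentage of replicate trees containing
#' it. Seed-reproducible.
#'
#' @param aln Alignment tibble.
#' @param method `"nj"` (on p-distances) or `"mp"` (exhaustive search).
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#'
#' @return List with `tree` (the point-estimate tree, internal nodes labeled
#'   with support percentages) and `support` (tibble `split`, `support`).
#' @export
bootstrap_tree <- function(aln, method = c("nj", "mp"), n_replicates = 100L,
                           seed = 1L) {
  method <- match.arg(method)
  if (n_replicates < 1L) {
    abort("need at least one replicate", class = "mito_error_input")
  }
  infer <- function(a) {
    if (method == "nj") nj_tree(dist_matrix(a, "p_distance"))
    else mp_search(a)$tree
  }
  point <- infer(aln)
  ref_splits <- tree_splits(point)
  hits <- setNames(numeric(nrow(ref_splits)), ref_splits$split)
  m <- aln_matrix(aln)
  set.seed(seed)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    rep_aln <- tibble(id = aln$id,
                      sequence = apply(m[, cols, drop = FALSE], 1,
                                       paste, collapse = ""))
    rep_splits <- tree_splits(infer(rep_aln))$split
    found <- ref_splits$split %in% rep_splits
    hits[found] <- hits[found] + 1
  }
  support <- round(100 * hits / n_replicates, 1)
  ntip <- length(point$tip.label)
  labels <- rep("", point$Nnode)
  labels[ref_splits$node - ntip] <- as.character(support)
  point$node.label <- labels
  list(tree = point,
       support = tibble(split = ref_splits$split, support = unname(support)))
}
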