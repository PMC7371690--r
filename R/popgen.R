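# Stage 5: pairwise substitution counts, p/K2P distances, between-group
# divergence, and one-level AMOVA on haplotypes with a permutation test.
#
# Conventions: transitions are A<->G and C<->T, every other base pair is a
# transversion; sites where either sequence has a gap/N are skipped under
# pairwise deletion (the default).

aln_pair <- function(aln, i, j) {
  idx <- function(k) if (is.character(k)) match(k, aln$id) else as.integer(k)
  i <- idx(i); j <- idx(j)
  if (any(is.na(c(i, j)))) {
    abort("sequence id/index not found in alignment", class = "mito_error_input")
  }
  m <- aln_matrix(aln[c(i, j), ])
  ok <- m[1, ] %in% c("A", "C", "G", "T") & m[2, ] %in% c("A", "C", "G", "T")
  list(x = m[1, ok], y = m[2, ok])
}

#' Pairwise substitution count between two aligned sequences
#'
#' Counts sites where both sequences carry unambiguous bases and they
#' differ; gap and N sites are skipped.
#'
#' @param aln Alignment tibble (see [alignment()]).
#' @param i,j Row indices or sequence ids.
#' @return Non-negative integer.
#' @export
pairwise_differences <- function(aln, i, j) {
  p <- aln_pair(aln, i, j)
  sum(p$x != p$y)
}

#' p-distance and Kimura 2-parameter distance
#'
#' `p_distance()` is the proportion of differing sites among comparable
#' sites. `k2p_distance()` corrects separately for transitions (proportion
#' `P`) and transversions (`Q`): `d = -0.5 * log((1 - 2P - Q) * sqrt(1 - 2Q))`.
#' Outside the K2P domain (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) the distance
#' is reported as `Inf`.
#'
#' @inheritParams pairwise_differences
#' @return A single distance.
#' @examples
#' aln <- alignment(c("a", "b"), c("ACGTACGTAC", "ACGAACGTAC"))
#' p_distance(aln, "a", "b")
#' @export
p_distance <- function(aln, i, j) {
  p <- aln_pair(aln, i, j)
  if (length(p$x) == 0L) {
    abort("no comparable sites between the two sequences",
          class = "mito_error_distance")
  }
  mean(p$x != p$y)
}

#' @rdname p_distance
#' @export
k2p_distance <- function(aln, i, j) {
  p <- aln_pair(aln, i, j)
  n <- length(p$x)
  if (n == 0L) {
    abort("no comparable sites between the two sequences",
          class = "mito_error_distance")
  }
  diff <- p$x != p$y
  ts <- (p$x == "A" & p$y == "G") | (p$x == "G" & p$y == "A") |
    (p$x == "C" & p$y == "T") | (p$x == "T" & p$y == "C")
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warn("K2P distance undefined (saturation); returning Inf")
    return(Inf)
  }
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise distance matrix over an alignment
#'
#' @param aln Alignment tibble.
#' @param model `"differences"` (substitution counts), `"p_distance"` or
#'   `"k2p"`.
#' @param site_handling `"pairwise_deletion"` (default) or
#'   `"complete_deletion"` (drop every column containing any gap/N first).
#'
#' @return Object of class `mito_dist`: list with `ids`, `matrix`
#'   (symmetric, zero diagonal) and `model`. `tidy()` returns the lower
#'   triangle as a long tibble.
#' @export
dist_matrix <- function(aln, model = c("p_distance", "differences", "k2p"),
                        site_handling = c("pairwise_deletion",
                                          "complete_deletion")) {
  model <- match.arg(model)
  site_handling <- match.arg(site_handling)
  if (nrow(aln) < 2L) {
    abort("need at least 2 sequences", class = "mito_error_input")
  }
  if (site_handling == "complete_deletion") {
    m <- aln_matrix(aln)
    keep <- colSums(!apply(m, 2, `%in%`, c("A", "C", "G", "T"))) == 0
    aln <- mutate(aln, sequence = apply(m[, keep, drop = FALSE], 1,
                                        paste, collapse = ""))
  }
  n <- nrow(aln)
  fun <- switch(model, differences = pairwise_differences,
                p_distance = p_distance, k2p = k2p_distance)
  d <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- fun(aln, i, j)
    }
  }
  structure(list(ids = aln$id, matrix = d, model = model,
                 site_handling = site_handling),
            class = "mito_dist")
}

#' @export
print.mito_dist <- function(x, ...) {
  cat(sprintf("<mito_dist> %d sequences, model = %s (%s)\n",
              length(x$ids), x$model, x$site_handling))
  print(round(x$matrix, 4))
  invisible(x)
}

#' @method tidy mito_dist
#' @export
tidy.mito_dist <- function(x, ...) {
  n <- length(x$ids)
  idx <- which(lower.tri(x$matrix), arr.ind = TRUE)
  tibble(id1 = x$ids[idx[, 2]], id2 = x$ids[idx[, 1]],
         distance = x$matrix[idx])
}

#' Mean between-group divergence
#'
#' The mean of all between-group pairwise distances under the chosen model
#' — the "genetic divergence" figure conventionally reported between
#' populations or species.
#'
#' @param aln Alignment tibble with a `group` column (or pass `groups`).
#' @param groups Optional vector of group labels, one per row of `aln`.
#' @param model Distance model, as in [dist_matrix()].
#' @return A single non-negative number.
#' @export
group_divergence <- function(aln, groups = NULL,
                             model = c("p_distance", "differences", "k2p")) {
  model <- match.arg(model)
  groups <- groups %||% (if ("group" %in% names(aln)) aln$group else NULL)
  if (is.null(groups)) {
    abort("no group labels supplied", class = "mito_error_grouping")
  }
  labs <- unique(groups)
  if (length(labs) != 2L) {
    abort("group divergence is defined between exactly two groups",
          class = "mito_error_grouping")
  }
  d <- dist_matrix(aln, model)$matrix
  between <- d[groups == labs[1], groups == labs[2], drop = FALSE]
  mean(between)
}

# AMOVA sums of squares and variance components from a squared-distance
# matrix and a grouping vector (the Excoffier one-level estimators).
amova_components <- function(d2, groups) {
  N <- nrow(d2)
  labs <- unique(groups)
  G <- length(labs)
  ssd_total <- sum(d2[lower.tri(d2)]) / N
  ssd_within <- sum(vapply(labs, function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2L) return(0)
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[lower.tri(sub)]) / length(idx)
  }, numeric(1)))
  ssd_among <- ssd_total - ssd_within
  n_g <- as.numeric(table(groups)[labs])
  n_bar <- (N - sum(n_g^2) / N) / (G - 1)
  sigma_w <- if (N - G > 0) ssd_within / (N - G) else NaN
  sigma_a <- (ssd_among / (G - 1) - sigma_w) / n_bar
  phi <- if (is.finite(sigma_a + sigma_w) && (sigma_a + sigma_w) > 0) {
    sigma_a / (sigma_a + sigma_w)
  } else NaN
  list(ssd_total = ssd_total, ssd_among = ssd_among, ssd_within = ssd_within,
       df_among = G - 1, df_within = N - G, n_bar = n_bar,
       sigma_a = sigma_a, sigma_w = sigma_w, phi_st = phi)
}

#' One-level AMOVA on haplotype groups with a permutation test
#'
#' Analysis of molecular variance from pairwise substitution counts: the
#' distance between two haplotypes is their number of nucleotide
#' differences, and the analysis partitions the total sum of squared
#' distances into among-group and within-group components, yielding the
#' variance components, the percent of variation among/within groups, and
#' the fixation index Phi_ST. Significance is assessed by permuting group
#' labels: the p-value is the fraction of permutations (the observed
#' labelling included) with Phi_ST at least as large as observed.
#'
#' A negative among-group variance component (possible when groups are no
#' more different than random draws) is reported as-is and flagged.
#'
#' @param aln Alignment tibble with a `group` column (or pass `groups`).
#' @param groups Optional group labels, one per row.
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Integer seed for the permutation test (required for
#'   reproducibility).
#'
#' @return Object of class `mito_amova`; see [tidy.mito_amova()] and
#'   [glance.mito_amova()].
#' @export
amova <- function(aln, groups = NULL, n_permutations = 1000, seed = 1L) {
  groups <- groups %||% (if ("group" %in% names(aln)) aln$group else NULL)
  if (is.null(groups)) {
    abort("no group labels supplied", class = "mito_error_grouping")
  }
  if (length(unique(groups)) < 2L) {
    abort("AMOVA needs at least two groups", class = "mito_error_grouping")
  }
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    warn("group(s) with a single haplotype present; within-group variance rests on the remaining groups")
  }
  d <- dist_matrix(aln, "differences")$matrix
  d2 <- d^2
  obs <- amova_components(d2, groups)
  perm_phi <- rep(NA_real_, n_permutations)
  set.seed(seed)
  for (b in seq_len(n_permutations)) {
    perm_phi[b] <- amova_components(d2, sample(groups))$phi_st
  }
  p_value <- (sum(perm_phi >= obs$phi_st, na.rm = TRUE) + 1) /
    (n_permutations + 1)
  total_var <- obs$sigma_a + obs$sigma_w
  structure(c(obs, list(
    n = nrow(aln), n_groups = length(unique(groups)),
    group_sizes = as.integer(sizes),
    pct_among = 100 * obs$sigma_a / total_var,
    pct_within = 100 * obs$sigma_w / total_var,
    negative_variance = is.finite(obs$sigma_a) && obs$sigma_a < 0,
    p_value = p_value, n_permutations = n_permutations, seed = seed
  )), class = "mito_amova")
}

#' @export
print.mito_amova <- function(x, ...) {
  cat(sprintf("<mito_amova> %d haplotypes in %d groups\n", x$n, x$n_groups))
  cat(sprintf("  among groups : sigma2 = %.3f (%.1f%%), df = %d\n",
              x$sigma_a, x$pct_among, x$df_among))
  cat(sprintf("  within groups: sigma2 = %.3f (%.1f%%), df = %d\n",
              x$sigma_w, x$pct_within, x$df_within))
  cat(sprintf("  Phi_ST = %.4f, permutation p = %.4g (%d permutations, seed %d)\n",
              x$phi_st, x$p_value, x$n_permutations, x$seed))
  if (isTRUE(x$negative_variance)) {
    cat("  note: negative among-group variance component\n")
  }
  invisible(x)
}

#' Component table of an AMOVA fit
#'
#' @param x A `mito_amova` object.
#' @param ... Unused.
#' @return Tibble with one row per variance component (`among_groups`,
#'   `within_groups`): df, sum of squared deviations, variance component,
#'   percent of variation.
#' @method tidy mito_amova
#' @export
tidy.mito_amova <- function(x, ...) {
  tibble(
    component = c("among_groups", "within_groups"),
    df = c(x$df_among, x$df_within),
    ssd = c(x$ssd_among, x$ssd_within),
    sigma2 = c(x$sigma_a, x$sigma_w),
    pct_variation = c(x$pct_among, x$pct_within)
  )
}

#' One-row summary of an AMOVA fit
#'
#' @param x A `mito_amova` object.
#' @param ... Unused.
#' @return One-row tibble: `phi_st`, `pct_among`, `pct_within`, `p_value`,
#'   `n`, `n_groups`, `n_permutations`, `seed`.
#' @method glance mito_amova
#' @export
glance.mito_amova <- function(x, ...) {
  tibble(phi_st = x$phi_st, pct_among = x$pct_among,
         pct_within = x$pct_within, p_value = x$p_value, n = x$n,
         n_groups = x$n_groups, n_permutations = x$n_permutations,
         seed = x$seed)
}
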