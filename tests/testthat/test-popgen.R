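test_that("pairwise differences skip ambiguous sites and match the site loop", {
  aln <- alignment(c("a", "b"), c("ACGT", "ACGT"))
  expect_identical(pairwise_differences(aln, "a", "b"), 0L)
  aln2 <- alignment(c("a", "b"), c("ACGT", "ACGA"))
  expect_identical(pairwise_differences(aln2, 1, 2), 1L)
  ambig <- alignment(c("a", "b"), c("ACGTN-A", "TCGAATA"))
  expect_identical(pairwise_differences(ambig, 1, 2),
                   oracle_pairwise_diff("ACGTN-A", "TCGAATA"))
  set.seed(61)
  for (i in 1:20) {
    a <- random_alignment(2, 120, seed = i, alphabet = c("A", "C", "G", "T", "N", "-"))
    expect_identical(pairwise_differences(a, 1, 2),
                     oracle_pairwise_diff(a$sequence[1], a$sequence[2]))
  }
})

test_that("a planted number of substitutions is recovered exactly", {
  cfg <- sim_config(seed = 13, groups = c(a = 2L), within_group_diffs = 33,
                    between_group_diffs = c(a = 0))
  sim <- generate_genome(cfg)
  hap <- generate_haplotypes(sim$genome, cfg)
  expect_identical(pairwise_differences(hap, 1, 2), 33L)
  cfg2 <- sim_config(seed = 13, groups = c(a = 1L, b = 1L),
                     within_group_diffs = 0,
                     between_group_diffs = c(a = 0, b = 304))
  hap2 <- generate_haplotypes(sim$genome, cfg2)
  expect_identical(pairwise_differences(hap2, 1, 2), 304L)
})

test_that("p-distance and K2P behave per their closed forms", {
  aln <- alignment(c("a", "b"),
                   c(strrep("A", 10), paste0("GG", strrep("A", 8))))
  expect_equal(p_distance(aln, 1, 2), 0.2)
  ident <- alignment(c("a", "b"), c("ACGTACGT", "ACGTACGT"))
  expect_equal(k2p_distance(ident, 1, 2), 0)
  # P = 0.1, Q = 0.05 over 100 sites
  x <- strrep("A", 100)
  y <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  aln2 <- alignment(c("a", "b"), c(x, y))
  expect_equal(k2p_distance(aln2, 1, 2), -0.5 * log(0.75 * sqrt(0.9)))
  # saturation leaves the K2P domain
  sat <- alignment(c("a", "b"), c(strrep("A", 10), strrep("C", 10)))
  expect_warning(d <- k2p_distance(sat, 1, 2), "Inf")
  expect_identical(d, Inf)
  gaps <- alignment(c("a", "b"), c("----", "ACGT"))
  expect_error(p_distance(gaps, 1, 2), class = "mito_error_distance")
})

test_that("K2P agrees with an independent reference implementation", {
  set.seed(62)
  for (i in 1:5) {
    base <- sample(c("A", "C", "G", "T"), 600, TRUE)
    mut <- base
    idx <- sample(600, 60)
    for (k in idx) mut[k] <- sample(setdiff(c("A", "C", "G", "T"), mut[k]), 1)
    aln <- alignment(c("x", "y"),
                     c(paste(base, collapse = ""), paste(mut, collapse = "")))
    bin <- ape::as.DNAbin(rbind(x = base, y = mut))
    expect_equal(k2p_distance(aln, 1, 2),
                 as.numeric(ape::dist.dna(bin, model = "K80")))
    expect_equal(p_distance(aln, 1, 2),
                 as.numeric(ape::dist.dna(bin, model = "raw")))
  }
})

test_that("K2P converges to p-distance for small divergence", {
  for (m in c(2, 5, 8)) {  # p <= 0.01 over 1000 sites, transitions only
    base <- strrep("A", 1000)
    mut <- paste0(strrep("G", m), strrep("A", 1000 - m))
    aln <- alignment(c("a", "b"), c(base, mut))
    p <- p_distance(aln, 1, 2)
    k <- k2p_distance(aln, 1, 2)
    expect_lt(abs(k - p) / p, 0.01)
  }
})

test_that("complete deletion drops every column containing a gap or N", {
  aln <- alignment(c("a", "b", "c"), c("ACGTA", "AC-TA", "ACGTN"))
  d <- dist_matrix(aln, "differences", site_handling = "complete_deletion")
  expect_equal(max(d$matrix), 0)
  td <- tidy(d)
  expect_identical(nrow(td), 3L)
})

test_that("group divergence is the mean between-group distance", {
  aln <- alignment(c("a1", "a2", "b1"),
                   c("AAAA", "AAAA", "AAAT"), groups = c("g1", "g1", "g2"))
  expect_equal(group_divergence(aln), 0.25)
  same <- alignment(c("a", "b"), c("ACGT", "ACGT"), groups = c("g1", "g2"))
  expect_equal(group_divergence(same), 0)
  two <- alignment(c("a", "b"), c("ACGT", "ACTT"), groups = c("g1", "g2"))
  expect_equal(group_divergence(two), p_distance(two, 1, 2))
  expect_error(group_divergence(alignment("a", "ACGT", groups = "g")),
               class = "mito_error_grouping")
})

test_that("group divergence recovers the simulated between-group distance", {
  cfg <- sim_config(seed = 77, groups = c(a = 3L, b = 3L),
                    within_group_diffs = 30,
                    between_group_diffs = c(a = 0, b = 300),
                    mutation_mode = "poisson")
  sim <- generate_genome(cfg)
  hap <- generate_haplotypes(sim$genome, cfg)
  # expected between-group p-distance: (300 + 15 + 15) / 16345
  delta <- 330 / 16345
  se <- sqrt(delta * (1 - delta) / 16345)
  est <- group_divergence(hap, model = "p_distance")
  expect_lt(abs(est - delta), 3 * se + 3 * sqrt(330) / 16345)
})

test_that("AMOVA partitions fixed between-group variation as 100% among", {
  aln <- alignment(
    c("a1", "a2", "b1", "b2"),
    c(strrep("A", 50), strrep("A", 50),
      paste0(strrep("T", 20), strrep("A", 30)),
      paste0(strrep("T", 20), strrep("A", 30))),
    groups = c("g1", "g1", "g2", "g2"))
  fit <- amova(aln, n_permutations = 100, seed = 2)
  expect_equal(fit$pct_among, 100)
  expect_equal(fit$phi_st, 1)
  expect_equal(fit$ssd_within, 0)
  g <- glance(fit)
  expect_identical(nrow(g), 1L)
  td <- tidy(fit)
  expect_identical(td$component, c("among_groups", "within_groups"))
  expect_error(amova(dplyr::mutate(aln, group = "g1")),
               class = "mito_error_grouping")
})

test_that("AMOVA sums of squares decompose exactly", {
  set.seed(63)
  for (i in 1:15) {
    n <- sample(5:9, 1)
    aln <- random_alignment(n, 80, seed = 100 + i)
    aln$group <- sample(c("g1", "g2"), n, replace = TRUE)
    if (length(unique(aln$group)) < 2) aln$group[1] <- setdiff(c("g1", "g2"), aln$group[1])
    fit <- suppressWarnings(amova(aln, n_permutations = 20, seed = i))
    expect_equal(fit$ssd_among + fit$ssd_within, fit$ssd_total,
                 tolerance = 1e-9)
    expect_equal(fit$pct_among + fit$pct_within, 100, tolerance = 1e-9)
  }
})

test_that("AMOVA permutation p-values are reproducible and calibrated", {
  aln <- random_alignment(8, 200, seed = 64)
  aln$group <- rep(c("g1", "g2"), each = 4)
  f1 <- amova(aln, n_permutations = 200, seed = 9)
  f2 <- amova(aln, n_permutations = 200, seed = 9)
  expect_identical(f1$p_value, f2$p_value)
  expect_identical(glance(f1), glance(f2))
  # exchangeable sequences with random labels: p roughly uniform
  ps <- vapply(1:20, function(s) {
    a <- random_alignment(8, 150, seed = 300 + s)
    a$group <- sample(rep(c("g1", "g2"), each = 4))
    amova(a, n_permutations = 100, seed = s)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps), 0.8)
})
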