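test_that("NJ solves the three-taxon tree by the three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 1)   # (dAB + dAC - dBC)/2
  expect_equal(bl[["B"]], 2)
  expect_equal(bl[["C"]], 3)
  expect_error(nj_tree(d[1:2, 1:2]), class = "mito_error_inference")
})

test_that("NJ reconstructs additive trees exactly (topology and lengths)", {
  for (n in 4:6) {
    for (seed in 1:4) {
      true <- random_additive_tree(n, seed = 10 * n + seed)
      d <- stats::cophenetic(true)
      got <- nj_tree(d)
      expect_identical(ape::dist.topo(ape::unroot(got), true)[[1]], 0)
      expect_equal(sort(got$edge.length), sort(true$edge.length),
                   tolerance = 1e-9)
      # and matches an independent NJ implementation topologically
      ref <- ape::nj(stats::as.dist(d))
      expect_identical(ape::dist.topo(ape::unroot(got), ape::unroot(ref))[[1]], 0)
    }
  }
})

test_that("NJ tie-breaking is deterministic", {
  d <- matrix(1, 5, 5); diag(d) <- 0
  rownames(d) <- colnames(d) <- c("e", "b", "d", "a", "c")
  t1 <- write_newick(nj_tree(d))
  t2 <- write_newick(nj_tree(d))
  expect_identical(t1, t2)
})

test_that("Fitch scoring matches exhaustive enumeration and ignores rooting", {
  ident <- alignment(paste0("t", 1:4), rep(strrep("ACGT", 5), 4))
  any_tree <- ape::rtree(4, tip.label = paste0("t", 1:4))
  expect_identical(fitch_score(ident, any_tree), 0L)
  # one binary site split 2-2 along the tree costs exactly 1
  split2 <- alignment(c("t1", "t2", "t3", "t4"), c("A", "A", "C", "C"))
  match_tree <- read_newick("((t1,t2),(t3,t4));")
  expect_identical(fitch_score(split2, match_tree), 1L)
  set.seed(71)
  for (i in 1:6) {
    aln <- random_alignment(5, 25, seed = 200 + i)
    tr <- ape::rtree(5, tip.label = paste0("s", 1:5))
    sc <- fitch_score(aln, tr)
    expect_identical(sc, as.integer(oracle_fitch(aln, tr)))
    rerooted <- ape::root(ape::unroot(tr), outgroup = "s3", resolve.root = TRUE)
    expect_identical(fitch_score(aln, rerooted), sc)
    # cross-check against an independent parsimony implementation
    m <- do.call(rbind, strsplit(aln$sequence, ""))
    rownames(m) <- aln$id
    pd <- phangorn::phyDat(m)
    expect_identical(sc, as.integer(phangorn::fitch(tr, pd)))
  }
})

test_that("exhaustive parsimony search finds the minimum and honors limits", {
  aln3 <- random_alignment(3, 30, seed = 72)
  res3 <- mp_search(aln3)
  expect_length(res3$optimal, 1L)  # the single unrooted 3-taxon topology
  # simulate ample signal on a known 5-taxon tree: two clades share many sites
  base <- strrep("A", 60)
  mut <- function(s, at, to) {
    v <- strsplit(s, "")[[1]]; v[at] <- to; paste(v, collapse = "")
  }
  cladeAB <- mut(base, 1:15, "T"); cladeCD <- mut(base, 31:45, "G")
  aln5 <- alignment(c("A", "B", "C", "D", "E"),
                    c(mut(cladeAB, 16, "C"), mut(cladeAB, 17, "C"),
                      mut(cladeCD, 46, "C"), mut(cladeCD, 47, "C"), base))
  res <- mp_search(aln5)
  splits <- function(tr) {
    ntip <- length(tr$tip.label)
    desc <- phangorn::Descendants(ape::unroot(tr), type = "tips")
    unlist(lapply(which(seq_len(max(tr$edge)) > ntip), function(nd) {
      paste(sort(tr$tip.label[desc[[nd]]]), collapse = "|")
    }))
  }
  expect_true("A|B" %in% splits(res$tree) || "C|D|E" %in% splits(res$tree))
  expect_true("C|D" %in% splits(res$tree) || "A|B|E" %in% splits(res$tree))
  # the found score lower-bounds every candidate topology
  all_tr <- phangorn::allTrees(5, rooted = FALSE, tip.label = aln5$id)
  expect_true(all(vapply(all_tr, function(tr) fitch_score(aln5, tr),
                         numeric(1)) >= res$score))
  # identical sequences tie every topology at score 0
  ident <- alignment(paste0("t", 1:4), rep(strrep("AC", 10), 4))
  tie <- mp_search(ident)
  expect_identical(tie$score, 0L)
  expect_length(tie$optimal, 3L)
  big <- random_alignment(10, 10, seed = 73)
  expect_error(mp_search(big), class = "mito_error_inference")
})

test_that("bootstrap support is seed-reproducible and finds strong clades", {
  cfg <- sim_config(seed = 31, groups = c(a = 3L, b = 3L),
                    within_group_diffs = 30,
                    between_group_diffs = c(a = 0, b = 400))
  sim <- generate_genome(cfg)
  hap <- generate_haplotypes(sim$genome, cfg)
  bt <- bootstrap_tree(hap, "nj", n_replicates = 50, seed = 5)
  sep <- bt$support$support[bt$support$split == "b_1|b_2|b_3"]
  expect_length(sep, 1L)
  expect_gte(sep, 95)
  bt2 <- bootstrap_tree(hap, "nj", n_replicates = 50, seed = 5)
  expect_identical(bt$support, bt2$support)
  one <- bootstrap_tree(hap, "nj", n_replicates = 1, seed = 2)
  expect_true(all(one$support$support %in% c(0, 100)))
})

test_that("the simulated gaur/mithun/outgroup design recovers the clade layout", {
  # gaur-like radiation, a mithun-like lineage nearer to it, and a distant
  # outgroup, at the study's divergence scale
  cfg <- sim_config(seed = 19,
                    groups = c(gaur = 4L, mithun = 2L, outgroup = 2L),
                    within_group_diffs = 33,
                    between_group_diffs = c(gaur = 0, mithun = 304,
                                            outgroup = 1200))
  sim <- generate_genome(cfg)
  hap <- generate_haplotypes(sim$genome, cfg)
  tr <- nj_tree(dist_matrix(hap, "p_distance"))
  pd <- stats::cophenetic(tr)
  gaur <- paste0("gaur_", 1:4); mith <- paste0("mithun_", 1:2)
  out <- paste0("outgroup_", 1:2)
  expect_lt(mean(pd[mith, gaur]), mean(pd[mith, out]))
  expect_lt(mean(pd[gaur, gaur][upper.tri(diag(4))]), mean(pd[gaur, mith]))
  # the outgroup pair forms its own clade on the unrooted tree
  desc <- phangorn::Descendants(ape::unroot(tr), type = "tips")
  keys <- vapply(desc, function(d) paste(sort(tr$tip.label[d]), collapse = "|"),
                 character(1))
  expect_true("outgroup_1|outgroup_2" %in% keys)
})
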