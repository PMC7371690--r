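test_that("adjacency ledger reproduces the published spacer/overlap entries", {
  led <- adjacency_ledger(gaur_gene_table())
  expect_identical(nrow(led), 38L)  # one entry per feature, circular closure
  get_gap <- function(up) led$gap_bp[led$upstream == up]
  expect_identical(get_gap("trnN"), 32L)    # largest spacer, trnN-trnC
  expect_identical(get_gap("atp8"), -40L)   # largest overlap, atp8-atp6
  expect_identical(get_gap("trnL2"), 2L)
  expect_identical(get_gap("nad5"), -17L)
  expect_identical(get_gap("control_region"), 0L)  # 16345 abuts position 1
  expect_identical(led$downstream[led$upstream == "control_region"], "trnF")
})

test_that("signed gaps and feature lengths close the circle (conservation law)", {
  gt <- gaur_gene_table()
  led <- adjacency_ledger(gt)
  lens <- feature_length(gt$start, gt$end, 16345)
  expect_identical(sum(led$gap_bp) + sum(lens), 16345L)
  for (seed in 1:40) {
    for (ov in c(TRUE, FALSE)) {
      rt <- random_gene_table(seed = seed, allow_overlap = ov)
      L <- attr(rt, "genome_length")
      led <- adjacency_ledger(rt)
      lens <- feature_length(rt$start, rt$end, L)
      expect_identical(sum(led$gap_bp) + sum(lens), L)
      expect_identical(nrow(led), nrow(rt))
      expect_identical(sum(led$type == "spacer") + sum(led$type == "overlap") +
                         sum(led$type == "abutting"), nrow(rt))
    }
  }
})

test_that("adjacency ledger recovers the gaps a random layout was built with", {
  for (seed in c(3, 17, 91)) {
    rt <- random_gene_table(seed = seed, allow_overlap = TRUE)
    built_gaps <- sort(attr(rt, "gaps"))
    expect_identical(sort(adjacency_ledger(rt)$gap_bp), as.integer(built_gaps))
  }
})

test_that("structural summary reproduces the published genome ledger", {
  s <- structural_summary(gaur_gene_table())
  expect_identical(s$genome_length, 16345L)
  expect_identical(c(s$n_pcg, s$n_trna, s$n_rrna, s$n_control), c(13L, 22L, 2L, 1L))
  expect_identical(c(s$strand_h, s$strand_l), c(28L, 9L))
  expect_identical(s$pcg_union_bp, 11339L)
  expect_identical(s$pcg_sum_bp, 11404L)
  expect_equal(s$pcg_pct, 69.37)
  expect_identical(s$rrna_bp, 2525L)
  expect_identical(s$control_bp, 902L)
  expect_identical(c(s$trna_min_bp, s$trna_max_bp), c(60L, 75L))
  expect_identical(c(s$trna_min_gene, s$trna_max_gene), c("trnS1", "trnL2"))
  expect_identical(c(s$igs_total_bp, s$igs_n, s$igs_max_bp), c(75L, 14L, 32L))
  expect_identical(s$igs_max_pair, "trnN-trnC")
  expect_identical(c(s$overlap_total_bp, s$overlap_n, s$overlap_max_bp),
                   c(72L, 7L, 40L))
  expect_identical(s$overlap_max_pair, "atp8-atp6")
  g <- glance(s)
  expect_identical(nrow(g), 1L)
  expect_identical(g$pcg_union_bp, 11339L)
})

test_that("class union lengths match brute-force coverage recomputation", {
  for (seed in c(2, 8)) {
    rt <- random_gene_table(seed = seed, allow_overlap = TRUE)
    L <- attr(rt, "genome_length")
    s <- structural_summary(rt)
    for (cl in c("PCG", "tRNA", "rRNA")) {
      sub <- rt[rt$feature_class == cl, ]
      expect_identical(
        switch(cl, PCG = s$pcg_union_bp, tRNA = s$trna_bp, rRNA = s$rrna_bp),
        oracle_union_length(sub$start, sub$end, L)
      )
    }
  }
})

test_that("a single-gene table yields one circular gap and no overlaps", {
  one <- tibble::tibble(name = "nad1", strand = "H", start = 11L, end = 110L,
                        feature_class = "PCG", anticodon = NA_character_)
  s <- structural_summary(one, genome_length = 500L)
  expect_identical(s$overlap_n, 0L)
  expect_identical(s$igs_n, 1L)
  expect_identical(s$igs_total_bp, 400L)
})

test_that("contained features are skipped from the ledger with a warning", {
  gt <- tibble::tibble(
    name = c("nad1", "trnF", "nad2"), strand = "H",
    start = c(1L, 20L, 200L), end = c(150L, 80L, 300L),
    feature_class = c("PCG", "tRNA", "PCG"), anticodon = NA_character_)
  expect_warning(led <- adjacency_ledger(gt, genome_length = 400L), "contained")
  expect_identical(nrow(led), 2L)
})

test_that("PCG validation classifies start and terminal codon states", {
  mk <- function(seq) {
    g <- mito_genome(seq)
    gt <- tibble::tibble(name = "nad1", strand = "H", start = 1L,
                         end = nchar(seq), feature_class = "PCG",
                         anticodon = NA_character_)
    validate_pcg(g, gt)
  }
  clean <- mk("ATGAAACCCGGGTAA")
  expect_identical(clean$terminal_state, "complete")
  expect_identical(clean$internal_stops, 0L)
  expect_true(clean$ok)
  inc <- mk("ATGAAACCCT")      # length = 1 mod 3, ends in T
  expect_identical(inc$terminal_state, "incomplete_T")
  inc2 <- mk("ATGAAACCCTA")    # length = 2 mod 3, ends in TA
  expect_identical(inc2$terminal_state, "incomplete_TA")
  agg <- mk("ATGAGACCCTAA")    # AGA is a stop under the vertebrate mito code
  expect_identical(agg$internal_stops, 1L)
  expect_false(agg$ok)
  expect_error(mk("ATG"), class = "mito_error_validation")
})

test_that("a frame shift inside a clean PCG is flagged as internal stops", {
  sim <- generate_genome(sim_config(seed = 4))
  gt <- sim$gene_table
  nd <- gt[gt$name == "nad2", ]
  cds <- slice_sequence(sim$genome, nd$start, nd$end, nd$strand)
  shifted <- paste0(substr(cds, 1, 3), "A", substr(cds, 4, nchar(cds) - 1))
  g2 <- mito_genome(shifted)
  gt2 <- tibble::tibble(name = "nad2", strand = "H", start = 1L,
                        end = nchar(shifted), feature_class = "PCG",
                        anticodon = NA_character_)
  expect_gte(validate_pcg(g2, gt2)$internal_stops, 1L)
})
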