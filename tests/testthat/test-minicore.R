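test_that("per-marker PIC matches closed forms in both parameterizations", {
  expect_equal(pic_per_marker(c(0.5, 0.5)), 0.5)
  expect_equal(pic_per_marker(1), 0)
  expect_equal(pic_per_marker(c(0.2, 0.8)), 0.32)
  # Botstein full form subtracts the double-heterozygote term
  expect_equal(pic_per_marker(c(0.5, 0.5), form = "botstein"),
               1 - 2 * 0.25 - 2 * 0.25 * 0.25)
  expect_error(pic_per_marker(c(0.5, 0.4)), "sum to 1")
})

test_that("average PIC reproduces the 4 x 3 worked example", {
  g <- pic_example()
  expect_equal(average_pic(g), mean(c(0.375, 0.5, 0.5)))
  expect_equal(average_pic(g, subset = c("a1", "a3", "a4")), 8 / 27)
  # identical accessions are monomorphic everywhere
  g0 <- gm(rbind(a = c(0, 1, 0), b = c(0, 1, 0)), ids = c("a", "b"))
  expect_equal(average_pic(g0), 0)
  expect_error(average_pic(g, subset = "a1"), ">= 2")
})

test_that("stepwise ranking follows the worked example including tie-break and peak", {
  rk <- rank_accessions(pic_example(), min_size = 2)
  # all removals from the full set give (0.4444, 0.2963, 0.4444, 0.4444);
  # tie among a1/a3/a4 broken lexicographically -> a1 removed first
  expect_equal(rk$ranking$accession[rk$ranking$rank == 4], "a1")
  expect_equal(rk$trajectory$avg_pic[1], 0.458333, tolerance = 1e-6)
  expect_equal(rk$trajectory$avg_pic[2], 4 / 9)
  # trajectory decreases from the start: peak is the full set
  expect_equal(rk$peak_size, 4)
})

test_that("incremental ranking equals the naive full-recomputation oracle", {
  for (seed in c(101, 102)) {
    cfg <- sim_config(n_per_subpop = c(10, 14, 14, 10, 4), n_admixed = 8,
                      n_markers = 200, seed = seed)
    sim <- sim_genotypes(cfg, sim_genetic_map(cfg))
    g <- sim$genotypes
    fast <- rank_accessions(g)
    slow <- naive_rank_accessions(g)
    removed_fast <- fast$ranking$accession[order(fast$ranking$removal_step,
                                                 na.last = NA)]
    expect_identical(removed_fast, slow$removal_order)
    expect_equal(fast$trajectory$avg_pic, slow$trajectory$avg_pic,
                 tolerance = 1e-12)
    expect_identical(fast$peak_size, slow$peak_size)
  }
})

test_that("exact duplicates are exchangeable up to the tie-break rule", {
  set.seed(23)
  calls <- matrix(rbinom(12 * 60, 1, 0.5), 12, 60)
  calls[2, ] <- calls[1, ] # rows 1 and 2 identical
  dimnames(calls) <- list(sprintf("a%02d", 1:12), sprintf("m%02d", 1:60))
  rk <- rank_accessions(genotype_matrix(calls))
  steps <- rk$ranking$removal_step[rk$ranking$accession %in% c("a01", "a02")]
  # one of the duplicate pair goes first; the id-ordered one leads
  first_removed <- rk$ranking$accession[!is.na(rk$ranking$removal_step) &
                                          rk$ranking$removal_step == min(steps)]
  expect_equal(first_removed, "a01")
})

test_that("selection warns below the peak and respects size bounds", {
  cfg <- sim_config(n_per_subpop = c(12, 12), n_subpops = 2, n_admixed = 6,
                    fst_per_subpop = c(0.2, 0.2), n_markers = 150, seed = 29,
                    duplicate_sets = c(2L, 2L))
  sim <- sim_genotypes(cfg, sim_genetic_map(cfg))
  rk <- rank_accessions(sim$genotypes)
  expect_gt(rk$peak_size, 2)
  expect_warning(select_minicore(rk, size = 2), "peak")
  sel_small <- suppressWarnings(select_minicore(rk, size = 2))
  expect_true(attr(sel_small, "below_peak"))
  n <- nrow(rk$ranking)
  sel_all <- select_minicore(rk, size = n)
  expect_equal(nrow(sel_all), n)
  expect_error(select_minicore(rk, size = n + 1), "exceeds")
  # fraction rounds to a count
  sel_frac <- suppressWarnings(select_minicore(rk, fraction = 0.10))
  expect_equal(nrow(sel_frac), round(0.10 * n))
  # selected accessions are exactly the top ranks
  expect_equal(sort(sel_frac$rank), seq_len(nrow(sel_frac)))
})

test_that("group-restricted rankings use within-group frequencies", {
  # group identity: whole set equals plain ranking
  g <- pic_example()
  rk_all <- rank_accessions(g)
  rk_grp <- group_restricted_ranking(g, rep(TRUE, 4))
  expect_identical(rk_all$ranking, rk_grp$ranking)

  # an accession carrying a group-private rare allele ranks top within its
  # group even when it is redundant globally
  set.seed(31)
  m <- 40
  groupA <- matrix(rbinom(6 * m, 1, 0.5), 6, m)
  groupB <- matrix(0, 6, m)
  groupB[6, 1:10] <- 1 # b6 holds all of group B's polymorphism
  calls <- rbind(groupA, groupB)
  dimnames(calls) <- list(c(sprintf("a%d", 1:6), sprintf("b%d", 1:6)),
                          sprintf("m%02d", 1:m))
  gg <- genotype_matrix(calls)
  rk_b <- group_restricted_ranking(gg, sprintf("b%d", 1:6))
  # b6 is never removed: it survives to the final retained pair
  expect_lte(rk_b$ranking$rank[rk_b$ranking$accession == "b6"], 2)
  expect_true(is.na(rk_b$ranking$removal_step[rk_b$ranking$accession == "b6"]))
  # rankings of disjoint groups do not depend on each other's data
  rk_b_alone <- rank_accessions(gg[sprintf("b%d", 1:6), ])
  expect_identical(rk_b$ranking, rk_b_alone$ranking)

  expect_error(group_restricted_ranking(gg, c("b1", "b2")), ">= 3")
})

test_that("tidy and glance summarize rankings", {
  rk <- rank_accessions(pic_example())
  td <- tidy(rk)
  expect_equal(nrow(td), 4)
  gl <- glance(rk)
  expect_equal(gl$peak_size, 4)
  expect_equal(gl$pic_form, "gene-diversity")
})
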