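test_that("map markers are apportioned by chromosome length and sorted", {
  cfg <- sim_config(n_markers = 700, seed = 2)
  map <- sim_genetic_map(cfg)
  counts <- table(map$chrom)
  expect_equal(sum(counts), 700)
  # proportional to length: each chromosome near 700 * len / 1113
  expected <- 700 * cfg$chrom_lengths_cM / sum(cfg$chrom_lengths_cM)
  expect_true(all(abs(as.numeric(counts) - expected) <= 1))
  # sorted ascending within chromosome, inside [0, length]
  by_chr <- split(map$cM, map$chrom)
  for (c in seq_along(by_chr)) {
    expect_true(all(diff(by_chr[[c]]) >= 0))
    expect_true(all(by_chr[[c]] >= 0 & by_chr[[c]] <= cfg$chrom_lengths_cM[c]))
  }

  tiny <- sim_config(n_chromosomes = 1, chrom_lengths_cM = 100, n_markers = 2,
                     seed = 5)
  m2 <- sim_genetic_map(tiny)
  expect_true(all(m2$cM >= 0 & m2$cM <= 100))
  expect_true(diff(m2$cM) >= 0)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_markers = 120, seed = 9, duplicate_sets = c(2L),
                    qtl_spec = data.frame(marker = 10, effect = 1))
  m1 <- sim_genetic_map(cfg)
  m2 <- sim_genetic_map(cfg)
  expect_identical(m1, m2)
  s1 <- sim_genotypes(cfg, m1)
  s2 <- sim_genotypes(cfg, m1)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  expect_identical(s1$truth$Q, s2$truth$Q)
  p1 <- sim_phenotype(s1$genotypes, cfg)
  p2 <- sim_phenotype(s2$genotypes, cfg)
  expect_identical(p1$value, p2$value)
})

test_that("subpopulation allele frequencies recover the Balding-Nichols draws", {
  cfg <- sim_config(
    n_subpops = 2, n_per_subpop = c(200, 200), n_admixed = 0,
    fst_per_subpop = c(0.2, 0.2), n_markers = 300, missing_rate = 0,
    ld_decay_cM = 0, seed = 13
  )
  sim <- sim_genotypes(cfg, sim_genetic_map(cfg))
  truth <- sim$truth
  for (s in 1:2) {
    rows <- names(truth$subpop)[truth$subpop == paste0("pop", s)]
    emp <- colMeans(sim$genotypes$calls[rows, ])
    mae <- mean(abs(emp - truth$subpop_freqs[s, ]))
    expect_lt(mae, 3 / sqrt(200))
  }
})

test_that("planted duplicates are identical at all co-observed markers", {
  cfg <- sim_config(n_per_subpop = c(20, 20), n_subpops = 2,
                    fst_per_subpop = c(0.2, 0.2), n_admixed = 0,
                    n_markers = 150, duplicate_sets = c(3L), seed = 21)
  sim <- sim_genotypes(cfg, sim_genetic_map(cfg))
  ids <- sim$truth$duplicate_sets[[1]]
  expect_length(ids, 3)
  calls <- sim$genotypes$calls[ids, ]
  for (i in 1:2) {
    for (j in (i + 1):3) {
      both <- !is.na(calls[i, ]) & !is.na(calls[j, ])
      expect_true(all(calls[i, both] == calls[j, both]))
    }
  }
})

test_that("zero decay length leaves adjacent pairs at unlinked-level LD", {
  cfg0 <- sim_config(n_subpops = 1, n_per_subpop = 250, n_admixed = 0,
                     fst_per_subpop = 0.2, n_markers = 300, missing_rate = 0,
                     ld_decay_cM = 0, seed = 31)
  sim0 <- sim_genotypes(cfg0, sim_genetic_map(cfg0))
  map <- sim_genetic_map(cfg0)
  ord <- order(map$chrom, map$cM)
  calls <- sim0$genotypes$calls
  adj_r2 <- vapply(seq_len(length(ord) - 1), function(i) {
    a <- map$marker[ord[i]]
    b <- map$marker[ord[i + 1]]
    if (map$chrom[ord[i]] != map$chrom[ord[i + 1]]) return(NA_real_)
    pair_r2(calls[, a], calls[, b])$r2
  }, numeric(1))
  set.seed(1)
  unl <- replicate(250, {
    ab <- sample(ncol(calls), 2)
    pair_r2(calls[, ab[1]], calls[, ab[2]])$r2
  })
  # same order of magnitude: means within a factor-ish band, both ~ 1/n
  expect_lt(abs(mean(adj_r2, na.rm = TRUE) - mean(unl, na.rm = TRUE)), 0.01)
})

test_that("positive decay length creates distance-decaying adjacent LD", {
  mk_sim <- function(lambda) {
    cfg <- sim_config(n_subpops = 1, n_per_subpop = 200, n_admixed = 0,
                      fst_per_subpop = 0.2, n_markers = 400, missing_rate = 0,
                      ld_decay_cM = lambda, seed = 41)
    map <- sim_genetic_map(cfg)
    sim <- sim_genotypes(cfg, map)
    dec <- decay_profile(sim$genotypes, map, max_distance_cM = 1,
                         bin_width_cM = 1, maf_min = 0.05)
    weighted.mean(dec$mean_r2, dec$n_pairs, na.rm = TRUE)
  }
  expect_gt(mk_sim(5), mk_sim(0.1))
})

test_that("phenotype heritability is realized and degenerate cases behave", {
  cfg <- sim_config(n_subpops = 1, n_per_subpop = 500, n_admixed = 0,
                    fst_per_subpop = 0.2, n_markers = 100, missing_rate = 0.02,
                    qtl_spec = data.frame(marker = 50, effect = 1),
                    heritability = 0.5, seed = 17)
  sim <- sim_genotypes(cfg, sim_genetic_map(cfg))
  ph <- sim_phenotype(sim$genotypes, cfg)
  g <- attr(ph, "genetic_values")
  ratio <- var(g) / var(ph$value)
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.6)

  # zero heritability: pure noise, no genetic component
  cfg0 <- sim_config(n_subpops = 1, n_per_subpop = 100, n_admixed = 0,
                     fst_per_subpop = 0.2, n_markers = 50,
                     heritability = 0, seed = 18)
  sim0 <- sim_genotypes(cfg0, sim_genetic_map(cfg0))
  ph0 <- sim_phenotype(sim0$genotypes, cfg0)
  expect_true(all(attr(ph0, "genetic_values") == 0))

  # binary thresholding at the median gives a balanced 0/1 trait
  phb <- sim_phenotype(sim0$genotypes, cfg0, binary = TRUE)
  expect_setequal(unique(phb$value), c(0, 1))
  expect_equal(sum(phb$value), 50)

  expect_error(
    sim_config(n_subpops = 1, n_per_subpop = 10, n_admixed = 0,
               fst_per_subpop = 0.2, n_markers = 20,
               qtl_spec = data.frame(marker = 1, effect = 1),
               heritability = 1, seed = 1),
    "heritability"
  )
  expect_error(
    sim_config(n_subpops = 1, n_per_subpop = 10, n_admixed = 0,
               fst_per_subpop = 1.2, n_markers = 20, seed = 1),
    "fst"
  )
})
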