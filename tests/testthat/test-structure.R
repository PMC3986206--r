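test_that("PCA separates strongly diverged subpopulations on PC1", {
  cfg <- sim_config(
    n_subpops = 2, n_per_subpop = c(40, 40), n_admixed = 0,
    fst_per_subpop = c(0.9, 0.9), n_markers = 300, missing_rate = 0.02,
    seed = 5
  )
  sim <- sim_genotypes(cfg, sim_genetic_map(cfg))
  pca <- pca_genotypes(sim$genotypes, n_components = 4)
  pc1 <- pca$scores$PC1
  grp <- sim$truth$subpop
  a <- pc1[grp == "pop1"]
  b <- pc1[grp == "pop2"]
  # zero overlap of scores between the two groups
  expect_true(max(a) < min(b) || max(b) < min(a))
  # variance fractions non-increasing and summing below 1
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  expect_lte(sum(pca$var_explained), 1)
})

test_that("PCA scores are invariant to accession order and duplicate rows coincide", {
  cfg <- sim_config(n_subpops = 2, n_per_subpop = c(25, 25), n_admixed = 0,
                    fst_per_subpop = c(0.3, 0.3), n_markers = 200,
                    missing_rate = 0, seed = 6)
  sim <- sim_genotypes(cfg, sim_genetic_map(cfg))
  g <- sim$genotypes
  pca <- pca_genotypes(g, 3)
  perm <- sample(nrow(g$calls))
  pca_p <- pca_genotypes(g[perm, ], 3)
  joined <- merge(pca$scores, pca_p$scores, by = "accession")
  expect_equal(joined$PC1.x, joined$PC1.y, tolerance = 1e-8)
  expect_equal(joined$PC2.x, joined$PC2.y, tolerance = 1e-8)

  # duplicated accession rows receive identical scores
  calls <- rbind(g$calls, dup1 = g$calls[1, ])
  rownames(calls) <- c(rownames(g$calls), "dup1")
  pca_d <- pca_genotypes(genotype_matrix(calls), 3)
  s <- pca_d$scores
  expect_equal(
    as.numeric(s[s$accession == "dup1", -1]),
    as.numeric(s[s$accession == rownames(g$calls)[1], -1]),
    tolerance = 1e-8
  )
})

test_that("an all-identical matrix has no variance beyond the first component", {
  calls <- matrix(rep(c(0, 1, 0, 1, 1), each = 6), 6, 5)
  dimnames(calls) <- list(paste0("a", 1:6), paste0("m", 1:5))
  pca <- pca_genotypes(genotype_matrix(calls), 2, maf_min = 0)
  expect_true(all(is.na(pca$var_explained) | pca$var_explained < 1e-12))
})

test_that("Evanno delta-k matches the hand example and its conventions", {
  base <- c(-1000, -900, -880, -875)
  lnpd <- tidyr::expand_grid(k = 1:4, run = 1:3)
  lnpd$lnpd <- base[lnpd$k] + c(-10, 0, 10)[lnpd$run]
  dk <- evanno_delta_k(lnpd)
  expect_equal(dk$k, c(2, 3))
  expect_equal(dk$delta_k[dk$k == 2], 8.0)

  # linear series: all interior delta-k are zero
  lin <- tidyr::expand_grid(k = 1:5, run = 1:3)
  lin$lnpd <- -1000 + 50 * lin$k + c(-5, 0, 5)[lin$run]
  expect_true(all(evanno_delta_k(lin)$delta_k == 0))

  # zero run-sd with a nonzero second difference flags infinite
  flat <- tidyr::expand_grid(k = 1:4, run = 1:3)
  flat$lnpd <- base[flat$k]
  dk0 <- evanno_delta_k(flat)
  expect_true(is.infinite(dk0$delta_k[dk0$k == 2]))

  expect_error(evanno_delta_k(data.frame(k = c(1, 1, 1, 2, 2, 2),
                                         run = rep(1:3, 2),
                                         lnpd = rnorm(6))), ">= 3 k")
  expect_error(evanno_delta_k(data.frame(k = rep(c(1, 2, 4), each = 3),
                                         run = rep(1:3, 3),
                                         lnpd = rnorm(9))), "contiguous")
})

test_that("delta-k peaks at the knee of a piecewise-linear LnP(D) series", {
  for (seed in 1:5) {
    set.seed(seed)
    k_true <- sample(3:8, 1)
    ks <- 1:10
    slope_hi <- 100
    slope_lo <- 10
    mean_l <- -2000 + cumsum(ifelse(ks <= k_true, slope_hi, slope_lo))
    lnpd <- tidyr::expand_grid(k = ks, run = 1:5)
    lnpd$lnpd <- mean_l[lnpd$k] + rnorm(nrow(lnpd), sd = 2)
    dk <- evanno_delta_k(lnpd)
    expect_equal(dk$k[which.max(dk$delta_k)], k_true)
  }
})

test_that("membership assignment uses a strict 0.8 threshold", {
  q <- tibble::tibble(
    accession = c("a", "b", "c"),
    pop1 = c(0.85, 0.80, 1),
    pop2 = c(0.10, 0.20, 0),
    pop3 = c(0.05, 0.00, 0)
  )
  lab <- assign_subpopulations(q, threshold = 0.8)
  expect_equal(lab$label, c("pop1", "admixed", "pop1"))

  # rows must sum to one
  bad <- tibble::tibble(accession = "x", pop1 = 0.7, pop2 = 0.2)
  expect_error(assign_subpopulations(bad), "sum to 1")
})

test_that("assignment recovers generating labels for pure accessions", {
  cfg <- sim_config(n_markers = 50, n_admixed = 40, seed = 23)
  sim <- sim_genotypes(cfg, sim_genetic_map(cfg))
  lab <- assign_subpopulations(sim$truth$Q)
  truth <- sim$truth$subpop
  pure <- truth != "admixed"
  expect_equal(lab$label[pure], unname(truth[pure]))
  # Dirichlet rows with max coefficient <= 0.8 all land in "admixed"
  mx <- apply(sim$truth$Q, 1, max)
  expect_true(all(lab$label[mx <= 0.8] == "admixed"))
})

test_that("bin thinning keeps the least-missing marker per identical position", {
  calls <- matrix(c(0, 1, NA, 1, 0, 1, 0, NA), 2, 4)
  g <- gm(calls)
  map <- tibble::tibble(
    marker = paste0("m", 1:4),
    chrom = "chr1",
    cM = c(5, 5, 9, 9)
  )
  kept <- thin_one_per_bin(g, map)
  expect_setequal(kept, c("m1", "m3"))
})
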