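test_that("kinship reproduces the single-marker worked example", {
  g <- gm(matrix(c(0, 1), 2, 1), ids = c("a", "b"))
  K <- kinship(g, maf_min = 0)
  expect_equal(unclass(K)[1:2, 1:2],
               matrix(c(1, -1, -1, 1), 2, dimnames = list(c("a", "b"), c("a", "b"))))
})

test_that("kinship is invariant to marker order and duplication, and mirrors duplicates", {
  set.seed(12)
  calls <- matrix(rbinom(400, 1, 0.5), 20, 20)
  calls[sample(length(calls), 20)] <- NA
  g <- gm(calls)
  calls <- g$calls
  K <- kinship(g)
  strip <- function(k) {
    k <- unclass(k)
    attr(k, "n_markers") <- NULL
    attr(k, "maf_min") <- NULL
    k
  }
  # marker order permutation
  perm <- sample(20)
  K_p <- kinship(g[, perm])
  expect_equal(strip(K), strip(K_p), tolerance = 1e-12)
  # doubling all markers leaves K unchanged
  doubled <- cbind(calls, calls)
  colnames(doubled) <- paste0("m", 1:40)
  K_d <- kinship(genotype_matrix(doubled))
  expect_equal(strip(K), strip(K_d), tolerance = 1e-12)
  # duplicated accessions: identical rows, mutual entry equals diagonal
  dup <- rbind(calls, calls[1, , drop = FALSE])
  rownames(dup) <- c(rownames(calls), "dup")
  K2 <- unclass(kinship(genotype_matrix(dup)))
  expect_equal(unname(K2["dup", ]), unname(K2["a1", ]))
  expect_equal(K2["dup", "a1"], K2["dup", "dup"])
  # symmetric, PSD within tolerance
  expect_equal(K2, t(K2))
  ev <- eigen(K2, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-8 * max(ev)))
})

test_that("two diverged groups show higher within- than between-group kinship", {
  cfg <- sim_config(n_subpops = 2, n_per_subpop = c(25, 25), n_admixed = 0,
                    fst_per_subpop = c(0.4, 0.4), n_markers = 800,
                    missing_rate = 0, ld_decay_cM = 0, seed = 14)
  sim <- sim_genotypes(cfg, sim_genetic_map(cfg))
  K <- unclass(kinship(sim$genotypes))
  grp <- sim$truth$subpop
  within <- c(K[grp == "pop1", grp == "pop1"][upper.tri(diag(25))],
              K[grp == "pop2", grp == "pop2"][upper.tri(diag(25))])
  between <- K[grp == "pop1", grp == "pop2"]
  expect_gt(min(within), max(between))
})

test_that("identity kinship without Q reduces the MLM to per-marker OLS", {
  set.seed(15)
  n <- 60
  calls <- matrix(rbinom(n * 30, 1, 0.5), n, 30)
  dimnames(calls) <- list(sprintf("a%02d", 1:n), sprintf("m%02d", 1:30))
  g <- genotype_matrix(calls)
  y <- rnorm(n) + 0.8 * calls[, 5]
  ph <- tibble::tibble(accession = rownames(calls), value = y)
  K <- diag(n)
  dimnames(K) <- list(rownames(calls), rownames(calls))
  res <- mlm_scan(g, ph, Q = NULL, K = K)
  ols_p <- vapply(res$marker, function(m) {
    summary(lm(y ~ calls[, m]))$coefficients[2, 4]
  }, numeric(1))
  expect_equal(res$p, unname(ols_p), tolerance = 1e-6)
})

test_that("the scan recovers a strong planted QTL and reports minor-allele effects", {
  cfg <- sim_config(
    n_per_subpop = c(30, 30, 30, 30, 30), n_admixed = 50, n_markers = 300,
    qtl_spec = data.frame(marker = 150, effect = 1.5), heritability = 0.5,
    seed = 16
  )
  map <- sim_genetic_map(cfg)
  sim <- sim_genotypes(cfg, map)
  ph <- sim_phenotype(sim$genotypes, cfg)
  res <- mlm_scan(sim$genotypes, ph, Q = sim$truth$Q)
  qtl <- sim$truth$qtl_markers
  expect_equal(res$marker[which.min(res$p)], qtl)
  expect_true(res$q[res$marker == qtl] < 0.05)
  expect_true(all(res$q >= res$p, na.rm = TRUE))
  # glance carries variance components and inflation factor
  gl <- glance(res)
  expect_true(gl$sigma_g2 >= 0 && gl$sigma_e2 >= 0)
  expect_true(is.finite(gl$lambda_gc))
})

test_that("BH adjustment matches the hand example and the step-up oracle", {
  expect_equal(bh_fdr(c(0.005, 0.03, 0.04)), c(0.015, 0.04, 0.04))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.02), 0.02)
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("manhattan tables order deterministically and flag strictly", {
  res <- tibble::tibble(
    marker = c("m1", "m2", "m3", "m4"),
    p = c(0.001, 0.02, 0.5, 0.04),
    q = c(0.004, 0.05, 0.8, 0.08)
  )
  map <- tibble::tibble(
    marker = c("m2", "m1", "m3"),
    chrom = c("chr1", "chr1", "chr2"),
    cM = c(5, 5, 1)
  )
  mt <- manhattan_table(res, map)
  # q = 0.05 exactly is NOT significant (strict <)
  expect_false(mt$significant[mt$marker == "m2"])
  expect_true(mt$significant[mt$marker == "m1"])
  # position tie on chr1 at 5 cM broken by marker id
  chr1 <- mt$marker[mt$chrom == "chr1" & !is.na(mt$chrom)]
  expect_equal(chr1, c("m1", "m2"))
  # unmapped marker emitted last and flagged
  expect_equal(mt$marker[nrow(mt)], "m4")
  expect_false(mt$mapped[nrow(mt)])
  # empty input keeps the schema
  mt0 <- manhattan_table(res[0, ], map)
  expect_equal(nrow(mt0), 0)
  expect_true(all(c("chrom", "cM", "significant") %in% names(mt0)))
})
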