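#' Simulate a genetic map
#'
#' Markers are distributed across chromosomes proportionally to chromosome
#' length (largest-remainder apportionment, so counts sum exactly to
#' `n_markers`) and placed uniformly at random along each chromosome, sorted
#' within chromosome.
#'
#' @param config a [sim_config()].
#' @return A tibble (genetic map) with columns `marker`, `chrom`, `cM`,
#'   ordered by chromosome then position.
#' @examples
#' map <- sim_genetic_map(sim_config(n_markers = 70, seed = 1))
#' dplyr::count(map, chrom)
#' @export
sim_genetic_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  len <- config$chrom_lengths_cM
  m <- config$n_markers
  quota <- m * len / sum(len)
  n_chr <- floor(quota)
  rem <- m - sum(n_chr)
  if (rem > 0) {
    extra <- order(quota - n_chr, decreasing = TRUE)[seq_len(rem)]
    n_chr[extra] <- n_chr[extra] + 1
  }
  purrr::map_dfr(seq_along(len), function(c) {
    pos <- sort(runif(n_chr[c], 0, len[c]))
    tibble(
      chrom = paste0("chr", c),
      cM = pos
    )
  }) |>
    dplyr::mutate(marker = sprintf("M%04d", dplyr::row_number()), .before = 1)
}

# Dirichlet draws via normalized gammas
rdirichlet <- function(n, alpha, k) {
  x <- matrix(rgamma(n * k, shape = alpha), nrow = n)
  x / rowSums(x)
}

#' Simulate structured genotypes
#'
#' Generates an accessions x markers biallelic call matrix under the
#' Balding-Nichols model: per marker an ancestral frequency is drawn uniformly
#' from `ancestral_maf_range`; each subpopulation's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with that subpopulation's F. Pure accessions
#' carry degenerate ancestry rows, admixed accessions symmetric Dirichlet
#' rows; each call is allele 1 with probability `sum_k q_ik p_kj`. Linkage
#' disequilibrium is imposed by a first-order copy chain along each
#' chromosome: with probability `exp(-d/lambda)` (d = adjacent map distance) a
#' call copies the same accession's call at the previous marker. Planted
#' duplicates are row copies made before missingness, so each copy receives
#' independent missing calls; missing entries are then set independently at
#' `missing_rate`.
#'
#' @param config a [sim_config()].
#' @param map a genetic map from [sim_genetic_map()] (one row per marker of
#'   `config`).
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `truth`, a list carrying `Q` (true ancestry matrix, rows sum to 1),
#'   `subpop` (generating subpopulation label or `"admixed"`),
#'   `duplicate_sets` (list of accession-id character vectors),
#'   `subpop_freqs` (k x markers matrix of subpopulation allele frequencies)
#'   and `qtl_markers`.
#' @examples
#' cfg <- sim_config(
#'   n_subpops = 2, n_per_subpop = c(20, 20), n_admixed = 0,
#'   n_markers = 50, seed = 3
#' )
#' sim <- sim_genotypes(cfg, sim_genetic_map(cfg))
#' sim$genotypes
#' @export
sim_genotypes <- function(config, map) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(map) != config$n_markers) {
    abort("map must have one row per configured marker")
  }
  set.seed(config$seed + 1L)
  k <- config$n_subpops
  m <- config$n_markers
  n_pure <- sum(config$n_per_subpop)
  n <- n_pure + config$n_admixed

  p_anc <- runif(m, config$ancestral_maf_range[1], config$ancestral_maf_range[2])
  freqs <- matrix(NA_real_, k, m)
  for (s in seq_len(k)) {
    f <- config$fst_per_subpop[s]
    freqs[s, ] <- rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  }

  Q <- matrix(0, n, k)
  subpop <- character(n)
  row <- 1L
  for (s in seq_len(k)) {
    ns <- config$n_per_subpop[s]
    if (ns > 0) {
      Q[row:(row + ns - 1L), s] <- 1
      subpop[row:(row + ns - 1L)] <- paste0("pop", s)
      row <- row + ns
    }
  }
  if (config$n_admixed > 0) {
    Q[row:n, ] <- rdirichlet(config$n_admixed, config$dirichlet_alpha, k)
    subpop[row:n] <- "admixed"
  }

  prob <- Q %*% freqs # n x m per-call allele-1 probabilities

  # copy chain within chromosomes, in map order
  calls <- matrix(NA_real_, n, m)
  ord <- order(map$chrom, map$cM)
  prev_idx <- NA_integer_
  prev_chrom <- ""
  for (jj in seq_len(m)) {
    j <- ord[jj]
    fresh <- as.numeric(runif(n) < prob[, j])
    if (identical(map$chrom[j], prev_chrom) && config$ld_decay_cM > 0) {
      d <- map$cM[j] - map$cM[prev_idx]
      copy <- runif(n) < exp(-d / config$ld_decay_cM)
      calls[, j] <- ifelse(copy, calls[, prev_idx], fresh)
    } else {
      calls[, j] <- fresh
    }
    prev_idx <- j
    prev_chrom <- map$chrom[j]
  }

  acc_ids <- sprintf("ACC%04d", seq_len(n))
  # planted duplicates: copy source rows (before missingness)
  dup_sets <- list()
  if (length(config$duplicate_sets) > 0) {
    sources <- seq_along(config$duplicate_sets)
    if (max(sources) > n) abort("not enough accessions to seed duplicate sets")
    extra <- list()
    extra_ids <- character()
    copy_no <- 0L
    for (i in seq_along(config$duplicate_sets)) {
      size <- config$duplicate_sets[i]
      src <- sources[i]
      ids <- acc_ids[src]
      for (cpy in seq_len(size - 1L)) {
        copy_no <- copy_no + 1L
        id <- sprintf("DUP%04d", copy_no)
        extra[[length(extra) + 1L]] <- calls[src, ]
        extra_ids <- c(extra_ids, id)
        ids <- c(ids, id)
      }
      dup_sets[[i]] <- ids
    }
    calls <- rbind(calls, do.call(rbind, extra))
    acc_ids <- c(acc_ids, extra_ids)
    Q <- rbind(Q, Q[rep(sources, config$duplicate_sets - 1L), , drop = FALSE])
    subpop <- c(subpop, subpop[rep(sources, config$duplicate_sets - 1L)])
  }

  if (config$missing_rate > 0) {
    miss <- matrix(runif(length(calls)) < config$missing_rate, nrow(calls))
    calls[miss] <- NA_real_
  }

  dimnames(calls) <- list(acc_ids, map$marker)
  rownames(Q) <- acc_ids
  colnames(Q) <- paste0("pop", seq_len(k))
  colnames(freqs) <- map$marker
  rownames(freqs) <- paste0("pop", seq_len(k))

  qtl <- if (!is.null(config$qtl_spec)) map$marker[config$qtl_spec$marker] else character()

  list(
    genotypes = genotype_matrix(calls),
    truth = list(
      Q = Q,
      subpop = setNames(subpop, acc_ids),
      duplicate_sets = dup_sets,
      subpop_freqs = freqs,
      qtl_markers = qtl
    )
  )
}

#' Simulate a phenotype with planted QTL
#'
#' Builds `y = sum_j effect_j * call_j + e`, with missing calls imputed to the
#' marker mean (for simulation only) and the residual variance chosen so that
#' the realized genetic variance over total variance equals `heritability`.
#' With no QTL (or zero heritability) the phenotype is pure standard-normal
#' noise.
#'
#' @param genotypes a [genotype_matrix()].
#' @param config a [sim_config()] carrying `qtl_spec` and `heritability`.
#' @param binary if TRUE, threshold the latent value at its median to give a
#'   0/1 trait.
#' @return A tibble with columns `accession`, `value` and (attribute
#'   `genetic_values`) the latent genetic component.
#' @export
sim_phenotype <- function(genotypes, config, binary = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- nrow(genotypes$calls)
  h2 <- config$heritability
  spec <- config$qtl_spec
  if (is.null(spec) || nrow(spec) == 0 || h2 == 0) {
    g <- rep(0, n)
  } else {
    qtl_ids <- markers(genotypes)[spec$marker]
    if (anyNA(qtl_ids)) abort("qtl markers not present in genotype matrix")
    X <- genotypes$calls[, qtl_ids, drop = FALSE]
    mu <- colMeans(X, na.rm = TRUE)
    for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
    g <- drop(X %*% spec$effect)
  }
  vg <- var(g)
  if (vg > 0 && h2 > 0) {
    ve <- vg * (1 - h2) / h2
    y <- g + rnorm(n, sd = sqrt(ve))
  } else {
    y <- g + rnorm(n)
  }
  if (binary) y <- as.numeric(y > median(y))
  out <- tibble(accession = accessions(genotypes), value = y)
  attr(out, "genetic_values") <- g
  out
}
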