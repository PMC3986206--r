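#' Genomic kinship matrix
#'
#' Centered cross-product relationship matrix on inbred 0/1 calls: with
#' missing calls mean-imputed and `p_m` the allele-1 frequency of marker m,
#' `W = X - p` and `K = W W' / sum_m p_m (1 - p_m)`. Markers below the MAF
#' floor are excluded.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min MAF floor for markers entering the kinship.
#' @return A symmetric accessions x accessions matrix of class
#'   `kinship_matrix` with attributes `n_markers` and `maf_min`.
#' @export
kinship <- function(g, maf_min = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g$calls) < 2) abort("need >= 2 accessions for kinship")
  keep <- maf_filter_markers(g, maf_min)
  X <- g$calls[, keep, drop = FALSE]
  p <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- p[j]
  W <- sweep(X, 2, p)
  K <- tcrossprod(W) / sum(p * (1 - p))
  attr(K, "n_markers") <- length(keep)
  attr(K, "maf_min") <- maf_min
  class(K) <- c("kinship_matrix", class(K))
  K
}

# REML profile over delta = sigma_e^2 / sigma_g^2 on the eigenbasis of K.
# s: eigenvalues of K; Uty, UtX: rotated response and fixed-effect design.
reml_delta <- function(s, Uty, UtX, interval = c(-10, 10)) {
  n <- length(Uty)
  p <- ncol(UtX)
  nll <- function(logd) {
    delta <- exp(logd)
    w <- 1 / (s + delta)
    XtWX <- crossprod(UtX * w, UtX)
    XtWy <- crossprod(UtX * w, Uty)
    beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
    if (is.null(beta)) return(1e10)
    r <- Uty - drop(UtX %*% beta)
    rss <- sum(r^2 * w)
    sigma_g2 <- rss / (n - p)
    0.5 * ((n - p) * log(sigma_g2) - sum(log(w)) +
      determinant(XtWX, logarithm = TRUE)$modulus[1] + (n - p))
  }
  opt <- optimize(nll, interval)
  delta <- exp(opt$minimum)
  w <- 1 / (s + delta)
  XtWX <- crossprod(UtX * w, UtX)
  beta <- solve(XtWX, crossprod(UtX * w, Uty))
  r <- Uty - drop(UtX %*% beta)
  sigma_g2 <- sum(r^2 * w) / (n - p)
  list(delta = delta, sigma_g2 = sigma_g2, sigma_e2 = sigma_g2 * delta,
       reml = -nll(opt$minimum))
}

#' Q+K mixed-linear-model association scan
#'
#' Single-marker GWAS under `y = mu + Q* alpha + x beta + u + e` with
#' `u ~ (0, sigma_g^2 K)` and `e ~ (0, sigma_e^2 I)`. `Q*` is the membership
#' matrix with its last column dropped (rows sum to one, so the full matrix
#' is collinear with the intercept). Variance components are estimated once
#' by REML on the no-marker model via the eigendecomposition of K
#' (population parameters previously determined, as in EMMAX/P3D); each
#' marker is then tested by generalized least squares with a Wald t-test.
#' Missing genotypes are mean-imputed per marker; effects are reported for
#' the minor allele.
#'
#' @param g a [genotype_matrix()].
#' @param phenotype data frame with columns `accession`, `value` (binary
#'   traits coded 0/1 are fitted as quantitative responses).
#' @param Q optional membership matrix / tibble (see
#'   [assign_subpopulations()] input conventions); NULL fits without
#'   structure covariates.
#' @param K optional [kinship()] matrix; NULL computes it from `g` at
#'   `kinship_maf`. Pass `diag(n)` (accession-named) for an unstructured
#'   model.
#' @param maf_min markers below this MAF are not tested.
#' @param kinship_maf MAF floor used when K is computed internally.
#' @param per_marker_reml re-estimate variance components for every marker
#'   (slower; default is the one-time P3D estimate).
#' @return A `gwas_scan` tibble: `marker`, `maf`, `minor_allele`, `effect`
#'   (minor-allele effect), `se`, `p`, `q` (BH-adjusted), `neg_log10_q`;
#'   variance components and the REML fit are attached as attributes.
#' @export
mlm_scan <- function(g, phenotype, Q = NULL, K = NULL, maf_min = 0.01,
                     kinship_maf = 0.01, per_marker_reml = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  stopifnot(all(c("accession", "value") %in% names(phenotype)))
  acc <- intersect(accessions(g), phenotype$accession)
  if (!is.null(Q)) {
    qm <- as_q_matrix(Q)
    acc <- intersect(acc, rownames(qm))
  }
  if (!is.null(K)) acc <- intersect(acc, rownames(K))
  g <- g[acc, ]
  y <- phenotype$value[match(acc, phenotype$accession)]
  if (anyNA(y)) {
    keep <- !is.na(y)
    acc <- acc[keep]
    g <- g[acc, ]
    y <- y[keep]
  }
  if (var(y) == 0) abort("phenotype is constant")
  n <- length(acc)
  if (is.null(K)) K <- kinship(g, maf_min = kinship_maf)
  Km <- unclass(K)[acc, acc]
  X0 <- matrix(1, n, 1)
  colnames(X0) <- "(Intercept)"
  if (!is.null(Q)) {
    qm <- qm[acc, , drop = FALSE]
    Qstar <- qm[, -ncol(qm), drop = FALSE] # drop last column (collinearity)
    # drop any additionally collinear columns
    Xtry <- cbind(X0, Qstar)
    qrX <- qr(Xtry)
    if (qrX$rank < ncol(Xtry)) {
      drop_cols <- qrX$pivot[(qrX$rank + 1):ncol(Xtry)]
      inform(sprintf("dropping %d collinear structure covariate(s)",
                     length(drop_cols)))
      Xtry <- Xtry[, -drop_cols, drop = FALSE]
    }
    X0 <- Xtry
  }
  eig <- eigen(Km, symmetric = TRUE)
  s <- pmax(eig$values, 0)
  U <- eig$vectors
  Uty <- drop(crossprod(U, y))
  UtX0 <- crossprod(U, X0)
  vc <- reml_delta(s, Uty, UtX0)
  if (!is.finite(vc$delta)) abort("REML did not converge for the null model")

  af <- allele_frequencies(g)
  test_mk <- af$marker[!af$no_calls & af$maf >= maf_min & af$maf > 0]
  Xg <- g$calls[, test_mk, drop = FALSE]
  p_hat <- colMeans(Xg, na.rm = TRUE)
  na_idx <- which(is.na(Xg))
  if (length(na_idx) > 0) {
    Xg[na_idx] <- p_hat[((na_idx - 1) %/% nrow(Xg)) + 1]
  }
  UtXg <- crossprod(U, Xg)

  if (!per_marker_reml) {
    w <- 1 / (s + vc$delta)
    sw <- sqrt(w)
    A <- UtX0 * sw
    ym <- Uty * sw
    M <- UtXg * sw
    qrA <- qr(A)
    ymr <- qr.resid(qrA, ym)
    Mr <- qr.resid(qrA, M)
    sxx <- colSums(Mr^2)
    sxy <- drop(crossprod(Mr, ymr))
    beta <- ifelse(sxx > 1e-12, sxy / sxx, NA_real_)
    df <- n - ncol(A) - 1
    rss <- sum(ymr^2) - ifelse(is.na(beta), 0, beta^2 * sxx)
    se <- sqrt(pmax(rss, 0) / df / sxx)
    tstat <- beta / se
    pval <- 2 * pt(-abs(tstat), df)
  } else {
    beta <- se <- pval <- rep(NA_real_, length(test_mk))
    for (j in seq_along(test_mk)) {
      vcj <- reml_delta(s, Uty, cbind(UtX0, UtXg[, j]))
      w <- 1 / (s + vcj$delta)
      Xj <- cbind(UtX0, UtXg[, j]) * sqrt(w)
      fit <- lm.wfit(x = Xj, y = Uty * sqrt(w), w = rep(1, n))
      cf <- length(fit$coefficients)
      r <- fit$residuals
      df <- n - cf
      sig <- sum(r^2) / df
      XtX_inv <- chol2inv(qr.R(fit$qr))
      se[j] <- sqrt(sig * XtX_inv[cf, cf])
      beta[j] <- fit$coefficients[cf]
      pval[j] <- 2 * pt(-abs(beta[j] / se[j]), df)
    }
  }

  freq1 <- af$freq1[match(test_mk, af$marker)]
  minor_is_1 <- freq1 <= 0.5
  out <- tibble(
    marker = test_mk,
    maf = pmin(freq1, 1 - freq1),
    minor_allele = ifelse(minor_is_1, "1", "0"),
    effect = unname(ifelse(minor_is_1, beta, -beta)),
    se = unname(se),
    p = unname(pval),
    q = bh_fdr(pval),
    neg_log10_q = -log10(bh_fdr(pval))
  )
  attr(out, "variance_components") <- vc
  attr(out, "n_accessions") <- n
  chisq <- qchisq(1 - pval, df = 1)
  attr(out, "lambda_gc") <- median(chisq, na.rm = TRUE) / qchisq(0.5, df = 1)
  class(out) <- c("gwas_scan", class(out))
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`q`-values): `q_(i) = min_{j >= i} m p_(j) / j`,
#' capped at 1, returned in the original order. NAs are preserved and do not
#' count toward m.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return The adjusted q-values.
#' @examples
#' bh_fdr(c(0.005, 0.03, 0.04)) # 0.015 0.040 0.040
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Manhattan-ready association table
#'
#' Joins scan results to the genetic map, orders deterministically by
#' chromosome then position (position ties broken by marker id), flags
#' significance at strict `q < alpha`, and places unmapped markers last with
#' missing positions.
#'
#' @param results a [mlm_scan()] result (or any tibble with `marker` and
#'   `q`).
#' @param map genetic map tibble.
#' @param alpha significance level on the q scale (strict inequality).
#' @return A tibble ordered by `chrom`, `cM`, `marker` with columns from
#'   `results` plus `chrom`, `cM`, `neg_log10_q`, `significant`, `mapped`.
#' @export
manhattan_table <- function(results, map, alpha = 0.05) {
  out <- results |>
    dplyr::left_join(map[, c("marker", "chrom", "cM")], by = "marker") |>
    dplyr::mutate(
      neg_log10_q = -log10(.data$q),
      significant = !is.na(.data$q) & .data$q < alpha,
      mapped = !is.na(.data$chrom)
    ) |>
    dplyr::arrange(dplyr::desc(.data$mapped), .data$chrom, .data$cM, .data$marker)
  class(out) <- unique(c("gwas_scan", class(out)))
  out
}
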