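# Firth-type penalized logistic regression (Jeffreys-prior score adjustment).
# Returns coefficients and the penalized log-likelihood; used as a fallback
# when the ordinary fit separates or fails to converge.
firth_logistic <- function(X, y, max_iter = 50, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    inv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(inv)) break
    h <- rowSums((X %*% inv) * X) * w # hat-matrix diagonal
    U <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- drop(inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
  w <- mu * (1 - mu)
  XtWX <- crossprod(X * sqrt(w))
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu)) +
    0.5 * determinant(XtWX, logarithm = TRUE)$modulus
  list(beta = unname(beta), loglik = as.numeric(ll))
}

# LRT p for the last column of X (the regressor marker), with Firth fallback
logistic_lrt_p <- function(X, y) {
  fit_full <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())
  )
  fit_null <- suppressWarnings(
    stats::glm.fit(X[, -ncol(X), drop = FALSE], y, family = stats::binomial())
  )
  separated <- !fit_full$converged ||
    any(abs(fit_full$coefficients[ncol(X)]) > 15, na.rm = TRUE) ||
    anyNA(fit_full$coefficients)
  if (!separated) {
    dev_diff <- fit_null$deviance - fit_full$deviance
    return(list(p = pchisq(max(dev_diff, 0), df = 1, lower.tail = FALSE),
                firth = FALSE, converged = TRUE))
  }
  ff <- tryCatch(firth_logistic(X, y), error = function(e) NULL)
  fn <- tryCatch(firth_logistic(X[, -ncol(X), drop = FALSE], y),
                 error = function(e) NULL)
  if (is.null(ff) || is.null(fn)) {
    return(list(p = NA_real_, firth = TRUE, converged = FALSE))
  }
  lrt <- 2 * (ff$loglik - fn$loglik)
  list(p = pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
       firth = TRUE, converged = TRUE)
}

#' Structure-corrected logistic-regression LD scan
#'
#' For each response marker M0 and every regressor marker at a map distance
#' in the half-open window `[window[1], window[2])` cM on the same chromosome
#' (taking M0 as the leftmost marker of each pair so pairs are generated
#' once), fits `allele(M0) ~ intercept + allele(M) + PC1..PCn` by logistic
#' regression on pairwise-complete accessions and reports the
#' likelihood-ratio p-value of the regressor term. With principal components
#' as covariates the p-value measures LD free of the population-structure
#' confound. Pairs that separate fall back to a Firth-type penalized fit
#' (flagged); non-converging pairs are flagged, not fatal.
#'
#' @param g a [genotype_matrix()].
#' @param map genetic map tibble.
#' @param pca a [pca_genotypes()] result (ignored when `n_pcs = 0`).
#' @param n_pcs number of principal-component covariates.
#' @param window numeric `(lo, hi)` distance window in cM.
#' @param maf_min MAF floor.
#' @param neglog10_cap cap on `-log10(p)` to keep output finite.
#' @param pairs optional two-column matrix/data frame of marker ids to test
#'   instead of window enumeration (used e.g. to push unlinked pairs through
#'   the same fitter).
#' @return A tibble: `marker_a` (M0), `marker_b`, `chrom`, `cM_a`, `cM_b`,
#'   `dist_cM`, `n`, `p_logistic`, `neg_log10_p`, `firth`, `converged`.
#' @export
logistic_ld_scan <- function(g, map, pca = NULL, n_pcs = 11,
                             window = c(1, 2), maf_min = 0.05,
                             neglog10_cap = 320, pairs = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (n_pcs > 0) {
    stopifnot(inherits(pca, "pca_result"))
    pcs <- as.matrix(pca$scores[match(accessions(g), pca$scores$accession),
                                paste0("PC", seq_len(n_pcs)), drop = FALSE])
    if (anyNA(pcs)) abort("PCA scores missing for some accessions")
  } else {
    pcs <- matrix(numeric(0), nrow(g$calls), 0)
  }
  keep <- intersect(maf_filter_markers(g, maf_min), map$marker)
  mp <- map |> dplyr::filter(.data$marker %in% keep)
  if (is.null(pairs)) {
    pair_tbl <- purrr::map_dfr(split(mp, mp$chrom), function(mc) {
      mc <- dplyr::arrange(mc, .data$cM)
      m <- nrow(mc)
      if (m < 2) return(tibble())
      pr <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
      # row < col and cM sorted: row marker is the leftmost (M0)
      d <- mc$cM[pr[, 2]] - mc$cM[pr[, 1]]
      sel <- d >= window[1] & d < window[2]
      tibble(
        marker_a = mc$marker[pr[sel, 1]], marker_b = mc$marker[pr[sel, 2]],
        chrom = mc$chrom[1],
        cM_a = mc$cM[pr[sel, 1]], cM_b = mc$cM[pr[sel, 2]],
        dist_cM = d[sel]
      )
    })
  } else {
    pairs <- as.data.frame(pairs)
    pos <- match(pairs[[1]], map$marker)
    pos2 <- match(pairs[[2]], map$marker)
    pair_tbl <- tibble(
      marker_a = pairs[[1]], marker_b = pairs[[2]],
      chrom = ifelse(map$chrom[pos] == map$chrom[pos2],
                     map$chrom[pos], NA_character_),
      cM_a = map$cM[pos], cM_b = map$cM[pos2],
      dist_cM = ifelse(map$chrom[pos] == map$chrom[pos2],
                       abs(map$cM[pos2] - map$cM[pos]), NA_real_)
    )
  }
  if (nrow(pair_tbl) == 0) {
    return(tibble(
      marker_a = character(), marker_b = character(), chrom = character(),
      cM_a = numeric(), cM_b = numeric(), dist_cM = numeric(),
      n = integer(), p_logistic = numeric(), neg_log10_p = numeric(),
      firth = logical(), converged = logical()
    ))
  }
  res <- purrr::pmap_dfr(
    pair_tbl[, c("marker_a", "marker_b")],
    function(marker_a, marker_b) {
      y <- g$calls[, marker_a]
      x <- g$calls[, marker_b]
      ok <- !is.na(y) & !is.na(x)
      X <- cbind(1, x[ok], pcs[ok, , drop = FALSE])
      yy <- y[ok]
      # regressor goes last for the LRT helper
      X <- X[, c(1, seq_len(ncol(pcs)) + 2, 2), drop = FALSE]
      if (sum(ok) < ncol(X) + 1 || length(unique(yy)) < 2 ||
          length(unique(x[ok])) < 2) {
        return(tibble(n = sum(ok), p_logistic = NA_real_,
                      firth = FALSE, converged = FALSE))
      }
      fit <- logistic_lrt_p(X, yy)
      tibble(n = sum(ok), p_logistic = fit$p,
             firth = fit$firth, converged = fit$converged)
    }
  )
  dplyr::bind_cols(pair_tbl, res) |>
    dplyr::mutate(
      neg_log10_p = pmin(-log10(.data$p_logistic), neglog10_cap)
    ) |>
    dplyr::relocate("neg_log10_p", .after = "p_logistic")
}
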