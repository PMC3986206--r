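#' Pairwise r-squared between two markers
#'
#' Inbred lines are treated as haplotypes. On pairwise-complete calls with
#' joint frequency `p_AB` and marginals `p_A`, `p_B`:
#' `D = p_AB - p_A p_B` and `r2 = D^2 / (p_A (1-p_A) p_B (1-p_B))`.
#'
#' @param x,y numeric 0/1/NA call vectors of equal length.
#' @return A list with `r2` (NA and `defined = FALSE` if either marker is
#'   monomorphic on the complete subset or fewer than two complete pairs
#'   exist) and `n` (complete pairs used).
#' @examples
#' x <- rep(c(1, 0, 1, 0), c(40, 40, 10, 10))
#' y <- rep(c(1, 0, 0, 1), c(40, 40, 10, 10))
#' pair_r2(x, y)$r2 # 0.36
#' @export
pair_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  x <- x[ok]
  y <- y[ok]
  pa <- mean(x)
  pb <- mean(y)
  if (n < 2 || pa %in% c(0, 1) || pb %in% c(0, 1)) {
    return(list(r2 = NA_real_, n = n, defined = FALSE))
  }
  d <- mean(x * y) - pa * pb
  list(r2 = d^2 / (pa * (1 - pa) * pb * (1 - pb)), n = n, defined = TRUE)
}

#' Two-sided Fisher exact p-value for a marker pair
#'
#' Builds the 2x2 table of joint calls on pairwise-complete data and applies
#' the two-sided exact test (point-probability method: the sum of
#' probabilities of all tables no more likely than the observed one).
#'
#' @param x,y numeric 0/1/NA call vectors.
#' @return The p-value.
#' @export
pair_fisher_p <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  tab <- table(factor(x, levels = c(0, 1)), factor(y, levels = c(0, 1)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate 2x2 table (empty row or column)")
  }
  fisher.test(tab)$p.value
}

# vectorized r2 for many pairs: a, b are column indices into calls
bulk_r2 <- function(calls, a, b) {
  xa <- calls[, a, drop = FALSE]
  xb <- calls[, b, drop = FALSE]
  oa <- !is.na(xa)
  ob <- !is.na(xb)
  ok <- oa & ob
  xa[!ok] <- 0
  xb[!ok] <- 0
  n <- colSums(ok)
  sa <- colSums(xa)
  sb <- colSums(xb)
  sab <- colSums(xa * xb)
  pa <- sa / n
  pb <- sb / n
  d <- sab / n - pa * pb
  den <- pa * (1 - pa) * pb * (1 - pb)
  r2 <- ifelse(n >= 2 & den > 0, d^2 / den, NA_real_)
  list(r2 = unname(r2), n = unname(n))
}

# Box-Cox profile log-likelihood MLE for positive data
boxcox_mle <- function(y, interval = c(-5, 5)) {
  stopifnot(all(y > 0))
  n <- length(y)
  slog <- sum(log(y))
  nll <- function(lambda) {
    z <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
    n / 2 * log(mean((z - mean(z))^2)) - (lambda - 1) * slog
  }
  opt <- optimize(nll, interval)
  opt$minimum
}

boxcox_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
}

boxcox_inverse <- function(z, lambda) {
  if (abs(lambda) < 1e-8) exp(z) else (lambda * z + 1)^(1 / lambda)
}

#' Significance threshold for r-squared from unlinked marker pairs
#'
#' Samples random inter-chromosomal ("unlinked") marker pairs, shifts their
#' r-squared values by a small epsilon, power-transforms them toward
#' normality, and returns the parametric percentile (`mean + z * sd` on the
#' transformed scale, back-transformed) as the r-squared level above which
#' LD is unlikely to arise without linkage.
#'
#' The default exponent is the Wilson-Hilferty cube root: the null
#' distribution of r-squared between unlinked markers on inbred haplotypes
#' is asymptotically chi-squared (1 df) scaled by sample size, and the cube
#' root is the classical normalizing power for that family, which keeps the
#' parametric tail honest. The full Box-Cox maximum-likelihood exponent is
#' available via `transform = "boxcox-mle"`; it optimizes whole-distribution
#' normality rather than tail fit and yields noticeably more conservative
#' thresholds.
#'
#' @param g a [genotype_matrix()] (typically already restricted to the
#'   subpopulation of interest with admixed accessions excluded).
#' @param map genetic map tibble (`marker`, `chrom`, `cM`).
#' @param n_pairs number of random inter-chromosomal pairs to sample.
#' @param percentile parametric percentile for the threshold.
#' @param maf_min MAF floor applied before sampling.
#' @param epsilon shift added to r2 before the power transform (zeros).
#' @param transform `"cube-root"` (default) or `"boxcox-mle"`.
#' @param seed sampling seed.
#' @return A list of class `ld_threshold`: `threshold` (r2 scale), `lambda`
#'   (power-transform exponent), `percentile`, `n_pairs` used, `mean_t`,
#'   `sd_t`, `transform`.
#' @export
unlinked_threshold <- function(g, map, n_pairs = 100000, percentile = 99,
                               maf_min = 0.05, epsilon = 1e-6,
                               transform = c("cube-root", "boxcox-mle"),
                               seed = 1) {
  transform <- match.arg(transform)
  stopifnot(inherits(g, "genotype_matrix"))
  keep <- intersect(maf_filter_markers(g, maf_min), map$marker)
  chrom <- map$chrom[match(keep, map$marker)]
  if (length(unique(chrom)) < 2) {
    abort("need markers on >= 2 chromosomes for unlinked pairs")
  }
  set.seed(seed)
  idx <- match(keep, markers(g))
  m <- length(idx)
  # rejection-sample inter-chromosomal pairs
  a <- integer(0)
  b <- integer(0)
  while (length(a) < n_pairs) {
    need <- n_pairs - length(a)
    ca <- sample.int(m, need, replace = TRUE)
    cb <- sample.int(m, need, replace = TRUE)
    ok <- chrom[ca] != chrom[cb]
    a <- c(a, ca[ok])
    b <- c(b, cb[ok])
  }
  r2 <- bulk_r2(g$calls, idx[a], idx[b])$r2
  r2 <- r2[!is.na(r2)]
  y <- r2 + epsilon
  lambda <- if (transform == "cube-root") 1 / 3 else boxcox_mle(y)
  z <- boxcox_transform(y, lambda)
  zq <- mean(z) + qnorm(percentile / 100) * sd(z)
  thr <- boxcox_inverse(zq, lambda) - epsilon
  structure(list(
    threshold = min(max(thr, 0), 1),
    lambda = lambda,
    percentile = percentile,
    n_pairs = length(r2),
    mean_t = mean(z),
    sd_t = sd(z),
    transform = transform
  ), class = "ld_threshold")
}

#' @export
print.ld_threshold <- function(x, ...) {
  cat(sprintf(
    "<ld_threshold> r2 > %.4f (parametric %gth percentile, Box-Cox lambda = %.3f, %d unlinked pairs)\n",
    x$threshold, x$percentile, x$lambda, x$n_pairs
  ))
  invisible(x)
}

#' Distance-binned LD decay profile
#'
#' All intra-chromosomal marker pairs within `max_distance_cM` are binned by
#' map distance; mean r-squared and pair counts are reported per chromosome
#' and bin (empty bins appear with `n = 0` and a missing mean).
#'
#' @param g a [genotype_matrix()].
#' @param map genetic map tibble.
#' @param max_distance_cM maximum pair distance considered.
#' @param bin_width_cM bin width.
#' @param maf_min MAF floor.
#' @param threshold optional `ld_threshold` to attach to the result.
#' @return A tibble: `chrom`, `bin_lo`, `bin_mid`, `bin_hi`, `n_pairs`,
#'   `mean_r2`, with the threshold (if given) as an attribute.
#' @export
decay_profile <- function(g, map, max_distance_cM = 20, bin_width_cM = 1,
                          maf_min = 0.05, threshold = NULL) {
  keep <- intersect(maf_filter_markers(g, maf_min), map$marker)
  mp <- map |> dplyr::filter(.data$marker %in% keep)
  bins <- seq(0, max_distance_cM, by = bin_width_cM)
  res <- purrr::map_dfr(split(mp, mp$chrom), function(mc) {
    m <- nrow(mc)
    if (m < 2) {
      return(tibble(chrom = character(), dist = numeric(), r2 = numeric()))
    }
    pr <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    d <- abs(mc$cM[pr[, 1]] - mc$cM[pr[, 2]])
    sel <- d <= max_distance_cM
    if (!any(sel)) {
      return(tibble(chrom = character(), dist = numeric(), r2 = numeric()))
    }
    pr <- pr[sel, , drop = FALSE]
    idx <- match(mc$marker, markers(g))
    r2 <- bulk_r2(g$calls, idx[pr[, 1]], idx[pr[, 2]])$r2
    tibble(chrom = mc$chrom[1], dist = d[sel], r2 = r2)
  })
  grid <- tidyr::expand_grid(
    chrom = sort(unique(mp$chrom)),
    bin_lo = bins[-length(bins)]
  ) |>
    dplyr::mutate(bin_hi = .data$bin_lo + bin_width_cM,
                  bin_mid = .data$bin_lo + bin_width_cM / 2)
  out <- res |>
    dplyr::mutate(bin_lo = bins[pmin(
      findInterval(.data$dist, bins, rightmost.closed = TRUE),
      length(bins) - 1
    )]) |>
    dplyr::group_by(.data$chrom, .data$bin_lo) |>
    dplyr::summarise(
      n_pairs = sum(!is.na(.data$r2)),
      mean_r2 = mean(.data$r2, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::right_join(grid, by = c("chrom", "bin_lo")) |>
    dplyr::mutate(
      n_pairs = tidyr::replace_na(.data$n_pairs, 0L),
      mean_r2 = ifelse(.data$n_pairs == 0, NA_real_, .data$mean_r2)
    ) |>
    dplyr::arrange(.data$chrom, .data$bin_lo) |>
    dplyr::select("chrom", "bin_lo", "bin_mid", "bin_hi", "n_pairs", "mean_r2")
  if (!is.null(threshold)) attr(out, "threshold") <- threshold
  class(out) <- c("ld_decay", class(out))
  out
}
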