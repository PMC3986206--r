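#' Principal component analysis of genotypes
#'
#' Markers below the MAF floor are dropped, missing calls are imputed to the
#' marker mean, columns are centered (no variance scaling — common practice
#' for genotype PCA) and scores are taken from the singular value
#' decomposition. The sign of each component is fixed so that its
#' largest-magnitude marker loading is positive, making scores reproducible
#' across runs and accession orderings.
#'
#' @param g a [genotype_matrix()].
#' @param n_components number of components to return.
#' @param maf_min minimum minor allele frequency for a marker to enter.
#' @return A list of class `pca_result`: `scores` (tibble, `accession` +
#'   `PC1..PCn`), `var_explained` (fractions, non-increasing), `loadings`,
#'   `center` (marker means used), `markers_used`.
#' @export
pca_genotypes <- function(g, n_components = 10, maf_min = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"))
  keep <- maf_filter_markers(g, maf_min)
  if (length(keep) < n_components) {
    abort("fewer markers than requested components after MAF filtering")
  }
  X <- g$calls[, keep, drop = FALSE]
  mu <- colMeans(X, na.rm = TRUE)
  if (anyNA(mu)) abort("marker with no observed calls after MAF filter")
  na_idx <- which(is.na(X))
  if (length(na_idx) > 0) {
    X[na_idx] <- mu[((na_idx - 1) %/% nrow(X)) + 1]
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(pc$x))
  rot <- pc$rotation[, seq_len(nc), drop = FALSE]
  flip <- vapply(seq_len(nc), function(c) {
    sign(rot[which.max(abs(rot[, c])), c])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(nc), drop = FALSE], 2, flip, `*`)
  rot <- sweep(rot, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  out <- list(
    scores = as_tibble(cbind(
      tibble(accession = accessions(g)),
      as.data.frame(scores)
    )),
    var_explained = ve[seq_len(nc)],
    loadings = rot,
    center = mu,
    markers_used = keep
  )
  class(out) <- "pca_result"
  out
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "<pca_result> %d accessions, %d components (%.1f%% variance), %d markers\n",
    nrow(x$scores), length(x$var_explained),
    100 * sum(x$var_explained), length(x$markers_used)
  ))
  invisible(x)
}

#' Evanno delta-k from STRUCTURE log-probability series
#'
#' For each interior k, the second difference `L(k+1) - 2 L(k) + L(k-1)` is
#' computed per run (runs aligned by run index within k), its absolute value
#' averaged across runs, and divided by the standard deviation of `L(k)`
#' across runs. Endpoint k values have no second difference and are omitted.
#' A zero standard deviation with a nonzero second difference yields `Inf`
#' (flagged, not an error).
#'
#' @param lnpd a data frame with columns `k`, `run`, `lnpd`; the k range must
#'   be contiguous with >= 3 values and >= 3 runs per k.
#' @return A tibble with columns `k`, `delta_k`, `sd_lnpd`, `mean_lnpd`.
#' @examples
#' lnpd <- tidyr::expand_grid(k = 1:4, run = 1:3)
#' lnpd$lnpd <- c(-1000, -900, -880, -875)[lnpd$k] + c(-10, 0, 10)[lnpd$run]
#' evanno_delta_k(lnpd) # delta_k at k = 2 is 8
#' @export
evanno_delta_k <- function(lnpd) {
  stopifnot(all(c("k", "run", "lnpd") %in% names(lnpd)))
  ks <- sort(unique(lnpd$k))
  if (length(ks) < 3) abort("need >= 3 k values for delta-k")
  if (!all(diff(ks) == 1)) abort("k range must be contiguous")
  runs_per_k <- table(lnpd$k)
  if (any(runs_per_k < 3)) abort("need >= 3 runs per k")
  if (length(unique(runs_per_k)) != 1) {
    abort("all k values must have the same number of runs")
  }
  wide <- lnpd |>
    dplyr::arrange(.data$k, .data$run) |>
    dplyr::group_by(.data$k) |>
    dplyr::mutate(run_idx = dplyr::row_number()) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(
      id_cols = "run_idx", names_from = "k", values_from = "lnpd"
    )
  L <- as.matrix(wide[, -1]) # runs x k
  interior <- seq(2, length(ks) - 1)
  purrr::map_dfr(interior, function(i) {
    second <- L[, i + 1] - 2 * L[, i] + L[, i - 1]
    s <- sd(L[, i])
    num <- mean(abs(second))
    tibble(
      k = ks[i],
      delta_k = if (s == 0) {
        if (num == 0) 0 else Inf
      } else {
        num / s
      },
      sd_lnpd = s,
      mean_lnpd = mean(L[, i])
    )
  })
}

#' Assign accessions to subpopulations from a membership (Q) matrix
#'
#' An accession is labeled with its arg-max subpopulation when the maximum
#' membership coefficient strictly exceeds `threshold`, otherwise
#' `"admixed"`.
#'
#' @param q a data frame with an `accession` column plus one numeric column
#'   per subpopulation (rows must sum to 1 within 1e-6), or a numeric matrix
#'   with accession rownames.
#' @param threshold membership threshold (strict inequality).
#' @return A tibble with columns `accession`, `label`, `max_membership`.
#' @examples
#' q <- tibble::tibble(accession = c("a", "b"), pop1 = c(0.85, 0.5), pop2 = c(0.15, 0.5))
#' assign_subpopulations(q)
#' @export
assign_subpopulations <- function(q, threshold = 0.8) {
  qm <- as_q_matrix(q)
  mx <- unname(apply(qm, 1, max))
  lab <- colnames(qm)[apply(qm, 1, which.max)]
  tibble(
    accession = rownames(qm),
    label = ifelse(mx > threshold, lab, "admixed"),
    max_membership = mx
  )
}

as_q_matrix <- function(q) {
  if (is.matrix(q)) {
    qm <- q
    if (is.null(colnames(qm))) colnames(qm) <- paste0("pop", seq_len(ncol(qm)))
  } else {
    stopifnot("accession" %in% names(q))
    qm <- as.matrix(q[, setdiff(names(q), "accession"), drop = FALSE])
    rownames(qm) <- q$accession
  }
  if (any(abs(rowSums(qm) - 1) > 1e-6)) {
    abort("membership rows must sum to 1 (tolerance 1e-6)")
  }
  qm
}

#' Read a membership (Q) matrix from TSV
#' @param path TSV with `accession` column plus one column per subpopulation.
#' @return A tibble.
#' @export
read_q_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Thin markers to one per map bin
#'
#' Markers sharing a consensus position (same chromosome and cM, the map's
#' "bin") are reduced to the single least-missing marker, mirroring the
#' one-marker-per-locus thinning used before structure inference.
#'
#' @param g a [genotype_matrix()].
#' @param map genetic map tibble (`marker`, `chrom`, `cM`).
#' @return Character vector of retained marker ids.
#' @export
thin_one_per_bin <- function(g, map) {
  miss <- colMeans(is.na(g$calls))
  map |>
    dplyr::filter(.data$marker %in% markers(g)) |>
    dplyr::mutate(missing = miss[.data$marker]) |>
    dplyr::group_by(.data$chrom, .data$cM) |>
    dplyr::slice_min(.data$missing, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::pull(.data$marker)
}
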