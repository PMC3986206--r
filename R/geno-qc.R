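#' Mask heterozygous calls to missing
#'
#' Inbred accessions are expected to be homozygous; residual heterozygous
#' calls (flagged at read time) are converted to missing values. Calls
#' without a het flag are untouched.
#'
#' @param g a [genotype_matrix()] with het flags (a flag-free matrix is
#'   returned unchanged).
#' @return A [genotype_matrix()] with flagged calls set to `NA` and flags
#'   cleared.
#' @export
mask_heterozygotes <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(g$het) || !any(g$het)) {
    return(genotype_matrix(g$calls))
  }
  calls <- g$calls
  calls[g$het] <- NA_real_
  genotype_matrix(calls)
}

#' Quality-control filter on missingness
#'
#' Markers with a missing fraction above `max_marker_missing` are removed
#' first; accessions with a missing fraction (computed over the surviving
#' markers) above `max_accession_missing` are removed second. This order is
#' fixed: marker failure is an assay-level problem and is resolved before
#' judging accessions.
#'
#' @param g a [genotype_matrix()].
#' @param max_marker_missing,max_accession_missing missing-fraction
#'   thresholds in \[0, 1\] (strictly-greater-than removal).
#' @return A filtered [genotype_matrix()]; attributes `removed_markers` and
#'   `removed_accessions` record what was dropped.
#' @export
qc_filter <- function(g, max_marker_missing = 0.10, max_accession_missing = 0.10) {
  stopifnot(inherits(g, "genotype_matrix"))
  stopifnot(max_marker_missing >= 0, max_marker_missing <= 1,
            max_accession_missing >= 0, max_accession_missing <= 1)
  miss_m <- colMeans(is.na(g$calls))
  keep_m <- miss_m <= max_marker_missing
  calls <- g$calls[, keep_m, drop = FALSE]
  miss_a <- if (ncol(calls) > 0) rowMeans(is.na(calls)) else rep(1, nrow(calls))
  keep_a <- miss_a <= max_accession_missing
  calls <- calls[keep_a, , drop = FALSE]
  if (nrow(calls) == 0 || ncol(calls) == 0) {
    abort("qc_filter removed everything; review the missingness thresholds")
  }
  out <- genotype_matrix(calls,
    het = if (!is.null(g$het)) g$het[keep_a, keep_m, drop = FALSE]
  )
  attr(out, "removed_markers") <- markers(g)[!keep_m]
  attr(out, "removed_accessions") <- accessions(g)[!keep_a]
  out
}

#' Per-marker allele frequencies
#'
#' Frequencies of allele 1 computed over non-missing calls; markers with no
#' observed calls get `NA` frequencies and are flagged.
#'
#' @param g a [genotype_matrix()].
#' @return A tibble with columns `marker`, `n_obs`, `freq1`, `maf`,
#'   `no_calls` (logical flag).
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, NA, 1), 1, 4,
#'   dimnames = list("a", paste0("m", 1:4))))
#' allele_frequencies(g)
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_obs <- colSums(!is.na(g$calls))
  s1 <- colSums(g$calls, na.rm = TRUE)
  freq1 <- unname(ifelse(n_obs > 0, s1 / n_obs, NA_real_))
  tibble(
    marker = markers(g),
    n_obs = as.integer(n_obs),
    freq1 = freq1,
    maf = pmin(freq1, 1 - freq1),
    no_calls = n_obs == 0
  )
}

# internal: marker-subset helper by MAF
maf_filter_markers <- function(g, maf_min) {
  af <- allele_frequencies(g)
  keep <- !af$no_calls & af$maf >= maf_min
  markers(g)[keep]
}
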