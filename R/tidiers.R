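#' Tidy a PIC ranking
#'
#' @param x a [rank_accessions()] result.
#' @param ... unused.
#' @return The per-accession ranking tibble (`accession`, `rank`,
#'   `removal_step`, `avg_pic_after_removal`).
#' @exportS3Method generics::tidy
tidy.pic_ranking <- function(x, ...) x$ranking

#' @rdname tidy.pic_ranking
#' @return For `glance()`: a one-row tibble with `n_accessions`,
#'   `n_markers`, `peak_size`, `peak_avg_pic`, `start_avg_pic`, `pic_form`.
#' @exportS3Method generics::glance
glance.pic_ranking <- function(x, ...) {
  tibble(
    n_accessions = nrow(x$ranking),
    n_markers = x$n_markers,
    peak_size = x$peak_size,
    peak_avg_pic = max(x$trajectory$avg_pic),
    start_avg_pic = x$trajectory$avg_pic[1],
    pic_form = x$form
  )
}

#' Tidy a GWAS scan
#'
#' @param x a [mlm_scan()] result.
#' @param ... unused.
#' @return `tidy()` returns the per-marker table as a plain tibble;
#'   `glance()` a one-row summary with the REML variance components,
#'   heritability estimate and genomic inflation factor.
#' @exportS3Method generics::tidy
tidy.gwas_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "gwas_scan")
  out
}

#' @rdname tidy.gwas_scan
#' @exportS3Method generics::glance
glance.gwas_scan <- function(x, ...) {
  vc <- attr(x, "variance_components")
  tibble(
    n_accessions = attr(x, "n_accessions") %||% NA_integer_,
    n_markers = nrow(x),
    sigma_g2 = vc$sigma_g2 %||% NA_real_,
    sigma_e2 = vc$sigma_e2 %||% NA_real_,
    h2_pseudo = if (!is.null(vc)) vc$sigma_g2 / (vc$sigma_g2 + vc$sigma_e2) else NA_real_,
    lambda_gc = attr(x, "lambda_gc") %||% NA_real_,
    n_significant = sum(x$q < 0.05, na.rm = TRUE)
  )
}

#' Tidy a PCA result
#'
#' @param x a [pca_genotypes()] result.
#' @param ... unused.
#' @return `tidy()` returns the score tibble; `glance()` one row with the
#'   component count and total variance explained.
#' @exportS3Method generics::tidy
tidy.pca_result <- function(x, ...) x$scores

#' @rdname tidy.pca_result
#' @exportS3Method generics::glance
glance.pca_result <- function(x, ...) {
  tibble(
    n_accessions = nrow(x$scores),
    n_components = length(x$var_explained),
    n_markers = length(x$markers_used),
    var_explained_total = sum(x$var_explained)
  )
}
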