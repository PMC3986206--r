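#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_hline geom_vline facet_grid facet_wrap labs theme_minimal vars
NULL

#' @export
ggplot2::autoplot

#' Plot a Phi-PT divergence scan
#'
#' Manhattan-style plot of the display-scaled statistic (`phi_pt^10`)
#' against map position, faceted by chromosome.
#'
#' @param object a `phi_scan` tibble from [phi_pt_scan()].
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.phi_scan <- function(object, ...) {
  if (!"cM" %in% names(object)) {
    abort("attach a map in phi_pt_scan() to plot by position")
  }
  ggplot(object, aes(x = .data$cM, y = .data$phi_pow10)) +
    geom_point(size = 0.6, alpha = 0.7) +
    facet_grid(cols = vars(.data$chrom), scales = "free_x", space = "free_x") +
    labs(x = "position (cM)", y = expression(Phi[PT]^10)) +
    theme_minimal()
}

#' Plot a GWAS scan as a Manhattan plot
#'
#' @param object a `gwas_scan` tibble joined to a map (see
#'   [manhattan_table()]).
#' @param alpha significance threshold drawn as a dashed line (q scale).
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gwas_scan <- function(object, alpha = 0.05, ...) {
  if (!"cM" %in% names(object)) {
    abort("join results to a map with manhattan_table() first")
  }
  ggplot(dplyr::filter(object, !is.na(.data$cM)),
         aes(x = .data$cM, y = .data$neg_log10_q)) +
    geom_point(size = 0.6, alpha = 0.7) +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    facet_grid(cols = vars(.data$chrom), scales = "free_x", space = "free_x") +
    labs(x = "position (cM)", y = expression(-log[10](q))) +
    theme_minimal()
}

#' Plot an LD decay profile
#'
#' Mean r-squared per distance bin and chromosome, with the unlinked-pair
#' significance threshold (if attached) as a dashed line.
#'
#' @param object an `ld_decay` tibble from [decay_profile()].
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ld_decay <- function(object, ...) {
  p <- ggplot(dplyr::filter(object, .data$n_pairs > 0),
              aes(x = .data$bin_mid, y = .data$mean_r2, colour = .data$chrom)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(x = "distance (cM)", y = expression(mean ~ r^2), colour = NULL) +
    theme_minimal()
  thr <- attr(object, "threshold")
  if (!is.null(thr)) {
    p <- p + geom_hline(yintercept = thr$threshold, linetype = "dashed")
  }
  p
}

#' Plot a PIC-ranking trajectory
#'
#' Average PIC of the retained set against retained-set size, with the peak
#' marked.
#'
#' @param object a [rank_accessions()] result.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pic_ranking <- function(object, ...) {
  ggplot(object$trajectory, aes(x = .data$size, y = .data$avg_pic)) +
    geom_line() +
    geom_vline(xintercept = object$peak_size, linetype = "dashed") +
    ggplot2::scale_x_reverse() +
    labs(x = "retained accessions", y = "average PIC") +
    theme_minimal()
}
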