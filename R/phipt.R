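# Vectorized one-level AMOVA on 0/1 calls across a marker matrix.
# Returns per-marker sums of squares, variance components and phi statistics;
# markers failing the >=2-groups-with->=2-calls rule get NA and a reason.
phi_pt_engine <- function(calls, labels) {
  obs <- !is.na(calls)
  calls0 <- calls
  calls0[!obs] <- 0
  grp <- factor(labels)
  S_g <- rowsum(calls0, grp) # group sums of x (x in {0,1} so sum x^2 = sum x)
  n_g <- rowsum(obs + 0, grp) # group counts of observed calls
  N <- colSums(n_g)
  S <- colSums(S_g)
  # groups qualifying at each marker: >= 2 observed calls
  qual <- n_g >= 2
  g_eff <- colSums(qual)
  # zero out non-qualifying groups
  S_g[!qual] <- 0
  n_gq <- n_g
  n_gq[!qual] <- 0
  Nq <- colSums(n_gq)
  Sq <- colSums(S_g)
  ss_total <- Sq - Sq^2 / Nq
  within_term <- S_g - ifelse(n_gq > 0, S_g^2 / pmax(n_gq, 1), 0)
  ss_within <- colSums(within_term)
  ss_among <- ss_total - ss_within
  df_among <- g_eff - 1
  df_within <- Nq - g_eff
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (Nq - colSums(n_gq^2) / Nq) / df_among
  v_wp <- ms_within
  v_ap <- (ms_among - ms_within) / n0
  denom <- v_ap + v_wp
  # markers with no variance at all (monomorphic over the used calls) carry
  # no information: phi is undefined there, not zero
  phi_raw <- ifelse(ss_total > 0 & denom > 0, v_ap / denom, NA_real_)
  v_ap_c <- pmax(v_ap, 0)
  denom_c <- v_ap_c + v_wp
  phi_pt <- ifelse(ss_total > 0 & denom_c > 0, v_ap_c / denom_c, NA_real_)
  valid <- g_eff >= 2 & df_within > 0
  bad <- !valid
  phi_raw[bad] <- NA_real_
  phi_pt[bad] <- NA_real_
  lapply(list(
    ss_among = ss_among, ss_within = ss_within,
    df_among = df_among, df_within = df_within,
    ms_among = ms_among, ms_within = ms_within, n0 = n0,
    v_ap = v_ap, v_wp = v_wp,
    phi_raw = phi_raw, phi_pt = phi_pt,
    n_used = Nq, valid = valid
  ), unname)
}

#' Phi-PT for a single marker
#'
#' One-level AMOVA on binary calls (squared-difference distance on 0/1
#' alleles, the haploid convention). Missing calls are dropped; only groups
#' with at least two observed calls enter. The variance component among
#' subpopulations is `V_AP = (MS_among - MS_within) / n0` with
#' `n0 = (N - sum(n_g^2)/N) / (g - 1)`; `V_WP = MS_within`; and
#' `phi_pt = V_AP / (V_AP + V_WP)` with negative `V_AP` clamped to zero
#' (the unclamped ratio is kept as `phi_raw`).
#'
#' @param calls numeric vector of 0/1/NA calls, one per accession.
#' @param labels group label per accession.
#' @return A tibble with the sums of squares, mean squares, `n0`, variance
#'   components, `phi_pt`, `phi_raw` and `n_used`; zero rows (with a reason
#'   attribute) if fewer than two groups qualify.
#' @examples
#' phi_pt_single(c(0, 0, 1, 1, 1, 1), rep(c("A", "B"), each = 3))$phi_pt # 0.5
#' @export
phi_pt_single <- function(calls, labels) {
  stopifnot(length(calls) == length(labels))
  e <- phi_pt_engine(matrix(calls, ncol = 1), labels)
  if (!e$valid[1]) {
    out <- tibble(
      ss_among = numeric(), ss_within = numeric(), df_among = integer(),
      df_within = integer(), ms_among = numeric(), ms_within = numeric(),
      n0 = numeric(), v_ap = numeric(), v_wp = numeric(),
      phi_pt = numeric(), phi_raw = numeric(), n_used = integer()
    )
    attr(out, "skip_reason") <- "fewer than 2 groups with >= 2 observed calls"
    return(out)
  }
  tibble(
    ss_among = e$ss_among, ss_within = e$ss_within,
    df_among = as.integer(e$df_among), df_within = as.integer(e$df_within),
    ms_among = e$ms_among, ms_within = e$ms_within, n0 = e$n0,
    v_ap = e$v_ap, v_wp = e$v_wp,
    phi_pt = e$phi_pt, phi_raw = e$phi_raw, n_used = as.integer(e$n_used)
  )
}

#' Permutation p-value for Phi-PT at one marker
#'
#' Group labels are permuted jointly across accessions; the p-value is
#' `(1 + #\{phi_perm >= phi_obs\}) / (1 + n_perm)` (add-one estimator, never
#' zero). Permuted statistics are compared on the unclamped `phi_raw` scale
#' so the null distribution stays continuous.
#'
#' @param calls,labels as in [phi_pt_single()].
#' @param n_perm number of permutations (> 0).
#' @param seed integer seed for the permutation stream.
#' @return The permutation p-value (scalar).
#' @export
phi_pt_permutation <- function(calls, labels, n_perm = 1000, seed = 1) {
  if (n_perm <= 0) abort("n_perm must be positive")
  obs <- phi_pt_single(calls, labels)
  if (nrow(obs) == 0) abort("phi_pt undefined for observed labels")
  set.seed(seed)
  n <- length(labels)
  cmat <- matrix(calls, ncol = 1)
  count <- 0L
  for (b in seq_len(n_perm)) {
    e <- phi_pt_engine(cmat, labels[sample.int(n)])
    if (!is.na(e$phi_raw[1]) && e$phi_raw[1] >= obs$phi_raw - 1e-12) {
      count <- count + 1L
    }
  }
  (1 + count) / (1 + n_perm)
}

#' Per-SNP Phi-PT divergence scan
#'
#' Runs the one-level AMOVA at every marker, with a shared set of label
#' permutations (regenerated per scan, reused across markers) for
#' permutation p-values. Only non-admixed accessions should be passed in;
#' accessions labeled `"admixed"` are dropped automatically.
#'
#' @param g a [genotype_matrix()].
#' @param labels a data frame (`accession`, `label`) as produced by
#'   [assign_subpopulations()], or a named character vector.
#' @param map optional genetic map tibble to attach positions and sort by
#'   them.
#' @param n_perm permutations for the p-value (0 skips the permutation test).
#' @param seed permutation seed.
#' @return A `phi_scan` tibble: `marker`, (optionally `chrom`, `cM`),
#'   `n_used`, group sizes, `phi_pt`, `phi_raw`, `phi_pow10`
#'   (`phi_pt^10`, the display scale that separates high values), `p_perm`.
#' @export
phi_pt_scan <- function(g, labels, map = NULL, n_perm = 1000, seed = 1) {
  stopifnot(inherits(g, "genotype_matrix"))
  lab <- normalize_labels(labels, accessions(g))
  keep <- !is.na(lab) & lab != "admixed"
  calls <- g$calls[keep, , drop = FALSE]
  lab <- lab[keep]
  if (length(unique(lab)) < 2) abort("need >= 2 non-admixed groups")
  e <- phi_pt_engine(calls, lab)
  p_perm <- rep(NA_real_, ncol(calls))
  if (n_perm > 0) {
    set.seed(seed)
    n <- nrow(calls)
    count <- integer(ncol(calls))
    for (b in seq_len(n_perm)) {
      ep <- phi_pt_engine(calls, lab[sample.int(n)])
      count <- count + as.integer(!is.na(ep$phi_raw) &
        ep$phi_raw >= e$phi_raw - 1e-12)
    }
    p_perm <- (1 + count) / (1 + n_perm)
    p_perm[is.na(e$phi_raw)] <- NA_real_
  }
  out <- tibble(
    marker = markers(g),
    n_used = as.integer(e$n_used),
    v_ap = e$v_ap,
    v_wp = e$v_wp,
    phi_pt = e$phi_pt,
    phi_raw = e$phi_raw,
    phi_pow10 = e$phi_pt^10,
    p_perm = p_perm
  )
  grp_n <- table(lab)
  attr(out, "group_sizes") <- setNames(as.integer(grp_n), names(grp_n))
  if (!is.null(map)) {
    out <- dplyr::inner_join(out, map[, c("marker", "chrom", "cM")], by = "marker") |>
      dplyr::arrange(.data$chrom, .data$cM) |>
      dplyr::relocate("chrom", "cM", .after = "marker")
  }
  class(out) <- c("phi_scan", class(out))
  out
}

#' Multilocus Phi-PT over a scan
#'
#' The ratio-of-sums estimator `sum(V_AP) / sum(V_AP + V_WP)` over markers
#' with defined components — the standard multilocus form. Unlike the mean
#' of per-marker ratios it is consistent for the generating differentiation
#' level (per-marker ratios are attenuated for loci drifted toward fixation
#' in both groups).
#'
#' @param scan a `phi_scan` tibble from [phi_pt_scan()].
#' @return The multilocus Phi-PT (scalar, clamped to \[0, 1\]).
#' @export
phi_pt_overall <- function(scan) {
  stopifnot(all(c("v_ap", "v_wp") %in% names(scan)))
  ok <- !is.na(scan$v_ap) & !is.na(scan$v_wp)
  min(max(sum(scan$v_ap[ok]) / sum(scan$v_ap[ok] + scan$v_wp[ok]), 0), 1)
}

#' One-vs-rest divergence scan
#'
#' All non-focal subpopulations are pooled into a single `"rest"` group and
#' [phi_pt_scan()] is run on the two-group contrast, highlighting markers
#' where the focal subpopulation diverges from everything else.
#'
#' @inheritParams phi_pt_scan
#' @param focal_label the subpopulation to contrast against the pooled rest.
#' @return A `phi_scan` tibble (see [phi_pt_scan()]).
#' @export
one_vs_rest_scan <- function(g, labels, focal_label, map = NULL,
                             n_perm = 1000, seed = 1) {
  lab <- normalize_labels(labels, accessions(g))
  keep <- !is.na(lab) & lab != "admixed"
  if (!focal_label %in% lab[keep]) {
    abort(sprintf("focal label '%s' not present", focal_label))
  }
  lab2 <- ifelse(lab == focal_label, focal_label, "rest")
  lab2[!keep] <- "admixed"
  phi_pt_scan(g, setNames(lab2, accessions(g)), map = map,
              n_perm = n_perm, seed = seed)
}

normalize_labels <- function(labels, acc) {
  if (is.data.frame(labels)) {
    lab <- setNames(labels$label, labels$accession)[acc]
  } else {
    lab <- labels[acc]
  }
  unname(lab)
}
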