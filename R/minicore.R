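#' Polymorphism information content of one marker
#'
#' Gene-diversity form `1 - sum_i p_i^2` over the observed allele
#' frequencies (bounded by 0.5 for biallelic markers); the full Botstein
#' form `1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2` is available via `form`.
#'
#' @param freqs numeric vector of allele frequencies at one marker (must sum
#'   to 1 over observed alleles).
#' @param form `"gene-diversity"` (default) or `"botstein"`.
#' @return The PIC value.
#' @examples
#' pic_per_marker(c(0.5, 0.5)) # 0.5
#' pic_per_marker(c(0.2, 0.8)) # 0.32
#' @export
pic_per_marker <- function(freqs, form = c("gene-diversity", "botstein")) {
  form <- match.arg(form)
  if (abs(sum(freqs) - 1) > 1e-8) abort("allele frequencies must sum to 1")
  h <- 1 - sum(freqs^2)
  if (form == "gene-diversity") return(h)
  k <- length(freqs)
  cross <- 0
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      cross <- cross + sum(2 * freqs[i]^2 * freqs[(i + 1):k]^2)
    }
  }
  h - cross
}

# per-marker PIC vector from allele-1 counts and observed counts (biallelic)
pic_from_counts <- function(c1, n_obs, form = "gene-diversity") {
  p <- ifelse(n_obs > 0, c1 / n_obs, NA_real_)
  h <- 2 * p * (1 - p)
  if (form == "botstein") {
    h <- h - 2 * p^2 * (1 - p)^2
  }
  h
}

#' Average PIC of an accession subset
#'
#' Per-marker allele frequencies are computed over the subset's non-missing
#' calls; the PIC is averaged over markers with at least one observed call
#' (markers that are all-missing within the subset are excluded from the
#' average, not counted as zero).
#'
#' @param g a [genotype_matrix()].
#' @param subset accession ids or indices (>= 2 accessions).
#' @param marker_mask optional marker ids/logical mask restricting the
#'   marker set (e.g. mapped markers only).
#' @param form PIC form, see [pic_per_marker()].
#' @return Mean PIC (scalar).
#' @export
average_pic <- function(g, subset = NULL, marker_mask = NULL,
                        form = c("gene-diversity", "botstein")) {
  form <- match.arg(form)
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- g$calls
  if (!is.null(marker_mask)) calls <- calls[, marker_mask, drop = FALSE]
  if (!is.null(subset)) calls <- calls[subset, , drop = FALSE]
  if (nrow(calls) < 2) abort("subset must contain >= 2 accessions")
  n_obs <- colSums(!is.na(calls))
  c1 <- colSums(calls, na.rm = TRUE)
  mean(pic_from_counts(c1, n_obs, form)[n_obs > 0])
}

#' Stepwise PIC-maximization ranking of accessions
#'
#' Iteratively removes the accession whose removal yields the highest
#' post-removal average PIC of the retained set (ties broken by
#' lexicographic accession id), recording the average-PIC trajectory, down
#' to `min_size` retained accessions. Rank 1 is the last accession standing
#' (highest diversity contribution). The peak size is the retained-set size
#' at which the trajectory attains its maximum (earliest/largest size if
#' tied): removals above the peak did not cost diversity; removing below it
#' does.
#'
#' The removal loop maintains per-marker allele counts so each candidate
#' evaluation is a vector update; a naive full-recomputation oracle is kept
#' in the test suite.
#'
#' @param g a [genotype_matrix()].
#' @param marker_mask optional marker restriction (e.g. mapped markers).
#' @param min_size stop when this many accessions remain (>= 2).
#' @param form PIC form.
#' @return A list of class `pic_ranking`: `ranking` tibble (`accession`,
#'   `rank`, `removal_step`, `avg_pic_after_removal`), `trajectory` tibble
#'   (`size`, `avg_pic`), `peak_size`, `form`, `n_markers`.
#' @export
rank_accessions <- function(g, marker_mask = NULL, min_size = 2,
                            form = c("gene-diversity", "botstein")) {
  form <- match.arg(form)
  stopifnot(inherits(g, "genotype_matrix"), min_size >= 2)
  calls <- g$calls
  if (!is.null(marker_mask)) calls <- calls[, marker_mask, drop = FALSE]
  n <- nrow(calls)
  if (n < min_size + 1) abort("need more than min_size accessions to rank")
  ids <- rownames(calls)
  is1 <- (calls == 1)
  is1[is.na(is1)] <- FALSE
  obs <- !is.na(calls)
  storage.mode(is1) <- "double"
  storage.mode(obs) <- "double"

  current <- rep(TRUE, n)
  c1 <- colSums(is1)
  n_obs <- colSums(obs)
  removal_order <- character(n - min_size)
  traj_size <- seq(n, min_size + 1) - 1L # sizes after each removal
  traj_pic <- numeric(length(traj_size))
  start_pic <- mean(pic_from_counts(c1, n_obs, form)[n_obs > 0])

  for (step in seq_len(n - min_size)) {
    cand <- which(current)
    # counts after removing each candidate: one row per candidate
    c1_new <- rep(c1, each = length(cand)) -
      is1[cand, , drop = FALSE]
    n_new <- rep(n_obs, each = length(cand)) -
      obs[cand, , drop = FALSE]
    dim(c1_new) <- dim(n_new) <- c(length(cand), length(c1))
    p <- c1_new / n_new
    h <- 2 * p * (1 - p)
    if (form == "botstein") h <- h - 2 * p^2 * (1 - p)^2
    h[n_new == 0] <- NA
    pics <- rowMeans(h, na.rm = TRUE)
    best <- max(pics)
    # tie-break: lexicographically smallest accession id among maximizers
    tied <- cand[pics >= best - 1e-12]
    pick <- tied[order(ids[tied])][1]
    pick_pic <- pics[match(pick, cand)]
    current[pick] <- FALSE
    c1 <- c1 - is1[pick, ]
    n_obs <- n_obs - obs[pick, ]
    removal_order[step] <- ids[pick]
    traj_pic[step] <- pick_pic
  }

  ranks <- setNames(integer(n), ids)
  ranks[removal_order] <- n - seq_along(removal_order) + 1L
  remaining <- ids[current]
  # last remaining accessions get top ranks, ordered by id for determinism
  ranks[sort(remaining)] <- seq_along(remaining)

  trajectory <- tibble(
    size = c(n, traj_size),
    avg_pic = c(start_pic, traj_pic)
  )
  peak_size <- trajectory$size[which.max(trajectory$avg_pic)]
  ranking <- tibble(
    accession = ids,
    rank = as.integer(ranks[ids]),
    removal_step = ifelse(ids %in% removal_order,
                          match(ids, removal_order), NA_integer_),
    avg_pic_after_removal = traj_pic[match(ids, removal_order)]
  ) |>
    dplyr::arrange(.data$rank)
  structure(list(
    ranking = ranking,
    trajectory = trajectory,
    peak_size = peak_size,
    form = form,
    n_markers = length(c1)
  ), class = "pic_ranking")
}

#' @export
print.pic_ranking <- function(x, ...) {
  cat(sprintf(
    "<pic_ranking> %d accessions over %d markers (%s PIC); peak average PIC %.4f at size %d\n",
    nrow(x$ranking), x$n_markers, x$form,
    max(x$trajectory$avg_pic), x$peak_size
  ))
  invisible(x)
}

#' Select a mini-core set from a PIC ranking
#'
#' Takes the top-ranked accessions. Selecting fewer accessions than the
#' ranking's PIC peak is allowed but flagged with a warning: below the peak,
#' every accession still contributes diversity.
#'
#' @param ranking a [rank_accessions()] result.
#' @param size number of accessions to select; alternatively give
#'   `fraction`.
#' @param fraction fraction of the collection (rounded to nearest integer
#'   count).
#' @return A tibble of selected accessions (`accession`, `rank`) with
#'   attribute `below_peak` (logical warning flag).
#' @export
select_minicore <- function(ranking, size = NULL, fraction = NULL) {
  stopifnot(inherits(ranking, "pic_ranking"))
  n <- nrow(ranking$ranking)
  if (is.null(size)) {
    if (is.null(fraction)) abort("give size or fraction")
    size <- round(fraction * n)
  }
  if (size > n) abort("size exceeds the number of ranked accessions")
  below <- size < ranking$peak_size
  if (below) {
    warn(sprintf(
      "selected size %d is below the PIC peak (%d accessions); sets smaller than the peak lose allelic diversity",
      size, ranking$peak_size
    ))
  }
  out <- ranking$ranking |>
    dplyr::filter(.data$rank <= size) |>
    dplyr::select("accession", "rank")
  attr(out, "below_peak") <- below
  out
}

#' Group-restricted PIC ranking
#'
#' Runs [rank_accessions()] on one group's accessions only, with allele
#' frequencies computed within the group — an accession carrying alleles
#' rare within its group can rank high here even if it ranks low globally.
#'
#' @param g a [genotype_matrix()].
#' @param group_mask accession ids (or logical/integer mask) defining the
#'   group (>= 3 accessions).
#' @param ... passed to [rank_accessions()].
#' @return A `pic_ranking` for the group.
#' @export
group_restricted_ranking <- function(g, group_mask, ...) {
  sub <- g[group_mask, ]
  if (nrow(sub$calls) < 3) abort("group must contain >= 3 accessions")
  rank_accessions(sub, ...)
}
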