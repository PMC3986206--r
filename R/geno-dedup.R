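#' Simple-matching similarity between two accessions
#'
#' The simple matching coefficient over co-observed markers: matches divided
#' by the number of markers where both accessions have a call. Missing calls
#' never count as matches or mismatches.
#'
#' @param g a [genotype_matrix()].
#' @param i,j accession ids or indices (distinct).
#' @return A list with `similarity` (NA if no co-observed markers) and
#'   `n_compared`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 0, 1, 1, 0, 1), 2, 3,
#'   dimnames = list(c("a", "b"), c("m1", "m2", "m3"))))
#' simple_matching_similarity(g, "a", "b")
#' @export
simple_matching_similarity <- function(g, i, j) {
  stopifnot(inherits(g, "genotype_matrix"))
  ii <- if (is.character(i)) match(i, accessions(g)) else as.integer(i)
  jj <- if (is.character(j)) match(j, accessions(g)) else as.integer(j)
  if (anyNA(c(ii, jj)) || ii < 1 || jj < 1 || ii > nrow(g$calls) || jj > nrow(g$calls)) {
    abort("i and j must name valid accessions")
  }
  if (ii == jj) abort("i and j must be distinct accessions")
  xi <- g$calls[ii, ]
  xj <- g$calls[jj, ]
  both <- !is.na(xi) & !is.na(xj)
  n <- sum(both)
  list(
    similarity = if (n == 0) NA_real_ else sum(xi[both] == xj[both]) / n,
    n_compared = n
  )
}

# internal: all-pairs match and overlap counts via matrix products
pairwise_match_counts <- function(calls) {
  A <- (calls == 1)
  A[is.na(A)] <- FALSE
  B <- (calls == 0)
  B[is.na(B)] <- FALSE
  storage.mode(A) <- "double"
  storage.mode(B) <- "double"
  O <- A + B # observed indicator
  list(
    matches = tcrossprod(A) + tcrossprod(B),
    overlap = tcrossprod(O)
  )
}

#' Detect genetically identical accessions
#'
#' Accession pairs that match at every co-observed marker (simple-matching
#' similarity exactly 1) and share at least `min_overlap_fraction` of the
#' marker panel are treated as duplicate edges; duplicate sets are the
#' connected components of the resulting graph. Components are reported, not
#' resolved; see [resolve_duplicates()].
#'
#' @param g a QC'd [genotype_matrix()].
#' @param min_overlap_fraction minimum co-observed fraction of the marker
#'   panel for a pair to qualify.
#' @return A list of class `duplicate_report` with `sets` (list of character
#'   vectors, each >= 2 accessions) and `pairs`, a tibble of qualifying edges
#'   (`accession_a`, `accession_b`, `n_compared`).
#' @export
find_duplicates <- function(g, min_overlap_fraction = 0.5) {
  stopifnot(inherits(g, "genotype_matrix"))
  m <- ncol(g$calls)
  cnt <- pairwise_match_counts(g$calls)
  eq <- cnt$matches == cnt$overlap & cnt$overlap >= min_overlap_fraction * m
  diag(eq) <- FALSE
  ids <- accessions(g)
  edge_idx <- which(eq & upper.tri(eq), arr.ind = TRUE)
  pairs <- tibble(
    accession_a = ids[edge_idx[, 1]],
    accession_b = ids[edge_idx[, 2]],
    n_compared = as.integer(cnt$overlap[edge_idx])
  )
  # connected components by repeated label propagation over the edge list
  comp <- seq_along(ids)
  if (nrow(edge_idx) > 0) {
    repeat {
      new <- comp
      mn <- pmin(comp[edge_idx[, 1]], comp[edge_idx[, 2]])
      new[edge_idx[, 1]] <- pmin(new[edge_idx[, 1]], mn)
      new[edge_idx[, 2]] <- pmin(new[edge_idx[, 2]], mn)
      # propagate via component minima
      new <- ave(new, new, FUN = min)
      if (identical(new, comp)) break
      comp <- new
    }
  }
  sizes <- table(comp)
  keep <- as.integer(names(sizes)[sizes >= 2])
  sets <- lapply(keep, function(c) ids[comp == c])
  structure(list(sets = sets, pairs = pairs), class = "duplicate_report")
}

#' @export
print.duplicate_report <- function(x, ...) {
  cat(sprintf(
    "<duplicate_report> %d duplicate set(s) covering %d accession(s)\n",
    length(x$sets), sum(lengths(x$sets))
  ))
  invisible(x)
}

#' Resolve duplicate sets to one retained accession each
#'
#' @param report a `duplicate_report` from [find_duplicates()].
#' @param g the [genotype_matrix()] the report was computed from (used for
#'   completeness under `keep-most-complete`).
#' @param metadata optional tibble with columns `accession` and `origin`;
#'   sets whose members disagree on `origin` are flagged.
#' @param policy `"keep-first"` retains the first member in input order;
#'   `"keep-most-complete"` retains the member with the fewest missing calls
#'   (ties by input order).
#' @return A tibble with one row per input accession: `accession`, `set`
#'   (set id or NA), `retained`, `reason`, `metadata_conflict`.
#' @export
resolve_duplicates <- function(report, g, metadata = NULL,
                               policy = c("keep-most-complete", "keep-first")) {
  policy <- match.arg(policy)
  ids <- accessions(g)
  out <- tibble(
    accession = ids,
    set = NA_integer_,
    retained = TRUE,
    reason = "unique",
    metadata_conflict = FALSE
  )
  n_miss <- rowSums(is.na(g$calls))
  for (s in seq_along(report$sets)) {
    members <- report$sets[[s]]
    idx <- match(members, ids)
    keep <- switch(policy,
      "keep-first" = idx[1],
      "keep-most-complete" = idx[which.min(n_miss[idx])]
    )
    conflict <- FALSE
    if (!is.null(metadata)) {
      org <- metadata$origin[match(members, metadata$accession)]
      conflict <- length(unique(na.omit(org))) > 1
    }
    out$set[idx] <- s
    out$metadata_conflict[idx] <- conflict
    out$retained[idx] <- FALSE
    out$reason[idx] <- sprintf("duplicate of %s", ids[keep])
    out$retained[keep] <- TRUE
    out$reason[keep] <- sprintf("retained (%s)", policy)
  }
  out
}
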