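#' Genotype matrix container
#'
#' A `genotype_matrix` wraps a dense accessions x markers matrix of biallelic
#' calls coded 0/1 with `NA` for missing, together with an optional logical
#' matrix flagging calls that were heterozygous in the raw data (inbred
#' accessions are expected, so heterozygous calls are normally masked to
#' missing with [mask_heterozygotes()]).
#'
#' @param calls numeric matrix with values in {0, 1, NA}; rownames are
#'   accession ids, colnames are marker ids (both required and unique).
#' @param het optional logical matrix of the same dimension flagging raw
#'   heterozygous calls.
#' @return An object of class `genotype_matrix`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, NA, 1), 2, 2,
#'   dimnames = list(c("a1", "a2"), c("m1", "m2"))))
#' g
#' @export
genotype_matrix <- function(calls, het = NULL) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  ids <- rownames(calls)
  mk <- colnames(calls)
  if (is.null(ids) || anyDuplicated(ids)) {
    abort("accession ids (rownames) must be present and unique")
  }
  if (is.null(mk) || anyDuplicated(mk)) {
    abort("marker ids (colnames) must be present and unique")
  }
  bad <- !(calls %in% c(0, 1)) & !is.na(calls)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "invalid call '%s' at accession '%s', marker '%s' (expected 0, 1 or NA)",
      calls[idx[1], idx[2]], ids[idx[1]], mk[idx[2]]
    ))
  }
  if (!is.null(het)) {
    stopifnot(is.logical(het), all(dim(het) == dim(calls)))
    dimnames(het) <- dimnames(calls)
  }
  structure(list(calls = calls, het = het), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- dim(x$calls)
  miss <- mean(is.na(x$calls))
  cat(sprintf(
    "<genotype_matrix> %d accessions x %d markers (%.1f%% missing%s)\n",
    d[1], d[2], 100 * miss,
    if (!is.null(x$het)) sprintf(", %d het-flagged", sum(x$het)) else ""
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Accession and marker identifiers
#' @param g a [genotype_matrix()].
#' @return Character vector of ids.
#' @export
accessions <- function(g) rownames(g$calls)

#' @rdname accessions
#' @export
markers <- function(g) colnames(g$calls)

#' Subset a genotype matrix by accession and/or marker
#' @param x a [genotype_matrix()].
#' @param i,j accession / marker indices (any form `[` accepts).
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  genotype_matrix(
    x$calls[i, j, drop = FALSE],
    het = if (!is.null(x$het)) x$het[i, j, drop = FALSE]
  )
}

#' Convert a genotype matrix to a long tibble
#' @param x a [genotype_matrix()].
#' @param ... unused.
#' @return A tibble with columns `accession`, `marker`, `call`.
#' @exportS3Method tibble::as_tibble
as_tibble.genotype_matrix <- function(x, ...) {
  tibble(
    accession = rep(rownames(x$calls), times = ncol(x$calls)),
    marker = rep(colnames(x$calls), each = nrow(x$calls)),
    call = as.vector(x$calls)
  )
}
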