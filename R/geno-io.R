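#' Read genotypes from TSV matrix, HapMap or VCF
#'
#' Three dialects are supported. `matrix-tsv`: first column accession id,
#' header row of marker ids, calls in {0, 1, NA}. `hapmap`: the standard
#' 11-metadata-column tab format with diploid letter codes; calls matching the
#' marker's two alleles are coded 0 (first allele) / 1 (second allele), calls
#' with two different letters are read as heterozygous and flagged, `NN`/`--`
#' are missing, and any other code is an error naming the cell. `vcf`:
#' biallelic SNP records with a GT field; `0/1` (or `0|1`) calls are flagged
#' heterozygous, `./.` is missing, and multi-allelic records are dropped with
#' a message reporting the count.
#'
#' @param path path to the genotype file.
#' @param format one of `"matrix-tsv"`, `"hapmap"`, `"vcf"`.
#' @return A [genotype_matrix()] with heterozygous raw calls flagged.
#' @export
read_genotypes <- function(path, format = c("matrix-tsv", "hapmap", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  switch(format,
    "matrix-tsv" = read_genotypes_tsv(path),
    "hapmap" = read_genotypes_hapmap(path),
    "vcf" = read_genotypes_vcf(path)
  )
}

read_genotypes_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids)) abort("duplicate accession ids in genotype TSV")
  calls <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(calls) <- "double"
  rownames(calls) <- ids
  genotype_matrix(calls)
}

read_genotypes_hapmap <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = "c"))
  meta_cols <- 11L
  if (ncol(d) <= meta_cols) abort("hapmap file has no sample columns")
  ids <- colnames(d)[-seq_len(meta_cols)]
  mk <- as.character(d[[1]])
  if (anyDuplicated(mk)) abort("duplicate marker ids in hapmap file")
  alleles <- strsplit(as.character(d[[2]]), "/", fixed = TRUE)
  n <- length(ids)
  m <- length(mk)
  calls <- matrix(NA_real_, n, m, dimnames = list(ids, mk))
  het <- matrix(FALSE, n, m, dimnames = list(ids, mk))
  raw <- as.matrix(d[, -seq_len(meta_cols), drop = FALSE])
  for (j in seq_len(m)) {
    a <- alleles[[j]]
    if (length(a) != 2) abort(sprintf("marker %s is not biallelic", mk[j]))
    cj <- raw[j, ]
    hom0 <- cj == strrep(a[1], 2) | cj == a[1]
    hom1 <- cj == strrep(a[2], 2) | cj == a[2]
    hetc <- cj %in% c(paste0(a[1], a[2]), paste0(a[2], a[1]))
    missing <- cj %in% c("NN", "--", "N", "-", "")
    bad <- !(hom0 | hom1 | hetc | missing)
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf(
        "unknown allele code '%s' at marker %s, accession %s (alleles %s/%s)",
        cj[i], mk[j], ids[i], a[1], a[2]
      ))
    }
    calls[hom0, j] <- 0
    calls[hom1, j] <- 1
    calls[hetc, j] <- 1 # placeholder value; flagged and masked downstream
    het[hetc, j] <- TRUE
  }
  genotype_matrix(calls, het = het)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    inform(sprintf("dropping %d multi-allelic VCF record(s)", sum(multi)))
    v <- v[!multi, ]
    fix <- vcfR::getFIX(v)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  mk <- fix[, "ID"]
  mk[is.na(mk) | mk == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(mk) | mk == "."]
  if (anyDuplicated(mk)) abort("duplicate marker ids in VCF")
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  n_alt <- vapply(strsplit(ifelse(is.na(gt_clean), "./.", gt_clean), "/"),
                  function(x) sum(x == "1"), integer(1))
  n_obs <- vapply(strsplit(ifelse(is.na(gt_clean), "./.", gt_clean), "/"),
                  function(x) sum(x %in% c("0", "1")), integer(1))
  calls <- matrix(NA_real_, ncol(gt), nrow(gt))
  het <- matrix(FALSE, ncol(gt), nrow(gt))
  n_alt <- matrix(n_alt, nrow(gt), ncol(gt))
  n_obs <- matrix(n_obs, nrow(gt), ncol(gt))
  calls <- t(ifelse(n_obs == 0, NA_real_, as.numeric(n_alt > 0)))
  het <- t(n_obs == 2 & n_alt == 1)
  dimnames(calls) <- list(colnames(gt), mk)
  dimnames(het) <- dimnames(calls)
  het[is.na(het)] <- FALSE
  genotype_matrix(calls, het = het)
}

#' Write genotypes
#'
#' `write_genotypes()` writes the plain matrix TSV dialect (round-trips
#' through [read_genotypes()]); `write_genotypes_hapmap()` and
#' `write_genotypes_vcf()` write minimal valid files in those formats using
#' A/C as the two allele letters.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @param map optional genetic map tibble (`marker`, `chrom`, `cM`) used for
#'   positional columns in hapmap/VCF output.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  d <- as.data.frame(g$calls)
  d <- cbind(accession = rownames(g$calls), d)
  readr::write_tsv(as_tibble(d), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
write_genotypes_hapmap <- function(g, path, map = NULL) {
  mk <- markers(g)
  pos <- marker_positions(mk, map)
  codes <- apply(g$calls, 2, function(x) {
    out <- ifelse(is.na(x), "NN", ifelse(x == 0, "AA", "CC"))
    out
  })
  header <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
              "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
              accessions(g))
  body <- cbind(mk, "A/C", pos$chrom, pos$pos, "+", "NA", "NA", "NA", "NA",
                "NA", "NA", t(codes))
  lines <- c(paste(header, collapse = "\t"),
             apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
write_genotypes_vcf <- function(g, path, map = NULL) {
  mk <- markers(g)
  pos <- marker_positions(mk, map)
  gt <- apply(g$calls, 2, function(x) {
    ifelse(is.na(x), "./.", ifelse(x == 0, "0/0", "1/1"))
  })
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", accessions(g)), collapse = "\t")
  )
  body <- cbind(pos$chrom, pos$pos, mk, "A", "C", ".", "PASS", ".", "GT", t(gt))
  writeLines(c(header, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

marker_positions <- function(mk, map) {
  if (is.null(map)) {
    list(chrom = rep("1", length(mk)), pos = seq_along(mk))
  } else {
    i <- match(mk, map$marker)
    list(
      chrom = sub("^chr", "", map$chrom[i]),
      # cM scaled to an integer pseudo-bp coordinate
      pos = as.integer(round(map$cM[i] * 1e4)) + 1L
    )
  }
}
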