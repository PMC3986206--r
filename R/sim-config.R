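#' Simulation configuration for structured genotype data
#'
#' Defaults emulate a barley-like germplasm core: five admixed subpopulations
#' (four large, one small and more diverged), biallelic SNPs spread over seven
#' chromosomes totalling 1113 cM, low missingness, and map-distance-decaying
#' linkage disequilibrium.
#'
#' @param n_subpops number of subpopulations `k`.
#' @param n_per_subpop integer vector (length `k`) of pure accessions per
#'   subpopulation.
#' @param n_admixed number of admixed accessions (Dirichlet ancestry).
#' @param dirichlet_alpha positive scalar; symmetric Dirichlet concentration
#'   for admixed ancestry rows.
#' @param n_markers total number of biallelic markers.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_lengths_cM positive numeric vector of chromosome lengths (cM).
#' @param fst_per_subpop numeric vector (length `k`) of Balding-Nichols F
#'   values in (0, 1), one per subpopulation.
#' @param ancestral_maf_range length-2 numeric `(low, high)` in (0, 0.5];
#'   ancestral allele frequencies are drawn uniformly from this range.
#' @param missing_rate per-call missing probability in \[0, 1).
#' @param ld_decay_cM decay length lambda (cM) of the adjacent-marker copy
#'   chain: with probability `exp(-d / lambda)` a call copies the accession's
#'   call at the previous marker.
#' @param duplicate_sets integer vector of planted duplicate set sizes (each
#'   >= 2); each set is seeded by copying one source accession.
#' @param qtl_spec data frame with columns `marker` (index into the map order)
#'   and `effect`, or NULL for no planted QTL.
#' @param heritability narrow-sense heritability of the simulated phenotype in
#'   \[0, 1\].
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_markers = 200, seed = 1)
#' cfg$chrom_lengths_cM
#' @export
sim_config <- function(n_subpops = 5,
                       n_per_subpop = c(40, 55, 55, 41, 17),
                       n_admixed = 164,
                       dirichlet_alpha = 1.5,
                       n_markers = 1000,
                       n_chromosomes = 7,
                       chrom_lengths_cM = c(145, 181, 164, 130, 185, 139, 169),
                       fst_per_subpop = c(0.15, 0.15, 0.15, 0.15, 0.25),
                       ancestral_maf_range = c(0.1, 0.5),
                       missing_rate = 0.02,
                       ld_decay_cM = 2,
                       duplicate_sets = integer(),
                       qtl_spec = NULL,
                       heritability = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_subpops = as.integer(n_subpops),
    n_per_subpop = as.integer(n_per_subpop),
    n_admixed = as.integer(n_admixed),
    dirichlet_alpha = dirichlet_alpha,
    n_markers = as.integer(n_markers),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_lengths_cM = as.numeric(chrom_lengths_cM),
    fst_per_subpop = as.numeric(fst_per_subpop),
    ancestral_maf_range = as.numeric(ancestral_maf_range),
    missing_rate = missing_rate,
    ld_decay_cM = ld_decay_cM,
    duplicate_sets = as.integer(duplicate_sets),
    qtl_spec = qtl_spec,
    heritability = heritability,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  k <- cfg$n_subpops
  if (k < 1) abort("n_subpops must be >= 1")
  if (length(cfg$n_per_subpop) != k) {
    abort("n_per_subpop must have length n_subpops")
  }
  if (length(cfg$fst_per_subpop) != k) {
    abort("fst_per_subpop must have length n_subpops")
  }
  if (any(cfg$fst_per_subpop <= 0 | cfg$fst_per_subpop >= 1)) {
    abort("fst_per_subpop values must lie in (0, 1)")
  }
  if (length(cfg$chrom_lengths_cM) != cfg$n_chromosomes) {
    abort("chrom_lengths_cM must have length n_chromosomes")
  }
  if (any(cfg$chrom_lengths_cM <= 0)) {
    abort("chromosome lengths must be positive")
  }
  if (cfg$n_markers < cfg$n_chromosomes) {
    abort("n_markers must be >= n_chromosomes")
  }
  r <- cfg$ancestral_maf_range
  if (length(r) != 2 || r[1] <= 0 || r[2] > 0.5 || r[1] > r[2]) {
    abort("ancestral_maf_range must be (low, high) with 0 < low <= high <= 0.5")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    abort("missing_rate must be in [0, 1)")
  }
  if (cfg$ld_decay_cM < 0) abort("ld_decay_cM must be non-negative")
  if (any(cfg$duplicate_sets < 2)) {
    abort("duplicate set sizes must be >= 2")
  }
  if (!is.null(cfg$qtl_spec)) {
    stopifnot(all(c("marker", "effect") %in% names(cfg$qtl_spec)))
  }
  if (cfg$heritability < 0 || cfg$heritability > 1) {
    abort("heritability must be in [0, 1]")
  }
  has_effects <- !is.null(cfg$qtl_spec) && any(cfg$qtl_spec$effect != 0)
  if (cfg$heritability >= 1 && has_effects) {
    abort("heritability must be < 1 when QTL effects are nonzero")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> k=%d subpops (%s pure + %d admixed), %d markers on %d chromosomes (%g cM), seed=%d\n",
    x$n_subpops, paste(x$n_per_subpop, collapse = "+"), x$n_admixed,
    x$n_markers, x$n_chromosomes, sum(x$chrom_lengths_cM), x$seed
  ))
  invisible(x)
}
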