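# default parameter blocks for each pipeline stage
pipeline_defaults <- function() {
  list(
    seed = 1L,
    output_dir = "corecurator-output",
    simulate = list(enabled = TRUE, n_markers = 500, n_admixed = 60,
                    n_per_subpop = c(20, 27, 27, 21, 9),
                    duplicate_sets = c(2L, 3L),
                    qtl = list(markers = c(50L, 250L, 400L),
                               effect = 1),
                    heritability = 0.5),
    input = list(genotypes = NULL, format = "matrix-tsv", map = NULL,
                 q_matrix = NULL, phenotype = NULL),
    qc = list(max_marker_missing = 0.10, max_accession_missing = 0.10),
    dedup = list(min_overlap = 0.5, policy = "keep-most-complete"),
    structure = list(membership_threshold = 0.8, n_components = 10,
                     maf_min = 0.01),
    phipt = list(n_perm = 1000L),
    ld = list(maf_min = 0.05, max_admixture = 0.8, n_pcs = 11L,
              windows = list(c(1, 2), c(4, 5)),
              n_unlinked_pairs = 100000L, percentile = 99),
    gwas = list(maf_min = 0.01),
    minicore = list(fraction = 0.10, pic_form = "gene-diversity")
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML config (or takes a list), fills stage defaults (QC 0.10/0.10
#' missingness; membership threshold 0.8; 1,000 permutations; LD MAF 0.05,
#' admixture cap 0.8, 11 PCs, 1-2 and 4-5 cM windows, 100,000 unlinked
#' pairs, 99th percentile; GWAS MAF 0.01; mini-core fraction 0.10), rejects
#' unknown keys by name, and range-checks every threshold, reporting all
#' violations at once.
#'
#' @param config path to a YAML file, or a (possibly partial) named list.
#' @return A fully populated list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  defs <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (sect in names(config)) {
    if (is.list(defs[[sect]]) && is.list(config[[sect]])) {
      bad <- setdiff(names(config[[sect]]), names(defs[[sect]]))
      if (length(bad) > 0) {
        abort(sprintf("unknown config key(s) in '%s': %s",
                      sect, paste(bad, collapse = ", ")))
      }
    }
  }
  cfg <- modifyList(defs, config)
  errs <- character()
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(cfg$qc$max_marker_missing >= 0 && cfg$qc$max_marker_missing <= 1,
      "qc.max_marker_missing must lie in [0, 1]")
  chk(cfg$qc$max_accession_missing >= 0 && cfg$qc$max_accession_missing <= 1,
      "qc.max_accession_missing must lie in [0, 1]")
  chk(cfg$dedup$min_overlap >= 0 && cfg$dedup$min_overlap <= 1,
      "dedup.min_overlap must lie in [0, 1]")
  chk(cfg$dedup$policy %in% c("keep-first", "keep-most-complete"),
      "dedup.policy must be keep-first or keep-most-complete")
  chk(cfg$structure$membership_threshold > 0 && cfg$structure$membership_threshold < 1,
      "structure.membership_threshold must lie in (0, 1)")
  chk(cfg$phipt$n_perm >= 0, "phipt.n_perm must be non-negative")
  chk(cfg$ld$maf_min >= 0 && cfg$ld$maf_min < 0.5,
      "ld.maf_min must lie in [0, 0.5)")
  chk(cfg$ld$percentile > 0 && cfg$ld$percentile < 100,
      "ld.percentile must lie in (0, 100)")
  chk(cfg$ld$n_pcs >= 0, "ld.n_pcs must be non-negative")
  chk(cfg$gwas$maf_min >= 0 && cfg$gwas$maf_min < 0.5,
      "gwas.maf_min must lie in [0, 0.5)")
  chk(cfg$minicore$fraction > 0 && cfg$minicore$fraction <= 1,
      "minicore.fraction must lie in (0, 1]")
  chk(cfg$minicore$pic_form %in% c("gene-diversity", "botstein"),
      "minicore.pic_form must be gene-diversity or botstein")
  if (length(errs) > 0) {
    abort(paste(c("invalid pipeline config:", errs), collapse = "\n  - "))
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

# stable per-stage seed derived from the global seed and the stage name,
# so adding a stage never perturbs the randomness of earlier stages
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.numeric(global_seed) * 7919 + h) %% 2147483647)
}

#' Run the full curation and diversity pipeline
#'
#' Stages run in dependency order: simulate (or load inputs) -> heterozygote
#' masking and QC -> duplicate detection and resolution -> structure (PCA +
#' membership assignment) -> per-SNP Phi-PT scan -> LD decay and threshold ->
#' Q+K GWAS -> mini-core selection. Every output file is a TSV recorded in a
#' manifest with its MD5 hash, the stage parameters and the stage seed; a
#' rerun with the same config is byte-identical. A stage failure halts the
#' pipeline with the stage named; files already written are retained.
#'
#' @param config a `pipeline_config` (see [validate_config()]), a path to a
#'   YAML config, or a partial list.
#' @return A tibble manifest (`stage`, `file`, `md5`, `seed`, `params`)
#'   invisibly; the same table is written to `manifest.tsv` in the output
#'   directory.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- tibble(stage = character(), file = character(),
                     md5 = character(), seed = integer(), params = character())
  emit <- function(stage, name, writer, seed = NA_integer_, params = "") {
    path <- file.path(cfg$output_dir, name)
    writer(path)
    manifest <<- dplyr::bind_rows(manifest, tibble(
      stage = stage, file = name,
      md5 = unname(tools::md5sum(path)), seed = seed, params = params
    ))
    path
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }

  # --- inputs ---
  truth <- NULL
  geno <- map <- pheno <- qmat <- pca <- labels <- NULL
  if (isTRUE(cfg$simulate$enabled) && is.null(cfg$input$genotypes)) {
    run_stage("simulate", {
      s <- cfg$simulate
      scfg <- sim_config(
        n_per_subpop = s$n_per_subpop, n_admixed = s$n_admixed,
        n_markers = s$n_markers, duplicate_sets = s$duplicate_sets,
        qtl_spec = if (!is.null(s$qtl)) {
          data.frame(marker = s$qtl$markers,
                     effect = rep(s$qtl$effect, length(s$qtl$markers)))
        },
        heritability = s$heritability,
        seed = stage_seed(cfg$seed, "simulate")
      )
      map <- sim_genetic_map(scfg)
      sim <- sim_genotypes(scfg, map)
      geno <- sim$genotypes
      truth <- sim$truth
      pheno <- sim_phenotype(geno, scfg)
      qtab <- as_tibble(cbind(tibble(accession = rownames(truth$Q)),
                              as.data.frame(truth$Q)))
      emit("simulate", "genotypes.tsv", \(p) write_genotypes(geno, p),
           scfg$seed, sprintf("n_markers=%d", scfg$n_markers))
      emit("simulate", "map.tsv", \(p) readr::write_tsv(map, p, progress = FALSE))
      emit("simulate", "phenotype.tsv", \(p) readr::write_tsv(pheno, p, progress = FALSE))
      emit("simulate", "true_q.tsv", \(p) readr::write_tsv(qtab, p, progress = FALSE))
      qmat <- qtab
    })
  } else {
    run_stage("load", {
      geno <- read_genotypes(cfg$input$genotypes, cfg$input$format)
      map <- readr::read_tsv(cfg$input$map, show_col_types = FALSE, progress = FALSE)
      qmat <- if (!is.null(cfg$input$q_matrix)) read_q_matrix(cfg$input$q_matrix)
      pheno <- if (!is.null(cfg$input$phenotype)) {
        readr::read_tsv(cfg$input$phenotype, show_col_types = FALSE, progress = FALSE)
      }
    })
  }

  # --- qc ---
  run_stage("qc", {
    geno <- qc_filter(mask_heterozygotes(geno),
                       cfg$qc$max_marker_missing, cfg$qc$max_accession_missing)
    emit("qc", "genotypes_qc.tsv", \(p) write_genotypes(geno, p),
         params = sprintf("max_marker=%g,max_accession=%g",
                          cfg$qc$max_marker_missing, cfg$qc$max_accession_missing))
  })

  # --- dedup ---
  run_stage("dedup", {
    rep <- find_duplicates(geno, cfg$dedup$min_overlap)
    res <- resolve_duplicates(rep, geno, policy = cfg$dedup$policy)
    emit("dedup", "duplicates.tsv", \(p) readr::write_tsv(res, p, progress = FALSE),
         params = sprintf("policy=%s", cfg$dedup$policy))
    geno <- geno[res$accession[res$retained], ]
  })

  # --- structure ---
  run_stage("structure", {
    pca <- pca_genotypes(geno, cfg$structure$n_components, cfg$structure$maf_min)
    emit("structure", "pca_scores.tsv",
         \(p) readr::write_tsv(pca$scores, p, progress = FALSE))
    if (!is.null(qmat)) {
      qk <- qmat[qmat$accession %in% accessions(geno), ]
      labels <- assign_subpopulations(qk, cfg$structure$membership_threshold)
      emit("structure", "labels.tsv",
           \(p) readr::write_tsv(labels, p, progress = FALSE),
           params = sprintf("threshold=%g", cfg$structure$membership_threshold))
    } else {
      labels <- NULL
    }
  })

  # --- phi_pt scan ---
  if (!is.null(labels) && length(setdiff(unique(labels$label), "admixed")) >= 2) {
    run_stage("phipt", {
      sc <- phi_pt_scan(geno, labels, map = map, n_perm = cfg$phipt$n_perm,
                        seed = stage_seed(cfg$seed, "phipt"))
      emit("phipt", "phi_scan.tsv", \(p) readr::write_tsv(sc, p, progress = FALSE),
           stage_seed(cfg$seed, "phipt"),
           sprintf("n_perm=%d", cfg$phipt$n_perm))
    })
  }

  # --- LD ---
  run_stage("ld", {
    sub <- geno
    if (!is.null(labels)) {
      # exclude accessions with admixture above the cap
      keep <- labels$accession[labels$max_membership > 1 - cfg$ld$max_admixture]
      if (length(keep) >= 10) sub <- geno[intersect(accessions(geno), keep), ]
    }
    thr <- unlinked_threshold(sub, map,
                              n_pairs = cfg$ld$n_unlinked_pairs,
                              percentile = cfg$ld$percentile,
                              maf_min = cfg$ld$maf_min,
                              seed = stage_seed(cfg$seed, "ld"))
    dec <- decay_profile(sub, map, maf_min = cfg$ld$maf_min, threshold = thr)
    emit("ld", "ld_threshold.tsv", \(p) readr::write_tsv(
      tibble(threshold = thr$threshold, lambda = thr$lambda,
             percentile = thr$percentile, n_pairs = thr$n_pairs), p, progress = FALSE),
      stage_seed(cfg$seed, "ld"))
    emit("ld", "ld_decay.tsv", \(p) readr::write_tsv(as_tibble(dec), p, progress = FALSE))
  })

  # --- GWAS ---
  if (!is.null(pheno)) {
    run_stage("gwas", {
      res <- mlm_scan(geno, pheno, Q = qmat, maf_min = cfg$gwas$maf_min)
      mt <- manhattan_table(res, map)
      emit("gwas", "gwas.tsv", \(p) readr::write_tsv(mt, p, progress = FALSE),
           params = sprintf("maf_min=%g", cfg$gwas$maf_min))
    })
  }

  # --- mini-core ---
  run_stage("minicore", {
    mapped <- intersect(markers(geno), map$marker)
    rk <- rank_accessions(geno, marker_mask = mapped, form = cfg$minicore$pic_form)
    sel <- suppressWarnings(select_minicore(rk, fraction = cfg$minicore$fraction))
    emit("minicore", "pic_ranking.tsv",
         \(p) readr::write_tsv(rk$ranking, p, progress = FALSE),
         params = sprintf("form=%s,peak_size=%d", cfg$minicore$pic_form, rk$peak_size))
    emit("minicore", "minicore.tsv", \(p) readr::write_tsv(sel, p, progress = FALSE),
         params = sprintf("fraction=%g", cfg$minicore$fraction))
  })

  manifest_path <- file.path(cfg$output_dir, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path, progress = FALSE)
  invisible(manifest)
}
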