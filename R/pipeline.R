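# End-to-end orchestration: simulate -> QC -> score -> model ->
# consistency from a single config, with deterministic seeding and a run
# manifest.

#' Default pipeline configuration
#'
#' Nested list mirroring the module parameters: `simulate` ([sim_config()]
#' arguments), `qc` ([qc_thresholds()] arguments plus `n_pcs` and
#' `kinship`), `prs` ([clump_params()] arguments plus `drop_ambiguous`),
#' `apoe` (site IDs), `models` (model IDs), `consistency` (`pairs`),
#' `seed`, `out_dir`.
#'
#' @param ... named overrides merged over the defaults (top level or a
#'   whole section).
#' @return config list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 42L,
    out_dir = tempfile("prsbench_run_"),
    simulate = list(),
    qc = list(n_pcs = 8L, kinship = FALSE),
    prs = list(drop_ambiguous = TRUE),
    apoe = list(e4_site = "APOE_e4", e2_site = "APOE_e2"),
    models = paste0("M", 1:5),
    consistency = list(pairs = "all"))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; returns invisibly `TRUE` or stops with
#' an aggregated, human-readable error list.
#'
#' @param config list as from [default_config()] or [yaml::read_yaml()].
#' @return `TRUE` (invisibly) when valid.
#' @export
validate_config <- function(config) {
  errs <- character()
  if (is.null(config$seed)) errs <- c(errs, "seed: required")
  sim_ok <- tryCatch({ do.call(sim_config, config$simulate %||% list()); TRUE },
                     error = function(e) { errs <<- c(errs, paste0("simulate: ", conditionMessage(e))); FALSE })
  prs_args <- config$prs %||% list()
  prs_args$drop_ambiguous <- NULL
  tryCatch(do.call(clump_params, prs_args),
           error = function(e) errs <<- c(errs, paste0("prs: ", conditionMessage(e))))
  qc_args <- config$qc %||% list()
  qc_args$n_pcs <- NULL; qc_args$kinship <- NULL
  tryCatch(do.call(qc_thresholds, qc_args),
           error = function(e) errs <<- c(errs, paste0("qc: ", conditionMessage(e))))
  models <- config$models %||% paste0("M", 1:5)
  bad <- setdiff(models, names(MODEL_SPECS))
  if (length(bad)) errs <- c(errs, paste0("models: unknown id(s) ",
                                          paste(bad, collapse = ", ")))
  if (any(c("M1", "M5") %in% models) &&
      (is.null(config$apoe$e4_site) || is.null(config$apoe$e2_site)))
    errs <- c(errs, "apoe: e4_site and e2_site required for M1/M5")
  if (length(errs)) stop("invalid configuration:\n  - ",
                         paste(errs, collapse = "\n  - "), call. = FALSE)
  invisible(TRUE)
}

checksum_files <- function(paths) {
  ok <- file.exists(paths)
  sums <- rep(NA_character_, length(paths))
  sums[ok] <- unname(tools::md5sum(paths[ok]))
  stats::setNames(sums, basename(paths))
}

#' Run the benchmark pipeline end to end
#'
#' Simulates a cohort and its two discovery GWAS, applies variant QC and
#' genotype PCA, builds C+T score sets for both GWAS across region modes
#' (whole genome, APOE region excluded, APOE region only,
#' microglia-selective), selects the optimal p-value threshold by M5 AUC,
#' fits the requested risk models (plus the e3e3 subgroup and microglia
#' models), computes the score-consistency matrix, and writes all tables
#' plus a run manifest with per-file checksums to `config$out_dir`.
#'
#' @param config list as from [default_config()]; validated first.
#' @return list with `results` (model results table), `consistency`,
#'   `pt_selected`, `cohort_table`, `manifest`, `paths`.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  t0 <- Sys.time()
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_args <- config$simulate %||% list()
  if (is.null(sim_args$seed)) sim_args$seed <- config$seed
  scfg <- do.call(sim_config, sim_args)

  ## stage: simulate
  cohort <- simulate_cohort(scfg)
  gm <- cohort$genotypes
  ss_a <- simulate_gwas(cohort$truth, scfg, "A", gm$variants)
  ss_b <- simulate_gwas(cohort$truth, scfg, "B", gm$variants)
  microglia <- annotate_microglia(gm$variants, scfg)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             gwas_a = file.path(out_dir, "gwas_A.tsv"),
             gwas_b = file.path(out_dir, "gwas_B.tsv"),
             regions = file.path(out_dir, "microglia.bed"),
             covar = file.path(out_dir, "covariates.tsv"),
             results = file.path(out_dir, "results.tsv"),
             consistency = file.path(out_dir, "consistency.tsv"),
             manifest = file.path(out_dir, "manifest.yaml"))
  write_vcf(gm, paths["vcf"])
  write_sumstats(ss_a, paths["gwas_a"])
  write_sumstats(ss_b, paths["gwas_b"])
  write_bed(microglia, paths["regions"])

  ## stage: apoe (called on the pre-QC matrix: the two defining sites are
  ## genotyped regardless of how the PRS variant filters treat them)
  calls <- apoe_call_gm(gm, config$apoe$e4_site, config$apoe$e2_site)

  ## stage: qc
  qc_args <- config$qc %||% list()
  n_pcs <- qc_args$n_pcs %||% 8L
  do_kinship <- isTRUE(qc_args$kinship)
  qc_args$n_pcs <- NULL; qc_args$kinship <- NULL
  th <- do.call(qc_thresholds, qc_args)
  qc_out <- variant_qc(gm, th)
  gm <- qc_out$genotypes
  if (do_kinship) {
    K <- kinship_matrix(gm)
    keep <- prune_related(K, th$kinship_max)
    gm <- subset_gm(gm, i = match(keep, gm$samples))
  }
  pcs <- genotype_pca(gm, k = n_pcs)
  phenotype <- cohort$phenotype[match(gm$samples, cohort$phenotype$sample), ]
  covariates <- cbind(phenotype[c("sample", "age", "sex")],
                      as.data.frame(pcs))
  write_covariates(cbind(phenotype["status"], covariates), paths["covar"])

  ## stage: score + model
  params <- do.call(clump_params, {
    a <- config$prs %||% list(); a$drop_ambiguous <- NULL; a })
  drop_amb <- config$prs$drop_ambiguous %||% TRUE
  gwas_list <- list(A = ss_a, B = ss_b)
  alpha <- bonferroni_threshold(test_grid())
  results <- list(); cons_sets <- list(); pt_selected <- list()
  for (g in names(gwas_list)) {
    ss <- gwas_list[[g]]
    # empty thresholded sets give constant zero scores; their models are
    # skipped below, so the empty-set warnings are silenced here
    sets <- suppressWarnings(list(
      full = ct_pipeline(ss, gm, params, "full", gwas_id = g,
                         drop_ambiguous = drop_amb),
      noAPOE = ct_pipeline(ss, gm, params, "noAPOE", gwas_id = g,
                           drop_ambiguous = drop_amb),
      APOEonly = ct_pipeline(ss, gm, params, "APOEonly", gwas_id = g,
                             drop_ambiguous = drop_amb),
      microglia = ct_pipeline(ss, gm, params, "microglia", regions = microglia,
                              gwas_id = g, drop_ambiguous = drop_amb)))
    # optimal pT by M5 AUC (PRS_noAPOE + APOE counts); thresholds whose
    # model cannot be fit (e.g. no variant passes) are not selectable
    m5_auc <- vapply(seq_along(params$pt_grid), function(i) {
      tryCatch(run_models(list(PRS_noAPOE = sets$noAPOE[[i]]), calls,
                          phenotype, covariates, which = "M5",
                          gwas = g)[[1]]$auc,
               error = function(e) NA_real_)
    }, numeric(1))
    usable <- which(!is.na(m5_auc))
    if (!length(usable)) stop("no usable p-value threshold for GWAS ", g)
    pt_opt <- select_pt(params$pt_grid[usable], m5_auc[usable])
    i_opt <- match(pt_opt, params$pt_grid)
    pt_selected[[g]] <- pt_opt

    prs_main <- list(PRS_full = sets$full[[i_opt]],
                     PRS_noAPOE = sets$noAPOE[[i_opt]],
                     PRS_APOEonly = sets$APOEonly[[i_opt]])
    main <- safe_models(prs_main, calls, phenotype, covariates,
                        which = config$models, gwas = g, method = "C+T",
                        region_mode = "main", pt = pt_opt)
    e33 <- tryCatch(list(e33_subgroup(prs_main$PRS_full, calls, phenotype,
                                      covariates, gwas = g, method = "C+T",
                                      region_mode = "e33", pt = pt_opt)),
                    error = function(e) list())
    # microglia analysis selects its own optimal threshold, again by M5
    mic_noapoe <- suppressWarnings(
      microglia_noapoe_sets(ss, gm, params, microglia, g, drop_amb))
    mic_auc <- vapply(seq_along(params$pt_grid), function(i) {
      tryCatch(run_models(list(PRS_noAPOE = mic_noapoe[[i]]), calls,
                          phenotype, covariates, which = "M5",
                          gwas = g)[[1]]$auc,
               error = function(e) NA_real_)
    }, numeric(1))
    mic_usable <- which(!is.na(mic_auc))
    mic <- list()
    if (length(mic_usable)) {
      pt_mic <- select_pt(params$pt_grid[mic_usable], mic_auc[mic_usable])
      i_mic <- match(pt_mic, params$pt_grid)
      pt_selected[[paste0(g, "_microglia")]] <- pt_mic
      prs_mic <- list(PRS_full = sets$microglia[[i_mic]],
                      PRS_noAPOE = mic_noapoe[[i_mic]],
                      PRS_APOEonly = sets$APOEonly[[i_opt]])
      mic <- safe_models(prs_mic, calls, phenotype, covariates,
                         which = intersect(config$models, c("M2", "M3", "M4", "M5")),
                         gwas = g, method = "C+T", region_mode = "microglia",
                         pt = pt_mic)
      cons_sets[[paste0("M3_microglia_", g)]] <- prs_mic$PRS_full
    }
    results <- c(results, main, e33, mic)
    cons_sets[[paste0("M3_full_", g)]] <- prs_main$PRS_full
  }
  res_tab <- model_results_table(results, alpha = alpha)
  utils::write.table(res_tab, paths["results"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## stage: consistency
  cons <- consistency_matrix(cons_sets, config$consistency$pairs %||% "all")
  utils::write.table(cons, paths["consistency"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## manifest
  ctab <- cohort_table(phenotype, calls)
  manifest <- list(
    seed = config$seed,
    config = utils::modifyList(config, list(out_dir = NULL)),
    n_samples = length(gm$samples), n_variants = nrow(gm$variants),
    pt_selected = pt_selected,
    checksums = as.list(checksum_files(paths[names(paths) != "manifest"])),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  yaml::write_yaml(manifest, paths["manifest"])
  list(results = res_tab, consistency = cons, pt_selected = pt_selected,
       cohort_table = ctab, manifest = manifest, paths = paths)
}

# run_models one model at a time, skipping (with a message) models that
# cannot be fit on this realization (degenerate predictor, separation).
safe_models <- function(prs, calls, phenotype, covariates, which, ...) {
  out <- list()
  for (mid in which) {
    r <- tryCatch(run_models(prs, calls, phenotype, covariates,
                             which = mid, ...),
                  error = function(e) {
                    message("skipping ", mid, ": ", conditionMessage(e))
                    NULL
                  })
    if (!is.null(r)) out <- c(out, r)
  }
  out
}

# Microglia-restricted score sets with the APOE sub-interval removed (the
# microglia M4/M5 analogues), one per threshold in the grid.
microglia_noapoe_sets <- function(ss, gm, params, microglia, gwas_id,
                                  drop_amb) {
  w <- harmonize(ss, gm, drop_ambiguous = drop_amb, gwas_id = gwas_id)
  w <- restrict_region(w, microglia, "include")
  w <- restrict_region(w, apoe_region(), "exclude")
  w <- clump(w, gm, params)
  lapply(params$pt_grid, function(pt) {
    prs_score(gm, threshold_weights(w, pt), gwas = gwas_id,
              region_mode = "microglia", pt = pt)
  })
}
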