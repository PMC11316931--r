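#' Default pipeline configuration
#'
#' Flat configuration for [run_pipeline()]: the synthetic-cohort settings
#' plus every analysis threshold, in one list so a single seed governs the
#' whole run. Any entry can be overridden via `...` or supplied from a YAML
#' file through [read_pipeline_config()].
#'
#' @param ... Overrides of individual fields (e.g. `n_perm = 99`, or
#'   `cohort = cohort_config(...)`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    cohort = cohort_config(),
    alpha = 0.05,             # BH threshold for differential features
    cpm_min = 5,              # strict CPM filter for the MTT group
    sim_min = 200,            # strict similarity filter for metabolites
    prev_min = 0.5,           # strict prevalence filter
    n_perm = 999,             # PERMANOVA permutations
    iv_p_max = 0.001,         # instrument threshold (BH-adjusted p)
    iv_use_adjusted = TRUE,
    iv_fallback_raw_p = TRUE, # fall back to raw p < iv_p_max if none pass
    ld_r2_max = 0.1,
    maf_min = 0.05, missing_max = 0.1, hwe_alpha = 1e-6,
    n_boot = 1000             # MR / mediation bootstrap resamples
  )
  over <- list(...)
  if (!is.null(over$cohort) && !inherits(over$cohort, "cohort_config")) {
    over$cohort <- do.call(cohort_config, over$cohort)
  }
  cfg <- utils::modifyList(cfg, over)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file is a flat mapping of [pipeline_config()] fields; a nested
#' `cohort:` mapping holds [cohort_config()] fields.
#'
#' @param path Path to the YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

stage_log <- function(stage, msg) {
  rlang::inform(sprintf("[%s] %s", stage, msg))
}

stage_error <- function(stage, e) {
  hg_abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           "stage_failure")
}

#' Run the full holo-omics pipeline on a synthetic cohort
#'
#' Executes, in order: cohort simulation (skipped when `resume = TRUE` and
#' the simulation outputs already exist in `out_dir`), CPM normalization and
#' differential testing per layer, MTP fold-change quartiling and COG
#' enrichment with quartile clustering, functional-group construction
#' (MTT/MTP/MTB) with Venn counts, Sankey export and per-layer Bray-Curtis
#' PERMANOVA, diversity summaries, variant QC + kinship + REML + marker
#' scans for the taxon (exposure) and mediator (outcome), instrument
#' selection + harmonization + the five-method MR report, and mediation
#' analysis of taxon -> mediator -> phenotype. All outputs are TSV/JSON
#' files named deterministically under `out_dir`; every source of randomness
#' derives from the cohort seed.
#'
#' @param config A [pipeline_config()] (or a list of overrides).
#' @param out_dir Output directory.
#' @param resume Reuse existing simulation outputs in `out_dir` if present.
#' @return A run manifest (list of class `run_manifest`): config snapshot,
#'   stage order, per-file MD5 digests, package version, and the key
#'   results (`groups`, `comparison`, `mr`, `mediation`, `reml`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, resume = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, as.list(config))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  ccfg <- config$cohort

  # --- simulate ---------------------------------------------------------
  sim_marker <- file.path(out_dir, "truth.json")
  cohort <- tryCatch({
    if (resume && file.exists(sim_marker)) {
      stage_log("simulate", "resuming from existing outputs")
      load_cohort_outputs(out_dir, ccfg)
    } else {
      stage_log("simulate", sprintf("generating cohort (seed %d)", ccfg$seed))
      co <- simulate_cohort(ccfg)
      write_cohort(co, out_dir)
      co
    }
  }, error = function(e) stage_error("simulate", e))
  stages <- c(stages, "simulate")

  # --- differential per layer ------------------------------------------
  diffs <- tryCatch({
    out <- list()
    for (layer in names(cohort$tables)) {
      cpm <- normalize_cpm(cohort$tables[[layer]])
      res <- diff_test(cpm, cohort$samples, alpha = config$alpha)
      if (layer == "MTP") {
        res <- fold_change_quartiles(res, alpha = config$alpha)
      }
      readr::write_tsv(res, file.path(out_dir,
                                      sprintf("differential_%s.tsv",
                                              tolower(layer))))
      out[[layer]] <- res
    }
    out
  }, error = function(e) stage_error("differential", e))
  stages <- c(stages, "differential")

  # --- enrichment (MTP, COG, per quartile) -----------------------------
  enr <- tryCatch({
    ann <- cohort$annotations$MTP
    res <- diffs$MTP
    bg <- res$feature_id
    per_q <- list()
    for (q in c("Q1", "Q2", "Q3", "Q4")) {
      ids <- res$feature_id[!is.na(res$quartile) & res$quartile == q]
      if (length(ids) > 0) {
        per_q[[q]] <- fisher_enrichment(ids, bg, ann, "COG")
      }
    }
    cl <- if (length(per_q) >= 2) {
      tryCatch(quartile_cluster_matrix(per_q, p_threshold = 0.05),
               hologuild_input_error = function(e) {
                 stage_log("enrichment", "no category retained for clustering")
                 NULL
               })
    } else NULL
    if (!is.null(cl)) {
      zt <- dplyr::bind_cols(tibble::tibble(category = rownames(cl$z)),
                             tibble::as_tibble(cl$z))
      readr::write_tsv(zt, file.path(out_dir, "enrichment_quartile_z.tsv"))
    }
    readr::write_tsv(dplyr::bind_rows(per_q, .id = "quartile"),
                     file.path(out_dir, "enrichment_mtp_cog.tsv"))
    list(per_quartile = per_q, clusters = cl)
  }, error = function(e) stage_error("enrichment", e))
  stages <- c(stages, "enrichment")

  # --- functional groups ------------------------------------------------
  grp_res <- tryCatch({
    groups <- list(
      MTT = build_mtt_group(cohort$tables$MTT, cohort$samples,
                            cohort$annotations$MTT, cpm_min = config$cpm_min,
                            alpha = config$alpha),
      MTP = build_mtp_group(normalize_cpm(cohort$tables$MTP), cohort$samples,
                            cohort$annotations$MTP,
                            diff_results = diffs$MTP, alpha = config$alpha),
      MTB = build_mtb_group(cohort$tables$MTB, cohort$samples,
                            cohort$annotations$MTB, alpha = config$alpha,
                            sim_min = config$sim_min,
                            prev_min = config$prev_min)
    )
    for (layer in names(groups)) {
      readr::write_tsv(groups[[layer]]$members,
                       file.path(out_dir, sprintf("group_%s_members.tsv",
                                                  tolower(layer))))
      if (nrow(groups[[layer]]$provenance) > 0) {
        readr::write_tsv(export_sankey(groups[[layer]]),
                         file.path(out_dir, sprintf("sankey_%s.tsv",
                                                    tolower(layer))))
      }
    }
    comparison <- compare_groups(groups, cohort$tables, cohort$samples,
                                 n_perm = config$n_perm,
                                 seed = ccfg$seed + 10L)
    jsonlite::write_json(comparison$venn,
                         file.path(out_dir, "venn_counts.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    readr::write_tsv(comparison$permanova,
                     file.path(out_dir, "group_permanova.tsv"))
    list(groups = groups, comparison = comparison)
  }, error = function(e) stage_error("groups", e))
  stages <- c(stages, "groups")

  # --- community stats (MTP layer) -------------------------------------
  community <- tryCatch({
    m <- ft_matrix(cohort$tables$MTP)
    div <- tibble::tibble(
      sample_id = colnames(m),
      shannon = apply(m, 2, shannon_index),
      chao1 = apply(round(m), 2, chao1_richness)
    )
    readr::write_tsv(div, file.path(out_dir, "diversity_mtp.tsv"))
    pca <- pca_scores(cohort$tables$MTP)
    readr::write_tsv(pca$scores[, 1:3],
                     file.path(out_dir, "pca_scores_mtp.tsv"))
    div
  }, error = function(e) stage_error("community", e))
  stages <- c(stages, "community")

  # --- gwas -------------------------------------------------------------
  gwas_res <- tryCatch({
    stage_log("gwas", "variant QC, kinship, REML, marker scans")
    qcd <- qc_variants(cohort$genotypes, maf_min = config$maf_min,
                       missing_max = config$missing_max,
                       hwe_alpha = config$hwe_alpha)
    K <- kinship_matrix(qcd)
    fit <- fit_null_reml(cohort$cohort$taxon, K)
    scan_exp <- marker_scan(cohort$cohort$taxon, qcd, fit)
    fit_out <- fit_null_reml(cohort$cohort$mediator, fit$eigen)
    scan_out <- marker_scan(cohort$cohort$mediator, qcd, fit_out)
    write_gwas_summary(scan_exp, file.path(out_dir, "gwas_taxon.tsv"))
    write_gwas_summary(scan_out, file.path(out_dir, "gwas_mediator.tsv"))
    list(qcd = qcd, fit = fit, exposure = scan_exp, outcome = scan_out)
  }, error = function(e) stage_error("gwas", e))
  stages <- c(stages, "gwas")

  # --- mr ---------------------------------------------------------------
  mr_res <- tryCatch({
    iv <- tryCatch(
      select_instruments(gwas_res$exposure, gwas_res$qcd,
                         p_adj_max = config$iv_p_max,
                         ld_r2_max = config$ld_r2_max,
                         use_adjusted = config$iv_use_adjusted),
      hologuild_empty_instruments = function(e) {
        if (!isTRUE(config$iv_fallback_raw_p)) stop(e)
        stage_log("mr", "no variant at the adjusted threshold; falling back to raw p")
        select_instruments(gwas_res$exposure, gwas_res$qcd,
                           p_adj_max = config$iv_p_max,
                           ld_r2_max = config$ld_r2_max,
                           use_adjusted = FALSE)
      })
    h <- harmonize_instruments(
      gwas_res$exposure[gwas_res$exposure$variant_id %in% iv, ],
      gwas_res$outcome[gwas_res$outcome$variant_id %in% iv, ]
    )
    rep <- mr_report(h, n_boot = config$n_boot, seed = ccfg$seed + 20L)
    write_mr_report(rep, file.path(out_dir, "mr_taxon_mediator.tsv"),
                    exposure = "taxon", outcome = "mediator")
    list(instruments = iv, harmonized = h, report = rep)
  }, error = function(e) stage_error("mr", e))
  stages <- c(stages, "mr")

  # --- mediation --------------------------------------------------------
  med <- tryCatch({
    fit <- fit_mediation(cohort$cohort, "taxon", "mediator", "phenotype",
                         n_boot = config$n_boot, seed = ccfg$seed + 30L)
    write_mediation(fit, file.path(out_dir, "mediation.tsv"))
    fit
  }, error = function(e) stage_error("mediation", e))
  stages <- c(stages, "mediation")

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  digests <- tools::md5sum(files)
  names(digests) <- basename(names(digests))
  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("hologuild")),
    seed = ccfg$seed,
    stages = stages,
    config = unclass(config[setdiff(names(config), "cohort")]),
    cohort_config = unclass(ccfg),
    files = as.list(digests),
    results = list(groups = grp_res$groups,
                   comparison = grp_res$comparison,
                   mr = mr_res$report, mediation = med,
                   reml = gwas_res$fit,
                   n_instruments = length(mr_res$instruments))
  ), class = "run_manifest")
  jsonlite::write_json(
    manifest[c("package_version", "seed", "stages", "config",
               "cohort_config", "files")],
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  manifest
}

# rebuild a synthetic_cohort from the files written by write_cohort()
load_cohort_outputs <- function(dir, config) {
  genos <- read_plink(file.path(dir, "genotypes"))
  tables <- list()
  annotations <- list()
  for (layer in c("MTT", "MTP", "MTB")) {
    tables[[layer]] <- read_feature_table(
      file.path(dir, sprintf("%s_abundance.tsv", tolower(layer))), layer)
    annotations[[layer]] <- read_annotations(
      file.path(dir, sprintf("%s_annotations.tsv", tolower(layer))))
  }
  samples <- read_phenotype(file.path(dir, "phenotype.tsv"))
  traits <- readr::read_tsv(file.path(dir, "cohort_traits.tsv"),
                            show_col_types = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(genotypes = genos, cohort = traits, tables = tables,
                 annotations = annotations, samples = samples, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> hologuild %s, seed %d\n", x$package_version,
              x$seed))
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  cat(sprintf("  files: %d (md5-digested)\n", length(x$files)))
  invisible(x)
}

#' PCA score plot coloured by group
#'
#' @param pca Output of [pca_scores()].
#' @param samples Sample tibble with `sample_id` and `group`.
#' @return A ggplot object.
#' @export
plot_pca <- function(pca, samples) {
  sc <- dplyr::left_join(pca$scores, samples, by = "sample_id")
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * pca$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * pca$explained[2])
    ) +
    ggplot2::theme_minimal()
}
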