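# end-to-end pipeline: simulate? -> preprocess -> mwas -> integrate -> score
# -> transfer? -> cox/km/grid -> pathways?, with a digest-bearing manifest

#' Pipeline configuration with the study-default thresholds
#'
#' Collects every stage threshold in one place: 90% presence and 10% CV for
#' metabolite QC, 0.8 correlation-pruning ceiling, 10-fold CV LASSO at the
#' minimum-CV-error penalty, >=10% variance per retained component, 5% FDR,
#' top-50 genes per metabolite, top-3 pathways per phenotype, and a 10-year
#' composite horizon.
#'
#' @param generator a [generator_config()] (used when simulating).
#' @param presence_min,cv_max metabolite QC thresholds.
#' @param prune_threshold absolute-correlation pruning ceiling.
#' @param folds,cv_seed,lasso_rule LASSO cross-validation settings.
#' @param min_prop minimum variance proportion per component.
#' @param fdr_level FDR threshold used throughout.
#' @param top_k,top_n pathway expansion and reporting sizes.
#' @param horizon_years composite-endpoint censoring horizon.
#' @param attenuation,hazard_scale younger-cohort generation settings.
#' @param run_mwas_stage,run_transfer,run_pathways stage switches.
#' @param mapping,pathway_sets optional pathway-stage tables.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            presence_min = 0.90, cv_max = 0.10,
                            prune_threshold = 0.8,
                            folds = 10L, cv_seed = 1L,
                            lasso_rule = "min",
                            min_prop = 0.10, fdr_level = 0.05,
                            top_k = 50L, top_n = 3L,
                            horizon_years = 10,
                            attenuation = 0.6, hazard_scale = 0.5,
                            run_mwas_stage = TRUE, run_transfer = TRUE,
                            run_pathways = FALSE,
                            mapping = NULL, pathway_sets = NULL) {
  if (run_pathways && (is.null(mapping) || is.null(pathway_sets)))
    stop("pathway stage requested without mapping/pathway tables")
  structure(as.list(environment()), class = "pipeline_config")
}

preprocess_cohort <- function(cohort, cfg) {
  qc <- qc_filter(cohort$metabolites, cfg$presence_min, cfg$cv_max)
  imputed <- impute_half_min(qc$matrix)
  std <- log_standardize(imputed)
  harmonized <- harmonize_phenotypes(cohort$phenotypes, cohort$pheno_config,
                                     heights = cohort$covariates$height)
  list(std = std, harmonized = harmonized, exclusions = qc$exclusions)
}

#' Run the aging-axes pipeline end to end
#'
#' Simulates (or accepts) paired cohorts, preprocesses the discovery cohort,
#' optionally runs the metabolome-wide association scan, fits the LASSO-PCA
#' integration and metabolic scores, transfers weights to the second cohort,
#' fits Cox models for each endpoint and the healthy-aging composite,
#' computes Kaplan-Meier tertile tables, the score-phenotype grid in the
#' transfer cohort, and (optionally) pathway enrichment. All tables are
#' written to `out_dir` together with a manifest of content digests.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory; created if needed.
#' @param cohorts optional list(older=, younger=) of `synthetic_cohort`
#'   objects; when NULL they are generated from `config$generator`.
#' @param seed overrides `config$generator$seed` when given.
#' @return list with every stage result plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         cohorts = NULL, seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  gen <- config$generator
  if (!is.null(seed)) gen$seed <- check_count(seed, "seed", 0L)
  if (is.null(cohorts)) {
    if (config$run_transfer) {
      cohorts <- generate_paired_cohorts(gen, config$attenuation,
                                         config$hazard_scale)
    } else {
      cohorts <- list(older = generate_cohort(gen))
    }
  }
  if (config$run_transfer && is.null(cohorts$younger))
    stop("transfer stage requested without a second cohort")
  older <- cohorts$older
  tick("simulate")

  prep <- preprocess_cohort(older, config)
  write_tsv(prep$exclusions, file.path(out_dir, "qc_exclusions.tsv"))
  tick("preprocess")

  mwas_res <- NULL
  if (config$run_mwas_stage) {
    mwas_res <- run_mwas(prep$harmonized, prep$std,
                         older$covariates[, c("age", "sex", "race")],
                         fdr_level = config$fdr_level)
    write_tsv(mwas_res, file.path(out_dir, "mwas.tsv"))
    overlap <- domain_overlap(mwas_res)
    write_tsv(overlap$intersections,
              file.path(out_dir, "domain_overlap.tsv"))
    tick("mwas")
  }

  pruned <- prune_correlated(prep$std, config$prune_threshold)
  Z <- prep$std$z[, pruned$kept, drop = FALSE]
  coefs <- lapply(colnames(prep$harmonized$values), function(ph)
    fit_lasso_phenotype(prep$harmonized$values[, ph], Z,
                        folds = config$folds, cv_seed = config$cv_seed,
                        rule = config$lasso_rule)$coef)
  names(coefs) <- colnames(prep$harmonized$values)
  B <- assemble_coefficients(coefs)
  axes <- pca_on_coefficients(B)
  k <- select_components(axes$variance_proportion, config$min_prop)
  scores <- compute_scores(axes, Z, k = k, cohort = older$cohort)
  ol <- orient_and_label(axes, scores, prep$harmonized)
  axes <- ol$axes
  scores <- ol$scores
  write_tsv(unclass(B), file.path(out_dir, "coefficients.tsv"),
            id_col = "metabolite")
  write_tsv(axes$loadings[, seq_len(k), drop = FALSE],
            file.path(out_dir, "loadings.tsv"), id_col = "phenotype")
  write_tsv(axes$weights[, seq_len(k), drop = FALSE],
            file.path(out_dir, "weights.tsv"), id_col = "metabolite")
  write_tsv(data.frame(component = names(axes$variance_proportion),
                       proportion = unname(axes$variance_proportion)),
            file.path(out_dir, "variance_proportion.tsv"))
  write_tsv(scores$scores, file.path(out_dir, "scores_older.tsv"))
  tick("integrate")

  transfer <- NULL
  if (config$run_transfer) {
    younger <- cohorts$younger
    prep_y <- preprocess_cohort(younger, config)
    scores_y <- transfer_scores(axes, prep_y$std, k = k, zero_fill = TRUE)
    grid <- association_grid(
      scores_y, prep_y$harmonized,
      younger$covariates,
      tiers = list(minimal = c("age", "sex", "race"),
                   full = c("age", "sex", "race", "education", "smoker",
                            "bmi", "hypertension", "diabetes")),
      fdr_level = config$fdr_level)
    write_tsv(scores_y$scores, file.path(out_dir, "scores_younger.tsv"))
    write_tsv(grid, file.path(out_dir, "association_grid.tsv"))
    transfer <- list(scores = scores_y, grid = grid, prep = prep_y)
    tick("transfer")
  }

  composite <- build_composite(older$outcomes, config$horizon_years)
  idx <- match(composite$participant_id, rownames(scores$scores))
  cox_rows <- list()
  km_tables <- list()
  endpoints <- unique(older$outcomes$endpoint)
  for (a in seq_len(k)) {
    s_comp <- scores$scores[idx, a]
    for (tier in c("minimal", "full")) {
      cx <- fit_cox(s_comp, composite$time_years, composite$event,
                    older$covariates[idx, ], tier = tier,
                    reciprocal = TRUE)
      cox_rows[[length(cox_rows) + 1L]] <- data.frame(
        score = colnames(scores$scores)[a], endpoint = "healthy_aging",
        tier = tier, hr = cx$hr, ci_lower = cx$ci_lower,
        ci_upper = cx$ci_upper, p = cx$p, n = cx$n, n_event = cx$n_event)
      for (ep in endpoints) {
        oc <- older$outcomes[older$outcomes$endpoint == ep, ]
        oc <- oc[oc$prevalent == 0L, ]
        j <- match(oc$participant_id, rownames(scores$scores))
        cxe <- fit_cox(scores$scores[j, a], oc$time_years, oc$event,
                       older$covariates[j, ], tier = tier)
        cox_rows[[length(cox_rows) + 1L]] <- data.frame(
          score = colnames(scores$scores)[a], endpoint = ep, tier = tier,
          hr = cxe$hr, ci_lower = cxe$ci_lower, ci_upper = cxe$ci_upper,
          p = cxe$p, n = cxe$n, n_event = cxe$n_event)
      }
    }
    km <- km_by_tertile(scores$scores[idx, a], composite$time_years,
                        composite$event)
    km$score <- colnames(scores$scores)[a]
    km_tables[[a]] <- km
  }
  cox_table <- do.call(rbind, cox_rows)
  km_table <- do.call(rbind, km_tables)
  write_tsv(composite, file.path(out_dir, "composite.tsv"))
  write_tsv(cox_table, file.path(out_dir, "cox.tsv"))
  write_tsv(km_table, file.path(out_dir, "km_tertiles.tsv"))
  tick("outcomes")

  pathway_report <- NULL
  if (config$run_pathways) {
    if (is.null(mwas_res))
      stop("pathway stage needs the mwas stage")
    bg <- build_background(colnames(prep$std$z), config$mapping,
                           config$top_k)
    by_ph <- split(mwas_res, mwas_res$phenotype)
    enr <- lapply(by_ph, function(d) {
      target <- expand_to_genes(d$metabolite[d$significant],
                                config$mapping, config$top_k)
      r <- enrich_pathways(target, config$pathway_sets, bg,
                           config$fdr_level)
      if (!any(d$significant)) attr(r, "note") <- "no significant metabolites"
      r
    })
    pathway_report <- top_pathways(enr, config$top_n)
    write_tsv(pathway_report, file.path(out_dir, "pathways.tsv"))
    tick("pathways")
  }

  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    seed = gen$seed,
    k_selected = k,
    variance_proportion = unname(axes$variance_proportion),
    labels = unname(axes$labels[seq_len(k)]),
    stage_timings = as.list(timings),
    outputs = as.list(tools::md5sum(outputs)))
  names(manifest$outputs) <- basename(outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(older = older, prep = prep, mwas = mwas_res, pruned = pruned,
       coefficients = B, axes = axes, k = k, scores = scores,
       transfer = transfer, composite = composite, cox = cox_table,
       km = km_table, pathways = pathway_report, manifest = manifest)
}
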