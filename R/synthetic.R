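#' Default phenotype design for the synthetic aging cohort
#'
#' Twenty phenotypes over the seven canonical aging domains, each driven by a
#' single latent axis: axis 1 (body composition: fat depots, vascular
#' stiffness, glycemic load), axis 2 (mental-physical performance: cognition
#' and physical function), axis 3 (muscle strength/mass), axis 4 (physical
#' activity and diet quality). Adverse-oriented, log-transformed and
#' height-indexed phenotypes mirror the usual cohort conventions.
#'
#' @param n_phenotypes number of phenotypes; the curated table is defined for
#'   20, other values cycle a generic design.
#' @param n_axes number of latent axes (phenotypes assigned round-robin when
#'   not using the curated 20/4 table).
#' @return data.frame: phenotype, domain, orientation, transform,
#'   index_to_height, axis.
#' @export
default_phenotype_design <- function(n_phenotypes = 20L, n_axes = 4L) {
  if (n_phenotypes == 20L && n_axes == 4L) {
    return(data.frame(
      phenotype = c("gait_speed", "epese_score", "perf_battery",
                    "walk_time", "energy_expenditure",
                    "cognition_3ms", "dsst", "clock_drawing", "exit15",
                    "intermuscular_fat", "visceral_fat", "subq_fat",
                    "visc_subq_ratio", "quad_muscle_area",
                    "isokinetic_strength", "grip_strength",
                    "pulse_wave_velocity", "diet_quality", "glycemic_load",
                    "psychosocial_risk"),
      domain = c(rep("physical_function", 3), rep("physical_activity", 2),
                 rep("neurocognitive", 4), rep("adiposity_sarcopenia", 7),
                 "vascular", rep("dietary", 2), "psychosocial"),
      orientation = c(rep("higher_better", 8), "adverse",
                      rep("adverse", 4), rep("higher_better", 3),
                      "adverse", "higher_better", "adverse", "adverse"),
      transform = c(rep("none", 3), "log", rep("none", 14), "log", "none"),
      index_to_height = c(rep(FALSE, 9), TRUE, TRUE, TRUE, FALSE, TRUE,
                          rep(FALSE, 6)),
      axis = c(2L, 2L, 3L, 4L, 4L, 2L, 2L, 3L, 2L,
               1L, 1L, 1L, 1L, 3L, 3L, 3L, 1L, 4L, 1L, 4L),
      stringsAsFactors = FALSE))
  }
  domains <- c("physical_function", "physical_activity", "neurocognitive",
               "adiposity_sarcopenia", "vascular", "dietary", "psychosocial")
  data.frame(
    phenotype = sprintf("pheno_%02d", seq_len(n_phenotypes)),
    domain = rep_len(domains, n_phenotypes),
    orientation = rep_len(c("higher_better", "higher_better", "adverse"),
                          n_phenotypes),
    transform = "none",
    index_to_height = FALSE,
    axis = rep_len(seq_len(n_axes), n_phenotypes),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic two-cohort generator
#'
#' The generator plants `n_axes` latent "aging axes" (unit variance by
#' construction) that drive disjoint blocks of metabolites on the log scale
#' and single-axis phenotypes, and whose linear combination sets the log
#' hazard of each survival endpoint. Signal-to-noise ratios are the ratio of
#' axis-explained to residual variance. The lowest `lod_quantile` of each
#' metabolite column is censored to missing (limit-of-detection behaviour)
#' plus a small uniform missingness component.
#'
#' @param n_participants participants per cohort (default 2500).
#' @param n_metabolites number of metabolites (default 500).
#' @param n_phenotypes number of phenotypes (default 20).
#' @param n_axes number of latent axes k (default 4).
#' @param phenotype_design optional data.frame as from
#'   [default_phenotype_design()]; derives the domain map.
#' @param metabolite_loading_sparsity fraction of metabolites loading on each
#'   axis (disjoint blocks; default 0.2).
#' @param snr_phenotype,snr_metabolite axis-signal to noise variance ratios
#'   (default 1).
#' @param lod_quantile fraction of each metabolite column censored as below
#'   detection (default 0.05).
#' @param extra_missing_rate additional missing-at-random fraction (default 0.01).
#' @param qc_replicates pooled-QC replicate rows (default 30).
#' @param cv_target analytic CV of QC replicates (default 0.05).
#' @param log_hr_per_sd per-axis log hazard ratios per axis SD (recycled to
#'   `n_axes`; default c(-0.3, -0.2, -0.2, -0.1)).
#' @param baseline_hazard constant baseline event rate per year (default 0.05).
#' @param followup_years administrative censoring horizon (default 10).
#' @param covariate_effects named vector of age/sex/race effects on phenotype
#'   latent scale.
#' @param seed integer RNG seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_participants = 2500L,
                             n_metabolites = 500L,
                             n_phenotypes = 20L,
                             n_axes = 4L,
                             phenotype_design = NULL,
                             metabolite_loading_sparsity = 0.2,
                             snr_phenotype = 1.0,
                             snr_metabolite = 1.0,
                             lod_quantile = 0.05,
                             extra_missing_rate = 0.01,
                             qc_replicates = 30L,
                             cv_target = 0.05,
                             log_hr_per_sd = c(-0.3, -0.2, -0.2, -0.1),
                             baseline_hazard = 0.05,
                             followup_years = 10,
                             covariate_effects = c(age = -0.15, sex = 0.10,
                                                   race = 0.05),
                             seed = 1L) {
  n_participants <- check_count(n_participants, "n_participants", 2L)
  n_metabolites <- check_count(n_metabolites, "n_metabolites", 1L)
  n_phenotypes <- check_count(n_phenotypes, "n_phenotypes", 1L)
  n_axes <- check_count(n_axes, "n_axes", 1L)
  if (n_axes > min(n_metabolites, n_phenotypes))
    stop_field("n_axes", "must be <= min(n_metabolites, n_phenotypes)")
  check_fraction(metabolite_loading_sparsity, "metabolite_loading_sparsity")
  if (metabolite_loading_sparsity * n_axes > 1)
    stop_field("metabolite_loading_sparsity",
               "sparsity * n_axes must be <= 1 (disjoint loading blocks)")
  check_fraction(lod_quantile, "lod_quantile")
  check_fraction(extra_missing_rate, "extra_missing_rate")
  qc_replicates <- check_count(qc_replicates, "qc_replicates", 0L)
  if (!is.numeric(snr_phenotype) || snr_phenotype <= 0)
    stop_field("snr_phenotype", "must be > 0 (use Inf for noise-free)")
  if (!is.numeric(snr_metabolite) || snr_metabolite <= 0)
    stop_field("snr_metabolite", "must be > 0 (use Inf for noise-free)")
  if (!is.numeric(followup_years) || followup_years <= 0)
    stop_field("followup_years", "must be > 0")
  if (!is.numeric(baseline_hazard) || baseline_hazard <= 0)
    stop_field("baseline_hazard", "must be > 0")
  if (!is.numeric(cv_target) || cv_target < 0)
    stop_field("cv_target", "must be >= 0")
  seed <- check_count(seed, "seed", 0L)
  if (is.null(phenotype_design))
    phenotype_design <- default_phenotype_design(n_phenotypes, n_axes)
  if (nrow(phenotype_design) != n_phenotypes)
    stop_field("phenotype_design", "row count must equal n_phenotypes")
  if (any(phenotype_design$axis > n_axes))
    stop_field("phenotype_design", "axis assignment exceeds n_axes")
  structure(list(n_participants = n_participants,
                 n_metabolites = n_metabolites,
                 n_phenotypes = n_phenotypes, n_axes = n_axes,
                 phenotype_design = phenotype_design,
                 metabolite_loading_sparsity = metabolite_loading_sparsity,
                 snr_phenotype = snr_phenotype,
                 snr_metabolite = snr_metabolite,
                 lod_quantile = lod_quantile,
                 extra_missing_rate = extra_missing_rate,
                 qc_replicates = qc_replicates, cv_target = cv_target,
                 log_hr_per_sd = rep_len(log_hr_per_sd, n_axes),
                 baseline_hazard = baseline_hazard,
                 followup_years = followup_years,
                 covariate_effects = covariate_effects, seed = seed),
            class = "generator_config")
}

ENDPOINTS <- c("CVD", "cancer", "dementia", "disability", "death")

# baseline-prevalence rates used for exclusion flags (independent of axes)
PREVALENCE_RATES <- c(CVD = 0.27, cancer = 0.20, dementia = 0.05,
                      disability = 0.10, death = 0)

# one cohort from an already-seeded RNG stream; loadings/design shared across
# cohorts of a pair
generate_cohort_impl <- function(config, loadings = NULL, axis_sd = 1,
                                 hazard_scale = 1, age_mean = 74.7,
                                 age_sd = 2.9, cohort = "older") {
  n <- config$n_participants
  m <- config$n_metabolites
  k <- config$n_axes
  des <- config$phenotype_design
  ids <- sprintf("%s_%05d", cohort, seq_len(n))

  # 1. covariates
  age <- stats::rnorm(n, age_mean, age_sd)
  sex <- stats::rbinom(n, 1L, 0.5)
  race <- stats::rbinom(n, 1L, 0.4)
  height <- stats::rnorm(n, 1.68, 0.09)
  covariates <- data.frame(
    participant_id = ids, age = age, sex = sex, race = race,
    height = height,
    education = stats::rbinom(n, 1L, 0.75),
    smoker = stats::rbinom(n, 1L, 0.1),
    bmi = stats::rnorm(n, 27, 4.8),
    hypertension = stats::rbinom(n, 1L, 0.5),
    diabetes = stats::rbinom(n, 1L, 0.14),
    cystatin_c = stats::rnorm(n, 1.1, 0.3),
    stringsAsFactors = FALSE)

  # 2. latent axes: exactly unit sample variance, then attenuated by axis_sd
  axes <- matrix(stats::rnorm(n * k), n, k)
  axes <- scale(axes) * axis_sd
  attr(axes, "scaled:center") <- NULL
  attr(axes, "scaled:scale") <- NULL
  colnames(axes) <- paste0("axis", seq_len(k))
  rownames(axes) <- ids

  # 3. metabolite loadings: disjoint per-axis blocks, random signs
  met_ids <- sprintf("met_%03d", seq_len(m))
  if (is.null(loadings)) {
    block <- floor(config$metabolite_loading_sparsity * m)
    loadings <- matrix(0, m, k, dimnames = list(met_ids, colnames(axes)))
    for (a in seq_len(k)) {
      idx <- ((a - 1L) * block + 1L):(a * block)
      loadings[idx, a] <- sample(c(-1, 1), block, replace = TRUE)
    }
  }

  # 4. log-intensities: per-metabolite SD 0.5, axis share snr/(1+snr)
  sigma_log <- 0.5
  share_m <- config$snr_metabolite / (1 + config$snr_metabolite)
  if (!is.finite(config$snr_metabolite)) share_m <- 1
  mu <- stats::runif(m, 8, 13)
  signal <- axes %*% t(loadings)              # n x m, sd = axis_sd per loaded
  noise <- matrix(stats::rnorm(n * m), n, m)
  # unloaded metabolites are pure noise at full log-scale SD, so the matrix
  # stays non-degenerate even in the noise-free (snr -> Inf) limit
  loaded <- rowSums(abs(loadings)) > 0
  noise_sd <- ifelse(loaded, sqrt(1 - share_m), 1) * sigma_log
  logx <- sweep(sqrt(share_m) * signal * sigma_log +
                  sweep(noise, 2L, noise_sd, "*"), 2L, mu, "+")
  raw <- exp(logx)
  dimnames(raw) <- list(ids, met_ids)

  # 5. QC replicate rows around the pooled column mean at cv_target
  qc <- NULL
  if (config$qc_replicates > 0L) {
    pm <- colMeans(raw)
    qc <- matrix(stats::rnorm(config$qc_replicates * m,
                              mean = rep(pm, each = config$qc_replicates),
                              sd = rep(config$cv_target * pm,
                                       each = config$qc_replicates)),
                 config$qc_replicates, m)
    qc <- pmax(qc, matrix(rep(0.01 * pm, each = config$qc_replicates),
                          config$qc_replicates, m))
    dimnames(qc) <- list(sprintf("QC_%03d", seq_len(config$qc_replicates)),
                         met_ids)
  }

  # 6. missingness: LOD censoring of the lowest lod_quantile per column,
  # then a uniform missing-at-random sprinkle
  observed <- raw
  n_lod <- floor(config$lod_quantile * n)
  if (n_lod > 0L) {
    for (j in seq_len(m)) {
      cut <- sort(observed[, j], partial = n_lod)[n_lod]
      observed[observed[, j] <= cut, j] <- NA
    }
  }
  if (config$extra_missing_rate > 0) {
    extra <- matrix(stats::runif(n * m) < config$extra_missing_rate, n, m)
    observed[extra] <- NA
  }

  # 7. phenotypes: pure single-axis latents, covariate effects, inverse of
  # the harmonization pipeline to produce raw columns
  share_p <- config$snr_phenotype / (1 + config$snr_phenotype)
  if (!is.finite(config$snr_phenotype)) share_p <- 1
  ce <- config$covariate_effects
  age_z <- (age - age_mean) / age_sd
  cov_term <- ce[["age"]] * age_z + ce[["sex"]] * sex + ce[["race"]] * race
  hfac <- height^1.7
  pheno_raw <- matrix(NA_real_, n, nrow(des),
                      dimnames = list(ids, des$phenotype))
  for (j in seq_len(nrow(des))) {
    t_j <- sqrt(share_p) * axes[, des$axis[j]] +
      sqrt(1 - share_p) * stats::rnorm(n) + cov_term
    y <- if (des$orientation[j] == "adverse") -t_j else t_j
    if (des$index_to_height[j]) {
      pheno_raw[, j] <- (2 * y + 20) * hfac
    } else if (des$transform[j] == "log") {
      pheno_raw[, j] <- exp(0.4 * y + 3)
    } else {
      pheno_raw[, j] <- 5 * y + 50
    }
  }

  # 8. survival endpoints: exponential PH in the axes, administrative
  # censoring at the horizon; independent across endpoints given the axes
  lp <- drop(axes %*% config$log_hr_per_sd)
  rate <- config$baseline_hazard * hazard_scale * exp(lp)
  outcomes <- do.call(rbind, lapply(ENDPOINTS, function(ep) {
    tt <- stats::rexp(n, rate)
    ev <- as.integer(tt <= config$followup_years)
    data.frame(participant_id = ids, endpoint = ep,
               time_years = pmin(tt, config$followup_years),
               event = ev,
               prevalent = as.integer(stats::runif(n) <
                                        PREVALENCE_RATES[[ep]]),
               stringsAsFactors = FALSE)
  }))
  rownames(outcomes) <- NULL

  pcfg <- pheno_config(des$phenotype, des$domain, des$orientation,
                       des$transform, des$index_to_height)

  structure(list(
    metabolites = metabolite_matrix(observed, qc_values = qc,
                                    cohort = cohort),
    phenotypes = pheno_raw,
    pheno_config = pcfg,
    covariates = covariates,
    outcomes = outcomes,
    truth = list(axes = axes, metabolite_loadings = loadings,
                 phenotype_design = des,
                 log_hr_per_sd = config$log_hr_per_sd,
                 axis_sd = axis_sd),
    config = config, cohort = cohort),
    class = "synthetic_cohort")
}

#' Generate a synthetic aging cohort with planted latent axes
#'
#' Draws one cohort under the configured stated world: latent axes of exactly
#' unit sample variance; metabolite log-intensities linear in the axes over
#' disjoint loading blocks; phenotypes as single-axis images passed through
#' the inverse of the harmonization pipeline (adverse sign, height indexing,
#' log transform); exponential proportional-hazards event times per endpoint
#' censored at the follow-up horizon; limit-of-detection missingness; pooled
#' QC replicate rows. Fully deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return list of class `synthetic_cohort` with elements `metabolites`
#'   ([metabolite_matrix()]), `phenotypes` (raw matrix), `pheno_config`,
#'   `covariates`, `outcomes` (long endpoint table) and `truth` (latent axes,
#'   loading matrices, hazard coefficients).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  generate_cohort_impl(config)
}

#' Generate an older discovery cohort and a younger transfer cohort
#'
#' The younger cohort reuses the older cohort's metabolite loading matrix and
#' phenotype design, with attenuated axis variance and a scaled-down baseline
#' hazard — the same metabolic structure expressed more weakly at an earlier
#' life stage.
#'
#' @param config a [generator_config()] (applies to both cohorts).
#' @param attenuation multiplier on the younger cohort's axis SD (default 0.6).
#' @param hazard_scale multiplier on the younger cohort's baseline hazard
#'   (default 0.5).
#' @return list with elements `older` and `younger`, both `synthetic_cohort`.
#' @export
generate_paired_cohorts <- function(config, attenuation = 0.6,
                                    hazard_scale = 0.5) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  older <- generate_cohort_impl(config)
  younger <- generate_cohort_impl(
    config, loadings = older$truth$metabolite_loadings,
    axis_sd = attenuation, hazard_scale = hazard_scale,
    age_mean = 32.1, age_sd = 3.6, cohort = "younger")
  list(older = older, younger = younger)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort '%s': %d participants, %d metabolites, %d phenotypes, %d axes\n",
              x$cohort, nrow(x$phenotypes), ncol(x$metabolites$values),
              ncol(x$phenotypes), ncol(x$truth$axes)))
  invisible(x)
}

# all injective assignments of k_est estimated axes to truth axes
perms <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = 1L))
  do.call(rbind, lapply(seq_along(v), function(i)
    cbind(v[i], perms(v[-i]))))
}

#' Match estimated axes to truth axes by maximal absolute correlation
#'
#' Finds the one-to-one assignment of estimated axes to distinct truth axes
#' maximizing the total absolute Pearson correlation (exhaustive search,
#' optimal for up to 8 axes). If fewer axes were estimated than planted, a
#' partial matching is returned with the unmatched truth axes listed.
#'
#' @param truth_axes numeric matrix, participants x k_true.
#' @param estimated_scores numeric matrix, participants x k_est (same rows).
#' @return list: `matching` (data.frame estimated, truth, abs_r),
#'   `unmatched_truth` (character), `total_abs_r`.
#' @export
truth_alignment <- function(truth_axes, estimated_scores) {
  truth_axes <- as.matrix(truth_axes)
  estimated_scores <- as.matrix(estimated_scores)
  if (nrow(truth_axes) != nrow(estimated_scores))
    stop("participant counts differ")
  k_true <- ncol(truth_axes)
  k_est <- ncol(estimated_scores)
  if (k_est > k_true)
    stop("more estimated axes than truth axes")
  if (k_true > 8L) stop("exhaustive matching supports at most 8 axes")
  r <- abs(stats::cor(estimated_scores, truth_axes))
  assignments <- perms(seq_len(k_true))
  if (k_est < k_true)
    assignments <- unique(assignments[, seq_len(k_est), drop = FALSE])
  totals <- apply(assignments, 1L, function(a)
    sum(r[cbind(seq_len(k_est), a)]))
  best <- assignments[which.max(totals), ]
  tn <- colnames(truth_axes)
  if (is.null(tn)) tn <- paste0("truth", seq_len(k_true))
  en <- colnames(estimated_scores)
  if (is.null(en)) en <- paste0("est", seq_len(k_est))
  matching <- data.frame(estimated = en, truth = tn[best],
                         abs_r = r[cbind(seq_len(k_est), best)],
                         stringsAsFactors = FALSE)
  list(matching = matching,
       unmatched_truth = tn[setdiff(seq_len(k_true), best)],
       total_abs_r = sum(matching$abs_r))
}
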