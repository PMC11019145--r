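# cross-cohort score transfer, composite healthy-aging endpoint, Cox and
# Kaplan-Meier outcome models, score-phenotype association grid

#' Transfer metabolite weights to a new cohort
#'
#' Applies the training cohort's per-axis metabolite weights to another
#' cohort's metabolite matrix (which must have been imputed, log-transformed
#' and standardized within its own cohort). Alignment is strictly by
#' metabolite id; axis signs and labels are inherited, and the resulting
#' scores are re-standardized within the new cohort.
#'
#' @param axes trained (oriented, labeled) `aging_axes`.
#' @param metabolome the new cohort's `standardized_metabolome` (or matrix).
#' @param k number of leading axes (default: all).
#' @param zero_fill allow missing panel metabolites to contribute zero; a
#'   warning reports coverage when it falls below 90%. Default FALSE (error).
#' @param cohort cohort tag (defaults to the metabolome's tag).
#' @return a `metabolic_scores` object for the new cohort.
#' @export
transfer_scores <- function(axes, metabolome, k = NULL, zero_fill = FALSE,
                            cohort = NULL) {
  stopifnot(inherits(axes, "aging_axes"))
  sc <- compute_scores(axes, metabolome, k = k, zero_fill = zero_fill,
                       cohort = cohort)
  if (zero_fill) {
    panel <- rownames(axes$weights)
    zcols <- if (inherits(metabolome, "standardized_metabolome"))
      colnames(metabolome$z) else colnames(as.matrix(metabolome))
    coverage <- mean(panel %in% zcols)
    if (coverage < 0.9)
      warning(sprintf("only %.1f%% of weighted metabolites available",
                      100 * coverage))
  }
  sc
}

#' Build the composite healthy-aging endpoint
#'
#' Time-to-first-event across the component endpoints with administrative
#' censoring at `horizon_years`; the composite event indicator is 1 when any
#' component event occurs first. A participant is an "exceptionally healthy
#' ager" when event-free and under observation through the horizon.
#' Participants prevalent for any component endpoint at baseline are
#' excluded. A participant missing a component endpoint is censored at the
#' last time observed across their available endpoints and flagged.
#'
#' @param outcomes long data.frame: participant_id, endpoint, time_years,
#'   event, and optionally prevalent.
#' @param horizon_years administrative censoring horizon (default 10).
#' @param endpoints component endpoints (default CVD, cancer, dementia,
#'   disability, death).
#' @return data.frame: participant_id, time_years, event, healthy_ager,
#'   incomplete (missing-component flag).
#' @export
build_composite <- function(outcomes, horizon_years = 10,
                            endpoints = c("CVD", "cancer", "dementia",
                                          "disability", "death")) {
  if (horizon_years <= 0) stop("horizon_years must be > 0")
  need <- c("participant_id", "endpoint", "time_years", "event")
  if (!all(need %in% names(outcomes)))
    stop("outcomes must have columns: ", paste(need, collapse = ", "))
  oc <- outcomes[outcomes$endpoint %in% endpoints, , drop = FALSE]
  if (any(oc$time_years <= 0)) stop("non-positive follow-up time")
  if (!all(oc$event %in% c(0L, 1L))) stop("event must be 0/1")
  if ("prevalent" %in% names(oc)) {
    prev_ids <- unique(oc$participant_id[oc$prevalent == 1L])
    oc <- oc[!oc$participant_id %in% prev_ids, , drop = FALSE]
  }
  res <- lapply(split(oc, oc$participant_id), function(d) {
    incomplete <- length(unique(d$endpoint)) < length(endpoints)
    tmin <- min(d$time_years)
    ev <- as.integer(any(d$event == 1L & d$time_years == tmin))
    if (tmin > horizon_years) {
      tmin <- horizon_years
      ev <- 0L
    }
    data.frame(participant_id = d$participant_id[1L], time_years = tmin,
               event = ev,
               healthy_ager = ev == 0L && tmin >= horizon_years,
               incomplete = incomplete, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cox proportional-hazards association of a metabolic score with an endpoint
#'
#' Hazard ratio per 1 SD of the (standardized) score from a proportional-
#' hazards model with Efron tie handling, serially adjusted at the requested
#' tier: `minimal` (age, sex, race) or `full` (adds education, smoking, BMI,
#' hypertension, diabetes and renal function when present in the covariate
#' table). For the healthy-aging composite the model is time-to-composite-
#' failure; `reciprocal = TRUE` reports 1/HR so that values above 1 mean a
#' higher score is protective.
#'
#' @param score numeric score vector (1 SD units).
#' @param time,event follow-up time and 0/1 event indicator.
#' @param covariates data.frame of adjustment covariates.
#' @param tier `"unadjusted"`, `"minimal"` or `"full"`.
#' @param reciprocal report the reciprocal hazard ratio (default FALSE).
#' @return list: hr, ci_lower, ci_upper, log_hr, se, p, n, n_event, tier.
#' @export
fit_cox <- function(score, time, event, covariates = NULL,
                    tier = c("minimal", "full", "unadjusted"),
                    reciprocal = FALSE) {
  tier <- match.arg(tier)
  if (sum(event) < 1L) stop("no events")
  tiers <- list(
    unadjusted = character(0),
    minimal = c("age", "sex", "race"),
    full = c("age", "sex", "race", "education", "smoker", "bmi",
             "hypertension", "diabetes", "cystatin_c"))
  dat <- data.frame(time = time, event = event, score = score)
  if (tier != "unadjusted") {
    if (is.null(covariates)) stop("covariates required for adjusted tiers")
    keep <- intersect(tiers[[tier]], names(covariates))
    if (tier == "minimal" && !all(c("age", "sex", "race") %in% keep))
      stop("minimal tier needs age, sex, race")
    dat <- cbind(dat, covariates[, keep, drop = FALSE])
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  rhs <- setdiff(names(dat), c("time", "event"))
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(rhs, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  b <- stats::coef(fit)[["score"]]
  se <- sqrt(stats::vcov(fit)["score", "score"])
  p <- 2 * stats::pnorm(abs(b / se), lower.tail = FALSE)
  lo <- b - stats::qnorm(0.975) * se
  hi <- b + stats::qnorm(0.975) * se
  if (reciprocal) {
    b <- -b
    tmp <- lo; lo <- -hi; hi <- -tmp
  }
  list(hr = exp(b), ci_lower = exp(lo), ci_upper = exp(hi), log_hr = b,
       se = se, p = p, n = nrow(dat), n_event = sum(dat$event),
       tier = tier, reciprocal = reciprocal)
}

#' Kaplan-Meier curves by metabolic-score tertile
#'
#' Cuts the score at its 1/3 and 2/3 empirical quantiles and computes
#' product-limit survival estimates per stratum (set `tertiles = FALSE` for a
#' single pooled curve).
#'
#' @param score numeric score vector.
#' @param time,event follow-up time and 0/1 event indicator.
#' @param tertiles stratify by tertile (default TRUE).
#' @return data.frame: stratum, time, n_risk, n_event, n_censor, surv.
#' @export
km_by_tertile <- function(score, time, event, tertiles = TRUE) {
  if (length(unique(score)) < 3L) stop("need at least 3 distinct scores")
  if (tertiles) {
    cuts <- stats::quantile(score, c(1, 2) / 3, names = FALSE)
    if (anyDuplicated(cuts))
      stop("tied tertile boundaries collapse a stratum; jitter the score ",
           "quantiles or disable tertiles")
    stratum <- cut(score, c(-Inf, cuts, Inf),
                   labels = c("T1", "T2", "T3"))
  } else {
    stratum <- factor(rep("all", length(score)))
  }
  out <- do.call(rbind, lapply(levels(stratum), function(s) {
    idx <- stratum == s
    sf <- survival::survfit(survival::Surv(time[idx], event[idx]) ~ 1)
    data.frame(stratum = s, time = sf$time, n_risk = sf$n.risk,
               n_event = sf$n.event, n_censor = sf$n.censor,
               surv = sf$surv, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Score-phenotype association grid
#'
#' Linear association of every metabolic score with every harmonized target
#' phenotype at each adjustment tier, with Benjamini-Hochberg flags within
#' tier across the whole grid.
#'
#' @param scores a `metabolic_scores` object (or standardized matrix).
#' @param phenotypes a [harmonize_phenotypes()] result (or matrix).
#' @param covariates data.frame of adjustment covariates.
#' @param tiers named list of covariate-column subsets, e.g.
#'   `list(minimal = c("age","sex","race"))`; defaults to a minimal tier.
#' @param fdr_level FDR threshold (default 0.05).
#' @return long data.frame: score, phenotype, tier, beta, se, p, q,
#'   significant.
#' @export
association_grid <- function(scores, phenotypes, covariates = NULL,
                             tiers = list(minimal = c("age", "sex", "race")),
                             fdr_level = 0.05) {
  S <- if (inherits(scores, "metabolic_scores")) scores$scores else
    as.matrix(scores)
  P <- if (inherits(phenotypes, "harmonized_phenotypes"))
    phenotypes$values else as.matrix(phenotypes)
  if (nrow(S) != nrow(P)) stop("participant counts differ")
  out <- list()
  for (tname in names(tiers)) {
    cv <- if (is.null(covariates) || !length(tiers[[tname]])) NULL else
      covariates[, intersect(tiers[[tname]], names(covariates)),
                 drop = FALSE]
    cmat <- covariate_design(cv, nrow(S))
    cells <- expand.grid(score = colnames(S), phenotype = colnames(P),
                         stringsAsFactors = FALSE)
    fits <- Map(function(s, ph) ols_focus(P[, ph], S[, s], cmat),
                cells$score, cells$phenotype)
    df <- data.frame(cells, tier = tname,
                     beta = vapply(fits, `[[`, 0, "beta"),
                     se = vapply(fits, `[[`, 0, "se"),
                     p = vapply(fits, `[[`, 0, "p"),
                     stringsAsFactors = FALSE)
    adj <- bh_adjust(df$p, fdr_level)
    df$q <- adj$q
    df$significant <- adj$significant
    out[[tname]] <- df
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
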