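#' Construct a metabolite intensity matrix
#'
#' Container for raw (positive) metabolite intensities from one cohort, with
#' missing values encoded as `NA`, optional pooled-QC replicate rows, and an
#' optional externally supplied per-metabolite coefficient of variation.
#'
#' @param values numeric matrix, participants x metabolites; rownames are
#'   participant ids, colnames are unique metabolite ids; `NA` = missing.
#' @param qc_values optional numeric matrix of pooled-QC replicate injections
#'   (replicates x metabolites, same column set). Used to compute the CV as
#'   sd/mean of raw intensities.
#' @param cv optional named numeric vector of per-metabolite CVs, used when no
#'   QC replicates are available.
#' @param cohort cohort tag carried through to standardization and scoring;
#'   all preprocessing statistics are cohort-local.
#' @return an object of class `metabolite_matrix`.
#' @export
metabolite_matrix <- function(values, qc_values = NULL, cv = NULL,
                              cohort = "cohort") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    if (ncol(values) == 0L) colnames(values) <- character(0)
    else stop("`values` must have metabolite colnames")
  }
  if (anyDuplicated(colnames(values)))
    stop("metabolite ids must be unique")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("P", seq_len(nrow(values)))
  if (any(values <= 0, na.rm = TRUE))
    stop("observed intensities must be positive")
  if (!is.null(qc_values)) {
    qc_values <- as.matrix(qc_values)
    if (!identical(colnames(qc_values), colnames(values)))
      stop("`qc_values` columns must match `values` columns")
  }
  if (!is.null(cv)) {
    cv <- cv[colnames(values)]
    names(cv) <- colnames(values)
  }
  structure(list(values = values, qc_values = qc_values, cv = cv,
                 cohort = cohort),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("metabolite_matrix: %d participants x %d metabolites (%s)\n",
              nrow(x$values), ncol(x$values), x$cohort))
  cat(sprintf("  missing: %.1f%%; QC replicates: %d\n",
              100 * mean(is.na(x$values)),
              if (is.null(x$qc_values)) 0L else nrow(x$qc_values)))
  invisible(x)
}

#' Per-metabolite presence fraction
#'
#' Fraction of participants with an observed (non-missing) value.
#' @param x a [metabolite_matrix()].
#' @return named numeric vector in [0, 1].
#' @export
presence_fraction <- function(x) {
  stopifnot(inherits(x, "metabolite_matrix"))
  colMeans(!is.na(x$values))
}

#' Per-metabolite coefficient of variation
#'
#' CV = sd/mean of raw intensities across pooled-QC replicate injections when
#' QC rows are present; otherwise the supplied `cv` vector; otherwise `NA`.
#' @param x a [metabolite_matrix()].
#' @return named numeric vector (NA where unavailable).
#' @export
metabolite_cv <- function(x) {
  stopifnot(inherits(x, "metabolite_matrix"))
  ids <- colnames(x$values)
  if (!is.null(x$qc_values)) {
    m <- colMeans(x$qc_values, na.rm = TRUE)
    s <- apply(x$qc_values, 2L, stats::sd, na.rm = TRUE)
    return(stats::setNames(s / m, ids))
  }
  if (!is.null(x$cv)) return(x$cv)
  stats::setNames(rep(NA_real_, length(ids)), ids)
}

#' Quality-control filter on presence and CV
#'
#' Keeps metabolites measured in at least `presence_min` of participants with
#' coefficient of variation at most `cv_max` (the conventional 90% presence /
#' 10% CV thresholds are the defaults). Metabolites with no available CV are
#' excluded with reason `"cv_unavailable"` rather than failing the run.
#'
#' @param x a [metabolite_matrix()].
#' @param presence_min minimum presence fraction (default 0.90).
#' @param cv_max maximum CV (default 0.10).
#' @return list with `matrix` (filtered `metabolite_matrix`) and `exclusions`
#'   (data.frame: metabolite, reason, presence, cv).
#' @export
qc_filter <- function(x, presence_min = 0.90, cv_max = 0.10) {
  stopifnot(inherits(x, "metabolite_matrix"))
  check_fraction(presence_min, "presence_min")
  check_fraction(cv_max, "cv_max")
  pres <- presence_fraction(x)
  cv <- metabolite_cv(x)
  reason <- rep(NA_character_, length(pres))
  reason[is.na(cv)] <- "cv_unavailable"
  reason[!is.na(cv) & cv > cv_max] <- "cv"
  low_pres <- pres < presence_min
  reason[low_pres & !is.na(reason)] <- paste0("presence+", reason[low_pres & !is.na(reason)])
  reason[low_pres & is.na(reason)] <- "presence"
  keep <- is.na(reason)
  exclusions <- data.frame(metabolite = colnames(x$values)[!keep],
                           reason = reason[!keep],
                           presence = unname(pres[!keep]),
                           cv = unname(cv[!keep]),
                           stringsAsFactors = FALSE)
  kept <- metabolite_matrix(x$values[, keep, drop = FALSE],
                            qc_values = if (is.null(x$qc_values)) NULL else
                              x$qc_values[, keep, drop = FALSE],
                            cv = if (is.null(x$cv)) NULL else x$cv[keep],
                            cohort = x$cohort)
  list(matrix = kept, exclusions = exclusions)
}

#' Half-minimum imputation of missing intensities
#'
#' Each missing cell in a metabolite column is replaced by 50% of the lowest
#' value observed for that metabolite within the cohort — the standard
#' left-censoring (limit-of-detection) convention. Imputation is strictly
#' cohort-local: never pool minima across cohorts.
#'
#' @param x a [metabolite_matrix()].
#' @return the matrix with all missing cells filled; the pre-imputation
#'   missingness mask is attached as attribute `"imputed_mask"`.
#' @export
impute_half_min <- function(x) {
  stopifnot(inherits(x, "metabolite_matrix"))
  v <- x$values
  all_missing <- colSums(!is.na(v)) == 0L
  if (any(all_missing))
    stop("all values missing for metabolite(s): ",
         paste(colnames(v)[all_missing], collapse = ", "))
  mask <- is.na(v)
  if (any(mask)) {
    mins <- apply(v, 2L, min, na.rm = TRUE)
    idx <- which(mask, arr.ind = TRUE)
    v[mask] <- 0.5 * mins[idx[, 2L]]
  }
  out <- metabolite_matrix(v, qc_values = x$qc_values, cv = x$cv,
                           cohort = x$cohort)
  attr(out, "imputed_mask") <- mask
  out
}

#' Log-transform and standardize metabolite intensities
#'
#' Natural-log transform followed by per-metabolite mean-centering and scaling
#' to unit sample SD (n-1), within the cohort. The returned centers/scales
#' allow the exact transform to be replayed (see [replay_standardize()]).
#'
#' @param x a fully imputed [metabolite_matrix()] (no missing values).
#' @return list of class `standardized_metabolome`: `z` (standardized
#'   log-abundance matrix), `center`, `scale`, `cohort`.
#' @export
log_standardize <- function(x) {
  stopifnot(inherits(x, "metabolite_matrix"))
  v <- x$values
  if (anyNA(v)) stop("matrix contains missing values; impute first")
  if (any(v <= 0)) stop("all values must be positive for log transform")
  lv <- log(v)
  cs <- col_center_scale(lv)
  zero_var <- cs$scale < .Machine$double.eps
  if (any(zero_var))
    stop("zero variance after log for metabolite(s): ",
         paste(colnames(v)[zero_var], collapse = ", "))
  structure(list(z = cs$z, center = cs$center, scale = cs$scale,
                 cohort = x$cohort),
            class = "standardized_metabolome")
}

#' Replay a stored log-standardization on a raw intensity matrix
#'
#' Applies previously estimated per-metabolite log-scale centers and scales.
#' Intended for bit-identical replay on the matrix they were estimated from;
#' cross-cohort transfer re-estimates cohort-local statistics instead.
#'
#' @param values positive intensity matrix with metabolite colnames.
#' @param std a `standardized_metabolome` (source of center/scale).
#' @return standardized log-abundance matrix.
#' @export
replay_standardize <- function(values, std) {
  stopifnot(inherits(std, "standardized_metabolome"))
  values <- as.matrix(values)
  ids <- names(std$center)
  if (!all(ids %in% colnames(values)))
    stop("matrix lacks metabolites: ",
         paste(setdiff(ids, colnames(values)), collapse = ", "))
  lv <- log(values[, ids, drop = FALSE])
  sweep(sweep(lv, 2L, std$center, "-"), 2L, std$scale, "/")
}

# phenotype harmonization -----------------------------------------------------

#' Phenotype metadata table
#'
#' Declares, per phenotype, its aging domain, orientation, optional log
#' transform and optional indexing to height^1.7. Orientation
#' `"higher_better"` means larger raw values are healthier; `"adverse"`
#' phenotypes (e.g. visceral fat area, pulse wave velocity) are negated during
#' harmonization so that every harmonized column is healthier-is-higher.
#'
#' @param phenotype character vector of phenotype ids.
#' @param domain aging-domain label per phenotype.
#' @param orientation `"higher_better"` or `"adverse"` per phenotype.
#' @param transform `"none"` or `"log"` per phenotype.
#' @param index_to_height logical per phenotype; divide by height^1.7.
#' @return data.frame of class `pheno_config`.
#' @export
pheno_config <- function(phenotype, domain,
                         orientation = "higher_better",
                         transform = "none",
                         index_to_height = FALSE) {
  n <- length(phenotype)
  cfg <- data.frame(phenotype = as.character(phenotype),
                    domain = rep_len(as.character(domain), n),
                    orientation = rep_len(orientation, n),
                    transform = rep_len(transform, n),
                    index_to_height = rep_len(index_to_height, n),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(cfg$phenotype)) stop("phenotype ids must be unique")
  if (any(is.na(cfg$domain) | cfg$domain == ""))
    stop("every phenotype needs a domain")
  bad <- !cfg$orientation %in% c("higher_better", "adverse")
  if (any(bad)) stop("orientation must be 'higher_better' or 'adverse'")
  if (any(!cfg$transform %in% c("none", "log")))
    stop("transform must be 'none' or 'log'")
  class(cfg) <- c("pheno_config", "data.frame")
  cfg
}

#' Harmonize raw phenotypes to a healthier-is-higher standardized scale
#'
#' Pipeline order per phenotype: optional log transform, optional indexing to
#' height^1.7 (divide by height in meters raised to 1.7), negation of
#' adverse-oriented phenotypes, then mean-centering and scaling to unit sample
#' SD. Every output column has mean 0, SD 1, and larger values mean healthier.
#'
#' @param values numeric matrix, participants x phenotypes (colnames must
#'   match `config$phenotype`).
#' @param config a [pheno_config()].
#' @param heights numeric vector of heights in meters (required if any
#'   phenotype is height-indexed).
#' @return list of class `harmonized_phenotypes`: `values` (standardized
#'   matrix), `config`, `center`, `scale`.
#' @export
harmonize_phenotypes <- function(values, config, heights = NULL) {
  stopifnot(inherits(config, "pheno_config"))
  values <- as.matrix(values)
  missing_cols <- setdiff(config$phenotype, colnames(values))
  if (length(missing_cols))
    stop("phenotype column(s) absent: ", paste(missing_cols, collapse = ", "))
  values <- values[, config$phenotype, drop = FALSE]
  if (any(config$index_to_height)) {
    if (is.null(heights) || length(heights) != nrow(values) ||
        anyNA(heights))
      stop("complete `heights` required for height-indexed phenotypes")
    hfac <- heights^1.7
  }
  out <- values
  for (j in seq_len(ncol(out))) {
    cj <- config[j, ]
    v <- out[, j]
    if (cj$transform == "log") {
      if (any(v <= 0, na.rm = TRUE))
        stop("non-positive values in log-transformed phenotype ",
             cj$phenotype)
      v <- log(v)
    }
    if (cj$index_to_height) v <- v / hfac
    if (cj$orientation == "adverse") v <- -v
    out[, j] <- v
  }
  cs <- col_center_scale(out)
  zero_var <- cs$scale < .Machine$double.eps
  if (any(zero_var))
    stop("zero-variance phenotype(s): ",
         paste(config$phenotype[zero_var], collapse = ", "))
  structure(list(values = cs$z, config = config, center = cs$center,
                 scale = cs$scale),
            class = "harmonized_phenotypes")
}
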