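# tab-separated table exchange with id-keyed alignment and validation

#' Write a table or matrix as TSV
#'
#' Matrices gain a leading id column from their rownames; missing values are
#' written as `NA`.
#'
#' @param x data.frame or matrix.
#' @param path output file.
#' @param id_col name for the rowname column of matrices.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, id_col = "participant_id") {
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1L] <- id_col
    x <- df
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input file.
#' @param as_matrix if TRUE, the first column becomes rownames of a numeric
#'   matrix.
#' @return data.frame or numeric matrix.
#' @export
read_tsv <- function(path, as_matrix = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  if (!as_matrix) return(df)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- names(df)[-1L][!vapply(df[-1L], is.numeric, TRUE)]
    stop("non-numeric column(s) in matrix file ", path, ": ",
         paste(bad, collapse = ", "))
  }
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Load and align the cohort tables by participant id
#'
#' Reads (or accepts in-memory) metabolite, phenotype, covariate and outcome
#' tables, validates unique participant ids, and aligns all tables to the
#' sorted id order of the metabolite matrix.
#'
#' @param metabolites,phenotypes numeric matrices (or TSV paths) with
#'   participant-id rownames/first column.
#' @param covariates,outcomes data.frames (or TSV paths) with a
#'   `participant_id` column.
#' @return list of aligned tables.
#' @export
load_tables <- function(metabolites, phenotypes, covariates,
                        outcomes = NULL) {
  if (is.character(metabolites)) metabolites <- read_tsv(metabolites, TRUE)
  if (is.character(phenotypes)) phenotypes <- read_tsv(phenotypes, TRUE)
  if (is.character(covariates)) covariates <- read_tsv(covariates)
  if (is.character(outcomes)) outcomes <- read_tsv(outcomes)
  for (nm in c("metabolites", "phenotypes")) {
    ids <- rownames(get(nm))
    if (anyDuplicated(ids))
      stop("duplicate participant ids in ", nm)
  }
  if (anyDuplicated(covariates$participant_id))
    stop("duplicate participant ids in covariates")
  ids <- sort(rownames(metabolites))
  if (!setequal(ids, rownames(phenotypes)) ||
      !setequal(ids, covariates$participant_id))
    stop("participant ids differ across tables")
  list(metabolites = metabolites[ids, , drop = FALSE],
       phenotypes = phenotypes[ids, , drop = FALSE],
       covariates = covariates[match(ids, covariates$participant_id), ,
                               drop = FALSE],
       outcomes = outcomes)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits metabolites.tsv (observed intensities, NA = missing),
#' metabolites_qc.tsv (pooled-QC replicate rows), phenotypes.tsv,
#' covariates.tsv, outcomes.tsv, pheno_config.tsv and a JSON sidecar
#' (cohort.json) holding the generator configuration and ground truth.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(cohort$metabolites$values, file.path(dir, "metabolites.tsv"))
  if (!is.null(cohort$metabolites$qc_values))
    write_tsv(cohort$metabolites$qc_values,
              file.path(dir, "metabolites_qc.tsv"), id_col = "qc_id")
  write_tsv(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"))
  write_tsv(cohort$outcomes, file.path(dir, "outcomes.tsv"))
  write_tsv(as.data.frame(cohort$pheno_config),
            file.path(dir, "pheno_config.tsv"))
  cfg <- unclass(cohort$config)
  cfg$phenotype_design <- NULL
  sidecar <- list(cohort = cohort$cohort, config = cfg,
                  truth = list(axes = cohort$truth$axes,
                               metabolite_loadings =
                                 cohort$truth$metabolite_loadings,
                               log_hr_per_sd = cohort$truth$log_hr_per_sd,
                               axis_sd = cohort$truth$axis_sd))
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing the cohort TSV files.
#' @return list of class `synthetic_cohort` (truth matrices as plain
#'   matrices).
#' @export
load_cohort <- function(dir) {
  values <- read_tsv(file.path(dir, "metabolites.tsv"), TRUE)
  qc_path <- file.path(dir, "metabolites_qc.tsv")
  qc <- if (file.exists(qc_path)) read_tsv(qc_path, TRUE) else NULL
  pheno <- read_tsv(file.path(dir, "phenotypes.tsv"), TRUE)
  covariates <- read_tsv(file.path(dir, "covariates.tsv"))
  outcomes <- read_tsv(file.path(dir, "outcomes.tsv"))
  pcfg_df <- read_tsv(file.path(dir, "pheno_config.tsv"))
  sidecar <- jsonlite::read_json(file.path(dir, "cohort.json"),
                                 simplifyVector = TRUE)
  tag <- sidecar$cohort
  truth <- sidecar$truth
  truth$axes <- as.matrix(truth$axes)
  truth$metabolite_loadings <- as.matrix(truth$metabolite_loadings)
  rownames(truth$axes) <- rownames(values)
  rownames(truth$metabolite_loadings) <- colnames(values)
  structure(list(
    metabolites = metabolite_matrix(values, qc_values = qc, cohort = tag),
    phenotypes = pheno,
    pheno_config = pheno_config(pcfg_df$phenotype, pcfg_df$domain,
                                pcfg_df$orientation, pcfg_df$transform,
                                pcfg_df$index_to_height),
    covariates = covariates, outcomes = outcomes, truth = truth,
    config = sidecar$config, cohort = tag),
    class = "synthetic_cohort")
}
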