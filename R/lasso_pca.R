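# LASSO-PCA integration: correlation pruning, per-phenotype LASSO over the
# metabolome, PCA of the coefficient matrix, component selection, metabolic
# scores, orientation and labeling

#' Iterative correlation pruning of the metabolite panel
#'
#' While any pairwise absolute Pearson correlation exceeds `threshold`, the
#' metabolite with the largest mean absolute correlation against all
#' currently retained metabolites is removed, and the means are recomputed.
#' Ties break to the lowest column index. The surviving panel has all
#' pairwise |r| <= threshold.
#'
#' @param Z standardized metabolite matrix (participants x metabolites,
#'   colnames required) or a `standardized_metabolome`.
#' @param threshold absolute-correlation ceiling (default 0.8).
#' @param use observation handling passed to [stats::cor()] (default
#'   `"pairwise.complete.obs"`).
#' @return list: `kept` (metabolite ids), `removed` (data.frame in removal
#'   order with the triggering pair), `cor_max` (final max off-diagonal |r|).
#' @export
prune_correlated <- function(Z, threshold = 0.8,
                             use = "pairwise.complete.obs") {
  if (inherits(Z, "standardized_metabolome")) Z <- Z$z
  Z <- as.matrix(Z)
  if (ncol(Z) < 2L) stop("need at least two metabolites")
  sds <- apply(Z, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds < .Machine$double.eps))
    stop("constant column(s), correlation undefined: ",
         paste(colnames(Z)[!is.finite(sds) | sds < .Machine$double.eps],
               collapse = ", "))
  ac <- abs(stats::cor(Z, use = use))
  diag(ac) <- NA
  alive <- rep(TRUE, ncol(ac))
  removed <- list()
  repeat {
    sub <- ac[alive, alive, drop = FALSE]
    mx <- max(sub, na.rm = TRUE)
    if (mx <= threshold) break
    means <- rowMeans(sub, na.rm = TRUE)
    victim_local <- which.max(means)   # which.max takes the first (lowest index) tie
    victim <- which(alive)[victim_local]
    pair <- which(sub == mx, arr.ind = TRUE)[1L, ]
    removed[[length(removed) + 1L]] <- data.frame(
      metabolite = colnames(ac)[victim],
      mean_abs_cor = unname(means[victim_local]),
      trigger_a = rownames(sub)[pair[1L]],
      trigger_b = colnames(sub)[pair[2L]],
      trigger_r = mx, stringsAsFactors = FALSE)
    alive[victim] <- FALSE
    if (sum(alive) < 2L) break
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(metabolite = character(0), mean_abs_cor = numeric(0),
               trigger_a = character(0), trigger_b = character(0),
               trigger_r = numeric(0), stringsAsFactors = FALSE)
  final <- ac[alive, alive, drop = FALSE]
  list(kept = colnames(ac)[alive], removed = removed,
       cor_max = if (sum(alive) > 1L) max(final, na.rm = TRUE) else 0)
}

#' Cross-validated LASSO of one phenotype on the pruned metabolome
#'
#' L1-penalized least squares (coordinate descent via glmnet) of the
#' harmonized phenotype on the standardized metabolite panel — metabolites
#' only, no covariates, and no internal re-standardization. The penalty is
#' chosen by k-fold cross-validation with a fixed fold seed: either the
#' minimum-CV-error penalty (default) or the one-standard-error rule.
#'
#' @param y harmonized phenotype vector.
#' @param X standardized, pruned metabolite matrix (colnames required).
#' @param folds number of CV folds (default 10).
#' @param cv_seed integer seed for fold assignment.
#' @param rule `"min"` or `"1se"`.
#' @param lambda optional fixed penalty overriding cross-validation.
#' @return list: `coef` (named vector over metabolites, exact zeros where
#'   unselected), `lambda`, `rule`.
#' @export
fit_lasso_phenotype <- function(y, X, folds = 10L, cv_seed = 1L,
                                rule = c("min", "1se"), lambda = NULL) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X needs metabolite colnames")
  ok <- !is.na(y) & stats::complete.cases(X)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  if (stats::sd(y) < .Machine$double.eps) stop("phenotype is constant")
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(X, y, alpha = 1, standardize = FALSE,
                          lambda = lambda)
    cf <- as.numeric(stats::coef(fit, s = lambda))[-1L]
    return(list(coef = stats::setNames(cf, colnames(X)), lambda = lambda,
                rule = "fixed"))
  }
  if (length(y) <= folds) stop("fewer complete rows than CV folds")
  set.seed(cv_seed)
  foldid <- sample(rep_len(seq_len(folds), length(y)))
  cv <- glmnet::cv.glmnet(X, y, alpha = 1, standardize = FALSE,
                          foldid = foldid)
  s <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  cf <- as.numeric(stats::coef(cv, s = s))[-1L]
  list(coef = stats::setNames(cf, colnames(X)), lambda = s, rule = rule)
}

#' Assemble per-phenotype LASSO coefficient vectors into a matrix
#'
#' @param coef_list named list of coefficient vectors (one per phenotype),
#'   all indexed on the identical pruned metabolite set.
#' @return matrix of class `coefficient_matrix`, metabolites x phenotypes;
#'   all-zero rows are retained, all-zero columns retained with a warning.
#' @export
assemble_coefficients <- function(coef_list) {
  if (!length(coef_list)) stop("empty coefficient list")
  ids <- names(coef_list[[1L]])
  for (v in coef_list)
    if (!identical(names(v), ids)) stop("mismatched metabolite lists")
  B <- do.call(cbind, coef_list)
  rownames(B) <- ids
  zero_cols <- colSums(B != 0) == 0L
  if (any(zero_cols))
    warning("phenotype(s) with no selected metabolites: ",
            paste(colnames(B)[zero_cols], collapse = ", "))
  class(B) <- c("coefficient_matrix", class(B))
  B
}

#' PCA of the LASSO coefficient matrix
#'
#' Singular value decomposition of the (column-centered) metabolites x
#' phenotypes coefficient matrix. Unlike conventional PCA of participant
#' data, the observation rows are metabolites and the variables are
#' phenotypes: right singular vectors are the phenotype loadings of each
#' aging axis, and the projections of metabolite rows onto the components are
#' the per-metabolite weights ("PC scores") used to build metabolic scores.
#'
#' @param B coefficient matrix (metabolites x phenotypes).
#' @param center column-center before decomposition (default TRUE).
#' @param scale scale columns to unit variance (default FALSE).
#' @return list of class `aging_axes`: `loadings` (phenotypes x r,
#'   orthonormal), `weights` (metabolites x r), `variance_proportion`
#'   (squared singular values normalized to sum 1; components beyond the
#'   numerical rank dropped), `center`, `scale`, `signs`, `labels`.
#' @export
pca_on_coefficients <- function(B, center = TRUE, scale = FALSE) {
  B <- unclass(as.matrix(B))
  if (any(!is.finite(B))) stop("coefficient matrix must be finite")
  ctr <- if (center) colMeans(B) else rep(0, ncol(B))
  Bc <- sweep(B, 2L, ctr, "-")
  scl <- rep(1, ncol(B))
  if (scale) {
    scl <- sqrt(colSums(Bc^2) / (nrow(B) - 1L))
    if (any(scl < .Machine$double.eps))
      stop("cannot scale zero-variance column(s)")
    Bc <- sweep(Bc, 2L, scl, "/")
  }
  sv <- svd(Bc)
  tol <- max(dim(Bc)) * .Machine$double.eps * sv$d[1L]
  r <- sum(sv$d > tol)
  if (r < 1L) stop("coefficient matrix has rank zero")
  comp <- paste0("axis", seq_len(r))
  loadings <- sv$v[, seq_len(r), drop = FALSE]
  dimnames(loadings) <- list(colnames(B), comp)
  weights <- sv$u[, seq_len(r), drop = FALSE] %*%
    diag(sv$d[seq_len(r)], r, r)
  dimnames(weights) <- list(rownames(B), comp)
  structure(list(loadings = loadings, weights = weights,
                 variance_proportion = stats::setNames(
                   sv$d[seq_len(r)]^2 / sum(sv$d^2), comp),
                 center = stats::setNames(ctr, colnames(B)),
                 scale = stats::setNames(scl, colnames(B)),
                 signs = stats::setNames(rep(1, r), comp),
                 labels = stats::setNames(rep(NA_character_, r), comp)),
            class = "aging_axes")
}

#' @export
print.aging_axes <- function(x, ...) {
  k <- length(x$variance_proportion)
  cat(sprintf("aging_axes: %d component(s) over %d phenotypes, %d metabolites\n",
              k, nrow(x$loadings), nrow(x$weights)))
  for (i in seq_len(k))
    cat(sprintf("  %s: %.1f%% variance%s\n", names(x$variance_proportion)[i],
                100 * x$variance_proportion[i],
                if (is.na(x$labels[i])) "" else paste0(" [", x$labels[i], "]")))
  invisible(x)
}

#' Select the number of aging axes by the variance-explained rule
#'
#' Counts the leading components whose variance proportion is at least
#' `min_prop` (default 10%). At least one component is always returned (with
#' a warning when none pass). The proportions double as scree-plot values.
#'
#' @param variance_proportion non-increasing numeric vector.
#' @param min_prop minimum variance proportion per retained component.
#' @return integer k >= 1.
#' @export
select_components <- function(variance_proportion, min_prop = 0.10) {
  if (!length(variance_proportion)) stop("empty variance proportions")
  if (any(diff(variance_proportion) > 1e-12))
    stop("variance proportions must be non-increasing")
  k <- sum(cumprod(variance_proportion >= min_prop))
  if (k < 1L) {
    warning("no component reaches min_prop; keeping the first")
    k <- 1L
  }
  as.integer(k)
}

#' Per-participant metabolic scores from metabolite weights
#'
#' Raw score = standardized log-metabolite matrix times the per-axis weight
#' vector; scores are then standardized within the cohort (mean 0, SD 1).
#'
#' @param axes an `aging_axes` object (or a weights matrix).
#' @param Z standardized metabolite matrix aligned by metabolite id, or a
#'   `standardized_metabolome`.
#' @param k number of leading axes to score (default: all).
#' @param zero_fill if TRUE, metabolites in the weight panel missing from `Z`
#'   contribute zero (with a warning); default errors instead.
#' @param cohort cohort tag.
#' @return list of class `metabolic_scores`: `scores` (participants x k,
#'   standardized), `raw`, `labels`, `cohort`.
#' @export
compute_scores <- function(axes, Z, k = NULL, zero_fill = FALSE,
                           cohort = NULL) {
  weights <- if (inherits(axes, "aging_axes")) axes$weights else
    as.matrix(axes)
  labels <- if (inherits(axes, "aging_axes")) axes$labels else
    stats::setNames(rep(NA_character_, ncol(weights)), colnames(weights))
  if (inherits(Z, "standardized_metabolome")) {
    if (is.null(cohort)) cohort <- Z$cohort
    Z <- Z$z
  }
  if (is.null(cohort)) cohort <- "cohort"
  Z <- as.matrix(Z)
  if (!is.null(k)) {
    weights <- weights[, seq_len(k), drop = FALSE]
    labels <- labels[seq_len(k)]
  }
  panel <- rownames(weights)
  missing_ids <- setdiff(panel, colnames(Z))
  if (length(missing_ids)) {
    if (!zero_fill)
      stop("metabolite(s) absent from matrix: ",
           paste(missing_ids, collapse = ", "))
    coverage <- 1 - length(missing_ids) / length(panel)
    warning(sprintf("zero-filling %d absent metabolite(s); coverage %.1f%%",
                    length(missing_ids), 100 * coverage))
    weights <- weights[setdiff(panel, missing_ids), , drop = FALSE]
    panel <- rownames(weights)
  }
  raw <- Z[, panel, drop = FALSE] %*% weights
  cs <- col_center_scale(raw)
  structure(list(scores = cs$z, raw = raw, labels = labels,
                 cohort = cohort),
            class = "metabolic_scores")
}

#' @export
print.metabolic_scores <- function(x, ...) {
  cat(sprintf("metabolic_scores (%s): %d participants x %d axes\n",
              x$cohort, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Orient and label aging axes by their top-loading phenotypes
#'
#' Each axis is labeled by the aging domain (and name) of the phenotype with
#' the largest absolute loading (ties to the lower phenotype index). Because
#' harmonized phenotypes are healthier-is-higher, an axis whose training
#' score correlates negatively with its top phenotype is flipped (weights,
#' loadings and scores negated) so that a higher score always indicates
#' better health.
#'
#' @param axes an `aging_axes` object.
#' @param scores the training-cohort [compute_scores()] result (columns
#'   matching `axes` components).
#' @param phenotypes the training [harmonize_phenotypes()] result (or
#'   standardized matrix).
#' @param domain_map named character vector phenotype -> domain (defaults to
#'   the harmonized table's config).
#' @return list: `axes` (signed, labeled), `scores` (reoriented).
#' @export
orient_and_label <- function(axes, scores, phenotypes, domain_map = NULL) {
  stopifnot(inherits(axes, "aging_axes"),
            inherits(scores, "metabolic_scores"))
  if (inherits(phenotypes, "harmonized_phenotypes")) {
    if (is.null(domain_map))
      domain_map <- stats::setNames(phenotypes$config$domain,
                                    phenotypes$config$phenotype)
    phenotypes <- phenotypes$values
  }
  if (is.null(domain_map)) stop("domain_map required")
  k <- ncol(scores$scores)
  for (a in seq_len(k)) {
    ld <- axes$loadings[, a]
    top <- which.max(abs(ld))          # first maximum = lowest index tie-break
    top_name <- rownames(axes$loadings)[top]
    r <- stats::cor(scores$scores[, a], phenotypes[, top_name],
                    use = "complete.obs")
    if (abs(r) < 1e-10) {
      warning("axis ", a, ": negligible correlation with top phenotype; ",
              "orientation left unchanged")
    } else if (r < 0) {
      axes$weights[, a] <- -axes$weights[, a]
      axes$loadings[, a] <- -axes$loadings[, a]
      axes$signs[a] <- -axes$signs[a]
      scores$scores[, a] <- -scores$scores[, a]
      scores$raw[, a] <- -scores$raw[, a]
    }
    axes$labels[a] <- sprintf("%s (%s)", unname(domain_map[top_name]),
                              top_name)
  }
  scores$labels <- axes$labels[seq_len(k)]
  list(axes = axes, scores = scores)
}
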