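# metabolome-wide association scan: covariate-adjusted linear models with
# Benjamini-Hochberg control and domain-overlap summaries

# build and rank-check a covariate design; returns the design matrix
covariate_design <- function(covariates, n) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L)
    return(matrix(numeric(0), n, 0L))
  covariates <- as.data.frame(covariates)
  mm <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
  mm
}

# OLS of y on [1, x, C]; complete-case; returns beta/se/p for x
ols_focus <- function(y, x, cmat) {
  X <- cbind(`(Intercept)` = 1, x = x, cmat)
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  p <- ncol(X)
  if (length(y) < p + 1L)
    stop("fewer complete cases than parameters + 1")
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  cf <- qr.coef(qr_x, y)
  res <- y - X %*% cf
  df <- length(y) - p
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(XtX_inv))[order(qr_x$pivot)]
  names(se) <- colnames(X)
  tval <- cf["x"] / se["x"]
  list(beta = unname(cf["x"]), se = unname(se["x"]),
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       n = length(y))
}

#' Covariate-adjusted linear association of a phenotype with a metabolite
#'
#' Ordinary least squares of the harmonized phenotype on the standardized
#' metabolite plus adjustment covariates (age continuous; sex/race and other
#' categorical covariates as indicator columns), complete cases only. Returns
#' the metabolite coefficient with its two-sided t-test p-value.
#'
#' @param y harmonized phenotype vector.
#' @param x standardized metabolite vector.
#' @param covariates data.frame of adjustment covariates (may be NULL).
#' @return list: beta, se, p, n.
#' @export
fit_adjusted_linear <- function(y, x, covariates = NULL) {
  if (length(y) != length(x)) stop("y and x lengths differ")
  cmat <- covariate_design(covariates, length(y))
  ols_focus(y, x, cmat)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate control: q_(i) = min over j >= i of
#' m * p_(j) / j, capped at 1, mapped back to the input order. A test is
#' flagged significant when q <= `fdr_level`.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param fdr_level FDR threshold for the significance flags (default 0.05).
#' @return list: `q` (adjusted values), `significant` (logical).
#' @export
bh_adjust <- function(p_values, fdr_level = 0.05) {
  if (!length(p_values))
    return(list(q = numeric(0), significant = logical(0)))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- p_values[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, significant = q <= fdr_level)
}

#' Metabolome-wide association scan
#'
#' Fits the covariate-adjusted linear model of every harmonized phenotype on
#' every standardized metabolite and applies Benjamini-Hochberg control. The
#' default multiplicity family is each phenotype's metabolite-wide scan
#' (`scope = "per_phenotype"`); `scope = "global"` adjusts across the full
#' phenotype x metabolite grid instead.
#'
#' @param phenotypes a [harmonize_phenotypes()] result (or a standardized
#'   matrix with colnames).
#' @param metabolome standardized metabolite matrix (participants x
#'   metabolites) or a `standardized_metabolome`.
#' @param covariates data.frame of adjustment covariates.
#' @param fdr_level FDR threshold (default 0.05).
#' @param scope `"per_phenotype"` or `"global"`.
#' @return long data.frame: metabolite, phenotype, domain, beta, se, p, q,
#'   significant.
#' @export
run_mwas <- function(phenotypes, metabolome, covariates = NULL,
                     fdr_level = 0.05,
                     scope = c("per_phenotype", "global")) {
  scope <- match.arg(scope)
  domain_map <- NULL
  if (inherits(phenotypes, "harmonized_phenotypes")) {
    domain_map <- stats::setNames(phenotypes$config$domain,
                                  phenotypes$config$phenotype)
    phenotypes <- phenotypes$values
  }
  if (inherits(metabolome, "standardized_metabolome"))
    metabolome <- metabolome$z
  phenotypes <- as.matrix(phenotypes)
  metabolome <- as.matrix(metabolome)
  if (nrow(phenotypes) != nrow(metabolome))
    stop("participant counts differ between phenotypes and metabolome")
  cmat <- covariate_design(covariates, nrow(phenotypes))
  res <- vector("list", ncol(phenotypes))
  for (jp in seq_len(ncol(phenotypes))) {
    y <- phenotypes[, jp]
    fits <- lapply(seq_len(ncol(metabolome)), function(jm)
      ols_focus(y, metabolome[, jm], cmat))
    df <- data.frame(metabolite = colnames(metabolome),
                     phenotype = colnames(phenotypes)[jp],
                     beta = vapply(fits, `[[`, 0, "beta"),
                     se = vapply(fits, `[[`, 0, "se"),
                     p = vapply(fits, `[[`, 0, "p"),
                     stringsAsFactors = FALSE)
    if (scope == "per_phenotype") {
      adj <- bh_adjust(df$p, fdr_level)
      df$q <- adj$q
      df$significant <- adj$significant
    }
    res[[jp]] <- df
  }
  out <- do.call(rbind, res)
  if (scope == "global") {
    adj <- bh_adjust(out$p, fdr_level)
    out$q <- adj$q
    out$significant <- adj$significant
  }
  out$domain <- if (is.null(domain_map)) NA_character_ else
    unname(domain_map[out$phenotype])
  rownames(out) <- NULL
  out[, c("metabolite", "phenotype", "domain", "beta", "se", "p", "q",
          "significant")]
}

#' Domain-overlap intersection counts for significant metabolites
#'
#' A metabolite belongs to a domain when it is significant for at least one
#' phenotype in that domain. Returns disjoint intersection-combination counts
#' (UpSet-style bins that partition the ever-significant metabolites) plus
#' per-domain totals.
#'
#' @param results a [run_mwas()] result (needs metabolite, phenotype,
#'   significant columns).
#' @param domain_map named character vector phenotype -> domain (defaults to
#'   the `domain` column of `results`).
#' @return list: `intersections` (data.frame domains, n_domains, count),
#'   `per_domain` (named totals), `n_significant` (metabolites in >= 1 domain).
#' @export
domain_overlap <- function(results, domain_map = NULL) {
  if (is.null(domain_map)) {
    if (any(is.na(results$domain)))
      stop("phenotype(s) without a domain")
    domain_map <- stats::setNames(results$domain, results$phenotype)
    domain_map <- domain_map[!duplicated(names(domain_map))]
  }
  unknown <- setdiff(unique(results$phenotype), names(domain_map))
  if (length(unknown))
    stop("phenotype(s) without a domain: ", paste(unknown, collapse = ", "))
  sig <- results[results$significant, , drop = FALSE]
  doms <- sort(unique(unname(domain_map)))
  if (!nrow(sig)) {
    return(list(intersections = data.frame(domains = character(0),
                                           n_domains = integer(0),
                                           count = integer(0)),
                per_domain = stats::setNames(integer(length(doms)), doms),
                n_significant = 0L))
  }
  sig$domain <- unname(domain_map[sig$phenotype])
  by_met <- split(sig$domain, sig$metabolite)
  combos <- vapply(by_met, function(d)
    paste(sort(unique(d)), collapse = "+"), "")
  tab <- table(combos)
  inter <- data.frame(domains = names(tab),
                      n_domains = lengths(strsplit(names(tab), "+",
                                                   fixed = TRUE)),
                      count = as.integer(tab),
                      stringsAsFactors = FALSE)
  inter <- inter[order(-inter$count, inter$domains), ]
  rownames(inter) <- NULL
  per_domain <- vapply(doms, function(d)
    sum(vapply(by_met, function(x) d %in% x, TRUE)), 0L)
  list(intersections = inter, per_domain = per_domain,
       n_significant = length(by_met))
}
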