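# independent oracles and fixture builders shared across the suite

# data with an exactly prescribed sample correlation matrix
exact_cor_data <- function(R, n, seed = 1) {
  set.seed(seed)
  p <- ncol(R)
  M <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  Q <- qr.Q(qr(M))
  X <- Q %*% chol(R)
  colnames(X) <- colnames(R)
  X
}

# reference pruning loop recoded at the data level: recompute the full
# correlation matrix of the surviving columns from scratch every iteration
oracle_prune <- function(X, threshold = 0.8) {
  kept <- colnames(X)
  removed <- character(0)
  repeat {
    if (length(kept) < 2L) break
    ac <- abs(cor(X[, kept, drop = FALSE]))
    diag(ac) <- NA
    if (max(ac, na.rm = TRUE) <= threshold) break
    means <- rowMeans(ac, na.rm = TRUE)
    victim <- kept[which.max(means)]
    removed <- c(removed, victim)
    kept <- setdiff(kept, victim)
  }
  list(kept = kept, removed = removed)
}

# PCA oracle via eigen-decomposition of the column-centered cross-product
oracle_pca_eigen <- function(B, center = TRUE) {
  Bc <- if (center) sweep(B, 2L, colMeans(B), "-") else B
  eg <- eigen(crossprod(Bc), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  list(loadings = eg$vectors, variance_proportion = ev / sum(ev))
}

# exhaustive hypergeometric upper tail: enumerate every possible target draw
oracle_hyper_enum <- function(N, K, n_draw, obs) {
  draws <- combn(N, n_draw)
  hits <- colSums(draws <= K)   # successes are items 1..K
  mean(hits >= obs)
}

# hand product-limit estimator at each distinct event time
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# closed-form event probability: exponential hazard lambda0*exp(lp),
# lp ~ N(0, sd^2), administrative censoring at C
oracle_event_fraction <- function(lp_sd, lambda0, C) {
  if (lp_sd == 0) return(1 - exp(-lambda0 * C))
  f <- function(z) (1 - exp(-lambda0 * exp(lp_sd * z) * C)) * dnorm(z)
  integrate(f, -8, 8)$value
}

# tiny positive intensity matrix with controllable missingness
make_mm <- function(values, qc = NULL, cv = NULL, cohort = "test") {
  metabolite_matrix(values, qc_values = qc, cv = cv, cohort = cohort)
}

# shared synthetic mapping/pathway fixture for the enrichment stage
make_pathway_fixture <- function(n_mets = 30, n_genes = 80, seed = 5) {
  set.seed(seed)
  mets <- sprintf("met_%03d", seq_len(n_mets))
  genes <- sprintf("G%03d", seq_len(n_genes))
  mapping <- do.call(rbind, lapply(mets, function(m) {
    g <- sample(genes, sample(3:10, 1))
    data.frame(metabolite_id = m, gene_id = g,
               mapping_score = round(runif(length(g), 1, 100), 1),
               stringsAsFactors = FALSE)
  }))
  pathways <- do.call(rbind, lapply(sprintf("pw%02d", 1:6), function(p) {
    data.frame(pathway_id = p, gene_id = sample(genes, 12),
               pathway_name = paste0("pathway ", p),
               stringsAsFactors = FALSE)
  }))
  list(mapping = mapping, pathways = pathways)
}
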