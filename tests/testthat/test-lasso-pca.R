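# correlation pruning, per-phenotype LASSO, coefficient-matrix PCA,
# component selection, scores, orientation

test_that("prune_correlated follows the hand-traced removal rule", {
  # r(A,B)=0.9, r(A,C)=0.85 force r(B,C) >= 0.535 for a valid correlation
  # matrix, so the off pair is set to 0.6 (still below threshold)
  R <- matrix(c(1, 0.9, 0.85,
                0.9, 1, 0.6,
                0.85, 0.6, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  X <- exact_cor_data(R, n = 50, seed = 1)
  # mean |r|: A 0.875, B 0.75, C 0.725 -> A removed, {B, C} kept
  res <- prune_correlated(X, 0.8)
  expect_identical(res$removed$metabolite, "A")
  expect_setequal(res$kept, c("B", "C"))
  expect_lte(res$cor_max, 0.8)
})

test_that("pruning is identity below threshold and breaks duplicates", {
  set.seed(2)
  X <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("m", 1:5)))
  res <- prune_correlated(X, 0.8)
  expect_identical(res$kept, paste0("m", 1:5))
  Xd <- cbind(X, m6 = X[, 1])                    # exact duplicate, r = 1
  resd <- prune_correlated(Xd, 0.8)
  expect_equal(nrow(resd$removed), 1L)
  expect_true(resd$removed$metabolite %in% c("m1", "m6"))
  expect_error(prune_correlated(cbind(X, k = rep(1, 200))), "constant.*k")
})

test_that("pruning trace matches the data-level reference on random instances", {
  set.seed(3)
  for (i in 1:30) {
    p <- 15
    n <- 40
    base <- matrix(rnorm(n * 4), n, 4)
    X <- base[, sample(4, p, replace = TRUE)] * 0.9 +
      matrix(rnorm(n * p), n, p) * 0.45
    colnames(X) <- sprintf("m%02d", seq_len(p))
    got <- prune_correlated(X, 0.8, use = "everything")
    ref <- oracle_prune(X, 0.8)
    expect_identical(got$removed$metabolite, ref$removed)
    expect_identical(got$kept, ref$kept)
    ac <- abs(cor(X[, got$kept])); diag(ac) <- 0
    expect_lte(max(ac), 0.8)
  }
})

test_that("lasso selects the true predictor in the strong-signal regime", {
  set.seed(4)
  n <- 300
  X <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, paste0("m", 1:30)))
  y <- X[, 1]
  fit <- fit_lasso_phenotype(y, X, cv_seed = 9)
  expect_gt(fit$coef[["m1"]], 0.9)
  expect_true(all(fit$coef[-1] == 0))
  # full-shrinkage limit: a huge fixed penalty zeroes everything
  fit_inf <- fit_lasso_phenotype(y, X, lambda = 1e6)
  expect_true(all(fit_inf$coef == 0))
  expect_error(fit_lasso_phenotype(rep(1, n), X), "constant")
  expect_error(fit_lasso_phenotype(y[1:5], X[1:5, ], folds = 10),
               "folds")
})

test_that("null lasso keeps the support small", {
  set.seed(5)
  sizes <- replicate(10, {
    y <- rnorm(500)
    X <- matrix(rnorm(500 * 100), 500, 100,
                dimnames = list(NULL, paste0("m", 1:100)))
    sum(fit_lasso_phenotype(y, X, cv_seed = 11)$coef != 0)
  })
  expect_gte(mean(sizes <= 5), 0.9)
})

test_that("assemble_coefficients builds B with zero rows/columns retained", {
  v1 <- c(m1 = 1, m2 = 0, m3 = 0)
  v2 <- c(m1 = 0, m2 = 2, m3 = 0)
  B <- assemble_coefficients(list(p1 = v1, p2 = v2))
  expect_equal(unclass(B), matrix(c(1, 0, 0, 0, 2, 0), 3, 2,
                                  dimnames = list(c("m1", "m2", "m3"),
                                                  c("p1", "p2"))),
               ignore_attr = FALSE)
  expect_warning(assemble_coefficients(list(p1 = v1, p2 = v1 * 0)),
                 "no selected")
  expect_error(assemble_coefficients(list(v1, c(m9 = 1, m2 = 0, m3 = 0))),
               "mismatched")
})

test_that("rank-1 coefficient matrix yields a single full-variance component", {
  u <- c(3, -1, 2, 0.5)
  v <- c(1, 2, -1)
  B <- u %*% t(v)
  dimnames(B) <- list(paste0("m", 1:4), paste0("p", 1:3))
  ax <- pca_on_coefficients(B, center = FALSE)
  expect_equal(unname(ax$variance_proportion[1]), 1, tolerance = 1e-12)
  expect_equal(abs(cor(ax$weights[, 1], u)), 1, tolerance = 1e-12)
  expect_equal(abs(sum(ax$loadings[, 1] * v / sqrt(sum(v^2)))), 1,
               tolerance = 1e-12)
})

test_that("coefficient PCA matches the eigen oracle up to sign", {
  set.seed(6)
  for (i in 1:10) {
    B <- matrix(rnorm(50 * 8), 50, 8,
                dimnames = list(paste0("m", 1:50), paste0("p", 1:8)))
    ax <- pca_on_coefficients(B)
    orc <- oracle_pca_eigen(B)
    expect_equal(unname(ax$variance_proportion),
                 orc$variance_proportion[seq_along(ax$variance_proportion)],
                 tolerance = 1e-8)
    for (j in 1:4)
      expect_equal(abs(ax$loadings[, j]), abs(orc$loadings[, j]),
                   tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(sum(ax$variance_proportion), 1, tolerance = 1e-12)
    expect_equal(crossprod(ax$loadings), diag(ncol(ax$loadings)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("select_components implements the >=10% rule with a floor", {
  expect_equal(select_components(c(0.18, 0.16, 0.12, 0.10, 0.05)), 4L)
  expect_equal(select_components(c(0.5, 0.3, 0.09)), 2L)
  expect_warning(k <- select_components(c(0.09, 0.08)), "keeping the first")
  expect_equal(k, 1L)
  expect_error(select_components(numeric(0)), "empty")
  expect_error(select_components(c(0.2, 0.5)), "non-increasing")
})

test_that("compute_scores is a standardized linear combination", {
  W <- matrix(c(1, 0, 0), 3, 1, dimnames = list(paste0("m", 1:3), "axis1"))
  Z <- matrix(c(0.5, -0.5, 1, 2, 0, 1), 2, 3,
              dimnames = list(c("a", "b"), paste0("m", 1:3)))
  sc <- compute_scores(W, Z)
  expect_equal(unname(sc$raw[, 1]), c(0.5, -0.5))     # z1 picked out
  expect_equal(mean(sc$scores[, 1]), 0, tolerance = 1e-12)
  expect_equal(sd(sc$scores[, 1]), 1, tolerance = 1e-12)
  expect_error(compute_scores(W, Z[, 1:2]), "m3")
  expect_warning(sc2 <- compute_scores(W, Z[, 1:2], zero_fill = TRUE),
                 "coverage")
  expect_equal(sc2$raw[, 1], sc$raw[, 1])              # m1 weight survives
})

test_that("scores replay identically and are scale-invariant in raw intensities", {
  set.seed(7)
  v <- matrix(exp(rnorm(40 * 6, 8)), 40, 6,
              dimnames = list(NULL, paste0("m", 1:6)))
  std <- log_standardize(make_mm(v))
  W <- matrix(rnorm(12), 6, 2,
              dimnames = list(paste0("m", 1:6), c("axis1", "axis2")))
  s1 <- compute_scores(W, std)
  s1_replay <- compute_scores(W, std)
  expect_identical(s1_replay$scores, s1$scores)
  s3 <- compute_scores(W, log_standardize(make_mm(3 * v)))
  expect_equal(s3$scores, s1$scores, tolerance = 1e-12)
})

test_that("orientation flips negative axes and labels by top-loading domain", {
  set.seed(8)
  n <- 100
  ph <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("fat", "gait")))
  loadings <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
                     dimnames = list(c("fat", "gait"), c("axis1", "axis2")))
  weights <- matrix(rnorm(10 * 2), 10, 2,
                    dimnames = list(paste0("m", 1:10),
                                    c("axis1", "axis2")))
  axes <- structure(list(loadings = loadings, weights = weights,
                         variance_proportion = c(axis1 = 0.6, axis2 = 0.4),
                         center = c(fat = 0, gait = 0),
                         scale = c(fat = 1, gait = 1),
                         signs = c(axis1 = 1, axis2 = 1),
                         labels = c(axis1 = NA, axis2 = NA)),
                    class = "aging_axes")
  scores <- structure(list(scores = cbind(axis1 = -scale(ph[, "fat"])[, 1],
                                          axis2 = scale(ph[, "gait"])[, 1]),
                           raw = cbind(axis1 = -ph[, "fat"],
                                       axis2 = ph[, "gait"]),
                           labels = c(NA, NA), cohort = "t"),
                      class = "metabolic_scores")
  res <- orient_and_label(axes, scores, ph,
                          domain_map = c(fat = "adiposity",
                                         gait = "physical"))
  expect_gt(cor(res$scores$scores[, 1], ph[, "fat"]), 0.99)   # flipped
  expect_equal(unname(res$axes$signs), c(-1, 1))
  expect_match(res$axes$labels[["axis1"]], "adiposity")
  expect_match(res$axes$labels[["axis2"]], "physical")
  # exact |loading| tie: lower phenotype index wins
  axes$loadings[, 1] <- c(0.5, 0.5)
  res2 <- orient_and_label(axes, scores, ph,
                           domain_map = c(fat = "adiposity",
                                          gait = "physical"))
  expect_match(res2$axes$labels[["axis1"]], "fat")
})
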