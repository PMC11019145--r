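# metabolite QC, half-minimum imputation, log-standardization, phenotype
# harmonization

mm_fixture <- function() {
  set.seed(10)
  v <- matrix(exp(rnorm(20 * 4, 8)), 20, 4,
              dimnames = list(sprintf("P%02d", 1:20), c("A", "B", "C", "D")))
  v[1:3, "B"] <- NA                         # presence 0.85
  cv <- c(A = 0.08, B = 0.05, C = 0.20, D = NA)
  make_mm(v, cv = cv)
}

test_that("qc_filter applies the presence/CV rule and reports exclusions", {
  res <- qc_filter(mm_fixture(), presence_min = 0.90, cv_max = 0.10)
  expect_identical(colnames(res$matrix$values), "A")
  ex <- res$exclusions
  expect_setequal(ex$metabolite, c("B", "C", "D"))
  expect_match(ex$reason[ex$metabolite == "B"], "presence")
  expect_identical(ex$reason[ex$metabolite == "C"], "cv")
  expect_identical(ex$reason[ex$metabolite == "D"], "cv_unavailable")
})

test_that("CV comes from pooled-QC replicate rows when present", {
  v <- matrix(exp(rnorm(30)), 10, 3,
              dimnames = list(NULL, c("x", "y", "z")))
  set.seed(15)
  qc <- cbind(rnorm(20, 100, 2), rnorm(20, 100, 2), rnorm(20, 100, 40))
  colnames(qc) <- c("x", "y", "z")
  mm <- make_mm(v, qc = qc)
  cv <- metabolite_cv(mm)
  expect_equal(unname(cv), unname(apply(qc, 2, sd) / colMeans(qc)))
  kept <- qc_filter(mm)$matrix
  expect_false("z" %in% colnames(kept$values))
})

test_that("loosening QC thresholds never shrinks the kept set", {
  mm <- mm_fixture()
  strict <- qc_filter(mm, 0.95, 0.06)$matrix$values
  loose <- qc_filter(mm, 0.80, 0.25)$matrix$values
  expect_true(all(colnames(strict) %in% colnames(loose)))
})

test_that("half-minimum imputation fills exactly 0.5 * column minimum", {
  v <- matrix(c(2, NA, 4, 1, 2, 3), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  out <- impute_half_min(make_mm(v))
  expect_identical(out$values[2, "a"], 1.0)
  expect_identical(unname(out$values[, "b"]), v[, "b"])  # untouched
  # exactness property on a random fixture
  set.seed(11)
  v2 <- matrix(exp(rnorm(200)), 20, 10,
               dimnames = list(NULL, paste0("m", 1:10)))
  v2[runif(200) < 0.2] <- NA
  mm2 <- make_mm(v2)
  imp <- impute_half_min(mm2)
  mask <- attr(imp, "imputed_mask")
  mins <- apply(v2, 2, min, na.rm = TRUE)
  idx <- which(mask, arr.ind = TRUE)
  expect_identical(imp$values[mask], unname(0.5 * mins[idx[, 2]]))
})

test_that("imputation is cohort-local and all-missing columns error", {
  a <- make_mm(matrix(c(2, NA, 6), 3, 1, dimnames = list(NULL, "m")),
               cohort = "A")
  b <- make_mm(matrix(c(6, NA, 12), 3, 1, dimnames = list(NULL, "m")),
               cohort = "B")
  expect_identical(impute_half_min(a)$values[2, 1], 1.0)
  expect_identical(impute_half_min(b)$values[2, 1], 3.0)
  allna <- matrix(NA_real_, 3, 1, dimnames = list(NULL, "gone"))
  expect_error(impute_half_min(metabolite_matrix(allna)), "gone")
})

test_that("log_standardize matches the hand-computed example", {
  # log values (0, 1, 2): mean 1, sample SD (n-1 convention) exactly 1,
  # hence z = (-1, 0, 1)
  v <- matrix(c(1, exp(1), exp(2)), 3, 1, dimnames = list(NULL, "m"))
  out <- log_standardize(make_mm(v))
  expect_equal(unname(out$z[, 1]), c(-1, 0, 1), tolerance = 1e-12)
  expect_error(log_standardize(make_mm(matrix(rep(2, 3), 3, 1,
                                              dimnames = list(NULL, "m")))),
               "zero variance")
})

test_that("standardization is exact, replayable, and scale-invariant", {
  set.seed(12)
  v <- matrix(exp(rnorm(300)), 30, 10,
              dimnames = list(sprintf("P%02d", 1:30), paste0("m", 1:10)))
  std <- log_standardize(make_mm(v))
  expect_lt(max(abs(colMeans(std$z))), 1e-12)
  expect_equal(unname(apply(std$z, 2, sd)), rep(1, 10), tolerance = 1e-12)
  expect_identical(replay_standardize(v, std), std$z)
  std3 <- log_standardize(make_mm(3 * v))
  expect_equal(std3$z, std$z, tolerance = 1e-12)
})

test_that("harmonization pipeline matches a hand-built reference", {
  set.seed(13)
  n <- 40
  heights <- runif(n, 1.5, 1.9)
  raw <- cbind(visceral_fat = runif(n, 50, 200),
               gait_speed = runif(n, 0.5, 2),
               glycemic_load = exp(rnorm(n, 3)))
  cfg <- pheno_config(colnames(raw),
                      domain = c("adiposity", "physical", "dietary"),
                      orientation = c("adverse", "higher_better", "adverse"),
                      transform = c("none", "none", "log"),
                      index_to_height = c(TRUE, FALSE, FALSE))
  h <- harmonize_phenotypes(raw, cfg, heights)
  # reference: log -> /height^1.7 -> negate adverse -> scale (n-1 SD)
  ref1 <- as.numeric(scale(-(raw[, 1] / heights^1.7)))
  ref3 <- as.numeric(scale(-log(raw[, 3])))
  expect_equal(unname(h$values[, "visceral_fat"]), ref1, tolerance = 1e-12)
  expect_equal(unname(h$values[, "glycemic_load"]), ref3, tolerance = 1e-12)
  # 1.6^1.7 indexing spot check: 100 cm^2 at 1.60 m -> 44.98 pre-scaling
  expect_equal(100 / 1.6^1.7, 44.98, tolerance = 1e-3)
  # adverse: smallest raw value becomes the largest harmonized value
  dense <- raw[, 1] / heights^1.7
  expect_equal(which.min(dense), which.max(h$values[, "visceral_fat"]))
  # orientation-preserving phenotype keeps rank order
  expect_identical(order(raw[, "gait_speed"]),
                   order(h$values[, "gait_speed"]))
  # every column standardized
  expect_lt(max(abs(colMeans(h$values))), 1e-12)
  expect_equal(unname(apply(h$values, 2, sd)), rep(1, 3), tolerance = 1e-12)
})

test_that("harmonization is idempotent once flags are cleared", {
  set.seed(14)
  raw <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("p1", "p2")))
  cfg <- pheno_config(c("p1", "p2"), domain = "d")
  h1 <- harmonize_phenotypes(raw, cfg)
  h2 <- harmonize_phenotypes(h1$values, cfg)
  expect_equal(h2$values, h1$values, tolerance = 1e-12)
})

test_that("harmonization errors are informative", {
  raw <- matrix(1:10, 5, 2, dimnames = list(NULL, c("a", "b")))
  cfg <- pheno_config(c("a", "b"), domain = "d",
                      index_to_height = c(TRUE, FALSE))
  expect_error(harmonize_phenotypes(raw, cfg), "heights")
  cfg2 <- pheno_config(c("a", "b"), domain = "d")
  raw2 <- raw; raw2[, 2] <- 5
  expect_error(harmonize_phenotypes(raw2, cfg2), "zero-variance.*b")
})
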