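# score transfer, composite endpoint, Cox and Kaplan-Meier models, grid

test_that("transfer to an identical cohort replays the training scores", {
  set.seed(30)
  v <- matrix(exp(rnorm(50 * 8, 8)), 50, 8,
              dimnames = list(sprintf("P%02d", 1:50), paste0("m", 1:8)))
  std <- log_standardize(make_mm(v))
  W <- matrix(rnorm(16), 8, 2,
              dimnames = list(paste0("m", 1:8), c("axis1", "axis2")))
  axes <- structure(list(loadings = NULL, weights = W,
                         variance_proportion = c(axis1 = .6, axis2 = .4),
                         signs = c(axis1 = 1, axis2 = 1),
                         labels = c(axis1 = "a", axis2 = "b")),
                    class = "aging_axes")
  train <- compute_scores(axes, std)
  moved <- transfer_scores(axes, std)
  expect_identical(moved$scores, train$scores)
  # column order is irrelevant: alignment is by metabolite id
  shuffled <- std
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  shuffled$z <- std$z[, perm]
  moved2 <- transfer_scores(axes, shuffled)
  expect_equal(moved2$scores, train$scores, tolerance = 1e-12)
  expect_identical(moved$labels, axes$labels)
})

test_that("composite takes the first event and flags healthy agers", {
  oc <- data.frame(
    participant_id = rep(c("p1", "p2"), each = 5),
    endpoint = rep(c("CVD", "cancer", "dementia", "disability", "death"), 2),
    time_years = c(3, 8, 10, 10, 5, rep(10, 5)),
    event = c(1, 1, 0, 0, 1, rep(0, 5)),
    stringsAsFactors = FALSE)
  comp <- build_composite(oc, horizon_years = 10)
  p1 <- comp[comp$participant_id == "p1", ]
  expect_equal(p1$time_years, 3)
  expect_equal(p1$event, 1L)
  expect_false(p1$healthy_ager)
  p2 <- comp[comp$participant_id == "p2", ]
  expect_equal(p2$event, 0L)
  expect_true(p2$healthy_ager)
})

test_that("composite excludes prevalent participants and flags incomplete ones", {
  oc <- data.frame(
    participant_id = c(rep("p1", 5), rep("p2", 5), rep("p3", 2)),
    endpoint = rep(c("CVD", "cancer", "dementia", "disability", "death"),
                   length.out = 12),
    time_years = c(rep(6, 10), 4, 7),
    event = c(rep(0, 10), 0, 0),
    prevalent = c(1, rep(0, 11)),
    stringsAsFactors = FALSE)
  comp <- build_composite(oc, horizon_years = 10)
  expect_false("p1" %in% comp$participant_id)
  p3 <- comp[comp$participant_id == "p3", ]
  expect_true(p3$incomplete)
  expect_equal(p3$time_years, 4)       # censored at last contact
  expect_error(build_composite(oc, horizon_years = 0), "horizon")
})

test_that("composite min/any algebra holds on a large synthetic fixture", {
  co <- generate_cohort(generator_config(n_participants = 1000,
                                         n_metabolites = 5, seed = 31))
  oc <- co$outcomes
  oc$prevalent <- 0L
  comp <- build_composite(oc, horizon_years = 10)
  wide_t <- tapply(oc$time_years, oc$participant_id, min)
  ref_t <- pmin(wide_t[comp$participant_id], 10)
  expect_equal(comp$time_years, as.vector(ref_t), tolerance = 1e-12)
  first_ev <- vapply(split(oc, oc$participant_id), function(d)
    as.integer(any(d$event == 1 & d$time_years == min(d$time_years))),
    0L)
  ref_e <- ifelse(wide_t[comp$participant_id] > 10, 0L,
                  first_ev[comp$participant_id])
  expect_identical(comp$event, as.vector(ref_e))
  expect_identical(comp$healthy_ager, comp$event == 0L & comp$time_years >= 10)
})

test_that("Cox HR inverts exactly under score negation and reciprocal reporting", {
  set.seed(32)
  n <- 500
  x <- rnorm(n)
  tt <- rexp(n, 0.08 * exp(-0.4 * x))
  ev <- as.integer(tt <= 8)
  tt <- pmin(tt, 8)
  f1 <- fit_cox(x, tt, ev, tier = "unadjusted")
  f2 <- fit_cox(-x, tt, ev, tier = "unadjusted")
  expect_equal(f2$hr, 1 / f1$hr, tolerance = 1e-10)
  fr <- fit_cox(x, tt, ev, tier = "unadjusted", reciprocal = TRUE)
  expect_equal(fr$hr * f1$hr, 1, tolerance = 1e-12)
  expect_equal(fr$ci_lower, 1 / f1$ci_upper, tolerance = 1e-12)
  expect_error(fit_cox(x, tt, rep(0L, n), tier = "unadjusted"), "no events")
})

test_that("adjusted Cox tiers use the declared covariate sets", {
  set.seed(33)
  n <- 600
  cov <- data.frame(age = rnorm(n, 74, 3), sex = rbinom(n, 1, .5),
                    race = rbinom(n, 1, .4), bmi = rnorm(n, 27, 4),
                    education = rbinom(n, 1, .7), smoker = rbinom(n, 1, .1),
                    hypertension = rbinom(n, 1, .5),
                    diabetes = rbinom(n, 1, .15), cystatin_c = rnorm(n, 1, .2))
  x <- rnorm(n)
  tt <- rexp(n, 0.08 * exp(-0.3 * x))
  ev <- as.integer(tt <= 10)
  tt <- pmin(tt, 10)
  fmin <- fit_cox(x, tt, ev, cov, tier = "minimal")
  ffull <- fit_cox(x, tt, ev, cov, tier = "full")
  expect_lt(abs(fmin$log_hr + 0.3), 0.15)
  expect_lt(abs(ffull$log_hr + 0.3), 0.15)
  expect_error(fit_cox(x, tt, ev, cov[, "bmi", drop = FALSE],
                       tier = "minimal"), "age")
})

test_that("Kaplan-Meier matches the hand product-limit on the toy record set", {
  km <- km_by_tertile(score = c(0.1, 0.5, 0.9), time = c(1, 2, 3),
                      event = c(1L, 0L, 1L), tertiles = FALSE)
  expect_equal(km$surv[km$time == 1], 2 / 3, tolerance = 1e-12)
  expect_equal(km$surv[km$time == 3], 0, tolerance = 1e-12)
  ref <- oracle_km(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$surv[km$n_event > 0], ref$surv, tolerance = 1e-12)
})

test_that("tertile KM stratifies at the empirical terciles", {
  set.seed(34)
  n <- 300
  score <- rnorm(n)
  tt <- rexp(n, 0.1 * exp(-0.5 * score))
  ev <- as.integer(tt <= 5)
  tt <- pmin(tt, 5)
  km <- km_by_tertile(score, tt, ev)
  expect_setequal(unique(km$stratum), c("T1", "T2", "T3"))
  # pooled sanity: no events -> flat curve at 1
  km0 <- km_by_tertile(score, rep(5, n), rep(0L, n), tertiles = FALSE)
  expect_true(all(km0$surv == 1))
  expect_error(km_by_tertile(rep(c(1, 2), 50), tt[1:100], ev[1:100]),
               "tertile|distinct")
})

test_that("association_grid returns exact unity for a self-regression", {
  set.seed(35)
  S <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "axis1"))
  S <- scale(S)
  grid <- association_grid(S, S, tiers = list(none = character(0)))
  expect_equal(grid$beta, 1, tolerance = 1e-12)
  expect_lt(grid$se, 1e-12)
})
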