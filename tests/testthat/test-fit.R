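test_that("intercept-only quasi-Poisson fit returns log(mean) exactly", {
  X <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_quasipoisson(X, c(2, 4, 6))
  expect_equal(unname(f$coefficients), log(4), tolerance = 1e-10)
})

test_that("equidispersed Poisson data yields dispersion near 1", {
  set.seed(11)
  n <- 20000
  x <- rnorm(n)
  mu <- exp(2 + 0.3 * x)
  y <- rpois(n, mu)
  X <- cbind("(Intercept)" = 1, x = x)
  f <- fit_quasipoisson(X, y)
  expect_gt(f$dispersion, 0.9)
  expect_lt(f$dispersion, 1.1)
})

test_that("duplicated columns trigger a named rank-deficiency failure", {
  X <- cbind(a = rep(1, 20), b = rnorm(20))
  X <- cbind(X, b_copy = X[, "b"])
  expect_error(fit_quasipoisson(X, rpois(20, 5)), "b_copy")
})

test_that("IRLS agrees with a generic optimizer on random small problems", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 80
    X <- cbind(1, rnorm(n), runif(n))
    colnames(X) <- c("int", "x1", "x2")
    beta0 <- c(1.5, 0.4, -0.6)
    y <- rpois(n, exp(X %*% beta0))
    f <- fit_quasipoisson(X, y)
    negll <- function(b) sum(exp(X %*% b)) - sum(y * (X %*% b))
    opt <- optim(c(0, 0, 0), negll, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
    expect_equal(unname(f$coefficients), opt$par, tolerance = 1e-5)
  }
})

test_that("coefficient covariance is the dispersion-scaled inverse information", {
  set.seed(13)
  n <- 500
  X <- cbind(1, rnorm(n))
  colnames(X) <- c("int", "x")
  y <- rnbinom(n, mu = exp(1 + 0.2 * X[, 2]), size = 5)
  f <- fit_quasipoisson(X, y)
  W <- exp(as.numeric(X %*% f$coefficients))
  V_manual <- f$dispersion * solve(t(X) %*% (W * X))
  expect_equal(unname(f$covariance), unname(V_manual), tolerance = 1e-6)
  # covariance is symmetric positive semi-definite
  expect_equal(f$covariance, t(f$covariance), tolerance = 1e-10)
  expect_true(all(eigen(f$covariance, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
})

test_that("QAIC follows its defining arithmetic", {
  fake <- structure(list(quasi_loglik = -100, dispersion = 2,
                         coefficients = rnorm(10)), class = "dlnm_fit")
  expect_equal(qaic(fake, dispersion_ref = 2), 120)
  # phi = 1 reduces QAIC to ordinary Poisson AIC
  X <- matrix(1, 50, 1, dimnames = list(NULL, "i"))
  set.seed(14)
  y <- rpois(50, 5)
  f <- fit_quasipoisson(X, y)
  aic <- -2 * sum(dpois(y, mean(y), log = TRUE)) + 2
  expect_equal(qaic(f, dispersion_ref = 1), aic, tolerance = 1e-8)
  # identical likelihood, extra parameters: penalty of 2 per parameter
  fake2 <- fake
  fake2$coefficients <- rnorm(13)
  expect_equal(qaic(fake2, 2) - qaic(fake, 2), 6)
  expect_error(qaic(fake, dispersion_ref = 0), "> 0")
})

test_that("design blocks have the documented shapes", {
  d <- small_series(365)  # one calendar year
  sp <- model_spec(date_df_per_year = 8)
  des <- build_design(d, sp)
  expect_equal(length(des$registry$trend), 8L)
  expect_equal(length(des$registry$crossbasis), 12L)  # model-11 form: 3 x 4
  expect_equal(length(des$registry$dow), 6L)
  expect_equal(length(des$registry$intercept), 1L)
  expect_equal(ncol(des$X), 1L + 6L + 1L + 8L + 12L)
  expect_equal(nrow(des$X), length(des$y))
  # rows with incomplete lag histories are dropped
  expect_false(any(des$rows < 31))
})

test_that("a minimal model reduces to intercept + trend + one exposure column", {
  d <- small_series(500)
  sp <- model_spec(exposure_fun = "linear", lag_fun = "constant",
                   covariates = character(0), lag_max = 0,
                   date_df_per_year = 7)
  des <- build_design(d, sp)
  expect_named(des$registry, c("intercept", "trend", "crossbasis"))
  expect_equal(length(des$registry$crossbasis), 1L)
})

test_that("constant covariates are dropped with a warning, not an error", {
  d <- small_series(500)
  d$holiday <- 0L
  sp <- model_spec(covariates = c("dow", "holiday", "pop"))
  expect_warning(expect_warning(build_design(d, sp), "holiday"), "pop")
})

test_that("the candidate grid enumerates 48 unique specs spanning df 1-20", {
  cands <- enumerate_candidates()
  expect_length(cands, 48L)
  key <- vapply(cands, function(sp)
    paste(sp$exposure_fun, sp$exposure_nknots, sp$lag_fun, sp$lag_nknots,
          sp$date_df_per_year), character(1))
  expect_equal(anyDuplicated(key), 0L)
  dfs <- vapply(cands, tempmort:::cb_df_of_spec, integer(1))
  expect_equal(min(dfs), 1L)
  expect_equal(max(dfs), 20L)
  expect_equal(vapply(cands, function(sp) attr(sp, "model_id"), integer(1)),
               1:48)
})

test_that("select_best ranks by QAIC and handles a single candidate", {
  d <- small_series(900, seed = 31)
  one <- select_best(d, list(model_spec(date_df_per_year = 7)))
  expect_equal(nrow(one$table), 1L)
  expect_equal(one$best_spec$date_df_per_year, 7L)

  cands <- list(model_spec(exposure_fun = "linear", lag_fun = "constant"),
                model_spec(),
                model_spec(date_df_per_year = 9))
  sel <- select_best(d, cands)
  expect_equal(nrow(sel$table), 3L)
  expect_true(all(diff(sel$table$qaic[sel$table$converged]) >= 0))
  expect_equal(qaic(sel$best_fit, sel$dispersion_ref), min(sel$table$qaic))
})

test_that("seasonal designs draw lags across season boundaries", {
  d <- small_series(800, seed = 41)
  sp <- model_spec(season = "winter")
  des <- build_design(d, sp)
  mon <- as.integer(format(d$date[des$rows], "%m"))
  expect_true(all(mon %in% c(12, 1, 2, 3)))
  # January rows keep full lag histories (drawn from December data):
  # the cross-basis block contains no NA
  expect_false(anyNA(des$X))
})
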