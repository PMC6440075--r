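# one moderately sized fit shared across prediction tests
fit_for_prediction <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- fit_dlnm(small_series(1500, seed = 51), model_spec())
    memo
  }
})

test_that("zeroed cross-basis coefficients give RR 1 everywhere", {
  f <- fit_for_prediction()
  idx <- f$registry$crossbasis
  f0 <- f
  f0$coefficients[idx] <- 0
  cc <- predict_cumulative(f0)
  expect_equal(cc$rr, rep(1, nrow(cc)), tolerance = 1e-12)
  expect_true(all(cc$rr_low <= 1 & 1 <= cc$rr_high))
  sf <- predict_surface(f0)
  expect_equal(max(abs(sf$log_rr)), 0, tolerance = 1e-12)
})

test_that("the reference temperature has RR exactly 1 with zero se", {
  f <- fit_for_prediction()
  ref <- f$cb_spec$ref_temp
  cc <- predict_cumulative(f, temp_grid = ref)
  expect_equal(cc$rr, 1)
  expect_equal(cc$se, 0)
  lc <- predict_lag(f, ref)
  expect_equal(lc$log_rr, rep(0, 31), tolerance = 1e-12)
  sf <- predict_surface(f, temp_grid = ref)
  expect_equal(as.numeric(sf$rr), rep(1, 31), tolerance = 1e-12)
})

test_that("bounds bracket the point estimate and follow the Wald form", {
  f <- fit_for_prediction()
  cc <- predict_cumulative(f)
  expect_true(all(cc$rr_low <= cc$rr & cc$rr <= cc$rr_high))
  expect_equal(cc$rr_high,
               exp(cc$log_rr + qnorm(0.975) * cc$se), tolerance = 1e-12)
})

test_that("linear x constant fits obey the closed-form 31-lag contrast", {
  d <- small_series(1200, seed = 52)
  sp <- model_spec(exposure_fun = "linear", lag_fun = "constant")
  f <- fit_dlnm(d, sp)
  idx <- f$registry$crossbasis
  b <- unname(f$coefficients[idx])
  v <- unname(f$covariance[idx, idx])
  ref <- f$cb_spec$ref_temp
  cc <- predict_cumulative(f, temp_grid = ref + 1)
  expect_equal(cc$rr, exp(31 * b), tolerance = 1e-10)
  expect_equal(cc$rr_low, exp(31 * b - qnorm(0.975) * 31 * sqrt(v)),
               tolerance = 1e-10)
  # constant lag basis: identical log-RR at every lag
  lc <- predict_lag(f, ref + 1)
  expect_equal(lc$log_rr, rep(b, 31), tolerance = 1e-10)
})

test_that("lag curves and surfaces are additive to the cumulative curve", {
  f <- fit_for_prediction()
  x <- f$data$tmean[f$rows]
  for (tp in quantile(x, c(0.01, 0.25, 0.99))) {
    lc <- predict_lag(f, tp)
    cc <- predict_cumulative(f, temp_grid = tp)
    expect_equal(sum(lc$log_rr), cc$log_rr, tolerance = 1e-10)
  }
  sf <- predict_surface(f, temp_grid = quantile(x, c(0.05, 0.5, 0.95)))
  cc <- predict_cumulative(f, temp_grid = sf$temp)
  expect_equal(rowSums(sf$log_rr), cc$log_rr, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("a surface built from known coefficients is reproduced exactly", {
  set.seed(53)
  x <- rnorm(400, 15, 5)
  spec <- random_cb_spec(x, 30)
  p <- prod(cb_dim(spec))
  beta <- rnorm(p, 0, 0.01)
  fake <- structure(list(
    coefficients = setNames(beta, paste0("cb", seq_len(p))),
    covariance = diag(1e-6, p),
    registry = list(crossbasis = seq_len(p)),
    cb_spec = spec
  ), class = "dlnm_fit")
  grid <- quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
  sf <- predict_surface(fake, temp_grid = grid)
  R <- oracle_exposure_basis(grid, spec)
  C <- oracle_lag_basis(spec)
  vl <- ncol(C)
  truth <- matrix(0, length(grid), 31)
  for (i in seq_along(grid)) for (l in 0:30)
    for (j in seq_len(ncol(R))) for (k in seq_len(vl))
      truth[i, l + 1] <- truth[i, l + 1] +
        R[i, j] * C[l + 1, k] * beta[(j - 1) * vl + k]
  expect_equal(sf$log_rr, truth, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("delta-method se matches a multivariate-normal coefficient simulation", {
  f <- fit_for_prediction()
  idx <- f$registry$crossbasis
  V <- f$covariance[idx, idx]
  beta <- f$coefficients[idx]
  set.seed(54)
  draws <- matrix(rnorm(2000 * length(beta)), 2000) %*% chol(V)
  draws <- sweep(draws, 2, beta, "+")
  x <- f$data$tmean[f$rows]
  for (tp in quantile(x, c(0.05, 0.95))) {
    w <- cumulative_contrast(f$cb_spec, tp)
    mc_se <- sd(draws %*% w)
    cc <- predict_cumulative(f, temp_grid = tp)
    expect_lt(abs(cc$se - mc_se) / mc_se, 0.05)
  }
})

test_that("spec dimension mismatches fail with an informative message", {
  f <- fit_for_prediction()
  other <- crossbasis_spec(exposure_fun = "linear",
                           exposure_boundary = f$cb_spec$exposure_boundary,
                           lag_fun = "constant", ref_temp = f$cb_spec$ref_temp)
  expect_error(predict_cumulative(f, spec = other), "mismatch")
})

test_that("percentile RR report covers mean and extreme temperatures", {
  f <- fit_for_prediction()
  pr <- rr_at_percentiles(f)
  expect_equal(pr$label, c("mean", "p1", "p99"))
  expect_true(all(pr$rr_low <= pr$rr & pr$rr <= pr$rr_high))
  # a cold-dominated truth: elevated risk at the 1st percentile
  expect_gt(pr$rr[pr$label == "p1"], 1)
})
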