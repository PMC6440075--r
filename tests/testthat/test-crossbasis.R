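test_that("quadratic B-spline basis has partition of unity and endpoint properties", {
  x <- seq(0, 1, by = 0.05)
  B <- bspline_basis(x, degree = 2, interior_knots = numeric(0),
                     boundary = c(0, 1), intercept = TRUE)
  expect_equal(ncol(B), 3L)
  expect_equal(rowSums(B), rep(1, length(x)), tolerance = 1e-12)
  Bl <- bspline_basis(0, degree = 2, boundary = c(0, 1), intercept = TRUE)
  expect_equal(as.numeric(Bl), c(1, 0, 0), tolerance = 1e-12)
})

test_that("B-spline values match a hand-coded Cox-de Boor recursion", {
  x <- c(0.1, 0.25, 0.5, 0.77, 0.99)
  B <- bspline_basis(x, degree = 2, interior_knots = 0.5,
                     boundary = c(0, 1), intercept = TRUE)
  O <- cdb_basis(x, 2, 0.5, c(0, 1), intercept = TRUE)
  expect_equal(B, O, ignore_attr = TRUE, tolerance = 1e-12)

  # and across degrees / knot layouts
  for (deg in 1:3) for (ik in list(numeric(0), 0.3, c(0.3, 0.7))) {
    B <- bspline_basis(x, degree = deg, interior_knots = ik,
                       boundary = c(0, 1), intercept = TRUE)
    O <- cdb_basis(x, deg, ik, c(0, 1), intercept = TRUE)
    expect_equal(B, O, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("knots outside the boundary are rejected", {
  expect_error(bspline_basis(0.5, 2, interior_knots = 1.5, boundary = c(0, 1)),
               "inside the boundary")
  expect_error(crossbasis_spec(exposure_knots = 50, exposure_boundary = c(0, 30),
                               ref_temp = 15),
               "inside the boundary")
})

test_that("linear x constant cross-basis is the centred 31-day moving sum", {
  set.seed(42)
  x <- rnorm(200, 15, 5)
  spec <- crossbasis_spec(exposure_fun = "linear", exposure_boundary = range(x),
                          lag_fun = "constant", lag_max = 30, ref_temp = 15)
  cb <- build_crossbasis(x, spec)
  expect_equal(ncol(cb), 1L)
  mov <- vapply(31:200, function(t) sum(x[t:(t - 30)] - 15), numeric(1))
  expect_equal(as.numeric(cb[31:200, 1]), mov, tolerance = 1e-10)
  expect_true(all(is.na(cb[1:30, ])))
  expect_equal(attr(cb, "valid_from"), 31L)
})

test_that("all-reference exposures give an all-zero cross-basis", {
  spec <- crossbasis_spec(exposure_boundary = c(0, 30), exposure_knots = 15,
                          lag_knots = 15, ref_temp = 12)
  cb <- build_crossbasis(rep(12, 100), spec)
  expect_equal(max(abs(cb[31:100, ])), 0, tolerance = 1e-12)
})

test_that("lag_max = 0 degenerates to the centred same-day exposure basis", {
  set.seed(7)
  x <- runif(50, 0, 30)
  spec <- crossbasis_spec(exposure_knots = 15, exposure_boundary = c(0, 30),
                          lag_fun = "constant", lag_max = 0, ref_temp = 14)
  cb <- build_crossbasis(x, spec)
  R <- oracle_exposure_basis(x, spec)
  expect_equal(unclass(cb)[, , drop = FALSE], R, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("cross-basis matches the naive triple-loop oracle on random specs", {
  set.seed(123)
  for (rep in 1:10) {
    L <- sample(5:30, 1)
    x <- rnorm(120, 15, 5)
    spec <- random_cb_spec(x, L)
    cb <- build_crossbasis(x, spec)
    O <- naive_crossbasis(x, spec)
    expect_equal(unclass(cb), O, ignore_attr = TRUE, tolerance = 1e-10)
    expect_equal(ncol(cb), prod(cb_dim(spec)))
  }
})

test_that("cumulative contrast weights reduce to closed forms", {
  spec <- crossbasis_spec(exposure_fun = "linear", exposure_boundary = c(0, 30),
                          lag_fun = "constant", lag_max = 30, ref_temp = 10)
  expect_equal(cumulative_contrast(spec, 10), 0)         # reference: zero vector
  expect_equal(cumulative_contrast(spec, 11), 31)        # (L + 1) lags of +1 C

  spec2 <- crossbasis_spec(exposure_knots = 15, exposure_boundary = c(0, 30),
                           lag_knots = 15, ref_temp = 12)
  expect_equal(cumulative_contrast(spec2, 12),
               rep(0, prod(cb_dim(spec2))), tolerance = 1e-12)
  # eta = 0 gives zero log-RR for any temperature
  w <- cumulative_contrast(spec2, 25)
  expect_equal(as.numeric(w %*% rep(0, length(w))), 0)
})

test_that("lag-response slice sums over lags to the cumulative contrast", {
  set.seed(9)
  x <- rnorm(300, 15, 5)
  for (rep in 1:5) {
    spec <- random_cb_spec(x, 30)
    beta <- rnorm(prod(cb_dim(spec)))
    for (tp in quantile(x, c(0.05, 0.5, 0.95))) {
      Wl <- lag_contrast(spec, tp)
      wc <- cumulative_contrast(spec, tp)
      expect_equal(sum(Wl %*% beta), as.numeric(wc %*% beta), tolerance = 1e-10)
    }
  }
})

test_that("the model-11 style spec yields exactly 12 cross-basis columns", {
  spec <- crossbasis_spec(exposure_fun = "bspline", exposure_knots = 13.5,
                          exposure_boundary = c(0, 27), lag_fun = "bspline",
                          lag_knots = 15, lag_max = 30, ref_temp = 13.5)
  expect_equal(unname(prod(cb_dim(spec))), 12L)
  expect_equal(unname(cb_dim(spec)), c(3L, 4L))
  cb <- build_crossbasis(rnorm(60, 14, 4), spec)
  expect_equal(ncol(cb), 12L)
})

test_that("temperatures outside the exposure boundary are flagged", {
  spec <- crossbasis_spec(exposure_knots = 15, exposure_boundary = c(0, 30),
                          lag_knots = 15, ref_temp = 15)
  expect_warning(cumulative_contrast(spec, 35), "outside the exposure boundary")
})
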