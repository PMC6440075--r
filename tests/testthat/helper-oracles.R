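# Independent oracles used across the suite. These deliberately avoid the
# package's own basis/crossbasis code paths (splines::splineDesign,
# stats::embed): the Cox-de Boor recursion is coded from the textbook
# definition, and the cross-basis oracle is a literal triple loop.

# B_{i,degree}(x) for a single x via the Cox-de Boor recursion on an
# explicit knot vector. The indicator at degree 0 is half-open except at
# the right end of the overall support.
cdb_basis_one <- function(x, knots, degree, i) {
  if (degree == 0) {
    right_end <- knots[i + 1] == max(knots)
    return(as.numeric(x >= knots[i] &
                      (x < knots[i + 1] | (right_end & x == knots[i + 1]))))
  }
  d1 <- knots[i + degree] - knots[i]
  d2 <- knots[i + degree + 1] - knots[i + 1]
  a <- if (d1 > 0) (x - knots[i]) / d1 * cdb_basis_one(x, knots, degree - 1, i) else 0
  b <- if (d2 > 0) (knots[i + degree + 1] - x) / d2 *
    cdb_basis_one(x, knots, degree - 1, i + 1) else 0
  a + b
}

# Full B-spline basis via the recursion (boundary knots repeated
# degree + 1 times, matching the conventional augmented knot vector).
cdb_basis <- function(x, degree, interior, boundary, intercept = TRUE) {
  knots <- c(rep(boundary[1], degree + 1), sort(interior),
             rep(boundary[2], degree + 1))
  nb <- length(knots) - degree - 1
  B <- sapply(seq_len(nb), function(i)
    vapply(x, cdb_basis_one, numeric(1), knots = knots, degree = degree, i = i))
  B <- matrix(B, nrow = length(x))
  if (!intercept) B <- B[, -1, drop = FALSE]
  B
}

# Centred exposure basis from the recursion oracle.
oracle_exposure_basis <- function(x, spec) {
  if (spec$exposure_fun == "linear") return(matrix(x - spec$ref_temp, ncol = 1))
  B <- cdb_basis(x, 2, spec$exposure_knots, spec$exposure_boundary, intercept = FALSE)
  Bref <- cdb_basis(spec$ref_temp, 2, spec$exposure_knots,
                    spec$exposure_boundary, intercept = FALSE)
  sweep(B, 2, as.numeric(Bref), "-")
}

oracle_lag_basis <- function(spec) {
  lags <- 0:spec$lag_max
  if (spec$lag_fun == "constant") return(matrix(1, length(lags), 1))
  cdb_basis(lags, 2, spec$lag_knots, c(0, spec$lag_max), intercept = TRUE)
}

# Literal triple-loop cross-basis: entry (t, (j-1)*vl + k) =
# sum_l R_j(x[t-l]) C_k(l). Rows with incomplete lag history are NA.
naive_crossbasis <- function(x, spec) {
  R <- oracle_exposure_basis(x, spec)
  C <- oracle_lag_basis(spec)
  n <- length(x); L <- spec$lag_max
  vx <- ncol(R); vl <- ncol(C)
  Q <- matrix(NA_real_, n, vx * vl)
  for (t in (L + 1):n)
    for (j in 1:vx)
      for (k in 1:vl) {
        s <- 0
        for (l in 0:L) s <- s + R[t - l, j] * C[l + 1, k]
        Q[t, (j - 1) * vl + k] <- s
      }
  Q
}

# Random cross-basis spec on a series' range, for property-style loops.
random_cb_spec <- function(x, lag_max) {
  ef <- sample(c("linear", "bspline"), 1)
  lf <- sample(c("constant", "bspline"), 1)
  ek <- if (ef == "bspline") sample(0:2, 1) else 0
  lk <- if (lf == "bspline") sample(0:2, 1) else 0
  bnd <- range(x)
  crossbasis_spec(
    exposure_fun = ef,
    exposure_knots = if (ek > 0) bnd[1] + diff(bnd) * seq_len(ek) / (ek + 1) else numeric(0),
    exposure_boundary = bnd,
    lag_fun = lf,
    lag_knots = if (lk > 0) lag_max * seq_len(lk) / (lk + 1) else numeric(0),
    lag_max = lag_max,
    ref_temp = median(x)
  )
}

# Small synthetic region series for fitting tests.
small_series <- function(n_days = 1200, seed = 5, ...) {
  sc <- truth_scenario(n_days = n_days, seed = seed, ...)
  generate_mortality(generate_temperature(sc), sc)
}
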