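#' Cross-basis specification for a distributed lag non-linear model
#'
#' Defines the bi-dimensional spline parameterization encoding a non-linear
#' exposure-response function \code{f(x)} and a lag-response function
#' \code{w(l)} over lags \code{0..lag_max}. The realized cross-basis is the
#' tensor product of the two marginal bases, summed over the lag window.
#'
#' The exposure basis is either a simple linear term (1 df) or a quadratic
#' B-spline without intercept (2 + number of interior knots df). The lag
#' basis is either a constant (1 df) or a quadratic B-spline with intercept
#' (3 + number of interior knots df). Only the lag basis carries an
#' intercept: a tensor product with intercepts in both margins would not be
#' identifiable next to the model intercept.
#'
#' All exposure basis columns are centred at \code{ref_temp}, so the fitted
#' relative risk is 1 at the reference temperature by construction.
#'
#' @param exposure_fun "linear" or "bspline" (quadratic B-spline, no
#'   intercept).
#' @param exposure_knots numeric vector of interior knots (degrees C), strictly
#'   inside \code{exposure_boundary}. Ignored for "linear".
#' @param exposure_boundary length-2 numeric, boundary knots (typically the
#'   observed temperature range).
#' @param lag_fun "constant" or "bspline" (quadratic B-spline with intercept).
#' @param lag_knots numeric vector of interior knots on the lag scale,
#'   strictly inside \code{(0, lag_max)}. Ignored for "constant".
#' @param lag_max maximum lag in days (default 30).
#' @param ref_temp reference temperature (degrees C) at which the exposure
#'   basis is centred; relative risks are reported against it.
#' @return an object of class \code{"crossbasis_spec"}.
#' @export
crossbasis_spec <- function(exposure_fun = c("bspline", "linear"),
                            exposure_knots = numeric(0),
                            exposure_boundary,
                            lag_fun = c("bspline", "constant"),
                            lag_knots = numeric(0),
                            lag_max = 30L,
                            ref_temp) {
  exposure_fun <- match.arg(exposure_fun)
  lag_fun <- match.arg(lag_fun)
  if (missing(exposure_boundary) || length(exposure_boundary) != 2L ||
      !(exposure_boundary[1] < exposure_boundary[2]))
    stop("'exposure_boundary' must be a length-2 increasing numeric vector")
  if (missing(ref_temp) || !is.finite(ref_temp))
    stop("'ref_temp' must be a finite reference temperature")
  lag_max <- as.integer(lag_max)
  if (lag_max < 0L) stop("'lag_max' must be >= 0")
  if (exposure_fun == "bspline" && length(exposure_knots) > 0 &&
      (any(exposure_knots <= exposure_boundary[1]) ||
       any(exposure_knots >= exposure_boundary[2])))
    stop("exposure knots must lie strictly inside the boundary")
  if (lag_fun == "bspline" && length(lag_knots) > 0 &&
      (any(lag_knots <= 0) || any(lag_knots >= lag_max)))
    stop("lag knots must lie strictly inside (0, lag_max)")
  if (exposure_fun == "linear") exposure_knots <- numeric(0)
  if (lag_fun == "constant") lag_knots <- numeric(0)
  structure(list(
    exposure_fun = exposure_fun,
    exposure_knots = as.numeric(sort(exposure_knots)),
    exposure_boundary = as.numeric(exposure_boundary),
    lag_fun = lag_fun,
    lag_knots = as.numeric(sort(lag_knots)),
    lag_max = lag_max,
    ref_temp = as.numeric(ref_temp)
  ), class = "crossbasis_spec")
}

#' @export
print.crossbasis_spec <- function(x, ...) {
  cat("Cross-basis specification\n")
  cat(sprintf("  exposure: %s, knots [%s], boundary [%.2f, %.2f], ref %.2f C\n",
              x$exposure_fun, paste(signif(x$exposure_knots, 4), collapse = ", "),
              x$exposure_boundary[1], x$exposure_boundary[2], x$ref_temp))
  cat(sprintf("  lag: %s, knots [%s], lags 0..%d\n",
              x$lag_fun, paste(x$lag_knots, collapse = ", "), x$lag_max))
  cat(sprintf("  dimension: %d x %d = %d columns\n",
              cb_dim(x)["vx"], cb_dim(x)["vl"], prod(cb_dim(x))))
  invisible(x)
}

#' Marginal basis dimensions of a cross-basis
#'
#' @param spec a \code{crossbasis_spec}.
#' @return named integer vector \code{c(vx =, vl =)}: exposure and lag basis
#'   dimensions. Total cross-basis df is the product.
#' @export
cb_dim <- function(spec) {
  vx <- if (spec$exposure_fun == "linear") 1L else 2L + length(spec$exposure_knots)
  vl <- if (spec$lag_fun == "constant") 1L else 3L + length(spec$lag_knots)
  c(vx = vx, vl = vl)
}

#' Evaluate a B-spline basis
#'
#' Thin wrapper around \code{splines::splineDesign} using the conventional
#' knot augmentation (boundary knots repeated degree + 1 times). With
#' \code{intercept = TRUE} the columns form a partition of unity on the
#' boundary interval; with \code{intercept = FALSE} the first column is
#' dropped. Values of \code{x} outside the boundary are clamped to it
#' (constant extrapolation of the basis).
#'
#' @param x numeric vector of evaluation points.
#' @param degree spline degree (2 = quadratic throughout this package).
#' @param interior_knots interior knots, strictly inside \code{boundary}.
#' @param boundary length-2 increasing numeric vector.
#' @param intercept keep the full basis (TRUE) or drop the first column.
#' @return numeric matrix with \code{length(x)} rows.
#' @export
bspline_basis <- function(x, degree = 2L, interior_knots = numeric(0),
                          boundary, intercept = TRUE) {
  if (length(boundary) != 2L || !(boundary[1] < boundary[2]))
    stop("'boundary' must be a length-2 increasing vector")
  if (length(interior_knots) > 0 &&
      (any(interior_knots <= boundary[1]) || any(interior_knots >= boundary[2])))
    stop("interior knots must lie strictly inside the boundary")
  degree <- as.integer(degree)
  knots <- c(rep(boundary[1], degree + 1L), sort(interior_knots),
             rep(boundary[2], degree + 1L))
  xc <- pmin(pmax(x, boundary[1]), boundary[2])
  B <- splines::splineDesign(knots, xc, ord = degree + 1L)
  if (!intercept) B <- B[, -1L, drop = FALSE]
  B
}

# Exposure-response basis evaluated at x, centred so each column is 0 at the
# reference temperature. Returns length(x) x vx matrix.
exposure_basis <- function(x, spec, centred = TRUE) {
  if (spec$exposure_fun == "linear") {
    R <- matrix(x, ncol = 1L)
    ref_row <- matrix(spec$ref_temp, 1L, 1L)
  } else {
    R <- bspline_basis(x, degree = 2L, interior_knots = spec$exposure_knots,
                       boundary = spec$exposure_boundary, intercept = FALSE)
    ref_row <- bspline_basis(spec$ref_temp, degree = 2L,
                             interior_knots = spec$exposure_knots,
                             boundary = spec$exposure_boundary, intercept = FALSE)
  }
  if (centred) R <- sweep(R, 2L, as.numeric(ref_row), "-")
  R
}

# Lag-response basis evaluated at integer lags 0..lag_max.
# Returns (lag_max + 1) x vl matrix.
lag_basis <- function(spec) {
  lags <- 0:spec$lag_max
  if (spec$lag_fun == "constant") {
    matrix(1, nrow = length(lags), ncol = 1L)
  } else {
    bspline_basis(lags, degree = 2L, interior_knots = spec$lag_knots,
                  boundary = c(0, spec$lag_max), intercept = TRUE)
  }
}

#' Build the cross-basis matrix for an exposure series
#'
#' Realizes the tensor-product design block: entry \code{(t, (j-1)*vl + k)}
#' is \code{sum_{l=0}^{L} R_j(x[t-l]) * C_k(l)}, where \code{R} is the
#' exposure basis centred at the reference temperature and \code{C} the lag
#' basis at integer lags. The first \code{lag_max} rows have incomplete lag
#' histories and are set to \code{NA}.
#'
#' @param x numeric exposure (temperature) series, daily, in time order.
#' @param spec a \code{crossbasis_spec}.
#' @return a matrix of class \code{"crossbasis"} with attributes
#'   \code{spec} and \code{valid_from} (first fully lagged row index).
#' @export
build_crossbasis <- function(x, spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  n <- length(x)
  L <- spec$lag_max
  if (n <= L) stop(sprintf("series length (%d) must exceed lag_max (%d)", n, L))
  R <- exposure_basis(x, spec)
  C <- lag_basis(spec)
  d <- cb_dim(spec)
  Q <- matrix(NA_real_, n, d["vx"] * d["vl"])
  for (j in seq_len(d["vx"])) {
    # lagged matrix: row t holds R[t], R[t-1], ..., R[t-L] for column j
    M <- stats::embed(R[, j], L + 1L)
    Q[(L + 1L):n, (j - 1L) * d["vl"] + seq_len(d["vl"])] <- M %*% C
  }
  colnames(Q) <- paste0("cb", rep(seq_len(d["vx"]), each = d["vl"]),
                        ".", rep(seq_len(d["vl"]), d["vx"]))
  structure(Q, spec = spec, valid_from = L + 1L, class = c("crossbasis", "matrix"))
}

#' Coefficient weights for the overall cumulative log-RR at a temperature
#'
#' Returns the vector \code{w} such that \code{w' beta} equals the overall
#' cumulative log relative risk at \code{temp} versus the reference
#' temperature, i.e. the sum of lag-specific contributions over lags
#' \code{0..lag_max}: \code{w[(j,k)] = R_j(temp) * sum_l C_k(l)}.
#'
#' @param spec a \code{crossbasis_spec}.
#' @param temp temperature(s), degrees C. Values outside the exposure
#'   boundary trigger a warning and are clamped.
#' @return if \code{temp} is scalar, a numeric weight vector of length
#'   \code{vx * vl}; otherwise a matrix with one row per temperature.
#' @export
cumulative_contrast <- function(spec, temp) {
  check_support(spec, temp)
  R <- exposure_basis(temp, spec)         # nt x vx
  csum <- colSums(lag_basis(spec))        # vl
  d <- cb_dim(spec)
  W <- R[, rep(seq_len(d["vx"]), each = d["vl"]), drop = FALSE] *
    matrix(csum, nrow(R), d["vx"] * d["vl"], byrow = TRUE)
  if (length(temp) == 1L) as.numeric(W) else W
}

#' Coefficient weights for the lag-response curve at a fixed temperature
#'
#' @param spec a \code{crossbasis_spec}.
#' @param temp single temperature, degrees C.
#' @param lags integer lags (default \code{0:lag_max}).
#' @return matrix with one row per lag; row l satisfies
#'   \code{w_l' beta = } log-RR contribution at that lag.
#' @export
lag_contrast <- function(spec, temp, lags = 0:spec$lag_max) {
  stopifnot(length(temp) == 1L)
  check_support(spec, temp)
  if (any(lags < 0 | lags > spec$lag_max)) stop("lags must lie in 0..lag_max")
  R <- exposure_basis(temp, spec)         # 1 x vx
  Cfull <- lag_basis(spec)
  C <- Cfull[lags + 1L, , drop = FALSE]   # nl x vl
  d <- cb_dim(spec)
  W <- matrix(0, length(lags), d["vx"] * d["vl"])
  for (j in seq_len(d["vx"]))
    W[, (j - 1L) * d["vl"] + seq_len(d["vl"])] <- R[1L, j] * C
  W
}

check_support <- function(spec, temp) {
  out <- temp < spec$exposure_boundary[1] | temp > spec$exposure_boundary[2]
  if (any(out))
    warning(sprintf(
      "%d temperature value(s) outside the exposure boundary [%.2f, %.2f]; clamped",
      sum(out), spec$exposure_boundary[1], spec$exposure_boundary[2]))
  invisible(NULL)
}
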