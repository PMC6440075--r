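#' Overall cumulative exposure-response curve with Wald intervals
#'
#' For each grid temperature the cumulative log-RR over lags 0..lag_max is
#' \code{w' beta} with \code{w} from \code{\link{cumulative_contrast}} and
#' \code{beta} the cross-basis coefficient block; its delta-method standard
#' error is \code{sqrt(w' V w)}. 95 percent bounds use the normal quantile
#' on the log scale. The curve is exactly 1 (RR) with zero standard error
#' at the reference temperature.
#'
#' @param fit a \code{dlnm_fit} from \code{\link{fit_dlnm}}.
#' @param temp_grid temperatures, degrees C; default 1-degree steps over
#'   the exposure boundary.
#' @param spec cross-basis spec; default the one stored on the fit. Must
#'   match the fit's cross-basis block dimension.
#' @param level confidence level (default 0.95).
#' @return data.frame of class \code{"cumulative_curve"}: \code{temp,
#'   log_rr, se, rr, rr_low, rr_high}.
#' @export
predict_cumulative <- function(fit, temp_grid = NULL, spec = fit$cb_spec,
                               level = 0.95) {
  bk <- cb_block(fit, spec)
  if (is.null(temp_grid))
    temp_grid <- seq(ceiling(spec$exposure_boundary[1]),
                     floor(spec$exposure_boundary[2]), by = 1)
  W <- cumulative_contrast(spec, temp_grid)
  if (length(temp_grid) == 1L) W <- matrix(W, nrow = 1L)
  curve_from_weights(W, bk$beta, bk$V, temp_grid, level,
                     cls = "cumulative_curve", xname = "temp")
}

#' Lag-response curve at a fixed temperature
#'
#' Log-RR contribution of each single lag 0..lag_max for exposure held at
#' \code{temp}, with delta-method intervals. Summing the curve's log-RR
#' over all lags reproduces the overall cumulative log-RR at \code{temp}.
#'
#' @inheritParams predict_cumulative
#' @param temp single temperature, degrees C.
#' @param lags integer lags (default 0..lag_max).
#' @return data.frame of class \code{"lag_curve"}: \code{lag, log_rr, se,
#'   rr, rr_low, rr_high}.
#' @export
predict_lag <- function(fit, temp, lags = NULL, spec = fit$cb_spec,
                        level = 0.95) {
  bk <- cb_block(fit, spec)
  if (is.null(lags)) lags <- 0:spec$lag_max
  W <- lag_contrast(spec, temp, lags)
  out <- curve_from_weights(W, bk$beta, bk$V, lags, level,
                            cls = "lag_curve", xname = "lag")
  attr(out, "temp") <- temp
  out
}

#' Exposure-lag relative-risk surface
#'
#' RR at every (temperature, lag) combination; the row at the reference
#' temperature is identically 1, and summing log-RR over the full lag axis
#' reproduces the cumulative curve.
#'
#' @inheritParams predict_cumulative
#' @param lag_grid integer lags (default 0..lag_max).
#' @return list of class \code{"rr_surface"} with \code{temp}, \code{lag},
#'   and matrices \code{rr} and \code{log_rr} (temperatures in rows).
#' @export
predict_surface <- function(fit, temp_grid = NULL, lag_grid = NULL,
                            spec = fit$cb_spec) {
  bk <- cb_block(fit, spec)
  if (is.null(temp_grid))
    temp_grid <- seq(ceiling(spec$exposure_boundary[1]),
                     floor(spec$exposure_boundary[2]), by = 1)
  if (is.null(lag_grid)) lag_grid <- 0:spec$lag_max
  log_rr <- matrix(0, length(temp_grid), length(lag_grid))
  for (i in seq_along(temp_grid)) {
    W <- lag_contrast(spec, temp_grid[i], lag_grid)
    log_rr[i, ] <- as.numeric(W %*% bk$beta)
  }
  dimnames(log_rr) <- list(signif(temp_grid, 6), lag_grid)
  structure(list(temp = temp_grid, lag = lag_grid,
                 log_rr = log_rr, rr = exp(log_rr)),
            class = "rr_surface")
}

# Extract the cross-basis coefficient block and its covariance from a fit,
# checking the spec's dimension against the fitted block.
cb_block <- function(fit, spec) {
  stopifnot(inherits(fit, "dlnm_fit"), inherits(spec, "crossbasis_spec"))
  idx <- fit$registry$crossbasis
  if (is.null(idx)) stop("fit has no cross-basis block in its registry")
  want <- prod(cb_dim(spec))
  if (length(idx) != want)
    stop(sprintf("cross-basis block size mismatch: spec implies %d columns, fit has %d",
                 want, length(idx)))
  list(beta = fit$coefficients[idx],
       V = fit$covariance[idx, idx, drop = FALSE])
}

curve_from_weights <- function(W, beta, V, xvals, level, cls, xname) {
  log_rr <- as.numeric(W %*% beta)
  se <- sqrt(pmax(0, rowSums((W %*% V) * W)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(x = xvals, log_rr = log_rr, se = se,
                    rr = exp(log_rr),
                    rr_low = exp(log_rr - z * se),
                    rr_high = exp(log_rr + z * se))
  names(out)[1] <- xname
  class(out) <- c(cls, "data.frame")
  out
}

#' Relative risks at the curve's summary temperatures
#'
#' Convenience report mirroring the usual presentation of cumulative
#' temperature-mortality associations: RR (95\% CI) at the mean and at the
#' 1st and 99th percentiles of the temperature distribution used for the
#' fit.
#'
#' @param fit a \code{dlnm_fit} with stored data.
#' @param probs percentiles to report alongside the mean.
#' @return data.frame \code{label, temp, rr, rr_low, rr_high}.
#' @export
rr_at_percentiles <- function(fit, probs = c(0.01, 0.99)) {
  if (is.null(fit$data)) stop("fit was created with keep_data = FALSE")
  x <- fit$data[[fit$model_spec$temperature_variable]][fit$rows]
  temps <- c(mean(x), stats::quantile(x, probs, names = FALSE))
  labels <- c("mean", paste0("p", round(100 * probs)))
  cc <- predict_cumulative(fit, temp_grid = temps)
  data.frame(label = labels, temp = temps, rr = cc$rr,
             rr_low = cc$rr_low, rr_high = cc$rr_high)
}
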