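#' Fit an empirical quantile-quantile calibration map
#'
#' Matches the empirical quantiles of a simulated (climate-model)
#' temperature series to those of an observed series at probabilities
#' \code{(1..n_quantiles) / (n_quantiles + 1)}, projecting the observed
#' distribution onto the simulated one. Corrected values are obtained by
#' monotone interpolation between matched quantiles, so the whole
#' distribution - including the tails, subject to the tail rule - is
#' corrected rather than just the mean.
#'
#' @param observed numeric observed temperatures, degrees C.
#' @param simulated numeric simulated temperatures, degrees C.
#' @param n_quantiles number of matched quantiles (default 99: percentile
#'   mapping).
#' @param tail_rule "constant-offset" (default): values beyond the
#'   outermost matched quantiles are shifted by the offset at that
#'   quantile; "linear-extrapolation": the outermost interpolation segment
#'   is extended.
#' @return object of class \code{"quantile_map"} with \code{probs},
#'   \code{obs_quantiles}, \code{sim_quantiles}, \code{tail_rule}.
#' @export
fit_quantile_map <- function(observed, simulated, n_quantiles = 99L,
                             tail_rule = c("constant-offset", "linear-extrapolation")) {
  tail_rule <- match.arg(tail_rule)
  observed <- observed[!is.na(observed)]
  simulated <- simulated[!is.na(simulated)]
  if (length(observed) == 0L || length(simulated) == 0L)
    stop("both series must be non-empty")
  n_quantiles <- as.integer(n_quantiles)
  if (n_quantiles < 2L) stop("'n_quantiles' must be >= 2")
  if (max(simulated) == min(simulated))
    stop("all simulated values are identical; the quantile map is not invertible")
  probs <- seq_len(n_quantiles) / (n_quantiles + 1)
  structure(list(
    probs = probs,
    obs_quantiles = stats::quantile(observed, probs, names = FALSE, type = 7),
    sim_quantiles = stats::quantile(simulated, probs, names = FALSE, type = 7),
    tail_rule = tail_rule
  ), class = "quantile_map")
}

#' @export
print.quantile_map <- function(x, ...) {
  cat(sprintf("Quantile-quantile calibration map: %d quantiles, tail rule '%s'\n",
              length(x$probs), x$tail_rule))
  cat(sprintf("  simulated range at mapped quantiles: [%.2f, %.2f] C\n",
              min(x$sim_quantiles), max(x$sim_quantiles)))
  cat(sprintf("  median offset (obs - sim): %.2f C\n",
              stats::median(x$obs_quantiles - x$sim_quantiles)))
  invisible(x)
}

#' Apply a quantile-quantile calibration map
#'
#' Values inside the mapped simulated range are corrected by monotone
#' interpolation between matched quantiles (tied simulated quantiles are
#' collapsed to the mean observed quantile); values outside are handled by
#' the map's tail rule. Output order matches input order; NAs pass
#' through.
#'
#' @param map a \code{quantile_map}.
#' @param values numeric simulated temperatures to correct.
#' @return corrected values, same length and order as \code{values}.
#' @export
apply_quantile_map <- function(map, values) {
  stopifnot(inherits(map, "quantile_map"))
  if (length(values) == 0L) return(numeric(0))
  sq <- map$sim_quantiles
  oq <- map$obs_quantiles
  # collapse ties in the simulated quantiles (flat CDF regions)
  if (anyDuplicated(sq)) {
    oq <- as.numeric(tapply(oq, sq, mean))
    sq <- sort(unique(sq))
  }
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  v <- values[ok]
  if (length(sq) == 1L) {
    res <- v + (oq[1] - sq[1])
  } else {
    res <- stats::approx(sq, oq, xout = v, rule = 2)$y
    lo <- v < sq[1]
    hi <- v > sq[length(sq)]
    if (map$tail_rule == "constant-offset") {
      res[lo] <- v[lo] + (oq[1] - sq[1])
      res[hi] <- v[hi] + (oq[length(oq)] - sq[length(sq)])
    } else {
      slope_lo <- (oq[2] - oq[1]) / (sq[2] - sq[1])
      slope_hi <- (oq[length(oq)] - oq[length(oq) - 1]) /
        (sq[length(sq)] - sq[length(sq) - 1])
      res[lo] <- oq[1] + slope_lo * (v[lo] - sq[1])
      res[hi] <- oq[length(oq)] + slope_hi * (v[hi] - sq[length(sq)])
    }
  }
  out[ok] <- res
  out
}

#' Seasonal quantile-quantile correction of a temperature series
#'
#' Fits a separate calibration map for each season (winter = Dec-Mar,
#' summer = Jun-Sep, other) - or a single all-year map - and corrects the
#' simulated series' temperature columns in place. Seasonal fitting is the
#' default because temperature-mortality analyses are seasonal and model
#' bias typically differs between cold and warm months.
#'
#' @param observed region series with observed temperatures.
#' @param simulated region series with simulated temperatures, same
#'   columns.
#' @param columns temperature columns to correct.
#' @param by_season fit per-season maps (default TRUE).
#' @param n_quantiles,tail_rule passed to \code{\link{fit_quantile_map}}.
#' @return list with \code{corrected} (the simulated series with corrected
#'   columns) and \code{maps} (nested list: column, then season).
#' @export
bias_correct_series <- function(observed, simulated,
                                columns = c("tmean", "tmin", "tmax"),
                                by_season = TRUE, n_quantiles = 99L,
                                tail_rule = "constant-offset") {
  columns <- intersect(columns, intersect(names(observed), names(simulated)))
  obs_season <- season_of_month(as.integer(format(observed$date, "%m")))
  sim_season <- season_of_month(as.integer(format(simulated$date, "%m")))
  corrected <- simulated
  maps <- list()
  groups <- if (by_season) unique(sim_season) else "all"
  for (col in columns) {
    maps[[col]] <- list()
    for (g in groups) {
      oi <- if (by_season) obs_season == g else TRUE
      si <- if (by_season) sim_season == g else TRUE
      m <- fit_quantile_map(observed[[col]][oi], simulated[[col]][si],
                            n_quantiles = n_quantiles, tail_rule = tail_rule)
      corrected[[col]][si] <- apply_quantile_map(m, simulated[[col]][si])
      maps[[col]][[g]] <- m
    }
  }
  list(corrected = corrected, maps = maps)
}
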