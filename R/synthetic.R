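#' Define a ground-truth scenario for synthetic daily series
#'
#' A scenario fixes everything needed to simulate region-like daily data:
#' the temperature process (annual sinusoid plus AR(1) noise), the true
#' exposure-lag-response surface on the log relative-risk scale, and the
#' mortality model (baseline rate, weekday and holiday offsets, a smooth
#' seasonal log-rate cycle, and an overdispersion factor).
#'
#' The true surface is separable: \code{surface(x, l) = f(x) * w(l)} with
#' exponentially decaying lag weights \code{w(l)} normalized to sum to 1
#' over lags \code{0..30}, so the overall cumulative log-RR at a sustained
#' temperature x is exactly \code{f(x)}. The exposure function \code{f} is a
#' piecewise-quadratic bowl: zero (with zero slope) at the reference
#' temperature, rising to \code{cold_effect} at the cold anchor and to
#' \code{heat_effect} at the heat anchor. Anchors default to the analytic
#' 1st and 99th percentiles of the scenario's marginal temperature
#' distribution and the reference to its median, all computed by quadrature
#' over the annual cycle (no simulation involved).
#'
#' @param n_days number of days to simulate (> 31, so the 30-day lag window
#'   fits).
#' @param start_date first calendar day (ISO string or Date).
#' @param temp_mean_annual annual mean temperature, degrees C.
#' @param temp_amplitude semi-amplitude of the annual temperature cycle,
#'   degrees C (peak in mid-July, trough in mid-January).
#' @param ar_coefficient AR(1) coefficient of daily temperature noise,
#'   in (-1, 1).
#' @param noise_sd innovation standard deviation of the AR(1) noise,
#'   degrees C.
#' @param diurnal_half_range half the typical daily temperature range,
#'   degrees C; tmin/tmax are tmean -/+ this (with mild day-to-day
#'   variation).
#' @param cold_effect true cumulative log-RR at the cold anchor temperature.
#' @param heat_effect true cumulative log-RR at the heat anchor temperature.
#' @param lag_decay e-folding constant (days) of the exponential lag
#'   weights.
#' @param baseline_log_rate log expected deaths/day at reference conditions.
#' @param dow_effects 7 log-rate offsets, Monday..Sunday (index matches
#'   \code{dow} 0..6).
#' @param holiday_effect log-rate offset on public holidays.
#' @param season_amplitude semi-amplitude of the smooth seasonal log-rate
#'   cycle (peak in mid-January), representing non-temperature seasonality.
#' @param overdispersion variance/mean ratio phi of the daily counts
#'   (>= 1; 1 = Poisson).
#' @param population constant annual population (covariate POP).
#' @param seed integer seed controlling all scenario randomness.
#' @return an object of class \code{"truth_scenario"} with derived fields
#'   \code{ref_temp}, \code{cold_temp}, \code{heat_temp} (degrees C).
#' @export
truth_scenario <- function(n_days = 3652L,
                           start_date = "1986-01-01",
                           temp_mean_annual = 15,
                           temp_amplitude = 6,
                           ar_coefficient = 0.7,
                           noise_sd = 2,
                           diurnal_half_range = 4,
                           cold_effect = 0.5,
                           heat_effect = 0.15,
                           lag_decay = 5,
                           baseline_log_rate = log(15),
                           dow_effects = c(0, -0.01, -0.01, 0, 0.01, 0.04, 0.06),
                           holiday_effect = 0.05,
                           season_amplitude = 0.1,
                           overdispersion = 1.5,
                           population = 1.7e6,
                           seed = 1L) {
  n_days <- as.integer(n_days)
  if (n_days <= 31L) stop("'n_days' must exceed 31 (the maximum lag window)")
  if (abs(ar_coefficient) >= 1)
    stop("'ar_coefficient' must lie strictly inside (-1, 1): the AR(1) ",
         "temperature noise must be stationary")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (temp_amplitude < 0) stop("'temp_amplitude' must be >= 0")
  if (overdispersion < 1) stop("'overdispersion' must be >= 1")
  if (length(dow_effects) != 7L) stop("'dow_effects' must have length 7")
  if (lag_decay <= 0) stop("'lag_decay' must be > 0")
  sc <- list(
    n_days = n_days, start_date = as.Date(start_date),
    temp_mean_annual = temp_mean_annual, temp_amplitude = temp_amplitude,
    ar_coefficient = ar_coefficient, noise_sd = noise_sd,
    diurnal_half_range = diurnal_half_range,
    cold_effect = cold_effect, heat_effect = heat_effect,
    lag_decay = lag_decay, lag_max = 30L,
    baseline_log_rate = baseline_log_rate, dow_effects = dow_effects,
    holiday_effect = holiday_effect, season_amplitude = season_amplitude,
    overdispersion = overdispersion, population = population,
    seed = as.integer(seed)
  )
  sc$ref_temp <- marginal_temp_quantile(sc, 0.5)
  sc$cold_temp <- marginal_temp_quantile(sc, 0.01)
  sc$heat_temp <- marginal_temp_quantile(sc, 0.99)
  structure(sc, class = "truth_scenario")
}

#' @export
print.truth_scenario <- function(x, ...) {
  cat(sprintf("Truth scenario: %d days from %s (seed %d)\n",
              x$n_days, format(x$start_date), x$seed))
  cat(sprintf("  temperature: mean %.1f C, amplitude %.1f C, AR(1) rho %.2f, innovation sd %.2f C\n",
              x$temp_mean_annual, x$temp_amplitude, x$ar_coefficient, x$noise_sd))
  cat(sprintf("  truth surface: cold log-RR %.2f at %.1f C, heat log-RR %.2f at %.1f C, ref %.1f C, lag decay %.1f d\n",
              x$cold_effect, x$cold_temp, x$heat_effect, x$heat_temp,
              x$ref_temp, x$lag_decay))
  cat(sprintf("  mortality: baseline %.1f deaths/day, overdispersion %.2f\n",
              exp(x$baseline_log_rate), x$overdispersion))
  invisible(x)
}

# annual-cycle phase: day-of-year 196 (~July 15) is the warm peak
temp_cycle <- function(doy, amplitude) {
  amplitude * cos(2 * pi * (doy - 196) / 365.25)
}

# Marginal CDF of daily mean temperature under the scenario: mixture over
# the annual cycle of normals with the stationary AR(1) sd. Quantile found
# by root-finding; deterministic (quadrature, not simulation).
marginal_temp_quantile <- function(sc, p) {
  s <- if (abs(sc$ar_coefficient) < 1 && sc$noise_sd > 0)
    sc$noise_sd / sqrt(1 - sc$ar_coefficient^2) else 0
  cyc <- temp_cycle(seq_len(365L), sc$temp_amplitude)
  mu <- sc$temp_mean_annual + cyc
  if (s == 0 && sc$temp_amplitude == 0) return(sc$temp_mean_annual)
  cdf <- function(x) {
    if (s == 0) mean(mu <= x) else mean(stats::pnorm(x, mean = mu, sd = s))
  }
  lo <- min(mu) - max(6 * s, 1e-6)
  hi <- max(mu) + max(6 * s, 1e-6)
  stats::uniroot(function(x) cdf(x) - p, c(lo, hi), tol = 1e-8)$root
}

# Fixed-date national holidays used by the generator (month, day).
HOLIDAYS_MD <- matrix(c(1, 1, 4, 25, 5, 1, 6, 10, 8, 15,
                        10, 5, 11, 1, 12, 1, 12, 8, 12, 25),
                      ncol = 2, byrow = TRUE)

season_of_month <- function(m) {
  ifelse(m %in% c(12, 1, 2, 3), "winter",
         ifelse(m %in% c(6, 7, 8, 9), "summer", "other"))
}

#' Generate a synthetic daily temperature series
#'
#' Daily mean temperature is an annual sinusoid plus stationary AR(1)
#' noise; tmin and tmax subtract/add a positive diurnal half-range.
#' Calendar covariates (weekday, fixed-date holidays, constant population,
#' season label) are attached so the result is a region series without the
#' death counts.
#'
#' @param scenario a \code{truth_scenario}.
#' @return data.frame with columns \code{date, tmean, tmin, tmax, dow,
#'   holiday, pop, season}; reproducible under the scenario seed.
#' @export
generate_temperature <- function(scenario) {
  stopifnot(inherits(scenario, "truth_scenario"))
  sc <- scenario
  n <- sc$n_days
  set.seed(sc$seed)
  dates <- sc$start_date + seq_len(n) - 1L
  doy <- as.integer(format(dates, "%j"))
  e <- numeric(n)
  if (sc$noise_sd > 0) {
    s_stat <- sc$noise_sd / sqrt(1 - sc$ar_coefficient^2)
    e[1] <- stats::rnorm(1, 0, s_stat)
    innov <- stats::rnorm(n - 1L, 0, sc$noise_sd)
    for (t in 2:n) e[t] <- sc$ar_coefficient * e[t - 1L] + innov[t - 1L]
  }
  tmean <- sc$temp_mean_annual + temp_cycle(doy, sc$temp_amplitude) + e
  # mild positive day-to-day variation in the diurnal range
  half <- sc$diurnal_half_range *
    (if (sc$diurnal_half_range > 0) pmax(0.2, 1 + stats::rnorm(n, 0, 0.15)) else rep(0, n))
  mon <- as.integer(format(dates, "%m"))
  mday <- as.integer(format(dates, "%d"))
  hol <- as.integer(paste(mon, mday) %in% paste(HOLIDAYS_MD[, 1], HOLIDAYS_MD[, 2]))
  data.frame(
    date = dates,
    tmean = tmean,
    tmin = tmean - half,
    tmax = tmean + half,
    dow = (as.integer(format(dates, "%u")) - 1L),  # 0 = Monday .. 6 = Sunday
    holiday = hol,
    pop = sc$population,
    season = season_of_month(mon),
    stringsAsFactors = FALSE
  )
}

#' Distort a temperature series to mimic climate-model bias
#'
#' Produces a "simulated climate" twin of an observed series whose
#' distribution differs by location (\code{shift}), scale (\code{scale}),
#' an upper-tail distortion (\code{tail_skew} inflates values above the
#' series' 90th percentile), and optional independent noise. Applied to
#' tmean, tmin and tmax alike; rank order is preserved up to the added
#' noise.
#'
#' @param series a region series data.frame (needs tmean; tmin/tmax
#'   distorted too when present).
#' @param shift additive bias, degrees C.
#' @param scale multiplicative bias (> 0), applied to the raw values.
#' @param tail_skew per-degree extra warming applied above the 90th
#'   percentile (0 = none).
#' @param noise_sd sd of independent Gaussian noise added after
#'   distortion (default 0).
#' @param seed RNG seed for the noise.
#' @return the series with distorted temperature columns.
#' @export
distort_temperature <- function(series, shift = 0, scale = 1, tail_skew = 0,
                                noise_sd = 0, seed = 1L) {
  if (scale <= 0) stop("'scale' must be > 0")
  set.seed(as.integer(seed))
  out <- series
  for (col in intersect(c("tmean", "tmin", "tmax"), names(series))) {
    x <- series[[col]]
    q90 <- stats::quantile(x, 0.9, names = FALSE)
    y <- shift + scale * x + tail_skew * pmax(0, x - q90)
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    out[[col]] <- y
  }
  out
}

# Exponential lag weights, normalized to sum to 1 over 0..lag_max.
true_lag_weights <- function(scenario) {
  w <- exp(-(0:scenario$lag_max) / scenario$lag_decay)
  w / sum(w)
}

# True exposure function f(x): cumulative log-RR at sustained temperature x.
# Piecewise quadratic, zero with zero slope at ref_temp.
true_exposure_function <- function(scenario, x) {
  sc <- scenario
  f <- numeric(length(x))
  cold <- x < sc$ref_temp
  f[cold] <- sc$cold_effect *
    ((sc$ref_temp - x[cold]) / (sc$ref_temp - sc$cold_temp))^2
  f[!cold] <- sc$heat_effect *
    ((x[!cold] - sc$ref_temp) / (sc$heat_temp - sc$ref_temp))^2
  f
}

#' Evaluate the true exposure-lag-response surface
#'
#' @param scenario a \code{truth_scenario}.
#' @param temp temperature vector, degrees C.
#' @param lag lag vector, days (0..30).
#' @return matrix of log-RR contributions, \code{length(temp)} x
#'   \code{length(lag)}.
#' @export
true_surface <- function(scenario, temp, lag) {
  w <- true_lag_weights(scenario)
  if (any(lag < 0 | lag > scenario$lag_max)) stop("lags must lie in 0..lag_max")
  outer(true_exposure_function(scenario, temp), w[lag + 1L])
}

#' Analytic overall cumulative log-RR curve of a scenario
#'
#' Sums the true surface over lags 0..30; because the lag weights sum to 1
#' this is exactly the exposure function, zero at the scenario's reference
#' temperature.
#'
#' @param scenario a \code{truth_scenario}.
#' @param temp_grid temperatures at which to evaluate (degrees C).
#' @return data.frame \code{temp, log_rr, rr}.
#' @export
true_cumulative_curve <- function(scenario, temp_grid) {
  log_rr <- true_exposure_function(scenario, temp_grid)
  data.frame(temp = temp_grid, log_rr = log_rr, rr = exp(log_rr))
}

#' Simulate daily death counts from a scenario
#'
#' The log-mean is baseline + weekday offset + holiday offset + a smooth
#' seasonal cycle + the true cumulative lagged temperature contribution
#' \code{sum_l surface(x[t-l], l)}. Counts are drawn from a
#' negative-binomial (Poisson-gamma) law whose size parameter is chosen per
#' day so that the variance/mean ratio equals the scenario overdispersion
#' exactly; with overdispersion 1 the draws are Poisson. The first 30 days
#' have incomplete lag histories: their deaths are NA and the returned
#' frame carries attribute \code{valid_from = 31}.
#'
#' @param temps a temperature series from \code{\link{generate_temperature}}
#'   (or any region series with \code{date, tmean, dow, holiday} columns).
#' @param scenario the \code{truth_scenario} supplying the mortality model.
#' @return the input frame with a \code{deaths} column prepended after
#'   \code{date}.
#' @export
generate_mortality <- function(temps, scenario) {
  stopifnot(inherits(scenario, "truth_scenario"))
  sc <- scenario
  n <- nrow(temps)
  L <- sc$lag_max
  if (n <= L + 1L)
    stop(sprintf("temperature series (%d days) must exceed the %d-day lag window", n, L))
  if (sc$overdispersion < 1) stop("'overdispersion' must be >= 1")
  set.seed(sc$seed + 1L)
  mu <- exp(true_log_mean(temps, sc))
  deaths <- rep(NA_integer_, n)
  ok <- !is.na(mu)
  deaths[ok] <- draw_overdispersed(mu[ok], sc$overdispersion)
  out <- cbind(temps[, "date", drop = FALSE],
               deaths = deaths,
               temps[, setdiff(names(temps), "date"), drop = FALSE])
  attr(out, "valid_from") <- L + 1L
  out
}

# Deterministic log expected deaths under the scenario: baseline + weekday
# + holiday + seasonal cycle + true cumulative lagged temperature
# contribution. NA for the first lag_max days (incomplete lag history).
true_log_mean <- function(temps, sc) {
  n <- nrow(temps)
  L <- sc$lag_max
  doy <- as.integer(format(temps$date, "%j"))
  w <- true_lag_weights(sc)
  fx <- true_exposure_function(sc, temps$tmean)
  contrib <- rep(NA_real_, n)
  contrib[(L + 1L):n] <- as.numeric(stats::embed(fx, L + 1L) %*% w)
  sc$baseline_log_rate +
    sc$dow_effects[temps$dow + 1L] +
    sc$holiday_effect * temps$holiday +
    sc$season_amplitude * cos(2 * pi * (doy - 15) / 365.25) +
    contrib
}

# NB draws with variance = phi * mu exactly (size = mu / (phi - 1));
# phi = 1 reduces to Poisson.
draw_overdispersed <- function(mu, phi) {
  if (phi == 1) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = mu / (phi - 1))
}
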