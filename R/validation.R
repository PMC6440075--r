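#' Relative RMSE and MAD between two effect vectors
#'
#' Core arithmetic of train/test effect validation: with \code{beta_hat}
#' the training-period effects and \code{beta} the test-period effects over
#' a common grid, \code{rmse_rel = sqrt(mean((beta_hat - beta)^2)) /
#' mean(beta)} and \code{mad_rel = |mean(beta_hat - beta)| / mean(beta)}.
#' A zero mean test effect makes both undefined; they are returned as NA
#' with an \code{undefined} flag rather than infinities.
#'
#' @param beta_hat,beta numeric vectors of equal length.
#' @return list \code{rmse_rel, mad_rel, undefined}.
#' @export
effect_metrics <- function(beta_hat, beta) {
  stopifnot(length(beta_hat) == length(beta), length(beta) > 0)
  denom <- mean(beta)
  if (denom == 0)
    return(list(rmse_rel = NA_real_, mad_rel = NA_real_, undefined = TRUE))
  list(
    rmse_rel = sqrt(mean((beta_hat - beta)^2)) / denom,
    mad_rel = abs(mean(beta_hat - beta)) / denom,
    undefined = FALSE
  )
}

#' Train/test validation of exposure-lag-response effects
#'
#' Compares the lag-specific log-RR effects estimated on a training period
#' with those estimated independently on a test period, over a fixed
#' evaluation grid: lags 0..lag_max crossed with the 1st, 50th and 99th
#' percentile temperatures of the training data (configurable). Reports
#' the relative RMSE and relative MAD of \code{\link{effect_metrics}}.
#'
#' @param fit_train,fit_test \code{dlnm_fit}s sharing the same cross-basis
#'   specification (the test fit may have been realized on its own data;
#'   effects are evaluated with each fit's own spec at common temperatures).
#' @param temps evaluation temperatures; default the training 1st, 50th,
#'   99th percentiles.
#' @param lags evaluation lags; default 0..lag_max.
#' @return list of class \code{"effect_validation"}: \code{rmse_rel,
#'   mad_rel, undefined, grid} (data.frame temp x lag with both effect
#'   vectors).
#' @export
effect_validation <- function(fit_train, fit_test, temps = NULL, lags = NULL) {
  spec_tr <- fit_train$cb_spec
  spec_te <- fit_test$cb_spec
  if (!identical(cb_dim(spec_tr), cb_dim(spec_te)))
    stop("training and test fits must share the cross-basis family")
  if (is.null(temps)) {
    if (is.null(fit_train$data)) stop("supply 'temps' or keep data on the training fit")
    x <- fit_train$data[[fit_train$model_spec$temperature_variable]][fit_train$rows]
    temps <- stats::quantile(x, c(0.01, 0.5, 0.99), names = FALSE)
  }
  if (is.null(lags)) lags <- 0:spec_tr$lag_max
  grid <- expand.grid(lag = lags, temp = temps)[, c("temp", "lag")]
  eff <- function(fit, spec) {
    unlist(lapply(temps, function(tp)
      predict_lag(fit, tp, lags = lags, spec = spec)$log_rr))
  }
  beta_hat <- eff(fit_train, spec_tr)
  beta <- eff(fit_test, spec_te)
  m <- effect_metrics(beta_hat, beta)
  grid$beta_hat <- beta_hat
  grid$beta <- beta
  structure(c(m, list(grid = grid)), class = "effect_validation")
}

#' Bootstrap validation of death predictions
#'
#' Resamples the validation rows with replacement (day-level i.i.d.
#' resampling) \code{n_boot} times; for each resample the expected deaths
#' predicted by the training fit are compared with the resampled observed
#' deaths via \code{RMSE = sqrt(mean((obs - pred)^2))}. The training
#' coefficients are reused throughout - no refitting. Also reported: the
#' RMSE on the original (unresampled) validation rows, the average error
#' (mean replicate RMSE minus original RMSE), and each replicate's mean
#' prediction bias in deaths/day.
#'
#' @param fit_train a \code{dlnm_fit}.
#' @param validation_data region series for the validation period (long
#'   enough that rows survive lag trimming).
#' @param n_boot number of resamples (default 50).
#' @param seed RNG seed for the resampling.
#' @return list of class \code{"bootstrap_validation"}: \code{n_boot,
#'   rmse_per_replicate, rmse_original, average_error, biases, n_days,
#'   seed}.
#' @export
bootstrap_validation <- function(fit_train, validation_data, n_boot = 50L,
                                 seed = 1L) {
  pred <- predict_deaths(fit_train, validation_data)
  if (nrow(pred) == 0L) stop("no usable validation rows after lag trimming")
  prediction_rmse_bootstrap(pred$observed, pred$predicted,
                            n_boot = n_boot, seed = seed)
}

#' Bootstrap RMSE of fixed predictions against observations
#'
#' The resampling arithmetic underlying
#' \code{\link{bootstrap_validation}}, operating directly on paired
#' observed/predicted vectors: day-level resamples with replacement, RMSE
#' per resample, RMSE on the original pairing, their mean difference, and
#' per-replicate mean prediction biases.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param n_boot number of resamples.
#' @param seed RNG seed.
#' @return a \code{bootstrap_validation} object.
#' @export
prediction_rmse_bootstrap <- function(observed, predicted, n_boot = 50L,
                                      seed = 1L) {
  stopifnot(length(observed) == length(predicted), length(observed) > 0)
  obs <- observed
  yhat <- predicted
  set.seed(as.integer(seed))
  n <- length(obs)
  rmse <- function(o, p) sqrt(mean((o - p)^2))
  rmse_rep <- numeric(n_boot)
  biases <- numeric(n_boot)
  mean_obs_rep <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    rmse_rep[b] <- rmse(obs[idx], yhat[idx])
    biases[b] <- mean(yhat[idx]) - mean(obs[idx])
    mean_obs_rep[b] <- mean(obs[idx])
  }
  rmse_orig <- rmse(obs, yhat)
  structure(list(
    n_boot = as.integer(n_boot),
    rmse_per_replicate = rmse_rep,
    rmse_original = rmse_orig,
    average_error = mean(rmse_rep) - rmse_orig,
    biases = biases,
    mean_obs_per_replicate = mean_obs_rep,
    mean_observed = mean(obs),
    n_days = n,
    seed = as.integer(seed)
  ), class = "bootstrap_validation")
}

#' Relative-bias histogram of bootstrap replicates
#'
#' Per replicate, relative bias = (mean predicted - mean observed) / mean
#' observed, using the replicate's resampled days. Returns histogram bins
#' plus the mean and standard deviation across replicates.
#'
#' @param boot a \code{bootstrap_validation}.
#' @param breaks passed to \code{\link[graphics]{hist}}-style binning
#'   (number of bins or break points).
#' @return list \code{rel_bias} (per replicate), \code{mean}, \code{sd},
#'   \code{bins} (data.frame mid, count).
#' @export
bias_histogram <- function(boot, breaks = 10) {
  stopifnot(inherits(boot, "bootstrap_validation"))
  rb <- boot$biases / boot$mean_obs_per_replicate
  h <- graphics::hist(rb, breaks = breaks, plot = FALSE)
  list(rel_bias = rb, mean = mean(rb), sd = stats::sd(rb),
       bins = data.frame(mid = h$mids, count = h$counts))
}
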