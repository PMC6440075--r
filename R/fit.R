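#' Candidate model specification
#'
#' A model specification names the cross-basis family (by marginal function
#' and interior-knot count), the trend flexibility, covariates, season
#' restriction and which temperature variable enters the cross-basis. Knot
#' positions are realized from the data when the design is built: exposure
#' knots equally spaced over the observed temperature range, lag knots
#' equally spaced on the 0..lag_max scale (15 for one knot, 10/20 for two).
#'
#' @param exposure_fun "linear" or "bspline" (quadratic, no intercept).
#' @param exposure_nknots interior knot count for a B-spline exposure
#'   function (0, 1 or 2).
#' @param lag_fun "constant" or "bspline" (quadratic with intercept).
#' @param lag_nknots interior knot count for a B-spline lag function.
#' @param date_df_per_year degrees of freedom per year for the natural
#'   cubic spline of calendar time (7, 8 or 9).
#' @param covariates subset of \code{c("dow", "holiday", "pop")}.
#' @param season "all", "winter" (Dec-Mar) or "summer" (Jun-Sep); outcome
#'   rows are restricted to the season's months after lagged exposures are
#'   computed from the full series.
#' @param temperature_variable "tmean", "tmin" or "tmax".
#' @param lag_max maximum lag, days.
#' @param ref_temp reference temperature; \code{NULL} = median of the
#'   temperature variable over the data used to build the design.
#' @return object of class \code{"model_spec"}.
#' @export
model_spec <- function(exposure_fun = c("bspline", "linear"),
                       exposure_nknots = 1L,
                       lag_fun = c("bspline", "constant"),
                       lag_nknots = 1L,
                       date_df_per_year = 8L,
                       covariates = c("dow", "holiday"),
                       season = c("all", "winter", "summer"),
                       temperature_variable = c("tmean", "tmin", "tmax"),
                       lag_max = 30L,
                       ref_temp = NULL) {
  exposure_fun <- match.arg(exposure_fun)
  lag_fun <- match.arg(lag_fun)
  season <- match.arg(season)
  temperature_variable <- match.arg(temperature_variable)
  if (!date_df_per_year %in% 7:9)
    stop("'date_df_per_year' must be 7, 8 or 9")
  stopifnot(all(covariates %in% c("dow", "holiday", "pop")))
  structure(list(
    exposure_fun = exposure_fun,
    exposure_nknots = if (exposure_fun == "linear") 0L else as.integer(exposure_nknots),
    lag_fun = lag_fun,
    lag_nknots = if (lag_fun == "constant") 0L else as.integer(lag_nknots),
    date_df_per_year = as.integer(date_df_per_year),
    covariates = covariates,
    season = season,
    temperature_variable = temperature_variable,
    lag_max = as.integer(lag_max),
    ref_temp = ref_temp
  ), class = "model_spec")
}

# Equally spaced interior knots: k knots split [a, b] into k + 1 intervals.
equispaced_knots <- function(k, a, b) {
  if (k == 0L) numeric(0) else a + (b - a) * seq_len(k) / (k + 1)
}

# Realize the crossbasis_spec of a model_spec from the data.
realize_cb_spec <- function(data, spec) {
  x <- data[[spec$temperature_variable]]
  bnd <- range(x)
  ref <- if (is.null(spec$ref_temp)) stats::median(x) else spec$ref_temp
  crossbasis_spec(
    exposure_fun = spec$exposure_fun,
    exposure_knots = equispaced_knots(spec$exposure_nknots, bnd[1], bnd[2]),
    exposure_boundary = bnd,
    lag_fun = spec$lag_fun,
    lag_knots = equispaced_knots(spec$lag_nknots, 0, spec$lag_max),
    lag_max = spec$lag_max,
    ref_temp = ref
  )
}

# Natural-spline calendar-time basis. Day indices inside the training
# boundary evaluate as usual. Out-of-range dates (prediction on a
# validation period) are folded back by whole years and averaged over
# every training year at the same day-of-year: the spline's mean seasonal
# profile is retained while the secular level is held at the training
# mean. Linear extrapolation of a high-df natural spline over multi-year
# horizons is numerically wild and is never used.
trend_basis <- function(day_index, knots, boundary) {
  b1 <- boundary[1]; b2 <- boundary[2]
  inside <- day_index >= b1 & day_index <= b2
  M <- matrix(NA_real_, length(day_index),
              length(knots) + 1L)
  if (any(inside))
    M[inside, ] <- splines::ns(day_index[inside], knots = knots,
                               Boundary.knots = boundary)
  if (any(!inside)) {
    n_span <- ceiling((b2 - b1) / 365.25) + 2L
    for (i in which(!inside)) {
      d <- day_index[i]
      dir <- if (d > b2) -1 else 1
      n_gap <- ceiling((if (d > b2) d - b2 else b1 - d) / 365.25)
      folds <- d + dir * 365.25 * seq_len(n_gap + n_span)
      folds <- folds[folds >= b1 & folds <= b2]
      if (length(folds) == 0) folds <- if (d > b2) b2 else b1
      M[i, ] <- colMeans(splines::ns(folds, knots = knots,
                                     Boundary.knots = boundary))
    }
  }
  M
}

season_months <- function(season) {
  switch(season,
         winter = c(12L, 1L, 2L, 3L),
         summer = c(6L, 7L, 8L, 9L),
         all = 1:12)
}

#' Build the regression design for a DLNM fit
#'
#' Assembles intercept, weekday contrasts, holiday indicator, population
#' (only when it varies), a natural cubic spline of the day index with
#' \code{date_df_per_year * n_years} degrees of freedom, and the
#' cross-basis block. Rows with incomplete lag histories (the first
#' \code{lag_max} days), rows outside the requested season, and rows with
#' missing deaths are excluded from the fit.
#'
#' @param data region series data.frame (see \code{\link{read_region_csv}}).
#' @param spec a \code{model_spec}.
#' @param cb_spec optionally a pre-realized \code{crossbasis_spec} (used to
#'   evaluate a training design on new data); default realizes one from
#'   \code{data}.
#' @param design_info optionally the \code{design_info} of a previous
#'   (training) design; when given, trend-spline knots, the day-index
#'   origin, the population centring and the cross-basis spec are reused so
#'   that the returned matrix is in the training model's coordinates.
#' @return list with \code{X} (design matrix), \code{y} (deaths for kept
#'   rows), \code{rows} (kept row indices of \code{data}), \code{registry}
#'   (named list of column-index blocks) and \code{design_info} (everything
#'   needed to rebuild the design on new data).
#' @export
build_design <- function(data, spec, cb_spec = NULL, design_info = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  validate_region_series(data)
  n <- nrow(data)
  if (is.null(design_info)) {
    if (is.null(cb_spec)) cb_spec <- realize_cb_spec(data, spec)
    origin <- data$date[1L]
    span_days <- as.numeric(data$date[n] - data$date[1L] + 1)
    if (span_days < 365) stop("at least one year of data is required")
    n_years <- span_days / 365.25
    trend_df <- max(2L, round(spec$date_df_per_year * n_years))
    day_index <- as.numeric(data$date - origin) + 1
    trend_proto <- splines::ns(day_index, df = trend_df)
    trend_knots <- attr(trend_proto, "knots")
    trend_boundary <- attr(trend_proto, "Boundary.knots")
    pop_center <- if ("pop" %in% spec$covariates && "pop" %in% names(data))
      mean(data$pop) else NA_real_
  } else {
    cb_spec <- design_info$cb_spec
    origin <- design_info$origin
    trend_knots <- design_info$trend_knots
    trend_boundary <- design_info$trend_boundary
    pop_center <- design_info$pop_center
    day_index <- as.numeric(data$date - origin) + 1
  }

  cb <- build_crossbasis(data[[spec$temperature_variable]], cb_spec)
  trend <- trend_basis(day_index, trend_knots, trend_boundary)

  blocks <- list(intercept = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  if ("dow" %in% spec$covariates) {
    if (length(unique(data$dow)) < 2L) {
      warning("covariate 'dow' is constant; dropped from the design")
    } else {
      f <- factor(data$dow, levels = 0:6)
      M <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(M) <- paste0("dow", 1:6)
      blocks$dow <- M
    }
  }
  if ("holiday" %in% spec$covariates) {
    if (length(unique(data$holiday)) < 2L) {
      warning("covariate 'holiday' is constant; dropped from the design")
    } else {
      blocks$holiday <- matrix(data$holiday, ncol = 1,
                               dimnames = list(NULL, "holiday"))
    }
  }
  if ("pop" %in% spec$covariates) {
    if (!"pop" %in% names(data) || stats::sd(data$pop) == 0 || is.na(pop_center)) {
      warning("covariate 'pop' is constant or absent; dropped from the design")
    } else {
      blocks$pop <- matrix(data$pop - pop_center, ncol = 1,
                           dimnames = list(NULL, "pop"))
    }
  }
  trend <- unclass(trend)
  colnames(trend) <- paste0("trend", seq_len(ncol(trend)))
  blocks$trend <- trend
  blocks$crossbasis <- unclass(cb)

  X <- do.call(cbind, blocks)
  registry <- list()
  at <- 0L
  for (nm in names(blocks)) {
    registry[[nm]] <- at + seq_len(ncol(blocks[[nm]]))
    at <- at + ncol(blocks[[nm]])
  }

  keep <- seq_len(n) >= attr(cb, "valid_from") &
    as.integer(format(data$date, "%m")) %in% season_months(spec$season)
  y <- data$deaths
  if (!is.null(y)) keep <- keep & !is.na(y)
  rows <- which(keep)
  list(
    X = X[rows, , drop = FALSE],
    y = if (is.null(y)) NULL else y[rows],
    rows = rows,
    registry = registry,
    design_info = list(cb_spec = cb_spec, origin = origin,
                       trend_knots = trend_knots,
                       trend_boundary = trend_boundary,
                       pop_center = pop_center, spec = spec)
  )
}

#' Fit a quasi-Poisson regression by IRLS
#'
#' Maximizes the Poisson quasi-likelihood with a log link via iteratively
#' reweighted least squares (the standard GLM algorithm, through
#' \code{stats::glm.fit}), then scales the coefficient covariance by the
#' Pearson dispersion: \code{V = phi * (X'WX)^{-1}} with
#' \code{phi = Pearson chi-square / residual df}. Convergence tolerance is
#' 1e-8 on the relative deviance change with at most 100 iterations.
#'
#' @param X design matrix (full column rank; collinear columns are
#'   reported by name).
#' @param y non-negative counts.
#' @param registry optional named list of column-index blocks, stored on
#'   the fit.
#' @return object of class \code{"dlnm_fit"}: \code{coefficients},
#'   \code{covariance}, \code{dispersion}, \code{quasi_loglik} (Poisson
#'   log-likelihood at the fit), \code{qaic} (using the fit's own
#'   dispersion), \code{n_used}, \code{fitted}, \code{converged},
#'   \code{registry}.
#' @export
fit_quasipoisson <- function(X, y, registry = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::glm.fit(X, y, family = stats::quasipoisson(),
                        control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged)
    stop(sprintf("IRLS did not converge within %d iterations (deviance %.6g)",
                 fit$iter, fit$deviance))
  p <- fit$rank
  n <- length(y)
  mu <- fit$fitted.values
  pearson <- sum((y - mu)^2 / mu)
  dispersion <- pearson / (n - p)
  Rmat <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  Rmat[lower.tri(Rmat)] <- 0
  V_unit <- chol2inv(Rmat)
  piv <- fit$qr$pivot[seq_len(p)]
  V <- matrix(NA_real_, p, p)
  V[piv, piv] <- V_unit
  covariance <- dispersion * V
  dimnames(covariance) <- list(colnames(X), colnames(X))
  ll <- sum(stats::dpois(y, mu, log = TRUE))
  out <- list(
    coefficients = stats::setNames(fit$coefficients, colnames(X)),
    covariance = covariance,
    dispersion = dispersion,
    quasi_loglik = ll,
    n_used = n,
    df_residual = n - p,
    fitted = mu,
    iterations = fit$iter,
    converged = TRUE,
    registry = registry
  )
  out$qaic <- qaic_value(ll, dispersion, p)
  class(out) <- "dlnm_fit"
  out
}

qaic_value <- function(loglik, dispersion_ref, n_params) {
  -2 * loglik / dispersion_ref + 2 * n_params
}

#' Quasi-AIC of a fitted model
#'
#' \code{QAIC = -2 logLik / phi_ref + 2 k}, where the Poisson
#' log-likelihood is evaluated at the quasi-Poisson fit, \code{phi_ref} is
#' a dispersion reference (by convention taken from the most complex
#' candidate when comparing models), and \code{k} the number of estimated
#' coefficients. Lower is better.
#'
#' @param fit a \code{dlnm_fit}.
#' @param dispersion_ref positive dispersion used to scale the likelihood;
#'   defaults to the fit's own Pearson dispersion.
#' @return the QAIC value.
#' @export
qaic <- function(fit, dispersion_ref = fit$dispersion) {
  if (dispersion_ref <= 0) stop("'dispersion_ref' must be > 0")
  qaic_value(fit$quasi_loglik, dispersion_ref, length(fit$coefficients))
}

#' @export
print.dlnm_fit <- function(x, ...) {
  cat(sprintf("Quasi-Poisson DLNM fit: %d coefficients, %d observations\n",
              length(x$coefficients), x$n_used))
  cat(sprintf("  dispersion %.3f, Poisson logLik %.1f, QAIC %.1f\n",
              x$dispersion, x$quasi_loglik, x$qaic))
  if (!is.null(x$model_spec))
    cat(sprintf("  cross-basis: %s x %s, %d columns; season %s, variable %s\n",
                x$model_spec$exposure_fun, x$model_spec$lag_fun,
                prod(cb_dim(x$cb_spec)), x$model_spec$season,
                x$model_spec$temperature_variable))
  invisible(x)
}

#' Fit a DLNM to a region series
#'
#' Convenience wrapper: builds the design per the model specification and
#' fits the quasi-Poisson regression. The returned fit keeps the realized
#' cross-basis spec, the design bookkeeping and (by default) the data, so
#' predictions on the training period and on new data are possible.
#'
#' @param data region series data.frame.
#' @param spec a \code{model_spec}.
#' @param keep_data store \code{data} on the fit (default TRUE).
#' @return a \code{dlnm_fit} with elements \code{model_spec},
#'   \code{cb_spec}, \code{design_info}, \code{rows} and optionally
#'   \code{data} in addition to the components of
#'   \code{\link{fit_quasipoisson}}.
#' @export
fit_dlnm <- function(data, spec, keep_data = TRUE) {
  des <- build_design(data, spec)
  fit <- fit_quasipoisson(des$X, des$y, registry = des$registry)
  fit$model_spec <- spec
  fit$cb_spec <- des$design_info$cb_spec
  fit$design_info <- des$design_info
  fit$rows <- des$rows
  if (keep_data) fit$data <- data
  fit
}

#' Predict expected deaths from a fitted DLNM
#'
#' Rebuilds the training design on \code{newdata} (trend spline knots,
#' day-index origin, cross-basis spec and population centring are reused
#' from the fit) and applies the training coefficients. Calendar dates
#' beyond the training span are folded back by whole years onto the final
#' training year, so the calendar-time spline's seasonal profile is
#' retained while its secular level is held at the end of training.
#'
#' @param fit a \code{dlnm_fit} from \code{\link{fit_dlnm}}.
#' @param newdata region series; default the training data.
#' @return data.frame \code{date, observed, predicted} for rows with
#'   complete lag histories (and inside the fit's season).
#' @export
predict_deaths <- function(fit, newdata = fit$data) {
  if (is.null(newdata)) stop("no data stored on the fit; supply 'newdata'")
  des <- build_design(newdata, fit$model_spec, design_info = fit$design_info)
  eta <- as.numeric(des$X %*% fit$coefficients)
  data.frame(date = newdata$date[des$rows],
             observed = if (is.null(des$y)) NA_real_ else des$y,
             predicted = exp(eta))
}

#' Enumerate the 48-model candidate grid
#'
#' Cartesian product of 4 exposure-response functions (linear; quadratic
#' B-spline with 0, 1 or 2 interior knots), 4 lag-response functions
#' (constant; quadratic B-spline with intercept and 0, 1 or 2 interior
#' knots) and trend flexibility 7-9 df/year: 48 candidate specifications
#' whose cross-basis dimension ranges from 1 x 1 = 1 to 4 x 5 = 20.
#'
#' @param season,temperature_variable,covariates,lag_max,ref_temp passed to
#'   every \code{\link{model_spec}}.
#' @return list of 48 \code{model_spec}s; each carries a \code{model_id}
#'   attribute (1..48).
#' @export
enumerate_candidates <- function(season = "all", temperature_variable = "tmean",
                                 covariates = c("dow", "holiday"),
                                 lag_max = 30L, ref_temp = NULL) {
  exposure <- list(list(fun = "linear", k = 0L), list(fun = "bspline", k = 0L),
                   list(fun = "bspline", k = 1L), list(fun = "bspline", k = 2L))
  lag <- list(list(fun = "constant", k = 0L), list(fun = "bspline", k = 0L),
              list(fun = "bspline", k = 1L), list(fun = "bspline", k = 2L))
  out <- list()
  id <- 0L
  for (e in exposure) for (l in lag) for (df in 7:9) {
    id <- id + 1L
    sp <- model_spec(exposure_fun = e$fun, exposure_nknots = e$k,
                     lag_fun = l$fun, lag_nknots = l$k,
                     date_df_per_year = df, covariates = covariates,
                     season = season,
                     temperature_variable = temperature_variable,
                     lag_max = lag_max, ref_temp = ref_temp)
    attr(sp, "model_id") <- id
    out[[id]] <- sp
  }
  out
}

cb_df_of_spec <- function(sp) {
  vx <- if (sp$exposure_fun == "linear") 1L else 2L + sp$exposure_nknots
  vl <- if (sp$lag_fun == "constant") 1L else 3L + sp$lag_nknots
  vx * vl
}

#' Fit all candidates and select the best by QAIC
#'
#' Every candidate is fitted to the data; QAIC is computed with a common
#' dispersion reference estimated from the most complex candidate (largest
#' cross-basis df, then largest trend df), so models are compared on one
#' scale. Candidates that fail to fit are recorded in the table with
#' \code{converged = FALSE} and excluded from the ranking.
#'
#' @param data region series.
#' @param candidates list of \code{model_spec}s (default the 48-model
#'   grid).
#' @param keep_fits return all fits (memory-heavy; default FALSE keeps the
#'   winner only).
#' @return list with \code{best_spec}, \code{best_fit}, \code{table} (one
#'   row per candidate: model_id, functions, knots, dfs, qaic, dispersion,
#'   converged, ranked by QAIC) and \code{dispersion_ref}.
#' @export
select_best <- function(data, candidates = enumerate_candidates(), keep_fits = FALSE) {
  stopifnot(length(candidates) >= 1L)
  complexity <- vapply(candidates, function(sp)
    cb_df_of_spec(sp) * 1000 + sp$date_df_per_year, numeric(1))
  fits <- vector("list", length(candidates))
  errs <- character(length(candidates))
  for (i in seq_along(candidates)) {
    fits[[i]] <- tryCatch(fit_dlnm(data, candidates[[i]], keep_data = FALSE),
                          error = function(e) {errs[i] <<- conditionMessage(e); NULL})
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all candidate fits failed; first error: ", errs[which(!ok)[1]])
  ref_i <- which(ok)[which.max(complexity[ok])]
  dispersion_ref <- fits[[ref_i]]$dispersion
  qaics <- rep(NA_real_, length(candidates))
  qaics[ok] <- vapply(fits[ok], qaic, numeric(1), dispersion_ref = dispersion_ref)
  tab <- data.frame(
    model_id = vapply(candidates, function(sp)
      if (is.null(attr(sp, "model_id"))) NA_integer_ else attr(sp, "model_id"),
      integer(1)),
    exposure_fun = vapply(candidates, `[[`, character(1), "exposure_fun"),
    exposure_knots = vapply(candidates, `[[`, integer(1), "exposure_nknots"),
    lag_fun = vapply(candidates, `[[`, character(1), "lag_fun"),
    lag_knots = vapply(candidates, `[[`, integer(1), "lag_nknots"),
    date_df = vapply(candidates, `[[`, integer(1), "date_df_per_year"),
    cb_df = vapply(candidates, cb_df_of_spec, integer(1)),
    qaic = qaics,
    dispersion = ifelse(ok, vapply(fits, function(f)
      if (is.null(f)) NA_real_ else f$dispersion, numeric(1)), NA_real_),
    converged = ok
  )
  if (all(is.na(tab$model_id))) tab$model_id <- seq_along(candidates)
  tab <- tab[order(!tab$converged, tab$qaic), ]
  rownames(tab) <- NULL
  best_i <- which(ok)[which.min(qaics[ok])]
  best_fit <- fits[[best_i]]
  best_fit$qaic <- qaics[best_i]
  list(best_spec = candidates[[best_i]], best_fit = best_fit,
       table = tab, dispersion_ref = dispersion_ref)
}
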