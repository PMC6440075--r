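test_that("scenario constructor enforces its invariants", {
  expect_error(truth_scenario(n_days = 20), "exceed 31")
  expect_error(truth_scenario(ar_coefficient = 1), "stationary")
  expect_error(truth_scenario(overdispersion = 0.5), ">= 1")
  sc <- truth_scenario(n_days = 400, seed = 2)
  # reference centring: true surface is 0 log-RR at the reference, all lags
  expect_equal(max(abs(true_surface(sc, sc$ref_temp, 0:30))), 0)
  expect_lt(sc$cold_temp, sc$ref_temp)
  expect_gt(sc$heat_temp, sc$ref_temp)
})

test_that("degenerate sinusoid gives a constant temperature series", {
  sc <- truth_scenario(n_days = 100, temp_amplitude = 0, noise_sd = 0,
                       temp_mean_annual = 17.3, seed = 1)
  temps <- generate_temperature(sc)
  expect_equal(temps$tmean, rep(17.3, 100))
  expect_true(all(temps$tmin <= temps$tmean & temps$tmean <= temps$tmax))
})

test_that("white-noise scenario recovers the stated innovation SD", {
  sc <- truth_scenario(n_days = 10000, ar_coefficient = 0, noise_sd = 1,
                       seed = 4)
  temps <- generate_temperature(sc)
  doy <- as.integer(format(temps$date, "%j"))
  detrended <- temps$tmean - sc$temp_mean_annual -
    sc$temp_amplitude * cos(2 * pi * (doy - 196) / 365.25)
  expect_lt(abs(sd(detrended) - 1), 0.05)
})

test_that("generators are deterministic under a fixed seed", {
  sc <- truth_scenario(n_days = 400, seed = 99)
  t1 <- generate_temperature(sc)
  t2 <- generate_temperature(sc)
  expect_identical(t1, t2)
  d1 <- generate_mortality(t1, sc)
  d2 <- generate_mortality(t2, sc)
  expect_identical(d1, d2)
  x1 <- distort_temperature(t1, shift = 1, scale = 1.1, tail_skew = 0.2,
                            noise_sd = 0.5, seed = 7)
  x2 <- distort_temperature(t1, shift = 1, scale = 1.1, tail_skew = 0.2,
                            noise_sd = 0.5, seed = 7)
  expect_identical(x1, x2)
  # a different seed changes the noisy distortion
  x3 <- distort_temperature(t1, shift = 1, scale = 1.1, tail_skew = 0.2,
                            noise_sd = 0.5, seed = 8)
  expect_false(identical(x1$tmean, x3$tmean))
})

test_that("distortion reduces to identity / pure shift / moment arithmetic", {
  sc <- truth_scenario(n_days = 5000, seed = 21)
  temps <- generate_temperature(sc)
  same <- distort_temperature(temps, shift = 0, scale = 1, tail_skew = 0)
  expect_equal(same$tmean, temps$tmean)
  shifted <- distort_temperature(temps, shift = 2, scale = 1, tail_skew = 0)
  expect_equal(shifted$tmean, temps$tmean + 2)
  scaled <- distort_temperature(temps, shift = 1, scale = 1.2, tail_skew = 0)
  expect_equal(mean(scaled$tmean), 1.2 * mean(temps$tmean) + 1, tolerance = 1e-8)
  expect_error(distort_temperature(temps, scale = 0), "> 0")
})

test_that("mortality draws honour the scenario's mean structure", {
  sc <- truth_scenario(n_days = 20031, cold_effect = 0, heat_effect = 0,
                       dow_effects = rep(0, 7), holiday_effect = 0,
                       season_amplitude = 0, baseline_log_rate = log(10),
                       seed = 6)
  d <- generate_mortality(generate_temperature(sc), sc)
  expect_true(all(is.na(d$deaths[1:30])))
  expect_equal(attr(d, "valid_from"), 31L)
  expect_lt(abs(mean(d$deaths, na.rm = TRUE) - 10), 0.15)
})

test_that("overdispersion 1 gives Poisson-like counts", {
  sc <- truth_scenario(n_days = 15031, cold_effect = 0, heat_effect = 0,
                       dow_effects = rep(0, 7), holiday_effect = 0,
                       season_amplitude = 0, overdispersion = 1, seed = 8)
  d <- generate_mortality(generate_temperature(sc), sc)
  y <- d$deaths[!is.na(d$deaths)]
  expect_lt(abs(var(y) / mean(y) - 1), 0.07)
})

test_that("Pearson dispersion under the true mean matches the scenario phi", {
  for (phi in c(1.3, 2)) {
    sc <- truth_scenario(n_days = 12031, overdispersion = phi, seed = 13)
    temps <- generate_temperature(sc)
    d <- generate_mortality(temps, sc)
    mu <- exp(tempmort:::true_log_mean(temps, sc))
    ok <- !is.na(mu)
    pearson <- mean((d$deaths[ok] - mu[ok])^2 / mu[ok])
    expect_lt(abs(pearson - phi) / phi, 0.1)
  }
})

test_that("a cold effect raises mortality on the coldest days", {
  sc <- truth_scenario(n_days = 4031, cold_effect = 0.5, heat_effect = 0,
                       seed = 15)
  d <- generate_mortality(generate_temperature(sc), sc)
  d <- d[!is.na(d$deaths), ]
  qs <- quantile(d$tmean, c(0.1, 0.9))
  expect_gt(mean(d$deaths[d$tmean <= qs[1]]), mean(d$deaths[d$tmean >= qs[2]]))
})

test_that("true cumulative curve is centred and degenerates correctly", {
  sc <- truth_scenario(n_days = 400, seed = 3)
  expect_equal(true_cumulative_curve(sc, sc$ref_temp)$log_rr, 0)
  sc0 <- truth_scenario(n_days = 400, cold_effect = 0, heat_effect = 0, seed = 3)
  grid <- seq(5, 25, by = 1)
  expect_equal(true_cumulative_curve(sc0, grid)$log_rr, rep(0, length(grid)))
  # the cumulative curve equals the sum of the surface over all lags
  s <- true_surface(sc, grid, 0:30)
  expect_equal(rowSums(s), true_cumulative_curve(sc, grid)$log_rr,
               tolerance = 1e-12)
})

test_that("season labels follow the winter/summer month sets", {
  sc <- truth_scenario(n_days = 730, seed = 1)
  temps <- generate_temperature(sc)
  mon <- as.integer(format(temps$date, "%m"))
  expect_true(all(temps$season[mon %in% c(12, 1, 2, 3)] == "winter"))
  expect_true(all(temps$season[mon %in% c(6, 7, 8, 9)] == "summer"))
  expect_true(all(temps$season[mon %in% c(4, 5, 10, 11)] == "other"))
})
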