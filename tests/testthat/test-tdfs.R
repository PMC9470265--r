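test_that("reconvolution fit recovers a single lifetime through a delta IRF", {
  tt <- seq(0, 25, by = 0.025)
  irf <- numeric(length(tt)); irf[1] <- 10000
  decay <- 5000 * exp(-tt / 2)
  fit <- fit_decay_reconvolution(decay, irf, tt, n_components = 1)
  expect_equal(fit$tau, 2, tolerance = 1e-4)
  expect_lt(fit$chisq_red, 1e-6)
})

test_that("three-exponential reconvolution recovers the mean lifetime within 2%", {
  set.seed(31)
  tt <- seq(0, 50, by = 0.025)
  dt <- 0.025
  irf <- dnorm(tt, 2, 0.05)
  alpha <- c(2500, 1500, 800); tau <- c(0.4, 2, 6)
  model <- memprobe:::convolve_irf(irf / (sum(irf) * dt),
                                   memprobe:::multiexp(tt, alpha, tau), dt)
  counts <- rpois(length(tt), pmax(model / max(model) * 5000, 0))
  fit <- fit_decay_reconvolution(counts, round(irf / max(irf) * 10000), tt)
  mean_true <- sum(alpha * tau) / sum(alpha)
  mean_fit <- sum(fit$alpha * fit$tau) / sum(fit$alpha)
  expect_equal(mean_fit, mean_true, tolerance = 0.02)
  # an under-parameterized single-exponential fit is strictly worse
  fit1 <- fit_decay_reconvolution(counts, round(irf / max(irf) * 10000), tt,
                                  n_components = 1)
  expect_gt(fit1$chisq_red, fit$chisq_red)
  expect_error(fit_decay_reconvolution(c(0, 3, 0, 2, 0, 0, 1, 0),
                                       rep(1, 8), seq_len(8) * 0.1),
               "fewer")
})

test_that("TRES reconstruction conserves the steady-state spectrum exactly", {
  sim <- small_decay_sim(seed = 21)
  fits <- fit_decay_set_global(sim$decays, n_components = 6)
  times <- seq(0, 10, by = 0.05)
  tr <- reconstruct_tres(fits, sim$decays$wavelengths, sim$steady_state, times)
  integ <- apply(tr$lambda_surface, 2, function(d) pracma::trapz(times, d))
  expect_equal(integ, sim$steady_state$intensities, tolerance = 1e-12)
})

test_that("without relaxation every TRES slice has the same normalized shape", {
  sim <- make_decay_set(nu_inf = 17500, delta_nu = 0, lifetime = 2,
                        window = 25, dt = 0.025, noise = FALSE, seed = 2)
  fits <- fit_decay_set_global(sim$decays, n_components = 4)
  times <- c(0.2, 1, 3, 8)
  tr <- reconstruct_tres(fits, sim$decays$wavelengths, sim$steady_state, times)
  ref <- tr$intensities[1, ] / max(tr$intensities[1, ])
  for (i in 2:length(times))
    expect_equal(tr$intensities[i, ] / max(tr$intensities[i, ]), ref,
                 tolerance = 5e-3)
})

test_that("log-normal peak extraction is exact on Gaussian and skewed slices", {
  nu <- seq(14000, 26000, by = 150)
  gauss <- exp(-(nu - 20000)^2 / (2 * 1000^2))
  pk <- tres_peak(nu, gauss)
  expect_equal(pk$nu_peak, 20000, tolerance = 1)
  expect_equal(pk$fwhm, 2 * sqrt(2 * log(2)) * 1000, tolerance = 5)
  shifted <- exp(-(nu - 20500)^2 / (2 * 1000^2))
  expect_equal(tres_peak(nu, shifted)$nu_peak - pk$nu_peak, 500, tolerance = 1)
  skew <- memprobe:::lognormal_lineshape(nu, 3, 18000, 2800, -0.35)
  pk2 <- tres_peak(nu, skew)
  expect_equal(pk2$nu_peak, 18000, tolerance = 18000 * 0.01)
  expect_equal(pk2$fwhm, 2800, tolerance = 28)
  edge <- exp(-(nu - 14000)^2 / (2 * 800^2))
  expect_warning(pk3 <- tres_peak(nu, edge), "edge")
  expect_false(pk3$fitted)
})

test_that("Lippert-Mataga polarity function and its monotonicity", {
  expect_equal(lippert_mataga_deltaf(1, 1), 0)
  expect_equal(lippert_mataga_deltaf(1.77, sqrt(1.77)), 0)
  expect_equal(round(lippert_mataga_deltaf(78.4, 1.333), 3), 0.320)
  expect_error(lippert_mataga_deltaf(0.5, 1), ">= 1")
  eps <- seq(2, 80, length.out = 30)
  expect_true(all(diff(lippert_mataga_deltaf(eps, 1.4)) > 0))
  ns <- seq(1.3, 1.6, length.out = 30)
  expect_true(all(diff(lippert_mataga_deltaf(40, ns)) < 0))
})

test_that("time-zero estimation extrapolates the Stokes shift to zero polarity", {
  eps_for <- function(df) (1 + df) / (1 - 2 * df)   # n = 1 makes Delta f = f(eps)
  two <- data.frame(epsilon = eps_for(c(0.1, 0.3)), n = 1,
                    nuA_cm1 = 21000, nuE_cm1 = 21000 - c(3000, 5000))
  # zero-residual two-point regressions make summary.lm warn; irrelevant here
  est <- suppressWarnings(estimate_time_zero(two, nuA_in_system = 20000))
  expect_equal(est$intercept, 2000, tolerance = 1e-9)
  expect_equal(est$nu0, 18000, tolerance = 1e-9)
  # perfectly linear series with a point at Delta f = 0
  lin <- data.frame(epsilon = eps_for(c(0, 0.15, 0.3)), n = 1,
                    nuA_cm1 = 21000,
                    nuE_cm1 = 21000 - (1800 + 9000 * c(0, 0.15, 0.3)))
  expect_equal(suppressWarnings(estimate_time_zero(lin, 21000))$intercept,
               1800, tolerance = 1e-9)
  expect_error(estimate_time_zero(two[c(1, 1), ], 20000), "distinct")
  # noisy series: intercept recovered within 2 standard errors
  set.seed(12)
  df6 <- seq(0.05, 0.32, length.out = 6)
  noisy <- data.frame(epsilon = eps_for(df6), n = 1, nuA_cm1 = 21000,
                      nuE_cm1 = 21000 - (2500 + 8000 * df6) +
                        rnorm(6, 0, 50))
  est6 <- estimate_time_zero(noisy, 21000)
  expect_lt(abs(est6$intercept - 2500), 2 * est6$intercept_se)
})

test_that("integrated relaxation time: quadrature matches closed forms", {
  expect_equal(total_shift(18000, 16000), 2000)
  expect_equal(total_shift(17000, 17000), 0)
  tt <- seq(0, 30, by = 0.05)
  nu1 <- 16000 + 2000 * exp(-tt)
  expect_equal(relaxation_time(tt, nu1, 16000, 2000), 1, tolerance = 1e-3)
  nu2 <- 16000 + 2000 * (0.5 * exp(-tt) + 0.5 * exp(-tt / 3))
  expect_equal(relaxation_time(tt, nu2, 16000, 2000), 2, tolerance = 5e-3)
  tt50 <- seq(0, 50, by = 0.05)
  nu3 <- 16000 + 1000 * exp(-tt50 / 1.5)
  expect_lt(abs(relaxation_time(tt50, nu3, 16000, 1000) - 1.5), 0.05)
  # C(t) not decayed at the window end: tail omitted with a warning
  tshort <- seq(0, 5, by = 0.05)
  nu4 <- 16000 + 2000 * (0.5 + 0.5 * exp(-tshort))
  expect_warning(t4 <- relaxation_time(tshort, nu4, 16000, 2000),
                 "window end")
  expect_true(isTRUE(attr(t4, "tail_unreliable")))
  expect_error(relaxation_time(tt, nu1, 16000, 0), "> 0")
})

test_that("full TDFS analysis recovers a planted relaxation", {
  sim <- small_decay_sim(delta_nu = 1200, tau_rel = 0.8, seed = 9)
  res <- analyze_decay_set(sim$decays, sim$steady_state,
                           nu0 = sim$truth$nu0)
  expect_equal(res$delta_nu, 1200, tolerance = 50 / 1200)
  expect_lt(abs(res$tau_r - 0.8), 0.05)
  expect_false(res$no_relaxation)
  # correlation function starts at 1 (internal time-zero) and relaxes to ~0
  res2 <- analyze_decay_set(sim$decays, sim$steady_state)
  expect_equal(res2$C_t[1], 1, tolerance = 1e-9)
  expect_lt(abs(mean(tail(res2$C_t, 10))), 0.05)
})

test_that("a non-relaxing sample is reported as such", {
  sim <- make_decay_set(nu_inf = 17500, delta_nu = 0, lifetime = 2,
                        window = 25, dt = 0.025, seed = 3)
  res <- analyze_decay_set(sim$decays, sim$steady_state)
  expect_true(res$no_relaxation)
  expect_equal(res$tau_r, 0)
  expect_lt(abs(res$delta_nu), 25)
})

test_that("relaxation slower than the lifetime is underestimated, not inflated", {
  sim <- make_decay_set(nu_inf = 17000, delta_nu = 1500, tau_rel = 10,
                        lifetime = 2.5, window = 25, dt = 0.025, seed = 4)
  res <- suppressWarnings(analyze_decay_set(sim$decays, sim$steady_state,
                                            nu0 = sim$truth$nu0))
  expect_true(res$incomplete_relaxation)
  expect_lt(res$tau_r, sim$truth$tau_r)   # truth is 10 ns
  expect_gt(res$tau_r, 0)
})

test_that("decay CSV round trip and the CSV-driven pipeline work", {
  sim <- small_decay_sim(seed = 6)
  d1 <- tempfile(fileext = ".csv"); d2 <- tempfile(fileext = ".csv")
  d3 <- tempfile(fileext = ".csv")
  write_decay_csv(sim$decays, d1, d2)
  back <- read_decay_csv(d1, d2)
  expect_equal(back$decays, sim$decays$decays)
  expect_equal(back$wavelengths, sim$decays$wavelengths)
  write.csv(data.frame(wavelength_nm = sim$steady_state$wavelengths,
                       intensity = sim$steady_state$intensities),
            d3, row.names = FALSE)
  out <- file.path(tempdir(), "tdfs_out")
  res <- run_tdfs_pipeline(d1, d2, d3, out, nu0 = sim$truth$nu0)
  expect_true(file.exists(file.path(out, "relaxation_result.json")))
  expect_true(file.exists(file.path(out, "relaxation_series.csv")))
  js <- jsonlite::read_json(file.path(out, "relaxation_result.json"))
  expect_true(all(c("nu0_cm1", "nu_inf_cm1", "delta_nu_cm1", "tau_r_ns")
                  %in% names(js)))
  expect_equal(js$delta_nu_cm1, res$delta_nu)
  # schema violations name the offending file
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_decay_csv(bad, d2), "columns")
  expect_error(run_tdfs_pipeline(d1, d2, bad, out), "steady")
  unlink(c(d1, d2, d3, bad, out), recursive = TRUE)
})
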