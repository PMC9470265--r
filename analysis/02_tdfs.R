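#!/usr/bin/env Rscript
# Time-dependent fluorescence shift analysis on synthetic TCSPC decay sets.
#
# Simulates wavelength-resolved decays (10 nm steps, peak 5000 counts,
# fluorescence lifetime 4 ns) for a grid of planted relaxations, runs the
# full TDFS pipeline (global reconvolution analysis, TRES reconstruction,
# nu(t)/FWHM(t) tracking, Delta nu and tau_R) and tabulates recovery against
# the planted values. One slow-relaxation case (tau_rel = 20 ns, far beyond
# the lifetime) illustrates the expected underestimation of tau_R when the
# relaxation outlasts the emission. Writes results/tdfs_recovery.csv and one
# nu(t)/FWHM(t) series.

suppressPackageStartupMessages(library(memprobe))
dir.create("results", showWarnings = FALSE)
seed <- 1L

grid <- expand.grid(delta_nu = c(500, 1500, 3000), tau_rel = c(0.2, 1, 3))
grid <- rbind(grid, data.frame(delta_nu = 1500, tau_rel = 20))

rows <- lapply(seq_len(nrow(grid)), function(i) {
  dnu <- grid$delta_nu[i]; trel <- grid$tau_rel[i]
  sim <- make_decay_set(nu_inf = 17000, delta_nu = dnu, tau_rel = trel,
                        lifetime = 4, peak_counts = 5000, seed = seed + i)
  res <- suppressWarnings(
    analyze_decay_set(sim$decays, sim$steady_state, nu0 = sim$truth$nu0))
  cat(sprintf(
    "planted (dnu=%4.0f cm-1, tau=%4.1f ns) -> recovered (%6.1f, %6.3f)%s\n",
    dnu, trel, res$delta_nu, res$tau_r,
    if (res$incomplete_relaxation) "  [incomplete relaxation]" else ""))
  if (i == 5)
    write.csv(data.frame(time_ns = res$times, nu_cm1 = res$nu_t,
                         fwhm_cm1 = res$fwhm_t, C = res$C_t),
              "results/tdfs_series_example.csv", row.names = FALSE)
  data.frame(delta_nu_planted = dnu, tau_rel_planted = trel,
             delta_nu_recovered = res$delta_nu, tau_r_recovered = res$tau_r,
             incomplete = res$incomplete_relaxation)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/tdfs_recovery.csv", row.names = FALSE)

core <- tab$tau_rel_planted <= 4
cat(sprintf(
  "grid (tau_rel <= lifetime): max |dnu error| = %.1f cm-1, max |tau error| = %.3f ns\n",
  max(abs(tab$delta_nu_recovered - tab$delta_nu_planted)[core]),
  max(abs(tab$tau_r_recovered - tab$tau_rel_planted)[core])))
cat(sprintf("slow case (tau_rel = 20 ns): recovered %.2f ns (underestimate)\n",
            tab$tau_r_recovered[!core]))

# time-zero estimation from a synthetic Lippert-Mataga solvent series
eps_for <- function(df) (1 + df) / (1 - 2 * df)
df8 <- seq(0.05, 0.32, length.out = 8)
set.seed(seed)
series <- data.frame(epsilon = eps_for(df8), n = 1, nuA_cm1 = 21000,
                     nuE_cm1 = 21000 - (2500 + 8000 * df8) + rnorm(8, 0, 20))
tz <- estimate_time_zero(series, nuA_in_system = 21000)
cat(sprintf("Lippert-Mataga time zero: nu(0) = %.0f cm-1 (planted 18500, se %.0f)\n",
            tz$nu0, tz$intercept_se))
write.csv(data.frame(nu0_cm1 = tz$nu0, intercept_cm1 = tz$intercept,
                     slope = tz$slope, intercept_se = tz$intercept_se),
          "results/time_zero_estimate.csv", row.names = FALSE)
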