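#!/usr/bin/env Rscript
# Bilayer-trajectory observables on synthetic planar-membrane trajectories.
#
# Emulates the three probe archetypes seen in atomistic simulations of
# POPC bilayers: a mostly-upright probe (mean tilt 38.5 deg), a bimodal one
# (modes 23 and 87 deg; a minor surface-parallel population), and a
# surface-parallel one (mean 71 deg). A cholesterol-containing counterpart
# with the mean tilt reduced by 5 deg probes the mean-shift readout, and
# cholesterol-OH reference atoms planted at 1.4 nm from the midplane check
# depth localization. Writes results/tilt_summary.csv,
# results/tilt_histograms.csv and results/density_profiles.csv.

suppressPackageStartupMessages(library(memprobe))
dir.create("results", showWarnings = FALSE)
seed <- 1L

archetypes <- list(
  upright   = list(copy = 1, tilt_mean = 38.5, tilt_sd = 12, depth_mean = 1.0),
  bimodal   = list(copy = 1, tilt_mean = c(23, 87), tilt_sd = 8,
                   tilt_weights = c(0.7, 0.3), depth_mean = 0.9),
  parallel  = list(copy = 1, tilt_mean = 71, tilt_sd = 10, depth_mean = 1.1))

hists <- list(); summaries <- list()
for (nm in names(archetypes)) {
  sim <- make_trajectory(n_frames = 4000, probes = list(archetypes[[nm]]),
                         extra_roles = list(
                           cholesterol_oh = list(n = 8, z_mean = 1.4,
                                                 z_sd = 0.08,
                                                 both_leaflets = TRUE)),
                         seed = seed)
  dist <- tilt_distribution(tilt_angles(sim$trajectory, 1))
  hists[[nm]] <- data.frame(archetype = nm, angle_deg = dist$mids,
                            freq = dist$freq)
  summaries[[nm]] <- data.frame(
    archetype = nm, mean_tilt = dist$mean,
    modes = paste(round(dist$modes, 1), collapse = "/"),
    planted = paste(archetypes[[nm]]$tilt_mean, collapse = "/"))
  cat(sprintf("%s: mean tilt %.1f deg, modes %s (planted %s)\n",
              nm, dist$mean, summaries[[nm]]$modes, summaries[[nm]]$planted))
}

# cholesterol reduces the average tilt: planted 5 degree shift
chol_pair <- lapply(c(38.5, 33.5), function(m)
  make_trajectory(n_frames = 6000,
                  probes = list(list(copy = 1, tilt_mean = m, tilt_sd = 12,
                                     depth_mean = 1.0)),
                  seed = seed + 1))
dists <- lapply(chol_pair, function(s)
  tilt_distribution(tilt_angles(s$trajectory, 1)))
shift <- mean_tilt_shift(dists[[1]], dists[[2]])
cat(sprintf("cholesterol tilt reduction: %.2f deg (planted 5.0)\n", shift))

# depth localization: cholesterol OH and the probe fluorophore
sim <- make_trajectory(n_frames = 1000,
                       probes = list(list(copy = 1, tilt_mean = 40,
                                          tilt_sd = 10, depth_mean = 1.0,
                                          depth_sd = 0.15)),
                       extra_roles = list(
                         cholesterol_oh = list(n = 8, z_mean = 1.4,
                                               z_sd = 0.08,
                                               both_leaflets = TRUE)),
                       seed = seed + 2)
profs <- lapply(c("cholesterol_oh", "probe_axis_head"), function(sel)
  cbind(selection = sel,
        as.data.frame(partial_density_profile(sim$trajectory, sel)[
          c("z", "density")])))
dp <- do.call(rbind, profs)
oh <- dp[dp$selection == "cholesterol_oh", ]
cat(sprintf("cholesterol OH density peak at %.2f nm (planted +-1.4)\n",
            oh$z[which.max(oh$density)]))

write.csv(do.call(rbind, summaries), "results/tilt_summary.csv",
          row.names = FALSE)
write.csv(do.call(rbind, hists), "results/tilt_histograms.csv",
          row.names = FALSE)
write.csv(dp, "results/density_profiles.csv", row.names = FALSE)
write.csv(data.frame(shift_deg = shift, planted_deg = 5),
          "results/tilt_shift.csv", row.names = FALSE)

cat(sprintf("simulated bilayer composition: %d lipids + %d probes = %.0f mol%%\n",
            200, 8, probe_mol_percent(200, 8)))
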