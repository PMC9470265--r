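#' Synthetic phase-separated vesicle scene with ground truth
#'
#' Renders ring-shaped (membrane-stained) vesicles into a hyperspectral
#' stack. Each vesicle is a circular or elliptical annulus; each phase
#' carries a Gaussian emission spectrum sampled at the channel centers; a
#' uniform background and shot noise are added. The analytic GP of every
#' phase at the configured reference channels is returned as ground truth,
#' together with the planted label and phase images and the
#' moment-eccentricity of each rendered object.
#'
#' @param size image side length (px, square image).
#' @param vesicles list of vesicle specs; each a list with `center` (row,
#'   col), `radius` (px), and optionally `thickness` (px, default 3),
#'   `axis_ratio` (major/minor, default 1 = circle), `angle_deg` (major-axis
#'   orientation), `phases` (list of spectra: `peak` nm, `width` nm,
#'   `amplitude`), `boundaries` (two angles, degrees, delimiting phase 2 of a
#'   two-phase vesicle).
#' @param channel_centers detection channel wavelengths (nm).
#' @param cfg a [gp_config] (defines the reference channels for the analytic
#'   GP ground truth).
#' @param background uniform background level (counts).
#' @param noise `"poisson"`, `"gaussian"` or `"none"`.
#' @param gaussian_sd read-noise s.d. for `noise = "gaussian"`.
#' @param blur_sigma optional Gaussian blur (px) applied to the expected
#'   intensities before noise; 0 disables.
#' @param seed RNG seed.
#' @return list with `image` ([spectral_image]), `labels` (matrix, 0 =
#'   background), `phase` (matrix, phase id within each vesicle) and `truth`
#'   (data.frame: vesicle, phase, gp_analytic, eccentricity, n_pixels).
#' @export
make_vesicle_image <- function(size, vesicles, channel_centers, cfg,
                               background = 20, noise = "poisson",
                               gaussian_sd = 5, blur_sigma = 0, seed = 1) {
  set.seed(seed)
  # reject overlapping vesicles (compare bounding radii)
  if (length(vesicles) > 1L) {
    for (i in seq_along(vesicles)) for (j in seq_along(vesicles)) {
      if (j <= i) next
      vi <- vesicles[[i]]; vj <- vesicles[[j]]
      ri <- vi$radius * max(1, vi$axis_ratio %||% 1)
      rj <- vj$radius * max(1, vj$axis_ratio %||% 1)
      d <- sqrt(sum((vi$center - vj$center)^2))
      if (d < ri + rj + (vi$thickness %||% 3))
        stop(sprintf("vesicles %d and %d overlap", i, j))
    }
  }
  nch <- length(channel_centers)
  expected <- array(background, dim = c(nch, size, size))
  labels <- matrix(0L, size, size)
  phase_img <- matrix(0L, size, size)
  rows <- matrix(rep(seq_len(size), size), size, size)
  cols <- t(rows)
  truth <- list()
  for (k in seq_along(vesicles)) {
    v <- vesicles[[k]]
    th <- v$thickness %||% 3
    ar <- v$axis_ratio %||% 1
    ang <- (v$angle_deg %||% 0) * pi / 180
    phases <- v$phases %||% list(list(peak = 450, width = 30, amplitude = 1000))
    a <- v$radius * ar; b <- v$radius
    dx <- rows - v$center[1L]; dy <- cols - v$center[2L]
    xr <- dx * cos(ang) + dy * sin(ang)
    yr <- -dx * sin(ang) + dy * cos(ang)
    rho <- sqrt((xr / a)^2 + (yr / b)^2)
    ring <- abs(rho - 1) * sqrt(a * b) <= th / 2
    if (!any(ring)) stop(sprintf("vesicle %d renders no pixels", k))
    ext <- a + th
    if (v$center[1L] - ext < 1 || v$center[1L] + ext > size ||
        v$center[2L] - ext < 1 || v$center[2L] + ext > size)
      stop(sprintf("vesicle %d out of image bounds", k))
    phi <- (atan2(yr, xr) * 180 / pi) %% 360
    ph <- matrix(1L, size, size)
    if (length(phases) > 1L && !is.null(v$boundaries)) {
      bnd <- v$boundaries %% 360
      in2 <- if (bnd[1L] <= bnd[2L]) phi >= bnd[1L] & phi < bnd[2L]
             else phi >= bnd[1L] | phi < bnd[2L]
      ph[in2] <- 2L
    }
    labels[ring] <- k
    phase_img[ring] <- ph[ring]
    for (p in seq_along(phases)) {
      spec_ch <- phases[[p]]$amplitude *
        exp(-(channel_centers - phases[[p]]$peak)^2 / (2 * phases[[p]]$width^2))
      sel <- ring & ph == p
      for (ch in seq_len(nch))
        expected[ch, , ][sel] <- expected[ch, , ][sel] + spec_ch[ch]
      ib <- spec_ch[which.min(abs(channel_centers - cfg$lambda_lo))]
      ir <- spec_ch[which.min(abs(channel_centers - cfg$lambda_ld))]
      truth[[length(truth) + 1L]] <- data.frame(
        vesicle = k, phase = p, gp_analytic = (ib - ir) / (ib + ir),
        eccentricity = pixel_eccentricity(which(ring, arr.ind = TRUE)),
        n_pixels = sum(sel))
    }
  }
  if (blur_sigma > 0) {
    kern <- stats::dnorm(seq(-ceiling(3 * blur_sigma), ceiling(3 * blur_sigma)),
                         sd = blur_sigma)
    kern <- kern / sum(kern)
    for (ch in seq_len(nch)) {
      m <- expected[ch, , ]
      m <- apply(m, 2L, function(col) blur1d(col, kern))
      m <- t(apply(m, 1L, function(row) blur1d(row, kern)))
      expected[ch, , ] <- m
    }
  }
  data <- switch(noise,
    poisson = array(stats::rpois(length(expected), expected), dim = dim(expected)),
    gaussian = pmax(expected + stats::rnorm(length(expected), sd = gaussian_sd), 0),
    none = expected,
    stop("noise must be poisson, gaussian or none"))
  list(image = spectral_image(data, channel_centers),
       labels = labels, phase = phase_img,
       truth = do.call(rbind, truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

blur1d <- function(x, kern) {
  h <- (length(kern) - 1L) / 2
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  stats::convolve(xp, rev(kern), type = "filter")
}

#' Synthetic wavelength-resolved TCSPC decay set with ground truth
#'
#' Builds a continuous time-resolved emission surface from a spectral
#' relaxation model, integrates it to per-wavelength decays, convolves with a
#' Gaussian IRF, scales each decay to the acquisition peak-count target and
#' applies Poisson counting noise. The relaxation model is
#' `nu(t) = nu_inf + delta_nu * C(t)` with
#' `C(t) = sum_i w_i exp(-t / tau_rel_i)`; the instantaneous lineshape is a
#' log-normal with constant FWHM; the population decays exponentially with
#' the fluorescence lifetime. The steady-state spectrum is the noiseless time
#' integral. Ground truth carries nu(0), nu(inf), Delta nu and the analytic
#' integrated relaxation time `tau_R = sum_i w_i tau_rel_i`.
#'
#' @param nu_inf relaxed emission maximum (cm^-1).
#' @param delta_nu total dynamic Stokes shift (cm^-1, >= 0).
#' @param tau_rel relaxation time constant(s) (ns).
#' @param rel_weights weights of the relaxation components (sum to 1).
#' @param lifetime fluorescence lifetime (ns).
#' @param fwhm instantaneous lineshape FWHM (cm^-1).
#' @param asym lineshape asymmetry (Fraser-Suzuki; negative = red tail).
#' @param window,dt acquisition window and bin width (ns).
#' @param irf_center,irf_sigma Gaussian IRF position and width (ns).
#' @param peak_counts per-decay peak count target (acquisition stops there).
#' @param wavelengths emission wavelengths (nm); default: 10 nm grid covering
#'   the emission band.
#' @param noise apply Poisson counting noise?
#' @param seed RNG seed.
#' @return list with `decays` ([decay_set]), `steady_state`
#'   (`emission_spectrum`) and `truth` (nu0, nu_inf, delta_nu, tau_r, ...).
#' @export
make_decay_set <- function(nu_inf = 17000, delta_nu = 1500, tau_rel = 1,
                           rel_weights = NULL, lifetime = 4,
                           fwhm = 2500, asym = -0.2,
                           window = 50, dt = 0.025,
                           irf_center = 2, irf_sigma = 0.05,
                           peak_counts = 5000, wavelengths = NULL,
                           noise = TRUE, seed = 1) {
  set.seed(seed)
  if (window < 10 * lifetime)
    stop("acquisition window must be at least 10x the fluorescence lifetime")
  if (is.null(rel_weights)) rel_weights <- rep(1 / length(tau_rel), length(tau_rel))
  if (abs(sum(rel_weights) - 1) > 1e-9) stop("rel_weights must sum to 1")
  if (delta_nu < 0) stop("delta_nu must be >= 0")
  tgrid <- seq(0, window - dt, by = dt)
  if (is.null(wavelengths)) {
    nu_hi <- nu_inf + delta_nu + 1.2 * fwhm
    nu_lo <- nu_inf - 1.2 * fwhm
    wavelengths <- seq(ceiling(1e7 / nu_hi / 10) * 10,
                       floor(1e7 / nu_lo / 10) * 10, by = 10)
  }
  C <- drop(exp(-outer(tgrid, 1 / tau_rel)) %*% rel_weights)
  nu_t <- nu_inf + delta_nu * C
  pop <- exp(-tgrid / lifetime)
  nl <- length(wavelengths)
  irf <- stats::dnorm(tgrid, irf_center, irf_sigma)
  irf_counts <- round(irf / max(irf) * 2 * peak_counts)
  irf_n <- irf / (sum(irf) * dt)
  decays <- matrix(0, length(tgrid), nl)
  ss <- numeric(nl)
  for (j in seq_len(nl)) {
    lam <- wavelengths[j]
    nuj <- 1e7 / lam
    # intensity per unit wavelength: lineshape (per wavenumber) times Jacobian
    d <- pop * lognormal_lineshape(nuj, 1, nu_t, fwhm, asym) * (1e7 / lam^2)
    ss[j] <- pracma::trapz(tgrid, d)
    conv <- convolve_irf(irf_n, d, dt)
    m <- max(conv)
    if (m <= 0) stop("wavelength grid misses the emission band")
    expected <- pmax(conv / m * peak_counts, 0)
    decays[, j] <- if (noise) stats::rpois(length(expected), expected)
                   else expected
  }
  tau_r <- if (delta_nu > 0) sum(rel_weights * tau_rel) else 0
  list(decays = decay_set(tgrid, irf_counts, decays, wavelengths),
       steady_state = emission_spectrum(wavelengths, ss),
       truth = list(nu0 = nu_inf + delta_nu, nu_inf = nu_inf,
                    delta_nu = delta_nu, tau_r = tau_r,
                    tau_rel = tau_rel, rel_weights = rel_weights,
                    lifetime = lifetime, fwhm = fwhm, asym = asym))
}

#' Synthetic bilayer trajectory with prescribed tilt and depth distributions
#'
#' Samples per-frame probe axis orientations (polar angle from a normal - or
#' mixture of normals - around the planted tilt, reflected into [0, 180];
#' azimuth uniform) and per-role atom depths from Gaussians about the
#' midplane, inside a planar-bilayer box. Chain-terminal reference atoms are
#' always generated near the midplane so the analysis can recenter.
#'
#' @param n_frames number of frames.
#' @param probes list of probe specs: `copy` id, `tilt_mean` (degrees; vector
#'   for a mixture), `tilt_sd` (degrees; 0 = degenerate), `tilt_weights`
#'   (mixture weights), `depth_mean`, `depth_sd` (nm from midplane),
#'   `leaflet` (+1 upper / -1 lower).
#' @param extra_roles named list: role -> list(`n`, `z_mean`, `z_sd`,
#'   `both_leaflets`) placing reference atoms (e.g. `cholesterol_oh` at
#'   1.4 nm).
#' @param box box dimensions (nm).
#' @param axis_length fluorophore long-axis length (nm).
#' @param seed RNG seed.
#' @return list with `trajectory` ([md_trajectory]) and `truth` (per-probe
#'   planted tilt means/modes and per-role depths).
#' @export
make_trajectory <- function(n_frames = 500, probes = list(), extra_roles = list(),
                            box = c(6, 6, 6), axis_length = 1, seed = 1) {
  set.seed(seed)
  mid <- box[3L] / 2
  n_ref <- 24L
  roles <- data.frame(atom = seq_len(n_ref), role = "chain_terminal",
                      copy = NA_integer_)
  n_atoms <- n_ref
  for (rn in names(extra_roles)) {
    er <- extra_roles[[rn]]
    roles <- rbind(roles, data.frame(atom = n_atoms + seq_len(er$n),
                                     role = rn, copy = NA_integer_))
    n_atoms <- n_atoms + er$n
  }
  head_idx <- integer(length(probes)); tail_idx <- integer(length(probes))
  for (i in seq_along(probes)) {
    head_idx[i] <- n_atoms + 1L; tail_idx[i] <- n_atoms + 2L
    roles <- rbind(roles,
      data.frame(atom = c(head_idx[i], tail_idx[i]),
                 role = c("probe_axis_head", "probe_axis_tail"),
                 copy = probes[[i]]$copy))
    n_atoms <- n_atoms + 2L
  }
  planted_tilts <- lapply(probes, function(p) {
    w <- p$tilt_weights %||% rep(1 / length(p$tilt_mean), length(p$tilt_mean))
    comp <- sample.int(length(p$tilt_mean), n_frames, replace = TRUE, prob = w)
    th <- stats::rnorm(n_frames, p$tilt_mean[comp],
                       rep(p$tilt_sd, length.out = length(p$tilt_mean))[comp])
    th <- abs(th)                      # reflect at 0
    th <- ifelse(th > 180, 360 - th, th)
    ifelse(th > 90, 180 - th, th)      # planted convention is folded
  })
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    m <- matrix(0, n_atoms, 3L)
    m[seq_len(n_ref), 1L] <- stats::runif(n_ref, 0, box[1L])
    m[seq_len(n_ref), 2L] <- stats::runif(n_ref, 0, box[2L])
    m[seq_len(n_ref), 3L] <- stats::rnorm(n_ref, mid, 0.03)
    at <- n_ref
    for (rn in names(extra_roles)) {
      er <- extra_roles[[rn]]
      side <- if (isTRUE(er$both_leaflets))
        rep_len(c(1, -1), er$n) else rep(1, er$n)
      idx <- at + seq_len(er$n)
      m[idx, 1L] <- stats::runif(er$n, 0, box[1L])
      m[idx, 2L] <- stats::runif(er$n, 0, box[2L])
      m[idx, 3L] <- mid + side * stats::rnorm(er$n, er$z_mean, er$z_sd %||% 0.05)
      at <- at + er$n
    }
    for (i in seq_along(probes)) {
      p <- probes[[i]]
      leaf <- p$leaflet %||% 1
      depth <- stats::rnorm(1L, p$depth_mean %||% 1, p$depth_sd %||% 0.1)
      hx <- stats::runif(1L, 0, box[1L]); hy <- stats::runif(1L, 0, box[2L])
      hz <- mid + leaf * depth
      th <- planted_tilts[[i]][f] * pi / 180
      phi <- stats::runif(1L, 0, 2 * pi)
      # inward normal is -leaf * z; tilt measured from it
      v <- c(sin(th) * cos(phi), sin(th) * sin(phi), -leaf * cos(th))
      m[head_idx[i], ] <- c(hx, hy, hz)
      m[tail_idx[i], ] <- c(hx, hy, hz) + axis_length * v
    }
    frames[[f]] <- m
  }
  truth <- list(
    tilt = lapply(seq_along(probes), function(i)
      list(copy = probes[[i]]$copy, modes = probes[[i]]$tilt_mean,
           mean = mean(planted_tilts[[i]]),
           angles = planted_tilts[[i]])),
    depths = c(lapply(extra_roles, function(er) er$z_mean),
               stats::setNames(lapply(probes, function(p) p$depth_mean %||% 1),
                               paste0("probe_", vapply(probes, function(p)
                                 p$copy, 1)))))
  list(trajectory = md_trajectory(frames, roles, box), truth = truth)
}

#' Synthetic plasma-membrane line profile for the internalization index
#'
#' Two membrane peaks of unit height with an interior plateau at `fraction`
#' of the peak height, plus additive Gaussian noise. The planted truth is
#' `fraction` (the expected internalization index).
#'
#' @param fraction internal / membrane intensity ratio (>= 0).
#' @param noise_sd additive noise s.d.
#' @param n profile length (samples).
#' @param seed RNG seed.
#' @return list with `profile`, `membrane_peaks` (indices),
#'   `internal_region` (indices), `truth`.
#' @export
make_internalization_profile <- function(fraction, noise_sd = 0, n = 101L,
                                         seed = 1) {
  if (fraction < 0) stop("fraction must be >= 0")
  set.seed(seed)
  x <- seq_len(n)
  p1 <- round(n * 0.15); p2 <- round(n * 0.85)
  prof <- exp(-(x - p1)^2 / 8) + exp(-(x - p2)^2 / 8)
  interior <- x > p1 + 6 & x < p2 - 6
  prof[interior] <- fraction
  prof <- prof + stats::rnorm(n, sd = noise_sd)
  list(profile = prof, membrane_peaks = c(p1, p2),
       internal_region = which(interior), truth = fraction)
}
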