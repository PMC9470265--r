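#' Wavelength-resolved TCSPC decay set
#'
#' Photon-count decay histograms recorded at a series of emission wavelengths
#' (10 nm steps spanning the steady-state spectrum) plus the instrument
#' response function (IRF), all on one uniform time axis.
#'
#' @param time_ns uniform time grid (ns).
#' @param irf IRF counts per bin.
#' @param decays counts matrix, `length(time_ns)` rows, one column per
#'   wavelength.
#' @param wavelengths emission wavelengths (nm), strictly increasing.
#' @param temperature acquisition temperature (degrees C).
#' @return An object of class `decay_set`.
#' @export
decay_set <- function(time_ns, irf, decays, wavelengths, temperature = 23) {
  decays <- as.matrix(decays)
  if (length(time_ns) != nrow(decays) || length(time_ns) != length(irf))
    stop("time axis, irf and decays must share one grid")
  if (length(wavelengths) != ncol(decays))
    stop("one decay column per wavelength")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(decays < 0) || any(irf < 0)) stop("counts must be nonnegative")
  structure(list(time_ns = time_ns, irf = irf, decays = decays,
                 wavelengths = wavelengths, temperature = temperature),
            class = "decay_set")
}

# linear convolution of the IRF (shifted by `shift` ns, linear interpolation)
# with a model decay sampled on the same uniform grid, truncated to the window
convolve_irf <- function(irf, model, dt, shift = 0) {
  n <- length(irf)
  if (shift != 0) {
    t0 <- seq_len(n)
    irf <- stats::approx(t0, irf, xout = t0 - shift / dt, rule = 2)$y
  }
  m <- stats::nextn(2L * n)
  f <- Re(stats::fft(stats::fft(c(irf, rep(0, m - n))) *
                     stats::fft(c(model, rep(0, m - n))), inverse = TRUE)) / m
  f[seq_len(n)] * dt
}

multiexp <- function(t, alpha, tau) {
  drop(exp(-outer(t, 1 / tau)) %*% alpha)
}

#' Reconvolution fit of a TCSPC decay
#'
#' Fits `irf (*) sum_i alpha_i exp(-t / tau_i)` to a photon-count histogram by
#' Poisson-weighted least squares (Levenberg-Marquardt), with a fitted sub-bin
#' IRF shift. Three exponential components are the default; the fit's purpose
#' is to deconvolve the instrument response, not to interpret individual
#' components. Initialization is deterministic: lifetimes log-spaced over
#' [0.05, 10] ns, equal amplitudes scaled to the observed peak.
#'
#' @param decay counts per bin.
#' @param irf IRF counts per bin (same grid).
#' @param time_ns uniform time grid (ns).
#' @param n_components number of exponential components (default 3).
#' @return An object of class `multiexp_fit`: list with `alpha`, `tau` (ns,
#'   increasing), `shift` (ns), `chisq_red`, `fitted` (model counts) and
#'   `time_ns`.
#' @export
fit_decay_reconvolution <- function(decay, irf, time_ns, n_components = 3L) {
  n <- length(time_ns)
  if (length(decay) != n || length(irf) != n) stop("grids must match")
  if (sum(decay) <= 0) stop("decay has no counts")
  if (sum(decay > 0) <= 2L * n_components + 1L)
    stop("fewer informative bins than parameters")
  dt <- time_ns[2L] - time_ns[1L]
  t0 <- time_ns - time_ns[1L]
  irf_n <- irf / (sum(irf) * dt)
  tau0 <- exp(seq(log(0.05), log(10), length.out = n_components))
  scale0 <- max(decay)
  # amplitudes unconstrained: red-edge decays of relaxing systems rise,
  # which needs negative pre-exponentials; lifetimes positive via log.
  # Pearson weights (from the model) avoid the low-count downward bias of
  # observed-count weighting
  resid_fn <- function(p) {
    alpha <- p[seq_len(n_components)]
    tau <- exp(p[n_components + seq_len(n_components)])
    shift <- p[2L * n_components + 1L]
    model <- convolve_irf(irf_n, multiexp(t0, alpha, tau), dt, shift)
    (model - decay) / sqrt(pmax(model, 1))
  }
  p0 <- c(rep(scale0 / n_components, n_components), log(tau0), 0)
  fit <- minpack.lm::nls.lm(p0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  p <- fit$par
  alpha <- p[seq_len(n_components)]
  tau <- exp(p[n_components + seq_len(n_components)])
  ord <- order(tau)
  alpha <- alpha[ord]; tau <- tau[ord]
  shift <- p[2L * n_components + 1L]
  model <- convolve_irf(irf_n, multiexp(t0, alpha, tau), dt, shift)
  chisq <- sum((model - decay)^2 / pmax(model, 1)) / (n - length(p))
  structure(list(alpha = alpha, tau = tau, shift = shift,
                 chisq_red = chisq, fitted = model, time_ns = time_ns,
                 n_components = n_components),
            class = "multiexp_fit")
}

#' @export
print.multiexp_fit <- function(x, ...) {
  cat(sprintf("multiexp_fit: %d components, chisq_red = %.3f\n",
              x$n_components, x$chisq_red))
  for (i in seq_along(x$tau))
    cat(sprintf("  tau = %.3f ns, alpha = %.3g\n", x$tau[i], x$alpha[i]))
  invisible(x)
}

# deconvolved model decay of a fit, evaluated from t = 0
model_decay <- function(fit, times) multiexp(times, fit$alpha, fit$tau)

# smallest component count (from n_components up) giving a satisfactory
# Poisson-weighted fit; stops once adding a component no longer helps
fit_decay_reconvolution_auto <- function(decay, irf, time_ns,
                                         n_components = 3L, max_components = 5L,
                                         chisq_ok = 1.1) {
  fit <- fit_decay_reconvolution(decay, irf, time_ns, n_components)
  n <- n_components
  while (fit$chisq_red > chisq_ok && n < max_components) {
    n <- n + 1L
    cand <- tryCatch(fit_decay_reconvolution(decay, irf, time_ns, n),
                     error = function(e) NULL)
    if (is.null(cand) || cand$chisq_red >= fit$chisq_red) break
    fit <- cand
  }
  fit
}

#' Global reconvolution analysis of a wavelength-resolved decay set
#'
#' Fits all decays of a set simultaneously with a common set of lifetimes
#' and a common IRF shift, while the per-wavelength amplitudes (which carry
#' the spectral relaxation, and may be negative at the red edge) are solved
#' by weighted linear least squares at every step (variable projection).
#' Spectral relaxation moves intensity between wavelengths but the set as a
#' whole evolves on one kinetic basis, so tying the lifetimes stabilizes the
#' late-time behaviour of every reconstructed decay.
#'
#' @param ds a [decay_set].
#' @param n_components number of shared exponential components (default 9;
#'   more than in a single-decay fit, because one basis must span the entire
#'   relaxing surface).
#' @param min_ratio smallest allowed ratio between neighbouring basis
#'   lifetimes (default 1.3).
#' @return list of `multiexp_fit` objects (one per wavelength, shared `tau`
#'   and `shift`), with attributes `tau`, `shift`, `chisq_red` (global).
#' @export
fit_decay_set_global <- function(ds, n_components = 9L, min_ratio = 1.3) {
  y <- ds$decays
  n <- nrow(y); nl <- ncol(y)
  dt <- ds$time_ns[2L] - ds$time_ns[1L]
  t0 <- ds$time_ns - ds$time_ns[1L]
  irf_n <- ds$irf / (sum(ds$irf) * dt)
  w <- 1 / sqrt(pmax(y, 1))
  # lifetimes parameterized as tau_1 plus ratio increments bounded below by
  # min_ratio: near-degenerate components let the tail spectrum wander
  # without data support, so the basis is kept spread out; a smooth penalty
  # keeps the slowest component inside the acquisition window
  tau_cap <- 2 * max(t0)
  par_tau <- function(p) {
    cumprod(c(exp(p[1L]), min_ratio + exp(p[2:n_components])))
  }
  cap_penalty <- function(tau) {
    50 * sqrt(n * nl) * pmax(0, log(tau / tau_cap))
  }
  basis_amps <- function(p) {
    tau <- par_tau(p)
    shift <- p[n_components + 1L]
    B <- vapply(tau, function(tk)
      convolve_irf(irf_n, exp(-t0 / tk), dt, shift), numeric(n))
    A <- matrix(0, n_components, nl)
    R <- matrix(0, n, nl)
    covs <- vector("list", nl)
    for (j in seq_len(nl)) {
      # Pearson weighting: weights from the model, not the observed counts
      # (weighting by observed counts biases low-count bins downward);
      # start from data weights, then reweight once from the model
      wj <- w[, j]
      a <- rep(0, n_components)
      qrB <- NULL
      for (it in 1:2) {
        Bw <- B * wj
        qrB <- qr(Bw)
        a <- tryCatch(qr.coef(qrB, y[, j] * wj),
                      error = function(e) rep(0, n_components))
        a[is.na(a)] <- 0
        wj <- 1 / sqrt(pmax(drop(B %*% a), 1))
      }
      A[, j] <- a
      R[, j] <- (drop(B %*% a) - y[, j]) * wj
      covs[[j]] <- tryCatch(chol2inv(qr.R(qrB)),
                            error = function(e) diag(0, n_components))
    }
    list(A = A, R = R, tau = tau, shift = shift, covs = covs)
  }
  r0 <- (10 / 0.05)^(1 / (n_components - 1L))
  p0 <- c(log(0.05), rep(log(r0 - min_ratio), n_components - 1L), 0)
  obj <- function(p) {
    sol <- basis_amps(p)
    c(as.vector(sol$R), cap_penalty(sol$tau))
  }
  fit <- minpack.lm::nls.lm(p0, fn = obj,
                            lower = c(log(dt / 4), rep(-8, n_components - 1L),
                                      -5 * dt),
                            upper = c(log(tau_cap), rep(5, n_components - 1L),
                                      5 * dt),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-10, ptol = 1e-10))
  sol <- basis_amps(fit$par)
  npar <- length(p0) + n_components * nl
  chisq <- sum(sol$R^2) / (n * nl - npar)
  fits <- lapply(seq_len(nl), function(j) {
    alpha <- sol$A[, j]
    tmod <- convolve_irf(irf_n, multiexp(t0, alpha, sol$tau), dt, sol$shift)
    structure(list(alpha = alpha, tau = sol$tau, shift = sol$shift,
                   chisq_red = sum(((tmod - y[, j]) * w[, j])^2) /
                     (n - n_components - 2L),
                   alpha_cov = sol$covs[[j]],
                   fitted = tmod, time_ns = ds$time_ns,
                   n_components = n_components),
              class = "multiexp_fit")
  })
  attr(fits, "tau") <- sol$tau
  attr(fits, "shift") <- sol$shift
  attr(fits, "chisq_red") <- chisq
  fits
}

# nu(inf) by a joint exponential-decay fit of the whole nu(t) curve,
# nu(t) = nu_inf + sum_i A_i exp(-t / tau_i). When the fit predicts that
# relaxation is still ongoing at the window end (or cannot be fitted), the
# last observed value is used instead and the estimate is flagged incomplete;
# tau_R computed downstream is then an underestimate, as it is for probes
# whose relaxation outlasts the fluorescence lifetime.
estimate_nu_inf <- function(times, nu_t, max_rel = 2L, weights = NULL) {
  t_end <- max(times)
  # weight each nu(t) sample by its reliability; the t = 0 sample is a pure
  # fit extrapolation and is excluded
  w <- if (is.null(weights)) rep(1, length(times)) else weights
  w[1L] <- 0
  last10 <- times >= 0.9 * t_end
  plateau <- mean(nu_t[last10])
  amp0 <- nu_t[2L] - plateau
  fit_n <- function(n_rel) {
    tryCatch({
      resid_fn <- function(p) {
        (p[1L] + drop(exp(-outer(times, 1 / exp(p[n_rel + 1L + seq_len(n_rel)]))) %*%
                        p[1L + seq_len(n_rel)]) - nu_t) * w
      }
      tau0 <- exp(seq(log(t_end / 60), log(t_end / 5), length.out = n_rel))
      minpack.lm::nls.lm(c(plateau, rep(amp0 / n_rel, n_rel), log(tau0)),
                         fn = resid_fn,
                         lower = c(-Inf, rep(-Inf, n_rel), rep(log(0.005), n_rel)),
                         upper = c(Inf, rep(Inf, n_rel), rep(log(t_end / 2), n_rel)),
                         control = minpack.lm::nls.lm.control(maxiter = 300))
    }, error = function(e) NULL)
  }
  # smallest number of relaxation components that the nu(t) data support: an
  # extra component must reduce the weighted SSR substantially, otherwise it
  # only chases the reconstruction noise floor
  fit <- fit_n(1L)
  n_rel <- 1L
  while (n_rel < max_rel) {
    cand <- fit_n(n_rel + 1L)
    if (is.null(cand)) break
    if (!is.null(fit) && cand$deviance > 0.8 * fit$deviance) break
    fit <- cand
    n_rel <- n_rel + 1L
  }
  if (is.null(fit))
    return(list(nu_inf = nu_t[length(nu_t)], incomplete = TRUE,
                curve = nu_t))
  p <- fit$par
  A <- p[1L + seq_len(n_rel)]
  tau <- exp(p[n_rel + 1L + seq_len(n_rel)])
  remaining <- sum(abs(A) * exp(-t_end / tau))
  # unrelaxed at the window end only if the predicted residual relaxation is
  # a substantial fraction of the fitted amplitude (small absolute leftovers
  # are indistinguishable from the reconstruction noise floor)
  if (remaining > max(20, 0.1 * sum(abs(A))))
    return(list(nu_inf = nu_t[length(nu_t)], incomplete = TRUE,
                curve = nu_t))
  curve <- p[1L] + drop(exp(-outer(times, 1 / tau)) %*% A)
  list(nu_inf = p[1L], incomplete = FALSE, amplitudes = A, tau = tau,
       curve = curve)
}

#' Reconstruct time-resolved emission spectra (TRES)
#'
#' Spectral reconstruction from per-wavelength reconvolution fits and the
#' steady-state emission spectrum: at each wavelength the fitted (deconvolved)
#' decay is scaled so that its time integral equals the steady-state intensity
#' there, `S(lambda, t) = D(lambda, t) SS(lambda) / int D(lambda, t) dt`. The
#' wavelength axis is converted to wavenumber (cm^-1); intensities acquire
#' the lambda^2 Jacobian so that spectral shapes are correct per unit
#' wavenumber.
#'
#' @param fits list of [fit_decay_reconvolution] results, one per wavelength.
#' @param wavelengths emission wavelengths (nm) matching `fits`.
#' @param steady_state an `emission_spectrum` covering the wavelength range.
#' @param times time points (ns, from 0) at which to evaluate the surface.
#' @param jacobian apply the lambda^2 Jacobian for the nm -> cm^-1 axis
#'   change (default TRUE).
#' @return An object of class `tres`: `times` (ns), `wavenumber` (cm^-1,
#'   increasing), `intensities` (time x wavenumber), and `lambda_surface`
#'   (time x wavelength, before the axis change; its per-wavelength time
#'   integral reproduces the steady-state spectrum exactly).
#' @export
reconstruct_tres <- function(fits, wavelengths, steady_state, times,
                             jacobian = TRUE) {
  ss <- stats::approx(steady_state$wavelengths, steady_state$intensities,
                      xout = wavelengths, rule = 1)$y
  if (any(is.na(ss))) stop("steady-state spectrum does not cover the decay wavelengths")
  nl <- length(wavelengths)
  lam_surf <- matrix(0, length(times), nl)
  lam_sd <- matrix(0, length(times), nl)
  for (j in seq_len(nl)) {
    d <- model_decay(fits[[j]], times)
    z <- pracma::trapz(times, d)
    if (z <= 0) stop(sprintf("zero time-integral at %g nm", wavelengths[j]))
    lam_surf[, j] <- d * ss[j] / z
    cv <- fits[[j]]$alpha_cov
    if (!is.null(cv)) {
      # propagate amplitude covariance: Var D(t) = b(t)' Cov b(t)
      bt <- exp(-outer(times, 1 / fits[[j]]$tau))
      lam_sd[, j] <- sqrt(pmax(rowSums((bt %*% cv) * bt), 0)) * ss[j] / z
    }
  }
  nu <- 1e7 / wavelengths
  jac <- if (jacobian) wavelengths^2 else rep(1, nl)
  surf <- sweep(lam_surf, 2L, jac, `*`)
  sds <- sweep(lam_sd, 2L, jac, `*`)
  ord <- order(nu)
  structure(list(times = times, wavenumber = nu[ord],
                 intensities = surf[, ord, drop = FALSE],
                 sd = sds[, ord, drop = FALSE],
                 lambda_surface = lam_surf, wavelengths = wavelengths,
                 jacobian = jacobian),
            class = "tres")
}

# Fraser-Suzuki (log-normal) lineshape with exact peak and FWHM.
# asym = 0 reduces to a Gaussian; negative asym tails toward low wavenumber.
lognormal_lineshape <- function(nu, height, peak, fwhm, asym) {
  if (abs(asym) < 1e-6)
    return(height * exp(-4 * log(2) * ((nu - peak) / fwhm)^2))
  delta <- fwhm * asym / sinh(asym)
  arg <- 1 + 2 * asym * (nu - peak) / delta
  out <- numeric(length(nu))
  ok <- arg > 0
  out[ok] <- height * exp(-log(2) * (log(arg[ok]) / asym)^2)
  out
}

#' Peak position and width of a TRES slice
#'
#' Fits a log-normal (Fraser-Suzuki) lineshape to one time-slice of a TRES
#' surface and returns the fitted peak position nu(t) and full width at half
#' maximum FWHM(t). If the maximum sits on the grid edge the slice cannot be
#' fitted; the argmax is returned with a warning and `fitted = FALSE`.
#'
#' @param nu wavenumber axis (cm^-1, increasing).
#' @param intensity slice intensities.
#' @param sigma optional per-point uncertainties (same units as
#'   `intensity`); points are weighted by 1/sigma, with a floor at 1e-3 of
#'   the slice maximum to bound the dynamic range.
#' @return list with `nu_peak`, `fwhm`, `asym`, `fitted`.
#' @export
tres_peak <- function(nu, intensity, sigma = NULL) {
  wts <- if (is.null(sigma) || all(sigma <= 0)) rep(1, length(nu))
         else 1 / pmax(sigma, 1e-3 * max(intensity))
  k <- which.max(intensity)
  if (k == 1L || k == length(nu)) {
    warning("slice maximum at grid edge; returning argmax without a fit")
    return(list(nu_peak = nu[k], fwhm = NA_real_, asym = NA_real_,
                fitted = FALSE))
  }
  h0 <- intensity[k]
  half <- h0 / 2
  lo <- nu[which(intensity >= half)[1L]]
  hi <- nu[rev(which(intensity >= half))[1L]]
  fwhm0 <- max(hi - lo, diff(range(nu)) / 10)
  resid_fn <- function(p) {
    (lognormal_lineshape(nu, exp(p[1L]), p[2L], exp(p[3L]), p[4L]) - intensity) * wts
  }
  fit <- minpack.lm::nls.lm(c(log(h0), nu[k], log(fwhm0), -0.1),
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-13, ptol = 1e-13))
  p <- fit$par
  list(nu_peak = p[2L], fwhm = exp(p[3L]), asym = p[4L], fitted = TRUE)
}

#' Lippert-Mataga orientation polarizability
#'
#' `Delta f = (eps - 1)/(2 eps + 1) - (n^2 - 1)/(2 n^2 + 1)` for a solvent
#' with dielectric constant `eps` and refractive index `n`. Zero for apolar
#' solvents (`eps = n^2`).
#'
#' @param epsilon dielectric constant (>= 1).
#' @param n refractive index (>= 1).
#' @return Delta f (dimensionless). Vectorized.
#' @export
lippert_mataga_deltaf <- function(epsilon, n) {
  if (any(epsilon < 1) || any(n < 1)) stop("epsilon and n must be >= 1")
  (epsilon - 1) / (2 * epsilon + 1) - (n^2 - 1) / (2 * n^2 + 1)
}

#' Time-zero emission maximum from a solvent series
#'
#' Simplified time-zero estimate: the dye's Stokes shift `nuA - nuE` measured
#' in a series of solvents is regressed on the Lippert-Mataga polarity
#' function `Delta f`; the intercept at `Delta f -> 0` is the intrinsic
#' (polarity-free) Stokes shift, and `nu(0) = nuA(system) - intercept`.
#'
#' @param series data.frame with columns `epsilon`, `n`, `nuA_cm1`, `nuE_cm1`
#'   (one row per solvent).
#' @param nuA_in_system absorption maximum (cm^-1) of the dye in the system
#'   of interest.
#' @return list with `nu0` (cm^-1), `intercept`, `slope`, `intercept_se`.
#' @export
estimate_time_zero <- function(series, nuA_in_system) {
  df <- lippert_mataga_deltaf(series$epsilon, series$n)
  if (length(unique(df)) < 2L)
    stop("need >= 2 solvents with distinct Delta f to extrapolate")
  shift <- series$nuA_cm1 - series$nuE_cm1
  fit <- stats::lm(shift ~ df)
  co <- summary(fit)$coefficients
  list(nu0 = nuA_in_system - co[1L, 1L],
       intercept = co[1L, 1L], slope = co[2L, 1L],
       intercept_se = co[1L, 2L])
}

#' Total dynamic Stokes shift
#'
#' `Delta nu = nu(0) - nu(inf)`: the full spectral relaxation amplitude, a
#' readout of the polarity (hydration) of the probe environment.
#'
#' @param nu0,nu_inf TRES peak positions (cm^-1) before and after relaxation.
#' @return Delta nu (cm^-1).
#' @export
total_shift <- function(nu0, nu_inf) {
  stopifnot(is.finite(nu0), is.finite(nu_inf))
  nu0 - nu_inf
}

#' Integrated relaxation time
#'
#' `tau_R = int_0^inf (nu(t) - nu(inf)) / Delta_nu dt`, evaluated by the
#' trapezoid rule on the sampled window plus an analytic exponential-tail
#' correction fitted to the last decade of the correlation function
#' `C(t) = (nu(t) - nu(inf)) / Delta_nu`. If C has not decayed at the end of
#' the window the tail cannot be fitted; the windowed integral is returned
#' with attribute `tail_unreliable = TRUE`.
#'
#' @param times time grid (ns, from 0; may be non-uniform).
#' @param nu_t TRES peak positions nu(t) (cm^-1).
#' @param nu_inf relaxed position (cm^-1).
#' @param delta_nu total shift (cm^-1), > 0.
#' @return tau_R (ns).
#' @export
relaxation_time <- function(times, nu_t, nu_inf, delta_nu) {
  if (delta_nu <= 0) stop("delta_nu must be > 0")
  C <- (nu_t - nu_inf) / delta_nu
  tau <- pracma::trapz(times, C)
  cT <- C[length(C)]
  T_end <- max(times)
  if (cT > 5e-3) {
    # last decade of C: points with C in [cT, 10 cT], log-linear fit
    sel <- which(C >= cT & C <= 10 * cT & C > 0)
    sel <- sel[sel > length(C) / 2]
    ok <- FALSE
    if (length(sel) >= 3L) {
      fit <- stats::lm(log(C[sel]) ~ times[sel])
      rate <- -stats::coef(fit)[2L]
      # accept only a resolvable tail (time constant shorter than the window)
      if (is.finite(rate) && rate > 1 / T_end) {
        tau <- tau + cT / rate
        ok <- TRUE
      }
    }
    if (!ok) {
      warning("C(t) has not decayed at the window end; tail omitted")
      attr(tau, "tail_unreliable") <- TRUE
    }
  }
  tau
}

#' Full TDFS analysis of a wavelength-resolved decay set
#'
#' Runs the complete pipeline: per-wavelength reconvolution fits, TRES
#' reconstruction against the steady-state spectrum, log-normal peak tracking
#' nu(t) / FWHM(t), plateau estimation of nu(inf), the total shift
#' `Delta nu = nu(0) - nu(inf)` and the integrated relaxation time tau_R.
#'
#' nu(inf) is the mean of nu(t) over the last 10 percent of the analysis
#' window when the relaxation has levelled off there; otherwise the last
#' available value is used and the result is flagged `incomplete_relaxation`
#' (tau_R is then an underestimate, as expected when relaxation outlasts the
#' fluorescence lifetime). nu(0) defaults to the t = 0 TRES peak; an external
#' estimate (deep-temperature scan or [estimate_time_zero]) can be supplied.
#'
#' @param ds a [decay_set].
#' @param steady_state an `emission_spectrum`.
#' @param times analysis time grid (ns); default: dense near zero, extending
#'   to 40 percent of the acquisition window (beyond that the histograms are
#'   essentially empty and the fitted extrapolation is data-free).
#' @param method `"global"` (default): one shared lifetime basis across all
#'   wavelengths ([fit_decay_set_global]); `"individual"`: independent
#'   per-wavelength fits with `n_components` components each.
#' @param n_components exponential components (shared basis size for the
#'   global method; per-decay count for the individual method, where
#'   components are added beyond 3 only until the fit is satisfactory).
#' @param nu0 optional external time-zero position (cm^-1).
#' @param jacobian apply the lambda^2 Jacobian (default TRUE).
#' @param min_shift_cm1 below this recovered shift the sample is reported as
#'   non-relaxing (`no_relaxation = TRUE`, tau_R = 0); default 25 cm^-1.
#' @return An object of class `relaxation_result`: `nu0`, `nu_inf`,
#'   `delta_nu`, `tau_r` (ns), `times`, `nu_t`, `fwhm_t`, `C_t`, `fits`,
#'   `tres`, flags `incomplete_relaxation`, `no_relaxation`.
#' @export
analyze_decay_set <- function(ds, steady_state, times = NULL,
                              method = c("global", "individual"),
                              n_components = NULL, nu0 = NULL,
                              jacobian = TRUE, min_shift_cm1 = 25) {
  method <- match.arg(method)
  if (is.null(times)) {
    # analyze only where the histograms still carry counts: beyond ~40% of
    # the acquisition window the fitted extrapolation is data-free
    t_end <- 0.4 * max(ds$time_ns)
    times <- unique(c(seq(0, min(1, t_end), by = 0.01),
                      seq(1, min(5, t_end), by = 0.05),
                      seq(5, t_end, by = 0.2)))
  }
  t_end <- max(times)
  fits <- if (method == "global")
    fit_decay_set_global(ds, n_components = n_components %||% 9L)
  else
    lapply(seq_along(ds$wavelengths), function(j)
      fit_decay_reconvolution_auto(ds$decays[, j], ds$irf, ds$time_ns,
                                   n_components = n_components %||% 3L))
  tr <- reconstruct_tres(fits, ds$wavelengths, steady_state, times,
                         jacobian = jacobian)
  pk <- lapply(seq_along(times), function(i)
    tres_peak(tr$wavenumber, tr$intensities[i, ], sigma = tr$sd[i, ]))
  nu_t <- vapply(pk, `[[`, numeric(1), "nu_peak")
  fwhm_t <- vapply(pk, `[[`, numeric(1), "fwhm")
  # weight nu(t) samples by the propagated reliability of their slice
  rel_sd <- vapply(seq_along(times), function(i) {
    m <- max(tr$intensities[i, ])
    if (m <= 0) Inf else max(tr$sd[i, ]) / m
  }, numeric(1))
  w_nu <- 1 / pmax(rel_sd, max(1e-4, stats::median(rel_sd) / 10))
  est <- estimate_nu_inf(times, nu_t, weights = w_nu)
  incomplete <- est$incomplete
  nu_inf <- est$nu_inf
  if (is.null(nu0)) nu0 <- nu_t[1L]
  dnu <- total_shift(nu0, nu_inf)
  no_relax <- dnu < min_shift_cm1
  # complete relaxation: integrate the fitted smooth nu(t) (free of slice
  # noise); incomplete: integrate the raw curve against the last observed
  # value, which underestimates tau_R by construction
  tau_r <- if (no_relax) 0 else
    relaxation_time(times, est$curve, nu_inf, dnu)
  structure(list(nu0 = nu0, nu_inf = nu_inf, delta_nu = dnu,
                 tau_r = as.numeric(tau_r),
                 times = times, nu_t = nu_t, fwhm_t = fwhm_t,
                 C_t = if (dnu > 0) (nu_t - nu_inf) / dnu else rep(NA_real_, length(nu_t)),
                 fits = fits, tres = tr,
                 incomplete_relaxation = incomplete,
                 no_relaxation = no_relax),
            class = "relaxation_result")
}

#' @export
print.relaxation_result <- function(x, ...) {
  cat(sprintf("relaxation_result: nu0 = %.0f cm-1, nu_inf = %.0f cm-1\n",
              x$nu0, x$nu_inf))
  cat(sprintf("  delta_nu = %.0f cm-1, tau_R = %.3f ns%s%s\n",
              x$delta_nu, x$tau_r,
              if (x$incomplete_relaxation) " [incomplete relaxation]" else "",
              if (x$no_relaxation) " [no relaxation detected]" else ""))
  invisible(x)
}

#' Write / read decay sets and TDFS results as CSV and JSON
#'
#' Long-format decays CSV (`wavelength_nm`, `time_ns`, `counts`), IRF CSV
#' (`time_ns`, `counts`), and a `relaxation_result` as JSON plus a CSV of the
#' nu(t), FWHM(t), C(t) series.
#'
#' @param ds a [decay_set]; `path` file paths; `res` a `relaxation_result`;
#'   `dir` output directory.
#' @name tdfs_io
#' @export
write_decay_csv <- function(ds, path, irf_path) {
  long <- data.frame(
    wavelength_nm = rep(ds$wavelengths, each = length(ds$time_ns)),
    time_ns = rep(ds$time_ns, length(ds$wavelengths)),
    counts = as.vector(ds$decays))
  utils::write.csv(long, path, row.names = FALSE)
  utils::write.csv(data.frame(time_ns = ds$time_ns, counts = ds$irf),
                   irf_path, row.names = FALSE)
  invisible(path)
}

#' @rdname tdfs_io
#' @export
read_decay_csv <- function(path, irf_path, temperature = 23) {
  long <- utils::read.csv(path)
  need <- c("wavelength_nm", "time_ns", "counts")
  if (!all(need %in% names(long)))
    stop(sprintf("decay CSV %s must have columns %s", path,
                 paste(need, collapse = ", ")))
  irf <- utils::read.csv(irf_path)
  if (!all(c("time_ns", "counts") %in% names(irf)))
    stop(sprintf("IRF CSV %s must have columns time_ns, counts", irf_path))
  wl <- sort(unique(long$wavelength_nm))
  tt <- sort(unique(long$time_ns))
  m <- matrix(0, length(tt), length(wl))
  for (j in seq_along(wl)) {
    sub <- long[long$wavelength_nm == wl[j], ]
    m[, j] <- sub$counts[order(sub$time_ns)]
  }
  decay_set(tt, irf$counts[order(irf$time_ns)], m, wl, temperature)
}

#' @rdname tdfs_io
#' @export
write_relaxation_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(nu0_cm1 = res$nu0, nu_inf_cm1 = res$nu_inf,
         delta_nu_cm1 = res$delta_nu, tau_r_ns = res$tau_r,
         incomplete_relaxation = res$incomplete_relaxation,
         no_relaxation = res$no_relaxation),
    file.path(dir, "relaxation_result.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(time_ns = res$times, nu_cm1 = res$nu_t,
                              fwhm_cm1 = res$fwhm_t, C = res$C_t),
                   file.path(dir, "relaxation_series.csv"), row.names = FALSE)
  invisible(dir)
}

#' Run the decay -> TDFS pipeline from CSV inputs
#'
#' Thin driver over [read_decay_csv], [analyze_decay_set] and
#' [write_relaxation_result].
#'
#' @param decays_csv,irf_csv,steady_csv input file paths (steady-state CSV:
#'   columns `wavelength_nm`, `intensity`).
#' @param out_dir output directory.
#' @param ... passed to [analyze_decay_set].
#' @return the `relaxation_result`, invisibly.
#' @export
run_tdfs_pipeline <- function(decays_csv, irf_csv, steady_csv, out_dir, ...) {
  ds <- read_decay_csv(decays_csv, irf_csv)
  sstab <- utils::read.csv(steady_csv)
  if (!all(c("wavelength_nm", "intensity") %in% names(sstab)))
    stop(sprintf("steady-state CSV %s must have columns wavelength_nm, intensity",
                 steady_csv))
  ss <- emission_spectrum(sstab$wavelength_nm, sstab$intensity)
  res <- analyze_decay_set(ds, ss, ...)
  write_relaxation_result(res, out_dir)
  invisible(res)
}
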