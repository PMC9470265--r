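# shared fixtures built in code

# small phase-separated scene: 3 circles (one Janus two-phase) + 2 ellipses
standard_scene <- function(seed = 3, noise = "poisson") {
  cfg <- gp_config("pro12a")
  ves <- list(
    list(center = c(40, 40), radius = 16,
         phases = list(list(peak = 440, width = 30, amplitude = 2000),
                       list(peak = 490, width = 30, amplitude = 2000)),
         boundaries = c(0, 180)),
    list(center = c(40, 120), radius = 18,
         phases = list(list(peak = 450, width = 35, amplitude = 1800))),
    list(center = c(120, 40), radius = 14,
         phases = list(list(peak = 470, width = 30, amplitude = 2200))),
    list(center = c(120, 120), radius = 12, axis_ratio = 2, angle_deg = 30,
         phases = list(list(peak = 450, width = 30, amplitude = 2000))),
    list(center = c(80, 80), radius = 10, axis_ratio = 2, angle_deg = 100,
         phases = list(list(peak = 450, width = 30, amplitude = 2000))))
  scene <- make_vesicle_image(160, ves, channel_grid("pro12a"), cfg,
                              background = 20, noise = noise, seed = seed)
  scene$cfg <- cfg
  scene
}

# small, fast decay set for unit tests (short window, short lifetime)
small_decay_sim <- function(delta_nu = 1200, tau_rel = 0.8, seed = 1,
                            noise = TRUE) {
  make_decay_set(nu_inf = 17500, delta_nu = delta_nu, tau_rel = tau_rel,
                 lifetime = 2, window = 25, dt = 0.025, seed = seed,
                 noise = noise)
}

# independent connected-component labelling (8-connectivity BFS) used as the
# clustering oracle
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), 1L)
    lab[i, j] <- cur
    while (nrow(queue)) {
      p <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        r <- p[1L] + di; c <- p[2L] + dj
        if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue <- rbind(queue, c(r, c))
        }
      }
    }
  }
  lab
}

# naive between-class-variance maximizer over a 256-bin histogram, written
# independently of the implementation (direct per-cut class statistics)
otsu_brute <- function(field, n_bins = 256L) {
  v <- as.vector(field)
  edges <- seq(min(v), max(v), length.out = n_bins + 1L)
  bin <- pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  best <- -Inf; best_k <- NA
  for (k in seq_len(n_bins - 1L)) {
    lo <- bin <= k
    n0 <- sum(lo); n1 <- length(v) - n0
    if (n0 == 0L || n1 == 0L) next
    mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
    m0 <- mean(mids[bin[lo]]); m1 <- mean(mids[bin[!lo]])
    s <- (n0 / length(v)) * (n1 / length(v)) * (m0 - m1)^2
    if (s > best) { best <- s; best_k <- k }
  }
  edges[best_k + 1L]
}
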