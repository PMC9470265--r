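test_that("GP is the normalized blue/red contrast bounded by +-1", {
  expect_equal(gp_value(100, 100), 0)
  expect_equal(gp_value(100, 0), 1)
  expect_equal(gp_value(0, 100), -1)
  expect_equal(gp_value(3, 1), 0.5)
  expect_true(is.na(gp_value(0, 0)))
  expect_error(gp_value(-1, 5), "nonnegative")
  # range, scale invariance, monotonicity over random pairs
  set.seed(42)
  ib <- runif(200, 0, 1e4); ir <- runif(200, 0, 1e4)
  g <- gp_value(ib, ir)
  expect_true(all(g >= -1 & g <= 1))
  expect_equal(gp_value(7.3 * ib, 7.3 * ir), g)
  expect_true(all(diff(gp_value(50, seq(1, 100, by = 1))) < 0))
})

test_that("gp_map selects the configured reference channels pixel-wise", {
  centers <- channel_grid("pro12a")
  cfg <- gp_config("pro12a")
  arr <- array(10, dim = c(20, 6, 6))
  img <- spectral_image(arr, centers)
  m <- gp_map(img, cfg)
  expect_true(all(m$values == 0))
  expect_true(all(m$defined))
  arr2 <- arr
  arr2[m$ch_b, , ] <- 2 * arr2[m$ch_r, , ]
  m2 <- gp_map(spectral_image(arr2, centers), cfg)
  expect_equal(unique(as.vector(m2$values)), 1 / 3)
  # both reference planes zero -> undefined
  arr3 <- array(0, dim = c(20, 6, 6))
  m3 <- gp_map(spectral_image(arr3, centers), cfg)
  expect_false(any(m3$defined))
})

test_that("Otsu threshold equals the brute-force between-class-variance maximizer", {
  set.seed(19)
  for (rep in 1:100) {
    n0 <- sample(50:400, 1); n1 <- sample(50:400, 1)
    field <- matrix(c(rnorm(n0, 10, 1), rnorm(n1, 200, 5)), ncol = 1)
    expect_equal(otsu_threshold(field), otsu_brute(field))
  }
})

test_that("Otsu mask separates a bright ring from background", {
  set.seed(7)
  field <- matrix(rnorm(100 * 100, 10, 1), 100)
  ring <- (row(field) - 50)^2 + (col(field) - 50)^2
  ring <- ring <= 30^2 & ring >= 26^2
  field[ring] <- rnorm(sum(ring), 200, 5)
  m <- otsu_mask(field)
  expect_true(all(m[ring]))
  expect_lt(mean(m[!ring]), 0.01)   # false positives < 1%
  # two-valued field: threshold strictly between, mask = the bright value
  f2 <- matrix(c(0, 255, 0, 255), 2)
  th <- otsu_threshold(f2)
  expect_gt(th, 0); expect_lt(th, 255)
  expect_identical(otsu_mask(f2), f2 == 255)
  expect_error(otsu_threshold(matrix(5, 3, 3)), "constant")
})

test_that("density clustering matches connected components for separated solid objects", {
  mask <- matrix(FALSE, 80, 80)
  for (ctr in list(c(20, 20), c(60, 60), c(20, 62))) {
    d2 <- (row(mask) - ctr[1])^2 + (col(mask) - ctr[2])^2
    mask[d2 <= 8^2] <- TRUE
  }
  cl <- cluster_vesicles(mask, eps = 3, min_samples = 8)
  expect_length(cl, 3L)
  lab <- label_components(mask)
  for (k in seq_along(cl)) {
    labs <- unique(lab[cl[[k]]])
    expect_length(labs, 1L)                       # one component per cluster
    expect_equal(nrow(cl[[k]]), sum(lab == labs)) # and all of it
  }
  expect_length(cluster_vesicles(matrix(FALSE, 5, 5)), 0L)
})

test_that("two rings separated by more than 3 eps form exactly two clusters", {
  mask <- matrix(FALSE, 90, 90)
  for (ctr in list(c(25, 25), c(65, 65))) {
    d2 <- sqrt((row(mask) - ctr[1])^2 + (col(mask) - ctr[2])^2)
    mask[abs(d2 - 12) <= 1.5] <- TRUE
  }
  cl <- cluster_vesicles(mask, eps = 3, min_samples = 8)
  expect_length(cl, 2L)
  expect_equal(sum(vapply(cl, nrow, 1L)), sum(mask))  # rings survive intact
})

test_that("moment eccentricity: disc near 0, 2:1 ellipse near sqrt(0.75), cutoff splits them", {
  sz <- 101
  d2 <- (row(matrix(0, sz, sz)) - 51)^2 + (col(matrix(0, sz, sz)) - 51)^2
  disc <- which(d2 <= 30^2, arr.ind = TRUE)
  expect_lt(pixel_eccentricity(disc), 0.1)
  x <- row(matrix(0, sz, sz)) - 51; y <- col(matrix(0, sz, sz)) - 51
  ell <- which((x / 40)^2 + (y / 20)^2 <= 1, arr.ind = TRUE)
  ecc <- pixel_eccentricity(ell)
  expect_equal(as.numeric(ecc), sqrt(0.75), tolerance = 0.01)
  # direct second-moment computation as an independent check
  mu20 <- mean((ell[, 1] - mean(ell[, 1]))^2)
  mu02 <- mean((ell[, 2] - mean(ell[, 2]))^2)
  expect_equal(as.numeric(ecc), sqrt(1 - min(mu20, mu02) / max(mu20, mu02)),
               tolerance = 1e-6)
  # under the 0.5 cutoff the ellipse is discarded and the circle retained
  expect_gte(as.numeric(ecc), 0.5)
  expect_lt(pixel_eccentricity(disc), 0.5)
  line <- cbind(1:10, 1:10)
  expect_true(isTRUE(attr(pixel_eccentricity(line), "degenerate")))
})

test_that("vesicle GP statistics use defined pixels only", {
  v <- matrix(NA_real_, 4, 4)
  v[1, 1:3] <- c(0.2, 0.2, 0.2)
  gp <- structure(list(values = v, defined = !is.na(v)), class = "gp_map")
  st <- vesicle_gp_stats(gp, cbind(1, 1:3))
  expect_equal(st$gp_median, 0.2)
  expect_equal(st$gp_sd, 0)
  v2 <- matrix(c(-1, 0, 1, NA), 2)
  gp2 <- structure(list(values = v2, defined = !is.na(v2)), class = "gp_map")
  st2 <- vesicle_gp_stats(gp2, which(!is.na(v2) | is.na(v2), arr.ind = TRUE))
  expect_equal(st2$gp_median, 0)
  expect_equal(st2$n_defined, 3L)
  expect_error(vesicle_gp_stats(gp, cbind(4, 4)), "no defined")
})

test_that("end-to-end detection: planted ellipses discarded, GP medians recovered", {
  scene <- standard_scene(seed = 3)
  det <- detect_vesicles(scene$image, scene$cfg)
  expect_equal(nrow(det$vesicles), 5L)
  expect_equal(sum(det$vesicles$retained), 3L)
  expect_true(all(det$vesicles$eccentricity[!det$vesicles$retained] >= 0.5))
  # uniform vesicles: detected GP median within 0.02 of the analytic value
  for (k in 2:3) {
    truth <- scene$truth$gp_analytic[scene$truth$vesicle == k]
    row <- det$vesicles[abs(det$vesicles$centroid_row -
                              c(NA, 40, 120)[k]) < 3 &
                        abs(det$vesicles$centroid_col -
                              c(NA, 120, 40)[k]) < 3, ]
    expect_equal(row$gp_median, truth, tolerance = 0.02)
  }
})

test_that("membrane profile resolves the two phases of a Janus vesicle", {
  cfg <- gp_config("pro12a")
  ves <- list(list(center = c(50, 50), radius = 20,
                   phases = list(list(peak = 440, width = 30, amplitude = 2000),
                                 list(peak = 490, width = 30, amplitude = 2000)),
                   boundaries = c(0, 180)))
  scene <- make_vesicle_image(100, ves, channel_grid("pro12a"), cfg,
                              background = 5, seed = 4)
  det <- detect_vesicles(scene$image, cfg)
  prof <- membrane_profile(det$gp, det$clusters[[1]])
  g <- scene$truth$gp_analytic
  ph2 <- prof$angle_deg > 10 & prof$angle_deg < 170    # boundaries excluded
  ph1 <- prof$angle_deg > 190 & prof$angle_deg < 350
  expect_equal(median(prof$gp[ph1]), g[1], tolerance = 0.03)
  expect_equal(median(prof$gp[ph2]), g[2], tolerance = 0.03)
  # transition width: crossing the midpoint happens within 3 steps of 0/180
  mid <- mean(g)
  cross <- which(diff(sign(prof$gp - mid)) != 0)
  expect_true(all(pmin(abs(prof$angle_deg[cross] - 180),
                       abs(prof$angle_deg[cross] - 360),
                       prof$angle_deg[cross]) <= 3))
})

test_that("membrane profile is constant for a uniform vesicle and rotates with it", {
  cfg <- gp_config("pro12a")
  mk <- function(bnd) {
    ves <- list(list(center = c(50, 50), radius = 20,
                     phases = list(list(peak = 440, width = 30, amplitude = 2000),
                                   list(peak = 490, width = 30, amplitude = 2000)),
                     boundaries = bnd))
    scene <- make_vesicle_image(100, ves, channel_grid("pro12a"), cfg,
                                background = 5, noise = "none", seed = 1)
    det <- detect_vesicles(scene$image, cfg)
    membrane_profile(det$gp, det$clusters[[1]])
  }
  p0 <- mk(c(0, 180))
  p30 <- mk(c(30, 210))
  shift <- 30L
  rotated <- c(p0$gp[(360 - shift + 1):360], p0$gp[1:(360 - shift)])
  expect_lt(median(abs(p30$gp - rotated), na.rm = TRUE), 0.02)

  ves_u <- list(list(center = c(50, 50), radius = 20,
                     phases = list(list(peak = 450, width = 30, amplitude = 2000))))
  scene_u <- make_vesicle_image(100, ves_u, channel_grid("pro12a"), cfg,
                                background = 5, seed = 2)
  det_u <- detect_vesicles(scene_u$image, cfg)
  prof_u <- membrane_profile(det_u$gp, det_u$clusters[[1]])
  expect_lt(sd(prof_u$gp, na.rm = TRUE), 0.02)
})

test_that("delta GP is the ordered-minus-disordered difference", {
  expect_equal(delta_gp(0.5, -0.26), 0.76)
  expect_equal(delta_gp(0.3, 0.3), 0)
  expect_error(delta_gp(NA, 0), "finite")
  # recovery from a planted two-phase vesicle within 0.03
  scene <- standard_scene(seed = 8)
  gp <- gp_map(scene$image, scene$cfg)
  g <- scene$truth$gp_analytic[scene$truth$vesicle == 1]
  med <- vapply(1:2, function(p) {
    px <- which(scene$labels == 1 & scene$phase == p, arr.ind = TRUE)
    vesicle_gp_stats(gp, px)$gp_median
  }, numeric(1))
  expect_equal(delta_gp(med[1], med[2]), delta_gp(g[1], g[2]),
               tolerance = 0.03)
})

test_that("internalization index is internal over membrane intensity", {
  prof <- c(0, 1, 100, 1, 50, 50, 1, 100, 1, 0)
  expect_equal(internalization_index(prof, c(3, 8), 5:6), 0.5)
  expect_equal(internalization_index(prof, c(3, 8), c(3, 8) * 0 + 5), 0.5)
  expect_equal(internalization_index(c(100, 10, 100), c(1, 3), 2), 0.1)
  expect_equal(internalization_index(c(100, 100, 100), c(1, 3), 2), 1)
  expect_equal(internalization_index(c(100, 0, 100), c(1, 3), 2), 0)
  expect_error(internalization_index(prof, c(3, 5), 5:6), "disjoint")
  expect_error(internalization_index(c(0, 0, 0), c(1, 3), 2), "undefined")
  # background subtraction happens before the ratio
  expect_equal(internalization_index(c(110, 60, 110), c(1, 3), 2,
                                     background = 10), 0.5)
})

test_that("noisy synthetic line profiles recover the planted fraction", {
  for (f in c(0, 0.4, 1)) {
    sim <- make_internalization_profile(f, noise_sd = 0.02, seed = 5)
    idx <- internalization_index(sim$profile, sim$membrane_peaks,
                                 sim$internal_region)
    expect_equal(idx, f, tolerance = 0.05)
  }
})

test_that("run_gp_pipeline writes a reproducible vesicle table", {
  scene <- standard_scene(seed = 3)
  out1 <- file.path(tempdir(), "gp_run1")
  tab1 <- run_gp_pipeline(scene$image, scene$cfg, out_dir = out1)
  expect_equal(sum(tab1$retained), 3)
  expect_true(file.exists(file.path(out1, "vesicle_table.csv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  tab2 <- run_gp_pipeline(scene$image, scene$cfg)
  expect_identical(tab1, tab2)
  # empty image: empty table with a warning, not an error
  blank <- spectral_image(array(0, dim = c(20, 32, 32)), channel_grid("pro12a"))
  expect_warning(tab0 <- run_gp_pipeline(blank, scene$cfg), "no intensity")
  expect_equal(nrow(tab0), 0L)
  unlink(out1, recursive = TRUE)
})
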