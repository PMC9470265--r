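#' Reference-wavelength configuration for GP computation
#'
#' GP contrasts the intensity at a blue-shifted reference wavelength (where
#' the liquid-ordered phase dominates) against a red-shifted one (liquid
#' disordered). Presets for the three probes are shipped as data
#' (`inst/extdata/probes.json`): 423/494 nm for Pro12A, 557/664 nm for NR12S
#' and 583/673 nm for NR12A. Different reference wavelengths can be chosen.
#'
#' @param probe preset name (`"pro12a"`, `"nr12s"`, `"nr12a"`), or `NULL` to
#'   give both wavelengths explicitly.
#' @param lambda_lo,lambda_ld blue / red reference wavelengths (nm);
#'   override the preset when supplied.
#' @return An object of class `gp_config` with `lambda_lo`, `lambda_ld`,
#'   `probe`.
#' @export
gp_config <- function(probe = NULL, lambda_lo = NULL, lambda_ld = NULL) {
  if (!is.null(probe)) {
    presets <- probe_presets()
    probe <- match.arg(tolower(probe), names(presets))
    p <- presets[[probe]]
    if (is.null(lambda_lo)) lambda_lo <- p$lambda_lo
    if (is.null(lambda_ld)) lambda_ld <- p$lambda_ld
  }
  if (is.null(lambda_lo) || is.null(lambda_ld))
    stop("give a probe preset or both lambda_lo and lambda_ld")
  if (lambda_lo >= lambda_ld) stop("lambda_lo must be bluer than lambda_ld")
  structure(list(lambda_lo = lambda_lo, lambda_ld = lambda_ld,
                 probe = if (is.null(probe)) "custom" else probe),
            class = "gp_config")
}

#' Probe presets shipped with the package
#' @return named list of presets (reference wavelengths, excitation, channel grid).
#' @export
probe_presets <- function() {
  jsonlite::read_json(system.file("extdata", "probes.json",
                                  package = "memprobe"),
                      simplifyVector = TRUE)
}

#' Generalized polarization of a blue/red intensity pair
#'
#' GP = (I_B - I_R) / (I_B + I_R), the normalized contrast between the
#' fluorescence intensity at the blue- and red-shifted reference wavelengths.
#' GP ranges between +1 (all intensity blue, maximally ordered/apolar
#' environment) and -1 (all intensity red). Undefined (NA) when both
#' intensities are zero.
#'
#' @param i_b,i_r nonnegative intensities at the blue / red reference
#'   wavelength. Vectorized.
#' @return GP value(s) in [-1, 1]; `NA` where `i_b + i_r <= 0`.
#' @examples
#' gp_value(100, 100)  # 0
#' gp_value(100, 0)    # +1
#' @export
gp_value <- function(i_b, i_r) {
  if (any(i_b < 0, na.rm = TRUE) || any(i_r < 0, na.rm = TRUE))
    stop("intensities must be nonnegative")
  s <- i_b + i_r
  out <- ifelse(s > 0, (i_b - i_r) / s, NA_real_)
  out
}

#' Pixel-wise GP map of a spectral image
#'
#' Selects the channel planes nearest the configured reference wavelengths
#' and applies [gp_value] element-wise. Pixels where both planes are zero are
#' undefined (NA).
#'
#' @param img a [spectral_image] (background-corrected).
#' @param cfg a [gp_config].
#' @return An object of class `gp_map`: list with `values` (matrix, NA where
#'   undefined), `defined` (logical matrix), `cfg`, and the channel indices
#'   used (`ch_b`, `ch_r`).
#' @export
gp_map <- function(img, cfg) {
  ch_b <- channel_for_wavelength(img, cfg$lambda_lo)
  ch_r <- channel_for_wavelength(img, cfg$lambda_ld)
  ib <- img$data[ch_b, , ]
  ir <- img$data[ch_r, , ]
  v <- gp_value(ib, ir)
  structure(list(values = v, defined = !is.na(v), cfg = cfg,
                 ch_b = ch_b, ch_r = ch_r,
                 intensity_b = ib, intensity_r = ir),
            class = "gp_map")
}

#' Otsu threshold of an intensity field
#'
#' The threshold over a 256-bin histogram that maximizes the between-class
#' variance of the two resulting intensity classes. `otsu_mask` applies it and
#' returns the foreground (`value > threshold`) mask.
#'
#' @param field numeric matrix with at least two distinct values.
#' @param n_bins histogram bins (default 256).
#' @return `otsu_threshold`: the threshold (intensity units, at a bin edge);
#'   `otsu_mask`: logical matrix.
#' @export
otsu_threshold <- function(field, n_bins = 256L) {
  v <- as.vector(field)
  rng <- range(v)
  if (diff(rng) == 0) stop("constant image: Otsu threshold undefined")
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)                      # class 0: bins 1..k
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  # between-class variance for a cut after bin k
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b[-n_bins])     # cut must leave both classes non-empty
  edges[k + 1L]
}

#' @rdname otsu_threshold
#' @export
otsu_mask <- function(field, n_bins = 256L) {
  field > otsu_threshold(field, n_bins)
}

#' Density-based clustering of foreground pixels (DBSCAN)
#'
#' Isolates single vesicles from a foreground mask: pixels with at least
#' `min_samples` neighbors (self included) within `eps` are core points;
#' clusters grow through density-connected cores; non-core pixels adjacent to
#' a core join its cluster; remaining pixels are noise and dropped.
#'
#' @param mask logical matrix (foreground = TRUE).
#' @param eps neighborhood radius (px).
#' @param min_samples minimum neighborhood size for a core point.
#' @return list of clusters, each a 2-column matrix (row, col) of pixel
#'   coordinates; empty list for an empty mask.
#' @export
cluster_vesicles <- function(mask, eps = 3, min_samples = 8L) {
  pts <- which(mask, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0L) return(list())
  # grid-bucket neighbor search: points within eps live in adjacent cells
  cell <- cbind(floor(pts[, 1L] / eps), floor(pts[, 2L] / eps))
  key <- paste(cell[, 1L], cell[, 2L])
  bucket <- split(seq_len(n), key)
  nbr <- vector("list", n)
  eps2 <- eps^2
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      k <- paste(cell[i, 1L] + dr, cell[i, 2L] + dc)
      b <- bucket[[k]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- (pts[cand, 1L] - pts[i, 1L])^2 + (pts[cand, 2L] - pts[i, 2L])^2
    nbr[[i]] <- cand[d2 <= eps2]
  }
  core <- lengths(nbr) >= min_samples
  label <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || label[i] != 0L) next
    cur <- cur + 1L
    frontier <- i
    label[i] <- cur
    while (length(frontier)) {
      nxt <- integer(0)
      for (j in frontier) {
        for (q in nbr[[j]]) {
          if (label[q] == 0L) {
            label[q] <- cur
            if (core[q]) nxt <- c(nxt, q)
          }
        }
      }
      frontier <- nxt
    }
  }
  lapply(seq_len(cur), function(k) {
    m <- pts[label == k, , drop = FALSE]
    colnames(m) <- c("row", "col")
    m
  })
}

#' Eccentricity of a pixel region
#'
#' Eccentricity of the ellipse with the same second central moments as the
#' pixel set: 0 for a circle, approaching 1 for elongated regions. Objects
#' with eccentricity >= 0.5 are discarded by the vesicle filter.
#'
#' @param pixels 2-column matrix (row, col).
#' @return eccentricity in [0, 1); collinear (degenerate) sets return a value
#'   approaching 1 with attribute `degenerate = TRUE`.
#' @export
pixel_eccentricity <- function(pixels) {
  if (nrow(pixels) < 3L) stop("need >= 3 pixels")
  x <- pixels[, 1L] - mean(pixels[, 1L])
  y <- pixels[, 2L] - mean(pixels[, 2L])
  mu20 <- mean(x^2); mu02 <- mean(y^2); mu11 <- mean(x * y)
  com <- (mu20 + mu02) / 2
  dif <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- com + dif; l2 <- com - dif
  if (l2 <= .Machine$double.eps * l1) {
    out <- 1 - .Machine$double.eps
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  sqrt(1 - l2 / l1)
}

#' Median and standard deviation of GP over a pixel set
#'
#' Statistics are taken over defined GP pixels only; undefined pixels
#' (zero blue+red intensity) are excluded rather than treated as zero.
#'
#' @param gp a [gp_map].
#' @param pixels 2-column matrix (row, col).
#' @return list with `gp_median`, `gp_sd`, `n_defined`.
#' @export
vesicle_gp_stats <- function(gp, pixels) {
  v <- gp$values[pixels]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no defined GP pixels in region")
  list(gp_median = stats::median(v),
       gp_sd = if (length(v) > 1L) stats::sd(v) else 0,
       n_defined = length(v))
}

#' Detect and filter vesicles in a spectral image
#'
#' The automatic pipeline: total-intensity projection, per-image Otsu mask,
#' density-based clustering into candidate objects, eccentricity filter
#' (objects with eccentricity >= `max_eccentricity` are discarded), and
#' per-vesicle GP median / standard deviation over defined GP pixels.
#'
#' @param img a background-corrected [spectral_image].
#' @param cfg a [gp_config].
#' @param eps,min_samples clustering parameters (px, count).
#' @param max_eccentricity retention cutoff (default 0.5).
#' @param min_pixels discard tiny clusters below this size.
#' @return list with `vesicles` (data.frame: label, centroid_row,
#'   centroid_col, n_pixels, eccentricity, gp_median, gp_sd, retained),
#'   `clusters` (pixel sets, all candidates), `gp` (the [gp_map]),
#'   `mask` (Otsu mask).
#' @export
detect_vesicles <- function(img, cfg, eps = 3, min_samples = 8L,
                            max_eccentricity = 0.5, min_pixels = 20L) {
  total <- apply(img$data, c(2L, 3L), sum)
  mask <- tryCatch(otsu_mask(total), error = function(e) {
    warning("no intensity contrast in image; no objects detected")
    matrix(FALSE, nrow(total), ncol(total))
  })
  clusters <- cluster_vesicles(mask, eps = eps, min_samples = min_samples)
  clusters <- clusters[vapply(clusters, nrow, 1L) >= min_pixels]
  gp <- gp_map(img, cfg)
  rows <- lapply(seq_along(clusters), function(k) {
    px <- clusters[[k]]
    ecc <- pixel_eccentricity(px)
    st <- vesicle_gp_stats(gp, px)
    data.frame(label = k,
               centroid_row = mean(px[, 1L]), centroid_col = mean(px[, 2L]),
               n_pixels = nrow(px), eccentricity = as.numeric(ecc),
               gp_median = st$gp_median, gp_sd = st$gp_sd,
               retained = as.numeric(ecc) < max_eccentricity)
  })
  vtab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), centroid_row = numeric(0),
               centroid_col = numeric(0), n_pixels = integer(0),
               eccentricity = numeric(0), gp_median = numeric(0),
               gp_sd = numeric(0), retained = logical(0))
  list(vesicles = vtab, clusters = clusters, gp = gp, mask = mask)
}

# algebraic (Kasa) circle fit: minimizes sum (x^2+y^2 + D x + E y + F)^2
fit_circle <- function(pixels) {
  x <- pixels[, 1L]; y <- pixels[, 2L]
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) stop("circle fit failed (degenerate pixel set)")
  cx <- -sol[1L] / 2; cy <- -sol[2L] / 2
  r2 <- cx^2 + cy^2 - sol[3L]
  if (!is.finite(r2) || r2 <= 0) stop("circle fit failed (non-positive radius)")
  list(center = c(cx, cy), radius = sqrt(r2))
}

#' GP profile along the membrane of a vesicle
#'
#' Estimates the membrane centerline by an algebraic circle fit to the
#' object's pixels, then slides a 3 x 1 px integrating element (3 px radial,
#' 1 px tangential) along the circle at 1 degree steps. At each position the
#' blue and red reference-channel intensities of the element are summed
#' before the GP is computed, which is shot-noise optimal.
#'
#' @param gp a [gp_map] (carries the two reference-channel planes).
#' @param pixels 2-column matrix of the vesicle's pixels.
#' @param step_deg angular sampling step (degrees).
#' @param radial_px radial extent of the integrating element (default 3).
#' @return An object of class `membrane_profile`: data.frame with
#'   `angle_deg` and `gp`; positions where the element has zero total
#'   intensity carry NA.
#' @export
membrane_profile <- function(gp, pixels, step_deg = 1, radial_px = 3L) {
  fit <- fit_circle(pixels)
  dims <- dim(gp$values)
  angles <- seq(0, 360 - step_deg, by = step_deg)
  half <- (radial_px - 1L) / 2
  offs <- seq(-half, half)
  th <- angles * pi / 180
  gpv <- numeric(length(angles))
  for (i in seq_along(angles)) {
    rr <- round(fit$center[1L] + (fit$radius + offs) * cos(th[i]))
    cc <- round(fit$center[2L] + (fit$radius + offs) * sin(th[i]))
    ok <- rr >= 1 & rr <= dims[1L] & cc >= 1 & cc <= dims[2L]
    if (!any(ok)) { gpv[i] <- NA_real_; next }
    idx <- cbind(rr[ok], cc[ok])
    ib <- sum(gp$intensity_b[idx]); ir <- sum(gp$intensity_r[idx])
    gpv[i] <- if (ib + ir > 0) (ib - ir) / (ib + ir) else NA_real_
  }
  structure(data.frame(angle_deg = angles, gp = gpv),
            class = c("membrane_profile", "data.frame"),
            center = fit$center, radius = fit$radius)
}

#' GP difference between ordered and disordered phases
#'
#' @param gp_ordered,gp_disordered GP values (scalars).
#' @return `gp_ordered - gp_disordered`.
#' @export
delta_gp <- function(gp_ordered, gp_disordered) {
  stopifnot(is.finite(gp_ordered), is.finite(gp_disordered))
  gp_ordered - gp_disordered
}

#' Internalization index from an intensity line profile
#'
#' Ratio of the mean internal (intracellular) intensity to the mean membrane
#' peak intensity, after background subtraction. An index of 1 corresponds
#' to equal distribution of the probe between the plasma membrane and
#' internal structures.
#'
#' @param profile numeric vector, an intensity line profile crossing the
#'   membrane twice.
#' @param membrane_peaks indices of the membrane peak positions.
#' @param internal_region indices of the internal region (disjoint from the
#'   peaks).
#' @param background scalar background intensity to subtract (default 0).
#' @return dimensionless index >= 0.
#' @export
internalization_index <- function(profile, membrane_peaks, internal_region,
                                  background = 0) {
  if (length(intersect(membrane_peaks, internal_region)))
    stop("membrane and internal regions must be disjoint")
  mem <- mean(profile[membrane_peaks]) - background
  int <- mean(profile[internal_region]) - background
  if (mem <= 0) stop("membrane intensity is zero: index undefined")
  max(int, 0) / mem
}

#' Run the full image -> GP pipeline on one or more spectral images
#'
#' Executes background correction (if a background ROI is given), vesicle
#' detection and per-vesicle GP statistics for each image, and writes the
#' combined vesicle table plus a small JSON manifest when `out_dir` is given.
#'
#' @param imgs a [spectral_image] or list of them.
#' @param cfg a [gp_config].
#' @param bg optional background [roi] applied to every image.
#' @param eps,min_samples,max_eccentricity detection parameters.
#' @param out_dir optional output directory for `vesicle_table.csv` and
#'   `manifest.json`.
#' @return data.frame: the vesicle table with an `image` column.
#' @export
run_gp_pipeline <- function(imgs, cfg, bg = NULL, eps = 3, min_samples = 8L,
                            max_eccentricity = 0.5, out_dir = NULL) {
  if (inherits(imgs, "spectral_image")) imgs <- list(imgs)
  tabs <- lapply(seq_along(imgs), function(i) {
    img <- imgs[[i]]
    if (!is.null(bg)) img <- subtract_background(img, bg)
    det <- detect_vesicles(img, cfg, eps = eps, min_samples = min_samples,
                           max_eccentricity = max_eccentricity)
    if (nrow(det$vesicles)) cbind(image = i, det$vesicles)
    else cbind(image = integer(0), det$vesicles)
  })
  tab <- do.call(rbind, tabs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "vesicle_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(probe = cfg$probe, lambda_lo = cfg$lambda_lo,
           lambda_ld = cfg$lambda_ld, eps = eps, min_samples = min_samples,
           max_eccentricity = max_eccentricity, n_images = length(imgs)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  }
  tab
}
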