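#' Minimal labeled bilayer trajectory
#'
#' Frames of Cartesian coordinates (nm) with a role map assigning a meaning
#' to each atom: per probe copy one `probe_axis_head` / `probe_axis_tail`
#' pair defining the fluorophore long axis, reference atoms such as
#' `chain_terminal` (lipid chain ends, defining the bilayer midplane) or
#' `cholesterol_oh`, and anything else the density analysis may select.
#'
#' @param frames list of n_atoms x 3 coordinate matrices (nm).
#' @param roles data.frame with columns `atom` (1-based index), `role`
#'   (character), and optionally `copy` (probe copy id for axis atoms).
#' @param box per-frame box dimensions: numeric length-3 vector (constant
#'   box) or a list of them.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(frames, roles, box) {
  na <- unique(vapply(frames, nrow, 1L))
  if (length(na) != 1L) stop("atom count must be consistent across frames")
  if (!all(c("atom", "role") %in% names(roles))) stop("roles needs atom, role")
  if (any(roles$atom < 1L | roles$atom > na)) stop("role atom index out of range")
  if (!is.list(box)) box <- rep(list(as.numeric(box)), length(frames))
  structure(list(frames = frames, roles = roles, box = box,
                 n_atoms = na), class = "md_trajectory")
}

role_atoms <- function(traj, role) traj$roles$atom[traj$roles$role %in% role]

# bilayer midplane per frame: mean z of the chain-terminal reference atoms
midplane_z <- function(traj) {
  ref <- role_atoms(traj, "chain_terminal")
  if (!length(ref)) ref <- seq_len(traj$n_atoms)
  vapply(traj$frames, function(f) mean(f[ref, 3L]), numeric(1))
}

#' Probe tilt angles relative to the membrane normal
#'
#' The tilt is the angle between the fluorophore long axis (head -> tail
#' vector of a probe copy) and the inward-pointing leaflet normal, taken as
#' the z axis for a planar bilayer. 0 degrees means the probe points along
#' the membrane normal toward the bilayer centre; 90 degrees means it lies in
#' the membrane plane. Leaflet assignment (sign of the head atom's z relative
#' to the midplane) is recomputed each frame. By default angles are folded to
#' [0, 90] by `theta -> min(theta, 180 - theta)`; `fold = FALSE` keeps the
#' [0, 180] convention.
#'
#' @param traj an [md_trajectory].
#' @param copy probe copy id (matched against `roles$copy`).
#' @param fold fold angles into [0, 90]?
#' @return numeric vector, one tilt angle (degrees) per frame.
#' @export
tilt_angles <- function(traj, copy, fold = TRUE) {
  r <- traj$roles
  head <- r$atom[r$role == "probe_axis_head" & r$copy == copy]
  tail <- r$atom[r$role == "probe_axis_tail" & r$copy == copy]
  if (length(head) != 1L || length(tail) != 1L)
    stop("probe copy must have exactly one head and one tail axis atom")
  mid <- midplane_z(traj)
  vapply(seq_along(traj$frames), function(i) {
    f <- traj$frames[[i]]
    v <- f[tail, ] - f[head, ]
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("zero-length probe axis vector")
    inward <- if (f[head, 3L] >= mid[i]) c(0, 0, -1) else c(0, 0, 1)
    th <- acos(max(-1, min(1, sum(v * inward) / nv))) * 180 / pi
    if (fold) min(th, 180 - th) else th
  }, numeric(1))
}

#' Tilt-angle histogram, mean and modes
#'
#' Normalized histogram of tilt angles over [0, 90] (or [0, 180] for
#' unfolded input), with the circular-free mean and the local maxima (modes)
#' detected after light smoothing (3-bin moving average).
#'
#' @param angles tilt angles (degrees).
#' @param bin_width histogram bin width (degrees, default 2.5).
#' @param max_angle histogram upper edge (90 folded, 180 unfolded).
#' @return An object of class `tilt_distribution`: `breaks`, `mids`, `freq`
#'   (sums to 1), `mean`, `modes` (degrees, decreasing prominence).
#' @export
tilt_distribution <- function(angles, bin_width = 2.5, max_angle = 90) {
  if (!length(angles)) stop("need at least one angle")
  breaks <- seq(0, max_angle, by = bin_width)
  if (breaks[length(breaks)] < max_angle) breaks <- c(breaks, max_angle)
  h <- graphics::hist(pmin(angles, max_angle), breaks = breaks, plot = FALSE)
  freq <- h$counts / sum(h$counts)
  sm <- stats::filter(c(freq[1L], freq, freq[length(freq)]), rep(1 / 3, 3))
  sm <- as.numeric(sm[2:(length(freq) + 1L)])
  n <- length(sm)
  cand <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) sm[i - 1L] else -Inf
    right <- if (i < n) sm[i + 1L] else -Inf
    sm[i] >= left && sm[i] >= right && freq[i] > 0.5 / n
  }, logical(1))
  # collapse plateaus of tied smoothed values to their highest-frequency bin
  runs <- rle(cand)
  keep <- logical(n)
  pos <- cumsum(c(1L, runs$lengths))
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    idx <- pos[r]:(pos[r + 1L] - 1L)
    keep[idx[which.max(freq[idx])]] <- TRUE
  }
  modes <- h$mids[keep][order(sm[keep], decreasing = TRUE)]
  structure(list(breaks = h$breaks, mids = h$mids, freq = freq,
                 mean = mean(angles), modes = modes,
                 bin_width = bin_width),
            class = "tilt_distribution")
}

#' Difference in mean tilt between two distributions
#'
#' @param dist_a,dist_b [tilt_distribution] objects.
#' @return `mean(dist_a) - mean(dist_b)` in degrees (e.g. the reduction of
#'   the average tilt upon adding cholesterol).
#' @export
mean_tilt_shift <- function(dist_a, dist_b) dist_a$mean - dist_b$mean

#' Partial density profile along the bilayer normal
#'
#' Histograms the z coordinates of the selected atoms, recentred so the
#' bilayer midplane (mean z of the `chain_terminal` reference atoms) is at 0,
#' averaged over frames and divided by the bin volume (box x-y area times bin
#' width), giving a number density in nm^-3. Profiles are not symmetrized
#' across leaflets.
#'
#' @param traj an [md_trajectory].
#' @param selection one or more role names.
#' @param bin_nm bin width (nm, default 0.1).
#' @return An object of class `density_profile`: `z` (bin centers, nm),
#'   `density` (nm^-3), `counts_per_frame`.
#' @export
partial_density_profile <- function(traj, selection, bin_nm = 0.1) {
  atoms <- role_atoms(traj, selection)
  if (!length(atoms)) stop("empty selection")
  mid <- midplane_z(traj)
  half <- max(vapply(traj$box, function(b) b[3L], numeric(1))) / 2
  breaks <- seq(-half, half, by = bin_nm)
  if (breaks[length(breaks)] < half) breaks <- c(breaks, half)
  counts <- rep(0, length(breaks) - 1L)
  area <- 0
  for (i in seq_along(traj$frames)) {
    z <- traj$frames[[i]][atoms, 3L] - mid[i]
    z <- pmax(pmin(z, half - 1e-9), -half + 1e-9)
    counts <- counts + graphics::hist(z, breaks = breaks, plot = FALSE)$counts
    area <- area + traj$box[[i]][1L] * traj$box[[i]][2L]
  }
  nf <- length(traj$frames)
  structure(list(z = (breaks[-1L] + breaks[-length(breaks)]) / 2,
                 density = counts / nf / (area / nf) / bin_nm,
                 counts_per_frame = counts / nf, bin_nm = bin_nm),
            class = "density_profile")
}

#' Probe mole fraction of a simulated bilayer
#'
#' @param n_lipids number of lipid molecules (phospholipid + cholesterol).
#' @param n_probes number of fluorescently labelled molecules.
#' @return probe content in mol percent, `100 n_probes / (n_lipids + n_probes)`.
#' @examples
#' probe_mol_percent(200, 8)  # ~4 mol%
#' @export
probe_mol_percent <- function(n_lipids, n_probes) {
  stopifnot(n_lipids >= 0, n_probes >= 0, n_lipids + n_probes > 0)
  100 * n_probes / (n_lipids + n_probes)
}

#' Read / write minimal trajectory files (GRO, XYZ) with a JSON role map
#'
#' `write_gro`/`read_gro` handle a single-frame GRO file (fixed-width
#' GROMACS format, coordinates in nm, box on the last line);
#' `write_xyz`/`read_xyz` handle multi-frame XYZ (coordinates in nm; the box
#' is carried in the comment line as `box <x> <y> <z>`). The role map is a
#' JSON array of `{atom, role, copy}` records.
#'
#' @param traj an [md_trajectory]; `path` file path; `roles_path` JSON path.
#' @name trajectory_io
#' @export
write_xyz <- function(traj, path, roles_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    f <- traj$frames[[i]]
    b <- traj$box[[i]]
    writeLines(as.character(nrow(f)), con)
    writeLines(sprintf("box %.6f %.6f %.6f", b[1L], b[2L], b[3L]), con)
    writeLines(sprintf("X %12.6f %12.6f %12.6f", f[, 1L], f[, 2L], f[, 3L]), con)
  }
  if (!is.null(roles_path)) write_role_map(traj$roles, roles_path)
  invisible(path)
}

#' @rdname trajectory_io
#' @export
read_xyz <- function(path, roles_path) {
  lines <- readLines(path)
  roles <- read_role_map(roles_path)
  frames <- list(); boxes <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    b <- as.numeric(strsplit(trimws(lines[i + 1L]), "\\s+")[[1]][-1L])
    blk <- lines[(i + 2L):(i + 1L + n)]
    m <- do.call(rbind, lapply(strsplit(trimws(blk), "\\s+"), function(x)
      as.numeric(x[2:4])))
    frames[[length(frames) + 1L]] <- m
    boxes[[length(boxes) + 1L]] <- b
    i <- i + 2L + n
  }
  md_trajectory(frames, roles, boxes)
}

#' @rdname trajectory_io
#' @export
write_gro <- function(traj, path, roles_path = NULL, frame = 1L) {
  f <- traj$frames[[frame]]
  b <- traj$box[[frame]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("synthetic bilayer frame", con)
  writeLines(sprintf("%5d", nrow(f)), con)
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     seq_len(nrow(f)), "MOL", "X", seq_len(nrow(f)),
                     f[, 1L], f[, 2L], f[, 3L]), con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", b[1L], b[2L], b[3L]), con)
  if (!is.null(roles_path)) write_role_map(traj$roles, roles_path)
  invisible(path)
}

#' @rdname trajectory_io
#' @export
read_gro <- function(path, roles_path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2L]))
  blk <- lines[3:(2L + n)]
  m <- cbind(as.numeric(substr(blk, 21, 28)),
             as.numeric(substr(blk, 29, 36)),
             as.numeric(substr(blk, 37, 44)))
  b <- as.numeric(strsplit(trimws(lines[3L + n]), "\\s+")[[1]][1:3])
  md_trajectory(list(m), read_role_map(roles_path), b)
}

write_role_map <- function(roles, path) {
  jsonlite::write_json(roles, path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

read_role_map <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(r$copy)) r$copy <- NA_integer_
  r
}
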