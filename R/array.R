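#' Build the spherical-cap phased array
#'
#' Deterministic equal-area tiling of the cap between hole rim and outer
#' rim: `n_rings` equal-area polar bands, each split into
#' `n_elements / n_rings` sectors, so every element has exactly the same
#' area. All element centers lie on the sphere of radius
#' `focal_distance_mm` about the geometric focus (the origin; beam axis
#' +z, cap at negative z), with outward normals pointing at the focus.
#'
#' @param focal_distance_mm focal distance (mm), default 100.
#' @param aperture_mm aperture diameter (mm), default 120 (f-number 5/6).
#' @param hole_mm center-hole diameter (mm), default 35.
#' @param n_elements element count, default 256.
#' @param frequency_hz drive frequency (Hz), default 2 MHz.
#' @param n_rings polar bands, must divide `n_elements`.
#' @return object of class `transducer_array` with per-element `position`
#'   (mm, focus at origin), `normal`, `area_mm2`, plus the geometry and
#'   `f_number`.
#' @export
build_array <- function(focal_distance_mm = 100, aperture_mm = 120, hole_mm = 35,
                        n_elements = 256L, frequency_hz = 2e6, n_rings = 8L) {
  g <- cap_angles(focal_distance_mm, aperture_mm, hole_mm)
  if (n_elements %% n_rings != 0) stop("n_rings must divide n_elements")
  per_ring <- n_elements / n_rings
  R <- focal_distance_mm
  # equal-area polar bands: equal increments in cos(theta)
  cos_edges <- seq(cos(g$theta_hole), cos(g$theta_max), length.out = n_rings + 1)
  area_el <- R^2 * (cos(g$theta_hole) - cos(g$theta_max)) * 2 * pi / n_elements
  pos <- matrix(0, n_elements, 3)
  e <- 0L
  for (b in seq_len(n_rings)) {
    thc <- acos((cos_edges[b] + cos_edges[b + 1]) / 2)
    for (s in seq_len(per_ring)) {
      e <- e + 1L
      psi <- (s - 0.5) * 2 * pi / per_ring
      pos[e, ] <- R * c(sin(thc) * cos(psi), sin(thc) * sin(psi), -cos(thc))
    }
  }
  normals <- -pos / R
  structure(list(position = pos, normal = normals,
                 area_mm2 = rep(area_el, n_elements),
                 focal_distance_mm = focal_distance_mm,
                 aperture_mm = aperture_mm, hole_mm = hole_mm,
                 n_elements = as.integer(n_elements),
                 frequency_hz = frequency_hz,
                 f_number = focal_distance_mm / aperture_mm,
                 theta_hole = g$theta_hole, theta_max = g$theta_max),
            class = "transducer_array")
}

#' @export
print.transducer_array <- function(x, ...) {
  cat("<transducer_array> ", x$n_elements, " elements, F = ", x$focal_distance_mm,
      " mm, D = ", x$aperture_mm, " mm (f-number ", signif(x$f_number, 4),
      "), hole ", x$hole_mm, " mm\n", sep = "")
  invisible(x)
}

#' Per-element drive parameters
#'
#' @param phase per-element phase shift (rad), wrapped to (-pi, pi].
#' @param amp per-element amplitude scale (>= 0).
#' @return object of class `drive_params`.
#' @export
drive_params <- function(phase, amp) {
  if (length(phase) != length(amp)) stop("phase and amp lengths differ")
  if (any(amp < 0)) stop("amplitudes must be non-negative")
  structure(list(phase = wrap_phase(phase), amp = amp), class = "drive_params")
}

wrap_phase <- function(ph) {
  w <- (ph + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi  # wrap to (-pi, pi]
  w
}

#' Uniform in-phase drive
#'
#' All phases 0, all amplitudes 1: the cap geometry alone supplies the
#' focusing (geometric focus on the target).
#'
#' @param array a `transducer_array` or 2D arc (for the element count).
#' @export
geometric_drive <- function(array) {
  n <- array$n_elements
  drive_params(rep(0, n), rep(1, n))
}

#' Cross-sectional arc of the array for 2D runs
#'
#' The cap reduces to two arcs (either side of the center hole) on the
#' circle of radius `focal_distance_mm` about the focus, split into equal
#' arc-length elements.
#'
#' @inheritParams build_array
#' @param n_elements total 2D element count (split over the two arcs).
#' @return object of class `transducer_arc` with per-element center angle
#'   (rad, from the beam axis; signed) and half-width.
#' @export
build_arc_2d <- function(focal_distance_mm = 40, aperture_mm = 48, hole_mm = 14,
                         n_elements = 64L, frequency_hz = 2e6) {
  g <- cap_angles(focal_distance_mm, aperture_mm, hole_mm)
  if (n_elements %% 2 != 0) stop("n_elements must be even (two arcs)")
  per_side <- n_elements / 2
  dth <- (g$theta_max - g$theta_hole) / per_side
  th <- g$theta_hole + (seq_len(per_side) - 0.5) * dth
  ang <- c(rev(-th), th)  # ordered low to high; near-axis elements in middle
  structure(list(angle = ang, half_width = dth / 2,
                 focal_distance_mm = focal_distance_mm,
                 aperture_mm = aperture_mm, hole_mm = hole_mm,
                 n_elements = as.integer(n_elements),
                 frequency_hz = frequency_hz,
                 f_number = focal_distance_mm / aperture_mm,
                 theta_hole = g$theta_hole, theta_max = g$theta_max),
            class = "transducer_arc")
}

# Bilinear footprint samples of every 2D arc element on the medium
# lattice: each element is sampled at half-cell arc spacing and each sample
# is spread over its four neighbouring cells with bilinear weights, so
# injection and recording are free of staircase phase jitter.
# pose_rad rotates the arc about the target within the plane; target_mm is
# the world position of the geometric focus.
arc_element_cells <- function(arc, medium, target_mm, pose_rad = 0) {
  d <- dim(medium$rho)
  sp <- medium$voxel_mm[1]
  step <- sp / 2 / arc$focal_distance_mm  # sub-cell angular sampling
  cells <- vector("list", arc$n_elements)
  for (e in seq_len(arc$n_elements)) {
    a0 <- arc$angle[e] - arc$half_width
    a1 <- arc$angle[e] + arc$half_width
    aa <- seq(a0, a1, by = step)
    phi <- pose_rad + aa
    px <- target_mm[1] + arc$focal_distance_mm * sin(phi)
    pz <- target_mm[2] + arc$focal_distance_mm * cos(phi)
    fx <- (px - medium$origin_mm[1]) / sp + 1
    fz <- (pz - medium$origin_mm[2]) / sp + 1
    i0 <- floor(fx); j0 <- floor(fz)
    wx <- fx - i0; wz <- fz - j0
    if (any(i0 < 1 | i0 + 1 > d[1] | j0 < 1 | j0 + 1 > d[2]))
      stop("array footprint outside the simulation domain")
    idx <- c(i0 + (j0 - 1) * d[1],
             i0 + 1 + (j0 - 1) * d[1],
             i0 + j0 * d[1],
             i0 + 1 + j0 * d[1])
    w <- c((1 - wx) * (1 - wz), wx * (1 - wz), (1 - wx) * wz, wx * wz) /
      length(aa)
    keep <- w > 0
    cells[[e]] <- list(idx = as.integer(idx[keep]), w = w[keep])
  }
  cells
}

#' Source spec for a driven 2D arc
#'
#' @param arc a `transducer_arc`.
#' @param medium the 2D `medium_field` (defines the lattice).
#' @param target_mm world position of the geometric focus (mm).
#' @param drive a `drive_params` (e.g. [geometric_drive()]).
#' @param pose_rad rotation of the arc about the target (rad).
#' @return list of per-element source specs for [fdtd_run()].
#' @export
array_source_2d <- function(arc, medium, target_mm, drive = geometric_drive(arc),
                            pose_rad = 0) {
  cells <- arc_element_cells(arc, medium, target_mm, pose_rad)
  lapply(seq_along(cells), function(e)
    list(idx = cells[[e]]$idx, amp = drive$amp[e] * cells[[e]]$w,
         phase = drive$phase[e]))
}

#' Receiver spec for a 2D arc
#'
#' @inheritParams array_source_2d
#' @return list(idx, elem, n_elem) for [fdtd_run()].
#' @export
arc_receivers_2d <- function(arc, medium, target_mm, pose_rad = 0) {
  cells <- arc_element_cells(arc, medium, target_mm, pose_rad)
  list(idx = unlist(lapply(cells, `[[`, "idx")),
       elem = rep(seq_along(cells), vapply(cells, function(c) length(c$idx), 1L)),
       w = unlist(lapply(cells, `[[`, "w")),
       n_elem = length(cells))
}

#' Source cells for the 3D spherical cap
#'
#' Samples the cap surface at half-cell spacing and maps samples to lattice
#' cells, one source entry per element.
#'
#' @param array a `transducer_array`.
#' @param medium 3D `medium_field`.
#' @param target_mm world position of the geometric focus (mm).
#' @param drive a `drive_params`.
#' @return list of per-element source specs for [fdtd_run()].
#' @export
cap_source_3d <- function(array, medium, target_mm, drive = geometric_drive(array)) {
  d <- dim(medium$rho)
  sp <- medium$voxel_mm[1]
  R <- array$focal_distance_mm
  step <- sp / 2 / R
  th <- seq(array$theta_hole, array$theta_max, by = step)
  out <- list()
  # assign each sampled surface point to the nearest element center
  for (t in th) {
    npsi <- max(8L, ceiling(2 * pi * sin(t) / step))
    psi <- (seq_len(npsi) - 0.5) * 2 * pi / npsi
    px <- target_mm[1] + R * sin(t) * cos(psi)
    py <- target_mm[2] + R * sin(t) * sin(psi)
    pz <- target_mm[3] - R * cos(t)
    ii <- round((px - medium$origin_mm[1]) / sp) + 1
    jj <- round((py - medium$origin_mm[2]) / sp) + 1
    kk <- round((pz - medium$origin_mm[3]) / sp) + 1
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    if (!all(ok)) stop("array footprint outside the simulation domain")
    lin <- as.integer(ii + (jj - 1) * d[1] + (kk - 1) * d[1] * d[2])
    pt <- cbind(px, py, pz) - matrix(target_mm, length(px), 3, byrow = TRUE)
    dmat <- pt %*% t(array$position)
    el <- max.col(dmat)  # nearest element direction
    out[[length(out) + 1]] <- data.frame(lin = lin, el = el)
  }
  df <- do.call(rbind, out)
  df <- df[!duplicated(df$lin), ]
  lapply(seq_len(array$n_elements), function(e)
    list(idx = df$lin[df$el == e], amp = drive$amp[e], phase = drive$phase[e]))
}

#' Time-reversal drive from element recordings
#'
#' For each element, the arrival lag relative to a reference element is the
#' argmax of their cross-correlation over one drive period (refined by
#' parabolic interpolation); the drive phase advances what arrived late
#' (`phase = +2 pi f lag`). Amplitude modes:
#' \describe{
#'   \item{`"matched"`}{(default) emit proportionally to what was received
#'     (`elem RMS / ref RMS`, normalized to mean 1): the true time-reversal
#'     weighting, which de-emphasizes shadowed, scattering-prone paths.}
#'   \item{`"rms_ratio"`}{inverse compensation `ref RMS / elem RMS`, which
#'     equalizes per-element arrivals at the target at the cost of pushing
#'     energy through lossy paths.}
#'   \item{`"uniform"`}{phase-only control, all amplitudes 1.}
#' }
#' All modes cap the scale at `amp_cap` to avoid exciting near-dead
#' channels; a zero-energy element gets amplitude 0 with a warning.
#'
#' @param recordings steps x elements matrix (see [element_recordings()]).
#' @param dt time step of the recordings (s).
#' @param frequency_hz drive frequency (Hz).
#' @param reference reference element index; default the element nearest
#'   the beam axis (middle of the ordered 2D arc).
#' @param amp_mode amplitude weighting, see above.
#' @param amp_cap maximum amplitude scale, default 4.
#' @param steady_frac fraction of the record (from the end) treated as
#'   steady state for the correlation, default 0.6.
#' @return a `drive_params`.
#' @export
time_reversal_drive <- function(recordings, dt, frequency_hz,
                                reference = NULL,
                                amp_mode = c("matched", "rms_ratio", "uniform"),
                                amp_cap = 4, steady_frac = 0.6) {
  amp_mode <- match.arg(amp_mode)
  ne <- ncol(recordings)
  ns <- nrow(recordings)
  if (is.null(reference)) reference <- (ne + 1L) %/% 2L
  i0 <- max(1L, ns - floor(steady_frac * ns) + 1L)
  seg <- recordings[i0:ns, , drop = FALSE]
  ref <- seg[, reference]
  ref_rms <- sqrt(mean(ref^2))
  if (ref_rms == 0) stop("reference element recorded no signal")
  L <- max(1L, round(1 / (2 * frequency_hz * dt)))  # half period in samples
  n <- nrow(seg)
  phases <- numeric(ne)
  amps <- numeric(ne)
  lags <- numeric(ne)
  for (e in seq_len(ne)) {
    sig <- seg[, e]
    rms <- sqrt(mean(sig^2))
    if (rms == 0) {
      warning("element ", e, " recorded no signal; amplitude set to 0")
      amps[e] <- 0
      next
    }
    cc <- vapply(-L:L, function(tau) {
      if (tau >= 0) sum(ref[1:(n - tau)] * sig[(1 + tau):n])
      else sum(ref[(1 - tau):n] * sig[1:(n + tau)])
    }, 1)
    m <- which.max(cc)
    lag <- (-L:L)[m]
    # parabolic sub-sample refinement
    if (m > 1 && m < length(cc)) {
      den <- cc[m - 1] - 2 * cc[m] + cc[m + 1]
      if (den < 0) lag <- lag + 0.5 * (cc[m - 1] - cc[m + 1]) / den
    }
    lags[e] <- lag * dt
    phases[e] <- 2 * pi * frequency_hz * lags[e]
    amps[e] <- switch(amp_mode,
                      matched = min(rms / ref_rms, amp_cap),
                      rms_ratio = min(ref_rms / rms, amp_cap),
                      uniform = 1)
  }
  if (amp_mode == "matched" && any(amps > 0))
    amps <- amps / mean(amps[amps > 0])
  dp <- drive_params(phases, pmin(amps, amp_cap))
  dp$lag_s <- lags
  dp$reference <- reference
  dp
}
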