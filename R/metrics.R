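#' Metric evaluation regions
#'
#' Concentric spheres (disks in 2D) about the target: the localized region
#' of radius `r_mm` and the entire region of radius `R_mm`.
#'
#' @param target_mm target position (mm).
#' @param r_mm localized-sphere radius, default 2.5 mm.
#' @param R_mm entire-sphere radius, default 10 mm.
#' @export
metric_regions <- function(target_mm, r_mm = 2.5, R_mm = 10) {
  if (!(r_mm > 0 && r_mm < R_mm)) stop("regions require 0 < r < R")
  structure(list(target_mm = target_mm, r_mm = r_mm, R_mm = R_mm),
            class = "metric_regions")
}

# squared distance of every voxel center to a point, for a field array with
# lattice geometry
dist2_map <- function(dims, voxel_mm, origin_mm, point_mm) {
  nd <- length(dims)
  out <- array(0, dims)
  for (a in seq_len(nd)) {
    co <- origin_mm[a] + (seq_len(dims[a]) - 1) * voxel_mm[a]
    idx <- slice.index(out, a)
    out <- out + array(((co - point_mm[a])^2)[idx], dims)
  }
  out
}

#' Localized heating ratio
#'
#' `beta = sum(Q over V_r) / sum(Q over V_R)` with voxel-center sphere
#' membership: the fraction of deposited heat concentrated in the small
#' target sphere. Equal voxel volumes cancel, so plain sums are used.
#'
#' @param Q heat map array (W/m^3, >= 0).
#' @param voxel_mm,origin_mm lattice geometry of `Q`.
#' @param regions a [metric_regions()].
#' @return beta in `[0, 1]`.
#' @export
localized_heating_ratio <- function(Q, voxel_mm, origin_mm, regions) {
  d2 <- dist2_map(dim(Q), voxel_mm, origin_mm, regions$target_mm)
  den <- sum(Q[d2 <= regions$R_mm^2])
  if (den <= 0) stop("localized heating ratio undefined: no heat deposited in V_R")
  sum(Q[d2 <= regions$r_mm^2]) / den
}

#' Focusing ratio
#'
#' `phi = sum(p^2/(rho c) over V_r) / sum(p^2/(rho c) over V_R)`: the
#' acoustic analogue of the localized heating ratio, insensitive to the
#' attenuation map.
#'
#' @param psq mean-square pressure array.
#' @param medium the `medium_field` of the run (for rho and c); pass `NULL`
#'   for a uniform medium.
#' @param voxel_mm,origin_mm lattice geometry.
#' @param regions a [metric_regions()].
#' @return phi in `[0, 1]`.
#' @export
focusing_ratio <- function(psq, medium, voxel_mm, origin_mm, regions) {
  integrand <- if (is.null(medium)) psq else psq / (medium$rho * medium$c)
  d2 <- dist2_map(dim(psq), voxel_mm, origin_mm, regions$target_mm)
  den <- sum(integrand[d2 <= regions$R_mm^2])
  if (den <= 0) stop("focusing ratio undefined: zero field in V_R")
  sum(integrand[d2 <= regions$r_mm^2]) / den
}

#' Primary pressure peak
#'
#' Global maximum of the field map; among exactly tied maxima the voxel
#' nearest the target is returned. The value is normalized by the
#' free-field reference peak when one is supplied.
#'
#' @param field pressure-peak (or mean-square) map array.
#' @param voxel_mm,origin_mm lattice geometry.
#' @param target_mm target position (mm).
#' @param reference free-field peak value for normalization (optional).
#' @return list with `location_mm`, `value`, `normalized` and
#'   `distance_mm` (Euclidean distance from the target).
#' @export
primary_peak <- function(field, voxel_mm, origin_mm, target_mm, reference = NULL) {
  if (length(field) == 0 || all(field <= 0)) stop("empty field")
  mx <- max(field)
  cand <- which(field == mx)
  d2 <- dist2_map(dim(field), voxel_mm, origin_mm, target_mm)
  best <- cand[which.min(d2[cand])]
  sub <- arrayInd(best, dim(field))
  loc <- origin_mm + (as.numeric(sub) - 1) * voxel_mm
  list(location_mm = loc, value = mx,
       normalized = if (is.null(reference)) NA_real_ else mx / reference,
       distance_mm = sqrt(d2[best]))
}

#' Beam-path region for the inhomogeneity indicator (2D)
#'
#' Truncated cone (triangle in the plane) with apex at the target and base
#' spanning the active aperture rim, restricted to tissue (non-water)
#' cells.
#'
#' @param medium 2D `medium_field` (its `labels` give the water mask).
#' @param arc the `transducer_arc` of the run.
#' @param target_mm target position (mm).
#' @param pose_rad arc rotation about the target (rad).
#' @return logical mask array on the medium lattice.
#' @export
beam_path_region <- function(medium, arc, target_mm, pose_rad = 0) {
  d <- dim(medium$rho)
  xs <- medium$origin_mm[1] + (seq_len(d[1]) - 1) * medium$voxel_mm[1]
  zs <- medium$origin_mm[2] + (seq_len(d[2]) - 1) * medium$voxel_mm[2]
  X <- matrix(xs, d[1], d[2])
  Z <- matrix(zs, d[1], d[2], byrow = TRUE)
  A <- target_mm[1:2]
  rim <- function(sgn) {
    phi <- pose_rad + sgn * arc$theta_max
    A + arc$focal_distance_mm * c(sin(phi), cos(phi))
  }
  B <- rim(1); C <- rim(-1)
  # barycentric point-in-triangle
  v0 <- C - A; v1 <- B - A
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  inv <- 1 / (d00 * d11 - d01 * d01)
  p0 <- X - A[1]; p1 <- Z - A[2]
  d20 <- p0 * v0[1] + p1 * v0[2]
  d21 <- p0 * v1[1] + p1 * v1[2]
  u <- (d11 * d20 - d01 * d21) * inv
  v <- (d00 * d21 - d01 * d20) * inv
  inside <- u >= 0 & v >= 0 & (u + v) <= 1
  inside & medium$labels != tissue_code("WATER")
}

#' Local acoustic inhomogeneity
#'
#' RMS magnitude of the characteristic-impedance gradient over a region on
#' the beam path, normalized by the water impedance per wavelength:
#' `chi = sqrt(mean |grad(rho c)|^2) / (rho_w c_w / lambda_w)` with
#' `lambda_w = c_w / f`. Gradients are central differences at the medium
#' resolution (one-sided at the map boundary); chi is 0 for homogeneous
#' regions and scales linearly with the impedance contrast.
#'
#' @param medium a `medium_field`.
#' @param region logical mask (e.g. [beam_path_region()]).
#' @param frequency_hz drive frequency (Hz); default from the medium.
#' @param water_rho,water_c water reference properties.
#' @return list with `chi`, `n_voxels`, and the normalization
#'   `impedance_per_wavelength`.
#' @export
local_acoustic_inhomogeneity <- function(medium, region,
                                         frequency_hz = medium$frequency_hz,
                                         water_rho = 998.2, water_c = 1482) {
  if (!any(region)) stop("empty inhomogeneity region")
  Z <- medium$impedance
  d <- dim(Z)
  nd <- length(d)
  h_m <- medium$voxel_mm * 1e-3
  g2 <- array(0, d)
  for (a in seq_len(nd)) {
    gr <- central_diff(Z, a, h_m[a])
    g2 <- g2 + gr^2
  }
  lam_w <- water_c / frequency_hz
  norm <- water_rho * water_c / lam_w
  chi <- sqrt(mean(g2[region])) / norm
  list(chi = chi, n_voxels = sum(region), impedance_per_wavelength = norm)
}

# central difference along axis a (one-sided at the array boundary)
central_diff <- function(Z, a, h) {
  d <- dim(Z)
  n <- d[a]
  if (n < 2) return(array(0, d))
  idx <- function(i) {
    args <- rep(list(quote(expr = )), length(d))
    args[[a]] <- i
    do.call(`[`, c(list(Z), args, list(drop = FALSE)))
  }
  up <- idx(c(2:n, n))
  dn <- idx(c(1, 1:(n - 1)))
  span <- array(2 * h, d)
  edge1 <- slice.index(Z, a) == 1
  edgeN <- slice.index(Z, a) == n
  span[edge1 | edgeN] <- h
  (up - dn) / span
}

#' Pearson correlation
#'
#' Product-moment correlation with the degenerate cases rejected
#' explicitly (fewer than 3 pairs, or zero variance).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}
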