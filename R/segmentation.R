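#' 3x3x3 median filter
#'
#' Replaces each voxel by the median of its 3x3x3 neighbourhood (3x3 in
#' 2D); boundaries are handled by edge replication.
#'
#' @param volume a [brightness_volume()].
#' @return the denoised [brightness_volume()].
#' @export
median_filter3 <- function(volume) {
  arr <- volume$values
  d <- dim(arr)
  if (length(d) == 2L) d <- c(d, 1L)
  out <- median3_cpp(as.numeric(arr), as.integer(d))
  dim(out) <- dim(arr)
  brightness_volume(out, volume$voxel_mm, volume$origin_mm)
}

# 256-bin histogram over [min, max] smoothed by a 5-bin moving average
# (edge-replicated), the binning the thresholding steps share.
smoothed_histogram <- function(values, bins = 256L, smooth = 5L) {
  rng <- range(values)
  if (diff(rng) <= 0) stop("degenerate histogram: all values identical")
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1L), bins),
                     nbins = bins)
  half <- (smooth - 1L) %/% 2L
  padded <- c(rep(counts[1], half), counts, rep(counts[bins], half))
  sm <- stats::filter(padded, rep(1 / smooth, smooth), sides = 2)
  sm <- as.numeric(sm)[(half + 1):(half + bins)]
  list(breaks = breaks, mids = (breaks[-1] + breaks[-(bins + 1)]) / 2,
       counts = counts, smoothed = sm)
}

# indices of local maxima of a series; ties broken toward the lower bin
# (a plateau counts once, at its first bin)
local_maxima <- function(s) {
  n <- length(s)
  prev <- c(-Inf, s[-n])
  nxt <- c(s[-1], -Inf)
  which(s > prev & s >= nxt)
}

# the two prominent modes of a smoothed histogram: the global maximum and
# the highest remaining maximum separated from it by a genuine valley (the
# minimum between them falls below half the smaller peak). Counting noise
# produces micro-maxima on mode flanks; taking the literal first two local
# maxima latches onto them.
find_two_modes <- function(s) {
  pk <- local_maxima(s)
  if (length(pk) < 2L) return(NULL)
  ord <- pk[order(s[pk], decreasing = TRUE)]
  A <- ord[1]
  for (m in ord[-1]) {
    lo <- min(A, m); hi <- max(A, m)
    if (hi - lo < 2L) next
    valley <- min(s[(lo + 1):(hi - 1)])
    if (valley < 0.5 * min(s[A], s[m])) return(sort(c(A, m)))
  }
  NULL
}

#' Air/breast brightness threshold
#'
#' Builds the smoothed brightness histogram of the whole volume and returns
#' the brightness at the minimum bin strictly between its two prominent
#' modes (air mode and breast mode; the valley between the selected modes
#' must drop below half the smaller mode, which keeps counting noise on a
#' mode flank from masquerading as a mode). Voxels below the threshold
#' are air.
#'
#' @param volume a [brightness_volume()] (typically median-filtered).
#' @param bins,smooth histogram bin count and moving-average width.
#' @return threshold brightness (scalar) with the histogram attached as
#'   attribute `"histogram"`.
#' @export
air_breast_threshold <- function(volume, bins = 256L, smooth = 5L) {
  h <- tryCatch(smoothed_histogram(as.numeric(volume$values), bins, smooth),
                error = function(e) stop("air/breast threshold: ", conditionMessage(e)))
  modes <- find_two_modes(h$smoothed)
  if (is.null(modes))
    stop("air/breast threshold: smoothed brightness histogram is not bimodal")
  lo <- modes[1]; hi <- modes[2]
  between <- (lo + 1):(hi - 1)
  valley <- between[which.min(h$smoothed[between])]
  thr <- h$mids[valley]
  attr(thr, "histogram") <- h
  thr
}

#' Zero out the air region
#'
#' Sets voxels strictly below the air/breast threshold to 0 (air); all
#' other voxels are untouched.
#'
#' @param volume a [brightness_volume()].
#' @param threshold from [air_breast_threshold()].
#' @export
apply_air_mask <- function(volume, threshold) {
  v <- volume$values
  v[v < threshold] <- 0
  brightness_volume(v, volume$voxel_mm, volume$origin_mm)
}

#' Detect the breast/air interface
#'
#' The threshold is 50 % of the mean brightness over non-air voxels
#' (brightness > 0). Scanning along all six axis-aligned directions from
#' the domain boundary inward, the first voxel meeting the threshold on
#' each scan line is marked; the interface is the union over directions.
#' Interior holes not reachable from the boundary are not marked.
#'
#' @param volume a [brightness_volume()] with air already zeroed.
#' @return list with `indices` (linear voxel indices of the interface),
#'   `threshold`, and `volume` (the working volume with interface voxels
#'   set to the -1 sentinel).
#' @export
detect_interface <- function(volume) {
  arr <- volume$values
  pos <- arr > 0
  if (!any(pos)) stop("detect_interface: empty breast region (no voxels > 0)")
  thr <- 0.5 * mean(arr[pos])
  hit <- arr >= thr
  d <- dim(arr)
  nd <- length(d)
  marked <- integer(0)
  for (ax in seq_len(nd)) {
    perm <- c(ax, setdiff(seq_len(nd), ax))
    m <- aperm(hit, perm)
    dim(m) <- c(d[ax], prod(d[-ax]))
    for (dir in 1:2) {
      mm <- if (dir == 1) m else m[rev(seq_len(nrow(m))), , drop = FALSE]
      first <- max.col(t(mm), ties.method = "first")
      has <- colSums(mm) > 0
      first <- first[has]
      lines <- which(has)
      if (dir == 2) first <- nrow(m) + 1L - first
      # rebuild full-array indices from (position along ax, line id)
      sub <- arrayInd(lines, .dim = d[-ax])
      full <- matrix(0L, nrow = length(lines), ncol = nd)
      full[, ax] <- first
      full[, setdiff(seq_len(nd), ax)] <- sub
      marked <- c(marked, as.integer((full - 1L) %*% cumprod(c(1L, d[-nd])) + 1L))
    }
  }
  marked <- sort(unique(marked))
  wv <- arr
  wv[marked] <- -1
  list(indices = marked, threshold = thr,
       volume = brightness_volume(wv, volume$voxel_mm, volume$origin_mm))
}

#' Add the skin layer
#'
#' Marks all former-air voxels (value 0) whose center lies within
#' `thickness_mm` (Euclidean distance) of an interface voxel center with
#' the -1 skin sentinel: an outward dilation of the surface by the skin
#' thickness. A sub-voxel thickness still marks the surface-adjacent air
#' layer (never a zero-thickness skin). Interface voxels themselves are
#' restored to their original brightness, so the skin is exactly the
#' air-side shell.
#'
#' @param volume the original (air-masked) [brightness_volume()].
#' @param interface result of [detect_interface()] (or a vector of linear
#'   indices).
#' @param thickness_mm skin thickness (mm), default 1.5.
#' @export
add_skin <- function(volume, interface, thickness_mm = 1.5) {
  if (thickness_mm <= 0) stop("skin thickness must be positive")
  idx <- if (is.list(interface)) interface$indices else as.integer(interface)
  if (length(idx) == 0) stop("add_skin: empty interface")
  arr <- volume$values
  d <- dim(arr)
  nd <- length(d)
  sp <- volume$voxel_mm
  # offsets whose Euclidean length is within the thickness (>= 1 layer)
  reach <- pmax(ceiling(thickness_mm / sp), 1L)
  offs <- as.matrix(do.call(expand.grid, lapply(seq_len(nd), function(a) -reach[a]:reach[a])))
  dist <- sqrt(colSums((t(offs) * sp)^2))
  eff_thick <- max(thickness_mm, min(sp))  # round sub-voxel thickness up to one layer
  offs <- offs[dist <= eff_thick + 1e-9 & dist > 0, , drop = FALSE]
  ind <- arrayInd(idx, .dim = d)
  skin <- logical(length(arr))
  strides <- cumprod(c(1L, d[-nd]))
  for (o in seq_len(nrow(offs))) {
    shifted <- ind + matrix(offs[o, ], nrow(ind), nd, byrow = TRUE)
    ok <- rowSums(shifted < 1L) == 0 & rowSums(shifted > matrix(d, nrow(ind), nd, byrow = TRUE)) == 0
    lin <- as.integer((shifted[ok, , drop = FALSE] - 1L) %*% strides + 1L)
    skin[lin] <- TRUE
  }
  out <- arr
  out[skin & arr == 0] <- -1
  brightness_volume(out, volume$voxel_mm, volume$origin_mm)
}

#' Fat/fibroglandular brightness threshold
#'
#' Returns the brightness cut for which the fraction of interior voxels
#' strictly below it is as close as possible to `fat_fraction`. Interior
#' voxels are those with brightness > 0 that are not skin (-1). Fat is
#' below the threshold; gland at/above it (the brighter class).
#'
#' @param volume [brightness_volume()] after air masking and skin addition.
#' @param fat_fraction assumed breast fat fraction in (0, 1); default 0.665.
#' @return threshold brightness (scalar) with attribute
#'   `"achieved_fraction"`.
#' @export
fat_gland_threshold <- function(volume, fat_fraction = 0.665) {
  if (fat_fraction <= 0 || fat_fraction >= 1)
    stop("fat_fraction must be in (0, 1)")
  v <- volume$values
  interior <- v[v > 0]
  if (length(interior) == 0) stop("fat_gland_threshold: empty interior")
  u <- sort(unique(interior))
  nbelow <- cumsum(tabulate(match(sort(interior), u), nbins = length(u)))
  # cutting at u[j] puts everything below u[j] (i.e. u[1..j-1]) in fat
  frac_below <- c(0, nbelow[-length(u)]) / length(interior)
  j <- which.min(abs(frac_below - fat_fraction))
  thr <- u[j]
  attr(thr, "achieved_fraction") <- frac_below[j]
  thr
}

#' Segment the working volume into tissue labels
#'
#' Maps the working volume to the four-class label volume: 0-valued voxels
#' to WATER (air is treated as the water coupling bath), -1 sentinels to
#' SKIN, interior voxels below the fat/gland threshold to FAT and the rest
#' to GLAND. The partition is total.
#'
#' @param volume [brightness_volume()] after the interface/skin steps.
#' @param fat_thr fat/gland threshold from [fat_gland_threshold()].
#' @param air_thr optional air/breast threshold; when given,
#'   [apply_air_mask()] is applied first (idempotent if already applied).
#' @return a [tissue_labels()] volume.
#' @export
segment_tissues <- function(volume, fat_thr, air_thr = NULL) {
  if (!is.null(air_thr)) {
    v <- volume$values
    v[v >= 0 & v < air_thr] <- 0
    volume <- brightness_volume(v, volume$voxel_mm, volume$origin_mm)
  }
  v <- volume$values
  lab <- array(tissue_code("GLAND"), dim(v))
  lab[v < fat_thr] <- tissue_code("FAT")
  lab[v == -1] <- tissue_code("SKIN")
  lab[v == 0] <- tissue_code("WATER")
  tissue_labels(lab, volume$voxel_mm, volume$origin_mm)
}

#' Full segmentation chain
#'
#' Median filter, air/breast histogram threshold, air masking, interface
#' detection, 1.5 mm skin, fat-fraction threshold, label assignment.
#'
#' @param volume raw [brightness_volume()].
#' @param fat_fraction assumed fat fraction (default 0.665).
#' @param skin_mm skin thickness (mm).
#' @return [tissue_labels()] with thresholds attached as attributes
#'   `"air_threshold"` and `"fat_threshold"`.
#' @export
segment_pipeline <- function(volume, fat_fraction = 0.665, skin_mm = 1.5) {
  den <- median_filter3(volume)
  air_thr <- air_breast_threshold(den)
  masked <- apply_air_mask(den, air_thr)
  iface <- detect_interface(masked)
  withskin <- add_skin(masked, iface, skin_mm)
  fat_thr <- fat_gland_threshold(withskin, fat_fraction)
  lab <- segment_tissues(withskin, fat_thr)
  attr(lab, "air_threshold") <- as.numeric(air_thr)
  attr(lab, "fat_threshold") <- as.numeric(fat_thr)
  lab
}

#' Acoustic tissue properties
#'
#' Density (kg/m^3), sound speed (m/s) and attenuation coefficient
#' (dB/m/MHz) for water, skin, fat and fibroglandular tissue, with the
#' derived characteristic impedance rho*c (Pa s/m). The skin attenuation
#' is not tabulated in the source data; it defaults to the fibroglandular
#' value (skin is a thin layer whose absorption barely matters) and is
#' configurable.
#'
#' @param skin_attenuation_db_m_mhz attenuation used for skin.
#' @return data.frame with one row per tissue, row names matching
#'   [tissue_names()].
#' @export
tissue_properties <- function(skin_attenuation_db_m_mhz = 60) {
  df <- data.frame(
    tissue = tissue_names(),
    density = c(998.2, 1090, 985, 1032),
    sound_speed = c(1482, 1615, 1465, 1547),
    attenuation_db_m_mhz = c(0.22, skin_attenuation_db_m_mhz, 40, 60),
    row.names = tissue_names()
  )
  df$impedance <- df$density * df$sound_speed
  df
}

#' Convert an attenuation coefficient to Np/m at a drive frequency
#'
#' `alpha0` is linear in frequency (dB/m/MHz); the Np value at `f` is
#' `alpha0 * (f / 1 MHz) * ln(10) / 20`.
#'
#' @param alpha0_db_m_mhz attenuation coefficient (dB/m/MHz).
#' @param frequency_hz drive frequency (Hz).
#' @export
attenuation_np_per_m <- function(alpha0_db_m_mhz, frequency_hz) {
  alpha0_db_m_mhz * (frequency_hz / 1e6) * log(10) / 20
}

#' Assign acoustic properties to a label volume
#'
#' Looks up per-voxel (rho, c, alpha0) from the tissue table, computes the
#' impedance map rho*c and converts alpha to Np/m at the drive frequency.
#'
#' @param labels a [tissue_labels()] volume.
#' @param props from [tissue_properties()].
#' @param frequency_hz drive frequency (Hz), default 2 MHz.
#' @return An object of class `medium_field` with fields `rho`, `c`,
#'   `alpha0`, `alpha_np`, `impedance`, `labels`, `voxel_mm`, `origin_mm`,
#'   `frequency_hz`.
#' @export
assign_properties <- function(labels, props = tissue_properties(), frequency_hz = 2e6) {
  lab <- labels$labels
  if (!all(lab %in% 0:3)) stop("unknown label code in volume")
  code <- lab + 1L  # row index in code order
  shp <- dim(lab)
  rho <- array(props$density[code], shp)
  cc <- array(props$sound_speed[code], shp)
  a0 <- array(props$attenuation_db_m_mhz[code], shp)
  structure(list(rho = rho, c = cc, alpha0 = a0,
                 alpha_np = attenuation_np_per_m(a0, frequency_hz),
                 impedance = rho * cc,
                 labels = lab,
                 voxel_mm = labels$voxel_mm, origin_mm = labels$origin_mm,
                 frequency_hz = frequency_hz),
            class = "medium_field")
}

#' Uniform water medium on a given lattice
#'
#' @param dim_out voxel counts per axis.
#' @param voxel_mm,origin_mm lattice geometry (mm).
#' @param frequency_hz drive frequency (Hz).
#' @param props tissue table.
#' @export
water_medium <- function(dim_out, voxel_mm, origin_mm = rep(0, length(dim_out)),
                         frequency_hz = 2e6, props = tissue_properties()) {
  lab <- array(tissue_code("WATER"), dim_out)
  assign_properties(tissue_labels(lab, voxel_mm, origin_mm), props, frequency_hz)
}

#' @export
print.medium_field <- function(x, ...) {
  cat("<medium_field> ", paste(dim(x$rho), collapse = " x "), " @ ",
      paste(signif(x$voxel_mm, 4), collapse = " x "), " mm, f = ",
      x$frequency_hz / 1e6, " MHz\n", sep = "")
  invisible(x)
}
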