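#' Phantom recipe for a synthetic breast MRI volume
#'
#' Parameters of the synthetic T1-like breast volume the generator draws:
#' a hemispherical-ish breast sitting on the chest plane (z = 0, z anterior),
#' surrounded by air, with a dark-fat / bright-fibroglandular bimodal
#' interior and a network-like gland compartment whose feature scale is set
#' by `gland_correlation_mm`.
#'
#' Brightness ordering is enforced as air < fat < gland. On conventional
#' T1 images fat is the bright class; here the contrast-enhanced convention
#' is used, in which raising the fat/gland threshold converts gland voxels
#' to fat, so the gland must be the brighter class for a fat-fraction
#' threshold sweep to behave monotonically.
#'
#' @param domain_size_mm domain edge lengths (mm), length 3.
#' @param voxel_mm voxel spacing (mm); default matches the 0.625 x 0.625 mm
#'   in-plane / 0.8 mm slice resolution of the emulated acquisitions.
#' @param breast_radius_mm breast footprint radius on the chest plane (mm).
#' @param nipple_height_mm anterior extent of the breast above the chest
#'   plane (mm).
#' @param gland_fraction_target fraction of interior (breast) voxels in the
#'   gland class, in (0, 1); default 0.335 = 1 - 0.665 fat fraction.
#' @param gland_correlation_mm correlation length of the random field that
#'   shapes the gland network (mm).
#' @param gland_center_frac axial position of the gland envelope between
#'   chest plane (0) and nipple (1).
#' @param fat_brightness_mean,fat_brightness_sd,gland_brightness_mean,gland_brightness_sd,air_brightness_mean,air_brightness_sd
#'   per-class brightness distribution parameters (arbitrary units).
#' @param noise_sd additive Gaussian noise applied last.
#' @param seed integer seed; all stochastic draws flow from it.
#' @return An object of class `phantom_recipe`.
#' @export
phantom_recipe <- function(domain_size_mm = c(120, 120, 70),
                           voxel_mm = c(0.625, 0.625, 0.8),
                           breast_radius_mm = 50,
                           nipple_height_mm = 45,
                           gland_fraction_target = 0.335,
                           gland_correlation_mm = 1.5,
                           gland_center_frac = 0.55,
                           fat_brightness_mean = 210, fat_brightness_sd = 35,
                           gland_brightness_mean = 460, gland_brightness_sd = 55,
                           air_brightness_mean = 15, air_brightness_sd = 8,
                           noise_sd = 15,
                           seed = 1L) {
  r <- list(domain_size_mm = rep_len(as.numeric(domain_size_mm), 3),
            voxel_mm = rep_len(as.numeric(voxel_mm), 3),
            breast_radius_mm = breast_radius_mm,
            nipple_height_mm = nipple_height_mm,
            gland_fraction_target = gland_fraction_target,
            gland_correlation_mm = gland_correlation_mm,
            gland_center_frac = gland_center_frac,
            fat_brightness_mean = fat_brightness_mean,
            fat_brightness_sd = fat_brightness_sd,
            gland_brightness_mean = gland_brightness_mean,
            gland_brightness_sd = gland_brightness_sd,
            air_brightness_mean = air_brightness_mean,
            air_brightness_sd = air_brightness_sd,
            noise_sd = noise_sd,
            seed = as.integer(seed))
  class(r) <- "phantom_recipe"
  validate_recipe(r)
  r
}

validate_recipe <- function(r) {
  if (any(r$voxel_mm <= 0)) stop("voxel_mm must be strictly positive")
  if (r$gland_fraction_target <= 0 || r$gland_fraction_target >= 1)
    stop("gland_fraction_target must be in (0, 1)")
  if (!(r$air_brightness_mean < r$fat_brightness_mean &&
        r$fat_brightness_mean < r$gland_brightness_mean))
    stop("brightness means must be ordered air < fat < gland")
  if (r$breast_radius_mm <= 0 || r$nipple_height_mm <= 0)
    stop("breast_radius_mm and nipple_height_mm must be positive")
  if (r$gland_correlation_mm <= 0) stop("gland_correlation_mm must be positive")
  if (r$noise_sd < 0) stop("noise_sd must be non-negative")
  invisible(r)
}

#' @export
print.phantom_recipe <- function(x, ...) {
  cat("<phantom_recipe> breast R=", x$breast_radius_mm, " mm, nipple h=",
      x$nipple_height_mm, " mm, gland fraction ", x$gland_fraction_target,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Read/write a phantom recipe as a YAML config section
#' @param recipe a `phantom_recipe`.
#' @param path YAML file path.
#' @export
write_recipe_yaml <- function(recipe, path) {
  yaml::write_yaml(list(phantom = unclass(recipe)), path)
  invisible(path)
}

#' @rdname write_recipe_yaml
#' @export
read_recipe_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(phantom_recipe, y$phantom)
}

#' Synthesize a breast-MRI brightness volume
#'
#' Deterministic for a fixed seed. The breast is a half-ellipsoid on the
#' chest plane; the interior is split into a fat background and a single
#' 26-connected, branching gland compartment occupying approximately
#' `gland_fraction_target` of the interior. The gland is the connected
#' superlevel set of a Gaussian-correlated random field (correlation length
#' `gland_correlation_mm`) multiplied by a duct-like envelope that decays
#' radially and is modulated into spokes about the chest-nipple axis, grown
#' from the field maximum until the target voxel count is reached. Class
#' brightness is drawn per voxel and additive noise is applied last.
#'
#' The pre-noise class map (0 air, 1 fat, 2 gland) is attached as attribute
#' `"classes"` of the returned values for validation.
#'
#' @param recipe a [phantom_recipe()].
#' @return A [brightness_volume()].
#' @export
synthesize_breast_mri <- function(recipe) {
  validate_recipe(recipe)
  r <- recipe
  dims <- pmax(floor(r$domain_size_mm / r$voxel_mm + 1e-9), 1) + 1
  dims <- as.integer(dims)
  if (2 * r$breast_radius_mm > r$domain_size_mm[1] ||
      2 * r$breast_radius_mm > r$domain_size_mm[2] ||
      r$nipple_height_mm > r$domain_size_mm[3])
    stop("breast does not fit in the domain: radius ", r$breast_radius_mm,
         " mm / height ", r$nipple_height_mm, " mm vs domain ",
         paste(r$domain_size_mm, collapse = " x "), " mm")
  cx <- r$domain_size_mm[1] / 2
  cy <- r$domain_size_mm[2] / 2
  xs <- (seq_len(dims[1]) - 1) * r$voxel_mm[1]
  ys <- (seq_len(dims[2]) - 1) * r$voxel_mm[2]
  zs <- (seq_len(dims[3]) - 1) * r$voxel_mm[3]

  X <- array(rep(xs, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dims)
  # half-ellipsoid breast on the chest plane
  inside <- ((X - cx)^2 + (Y - cy)^2) / r$breast_radius_mm^2 +
    (Z / r$nipple_height_mm)^2 <= 1

  set.seed(r$seed)
  n <- prod(dims)
  noise <- array(stats::rnorm(n), dims)
  sig_vox <- r$gland_correlation_mm / r$voxel_mm
  kerns <- lapply(sig_vox, function(s) {
    if (s < 0.3) return(1)
    half <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-half:half) / s)^2)
    k / sum(k)
  })
  field <- sep_conv3_cpp(as.numeric(noise), dims, kerns)
  field <- (field - mean(field)) / stats::sd(field)
  dim(field) <- dims

  # duct envelope: radial decay from the chest-nipple axis, spoke modulation,
  # centered axially at gland_center_frac of the breast height
  zc <- r$gland_center_frac * r$nipple_height_mm
  raxis2 <- (X - cx)^2 + (Y - cy)^2
  phi <- atan2(Y - cy, X - cx)
  env <- exp(-raxis2 / (2 * (0.35 * r$breast_radius_mm)^2) -
             (Z - zc)^2 / (2 * (0.4 * r$nipple_height_mm)^2)) *
    (1 + 0.5 * cos(6 * phi))
  # the correlated field dominates (network-like texture); the envelope
  # biases where the network concentrates without collapsing it to a blob
  score <- field + 0.6 * env

  n_target <- round(r$gland_fraction_target * sum(inside))
  gland <- grow_connected_cpp(as.numeric(score), as.logical(inside), dims, n_target)
  dim(gland) <- dims

  classes <- array(0L, dims)
  classes[inside] <- 1L
  classes[gland] <- 2L

  vals <- array(0, dims)
  nair <- sum(classes == 0L); nfat <- sum(classes == 1L); ngl <- sum(classes == 2L)
  vals[classes == 0L] <- stats::rnorm(nair, r$air_brightness_mean, r$air_brightness_sd)
  vals[classes == 1L] <- stats::rnorm(nfat, r$fat_brightness_mean, r$fat_brightness_sd)
  vals[classes == 2L] <- stats::rnorm(ngl, r$gland_brightness_mean, r$gland_brightness_sd)
  if (r$noise_sd > 0) vals <- vals + stats::rnorm(n, 0, r$noise_sd)
  vals <- pmax(vals, 0)
  attr(vals, "classes") <- classes
  brightness_volume(vals, r$voxel_mm)
}

#' Reference phantom recipes
#'
#' A deterministic fixture set covering four gland morphologies: gland
#' concentrated near the chest wall, gland reaching toward the nipple,
#' sparse gland and dense gland.
#'
#' @param breast_radius_mm breast radius shared by the set (mm).
#' @param nipple_height_mm breast height shared by the set (mm).
#' @param domain_size_mm domain (mm); default sized to fit the breast.
#' @param seed base seed; recipe k uses `seed + k`.
#' @return list of entries, each `list(recipe =, description =)`.
#' @export
reference_phantoms <- function(breast_radius_mm = 50, nipple_height_mm = 45,
                               domain_size_mm = NULL, seed = 100L) {
  if (is.null(domain_size_mm))
    domain_size_mm <- c(2.2 * breast_radius_mm, 2.2 * breast_radius_mm,
                        1.4 * nipple_height_mm)
  base <- function(k, ...) {
    phantom_recipe(domain_size_mm = domain_size_mm,
                   breast_radius_mm = breast_radius_mm,
                   nipple_height_mm = nipple_height_mm,
                   seed = seed + k, ...)
  }
  list(
    list(recipe = base(1, gland_center_frac = 0.25),
         description = "gland concentrated near the chest wall"),
    list(recipe = base(2, gland_center_frac = 0.85),
         description = "gland reaching toward the nipple"),
    list(recipe = base(3, gland_fraction_target = 0.18, gland_center_frac = 0.5),
         description = "sparse gland"),
    list(recipe = base(4, gland_fraction_target = 0.50, gland_center_frac = 0.5),
         description = "dense gland")
  )
}
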