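#' Brightness volume
#'
#' A scalar MRI-like lattice with voxel spacing and world origin. Works in
#' 2D (matrix) or 3D (array); index order is (x, y, z) with z the anterior
#' beam axis. The world coordinate of voxel `i` along an axis is
#' `origin_mm + (i - 1) * voxel_mm`.
#'
#' Raw brightness is non-negative; the value `-1` is reserved by the
#' segmentation stage as the skin sentinel and `0` marks air/water.
#'
#' @param values numeric matrix or 3D array of brightness values.
#' @param voxel_mm voxel spacing per axis (mm), length matching `dim(values)`.
#' @param origin_mm world coordinate (mm) of the first voxel center.
#' @return An object of class `brightness_volume`.
#' @export
brightness_volume <- function(values, voxel_mm, origin_mm = rep(0, length(voxel_mm))) {
  nd <- length(dim(values))
  if (nd < 2L || nd > 3L) stop("values must be a matrix or a 3D array")
  voxel_mm <- rep_len(as.numeric(voxel_mm), nd)
  origin_mm <- rep_len(as.numeric(origin_mm), nd)
  if (any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("voxel spacing must be strictly positive")
  if (any(!is.finite(values))) stop("brightness values must be finite")
  structure(list(values = values, voxel_mm = voxel_mm, origin_mm = origin_mm),
            class = "brightness_volume")
}

#' Tissue label volume
#'
#' Voxelwise labels over \{WATER, SKIN, FAT, GLAND\} on the same lattice as
#' the source brightness volume. Labels are stored as integer codes
#' (`WATER = 0`, `SKIN = 1`, `FAT = 2`, `GLAND = 3`).
#'
#' @param labels integer matrix/array with values in 0:3.
#' @param voxel_mm,origin_mm lattice geometry as in [brightness_volume()].
#' @return An object of class `tissue_labels`.
#' @export
tissue_labels <- function(labels, voxel_mm, origin_mm = rep(0, length(voxel_mm))) {
  nd <- length(dim(labels))
  if (nd < 2L || nd > 3L) stop("labels must be a matrix or a 3D array")
  if (!all(labels %in% 0:3)) stop("labels must be in {0 (WATER), 1 (SKIN), 2 (FAT), 3 (GLAND)}")
  voxel_mm <- rep_len(as.numeric(voxel_mm), nd)
  origin_mm <- rep_len(as.numeric(origin_mm), nd)
  if (any(voxel_mm <= 0)) stop("voxel spacing must be strictly positive")
  structure(list(labels = labels, voxel_mm = voxel_mm, origin_mm = origin_mm),
            class = "tissue_labels")
}

#' @export
print.brightness_volume <- function(x, ...) {
  cat("<brightness_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", paste(signif(x$voxel_mm, 4), collapse = " x "), " mm\n",
      "  range [", signif(min(x$values), 4), ", ", signif(max(x$values), 4), "]\n",
      sep = "")
  invisible(x)
}

#' @export
print.tissue_labels <- function(x, ...) {
  tb <- table(factor(x$labels, levels = 0:3, labels = tissue_names()))
  cat("<tissue_labels> ", paste(dim(x$labels), collapse = " x "), " voxels\n", sep = "")
  print(tb)
  invisible(x)
}

#' Tissue label names in code order
#' @return character vector `c("WATER","SKIN","FAT","GLAND")`.
#' @export
tissue_names <- function() c("WATER", "SKIN", "FAT", "GLAND")

#' Integer code of a tissue label
#' @param name one of `"WATER"`, `"SKIN"`, `"FAT"`, `"GLAND"`.
#' @export
tissue_code <- function(name) {
  i <- match(toupper(name), tissue_names())
  if (any(is.na(i))) stop("unknown tissue label: ", paste(name[is.na(i)], collapse = ", "))
  i - 1L
}

#' Voxel-center coordinates along each axis
#' @param x a `brightness_volume` or `tissue_labels`.
#' @return list of numeric vectors (mm), one per axis.
#' @export
axis_coords <- function(x) {
  d <- dim(x$values %||% x$labels)
  lapply(seq_along(d), function(a) x$origin_mm[a] + (seq_len(d[a]) - 1) * x$voxel_mm[a])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a 2D slice from a 3D volume
#'
#' Takes the plane `y = y_mm` (nearest voxel plane) from a 3D brightness or
#' label volume, returning a 2D object of the same class with (x, z) axes.
#'
#' @param x 3D `brightness_volume` or `tissue_labels`.
#' @param y_mm world y-coordinate of the requested plane (mm).
#' @export
slice_xz <- function(x, y_mm) {
  arr <- x$values %||% x$labels
  if (length(dim(arr)) != 3L) stop("slice_xz needs a 3D volume")
  j <- round((y_mm - x$origin_mm[2]) / x$voxel_mm[2]) + 1
  j <- min(max(j, 1L), dim(arr)[2])
  sl <- arr[, j, , drop = TRUE]
  sp <- x$voxel_mm[c(1, 3)]
  org <- x$origin_mm[c(1, 3)]
  if (inherits(x, "tissue_labels")) tissue_labels(sl, sp, org)
  else brightness_volume(sl, sp, org)
}

#' Write a volume to NIfTI
#'
#' @param x `brightness_volume` or `tissue_labels`.
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_volume_nifti <- function(x, path) {
  arr <- x$values %||% x$labels
  img <- RNifti::asNifti(arr, pixdim = x$voxel_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a brightness volume
#'
#' @param path NIfTI file.
#' @param origin_mm world origin override (mm); defaults to zero.
#' @export
read_volume_nifti <- function(path, origin_mm = NULL) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  arr <- as.array(img)
  nd <- length(dim(arr))
  brightness_volume(arr, sp[seq_len(nd)],
                    origin_mm %||% rep(0, nd))
}

#' Resample a volume to a new grid spacing
#'
#' Brightness volumes are interpolated tri-linearly (bi-linearly in 2D);
#' label volumes use nearest-neighbour interpolation so no new labels are
#' invented. World coordinates are preserved: the new lattice starts at the
#' same origin and covers the same extent. Queries outside the source
#' domain are filled with `fill` (defaults: 0 for brightness, WATER for
#' labels) and a message is emitted.
#'
#' @param x `brightness_volume` or `tissue_labels`.
#' @param target_spacing_mm new spacing (scalar or per-axis, mm).
#' @param origin_mm,dim_out optional target window (world origin and voxel
#'   counts); defaults to covering the source extent.
#' @param fill value used outside the source domain.
#' @return object of the same class on the target lattice.
#' @export
resample_to_grid <- function(x, target_spacing_mm, origin_mm = NULL,
                             dim_out = NULL, fill = NULL) {
  is_lab <- inherits(x, "tissue_labels")
  arr <- x$values %||% x$labels
  nd <- length(dim(arr))
  sp_new <- rep_len(as.numeric(target_spacing_mm), nd)
  if (any(sp_new <= 0)) stop("target spacing must be strictly positive")
  if (is.null(fill)) fill <- 0
  org_new <- if (is.null(origin_mm)) x$origin_mm else rep_len(as.numeric(origin_mm), nd)
  if (is.null(dim_out)) {
    extent <- (dim(arr) - 1) * x$voxel_mm
    dim_out <- pmax(floor(extent / sp_new + 1e-9), 0) + 1
  }
  dim_out <- as.integer(rep_len(dim_out, nd))
  coords <- lapply(seq_len(nd), function(a) org_new[a] + (seq_len(dim_out[a]) - 1) * sp_new[a])
  # fractional source indices per axis (1-based)
  fidx <- lapply(seq_len(nd), function(a) (coords[[a]] - x$origin_mm[a]) / x$voxel_mm[a] + 1)
  out <- sample_lattice(arr, fidx, nearest = is_lab, fill = fill)
  if (attr(out, "n_outside") > 0)
    message("resample_to_grid: ", attr(out, "n_outside"),
            " target voxels outside the source domain filled with ", fill)
  attr(out, "n_outside") <- NULL
  if (is_lab) tissue_labels(out, sp_new, org_new) else brightness_volume(out, sp_new, org_new)
}

# Interpolate arr at the tensor grid of fractional indices fidx (list of
# per-axis vectors). nearest = TRUE snaps to the closest voxel.
sample_lattice <- function(arr, fidx, nearest, fill) {
  nd <- length(dim(arr))
  d <- dim(arr)
  dims_out <- vapply(fidx, length, 1L)
  outside <- Reduce(`|`, lapply(seq_len(nd), function(a) {
    o <- fidx[[a]] < 1 - 1e-9 | fidx[[a]] > d[a] + 1e-9
    ar <- array(FALSE, dims_out)
    idx <- slice.index(ar, a)
    array(o[idx], dims_out)
  }))
  if (nearest) {
    ii <- lapply(seq_len(nd), function(a) pmin(pmax(round(fidx[[a]]), 1L), d[a]))
    out <- do.call(`[`, c(list(arr), ii, list(drop = FALSE)))
    dim(out) <- dims_out
  } else {
    lo <- lapply(seq_len(nd), function(a) pmin(pmax(floor(fidx[[a]]), 1L), d[a] - 1L))
    wts <- lapply(seq_len(nd), function(a) pmin(pmax(fidx[[a]] - lo[[a]], 0), 1))
    out <- array(0, dims_out)
    for (corner in 0:(2^nd - 1)) {
      bits <- as.integer(intToBits(corner))[seq_len(nd)]
      ii <- lapply(seq_len(nd), function(a) pmin(lo[[a]] + bits[a], d[a]))
      piece <- do.call(`[`, c(list(arr), ii, list(drop = FALSE)))
      dim(piece) <- dims_out
      w <- array(1, dims_out)
      for (a in seq_len(nd)) {
        wa <- if (bits[a] == 1L) wts[[a]] else 1 - wts[[a]]
        idx <- slice.index(w, a)
        w <- w * array(wa[idx], dims_out)
      }
      out <- out + piece * w
    }
  }
  n_out <- sum(outside)
  if (n_out > 0) out[outside] <- fill
  attr(out, "n_outside") <- n_out
  out
}
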