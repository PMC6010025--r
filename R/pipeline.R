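#' Study setup for desk-scale 2D treatment simulations
#'
#' The package's standard conditions for phantom treatment runs: a 2D
#' cross-sectional simulation with a geometrically similar transducer arc
#' (f-number 5/6 preserved; focal distance 55 mm, aperture 66 mm, hole
#' 19.25 mm), 2 MHz drive on a 0.12 mm grid (just over 6 points per
#' wavelength in water), and the standard metric disks r = 2.5 mm and
#' R = 10 mm. The metric radii are not scaled down with the transducer:
#' the focal-lobe dimensions are set by the wavelength and f-number, which
#' are unchanged, so the absolute integration scales stay appropriate.
#' The simulation window is fixed relative to the target; arc poses within
#' roughly +/-35 degrees stay inside it.
#'
#' @param focal_distance_mm,aperture_mm,hole_mm arc geometry (mm).
#' @param n_elements 2D element count.
#' @param dx_mm grid spacing (mm).
#' @param frequency_hz drive frequency (Hz).
#' @param r_mm,R_mm metric disk radii (mm).
#' @param cycles total drive cycles; default sized to cover the focal
#'   distance in the slowest tissue plus ramp, settling and averaging.
#' @return object of class `study_setup`.
#' @export
study_setup <- function(focal_distance_mm = 55, aperture_mm = 66, hole_mm = 19.25,
                        n_elements = 64L, dx_mm = 0.12, frequency_hz = 2e6,
                        r_mm = 2.5, R_mm = 10, cycles = NULL) {
  if (is.null(cycles))
    cycles <- ceiling(frequency_hz * (focal_distance_mm + 5) * 1e-3 / 1400) + 12
  arc <- build_arc_2d(focal_distance_mm, aperture_mm, hole_mm, n_elements,
                      frequency_hz)
  config <- sim_config(ndim = 2, dx_mm = dx_mm, frequency_hz = frequency_hz,
                       cycles = cycles)
  # window relative to the target (mm): x half-width, z below, z above
  window <- list(half_x = focal_distance_mm * 0.96 + 5,
                 below = 16, above = focal_distance_mm + 6)
  structure(list(arc = arc, config = config, r_mm = r_mm, R_mm = R_mm,
                 window = window, props = tissue_properties()),
            class = "study_setup")
}

# simulation lattice of a setup, with the target at world position
# target_mm (2D: x, z)
sim_lattice <- function(setup, target_mm = c(0, 0)) {
  dx <- setup$config$dx_mm
  org <- c(target_mm[1] - setup$window$half_x, target_mm[2] - setup$window$below)
  nx <- as.integer(round(2 * setup$window$half_x / dx)) + 1L
  nz <- as.integer(round((setup$window$below + setup$window$above) / dx)) + 1L
  list(origin = org, dim = c(nx, nz), dx = dx)
}

.ff_cache <- new.env(parent = emptyenv())

#' Free-field reference run
#'
#' Runs the arc in pure water on the standard window (geometric drive) and
#' caches `phi0` (free-field focusing ratio) and the reference peak
#' pressure, keyed by the setup parameters.
#'
#' @param setup a [study_setup()].
#' @return list with `phi0`, `peak`, and the `sim_result`.
#' @export
free_field_reference <- function(setup) {
  key <- paste(setup$arc$focal_distance_mm, setup$arc$aperture_mm,
               setup$arc$hole_mm, setup$arc$n_elements, setup$config$dx_mm,
               setup$config$frequency_hz, setup$config$cycles,
               setup$r_mm, setup$R_mm, sep = "|")
  if (!is.null(.ff_cache[[key]])) return(.ff_cache[[key]])
  lat <- sim_lattice(setup, c(0, 0))
  med <- water_medium(lat$dim, lat$dx, lat$origin,
                      frequency_hz = setup$config$frequency_hz, props = setup$props)
  src <- array_source_2d(setup$arc, med, c(0, 0), geometric_drive(setup$arc))
  res <- fdtd_run(setup$config, med, src,
                  min_travel_mm = setup$arc$focal_distance_mm)
  reg <- metric_regions(c(0, 0), setup$r_mm, setup$R_mm)
  phi0 <- focusing_ratio(res$psq, med, med$voxel_mm, med$origin_mm, reg)
  out <- list(phi0 = phi0, peak = max(res$pmax), result = res)
  .ff_cache[[key]] <- out
  out
}

#' Specify a treatment-simulation case
#'
#' @param recipe a [phantom_recipe()], or `NULL` for a water-only run.
#' @param target_mm target position in phantom world coordinates (mm,
#'   length 3); the 2D plane is `y = target_mm[2]`.
#' @param pose_deg rotation of the arc about the target in the plane
#'   (degrees).
#' @param drive `"geometric"` or `"time_reversal"`.
#' @param ablate_gland replace gland with fat properties (ablation study).
#' @param label case label for reports.
#' @export
case_spec <- function(recipe, target_mm, pose_deg = 0, drive = "geometric",
                      ablate_gland = FALSE, label = "") {
  drive <- match.arg(drive, c("geometric", "time_reversal"))
  structure(list(recipe = recipe, target_mm = target_mm, pose_deg = pose_deg,
                 drive = drive, ablate_gland = ablate_gland, label = label),
            class = "case_spec")
}

.phantom_cache <- new.env(parent = emptyenv())

# synthesize + segment a phantom, cached per recipe (several cases share
# one phantom under different arrangements)
segmented_phantom <- function(recipe) {
  key <- paste(unlist(recipe), collapse = "|")
  if (is.null(.phantom_cache[[key]])) {
    vol <- synthesize_breast_mri(recipe)
    .phantom_cache[[key]] <- segment_pipeline(vol)
  }
  .phantom_cache[[key]]
}

#' Place a target deep inside the gland network
#'
#' Treatment targets are tumours, which the segmentation folds into the
#' fibroglandular class, so a realistic target sits inside a solid gland
#' mass, not on a thin strand. Among gland voxels within `search_mm` of
#' the nominal position (in the plane `y = nominal_mm[2]`), the voxel
#' whose `ball_mm` neighbourhood has the highest gland fraction is
#' selected; ties break toward the nominal position.
#'
#' @param recipe a [phantom_recipe()].
#' @param nominal_mm nominal target position (mm, length 3).
#' @param search_x_mm lateral search half-width about the nominal position
#'   (mm).
#' @param search_z_mm axial search half-width (mm); kept small so the
#'   tissue path length above the target stays comparable across phantoms.
#' @param ball_mm neighbourhood radius for the gland-fraction score (mm).
#' @return adjusted target position (mm, length 3).
#' @export
gland_target <- function(recipe, nominal_mm, search_x_mm = 10,
                         search_z_mm = 2, ball_mm = 2.5) {
  lab3 <- segmented_phantom(recipe)
  sl <- slice_xz(lab3, nominal_mm[2])
  gl <- sl$labels == tissue_code("GLAND")
  d <- dim(gl)
  xs <- sl$origin_mm[1] + (seq_len(d[1]) - 1) * sl$voxel_mm[1]
  zs <- sl$origin_mm[2] + (seq_len(d[2]) - 1) * sl$voxel_mm[2]
  D2 <- outer((xs - nominal_mm[1])^2, (zs - nominal_mm[3])^2, "+")
  inwin <- outer(abs(xs - nominal_mm[1]) <= search_x_mm,
                 abs(zs - nominal_mm[3]) <= search_z_mm, "&")
  cand <- which(gl & inwin, arr.ind = TRUE)
  if (nrow(cand) == 0) stop("no gland voxels within the target search window")
  ri <- ceiling(ball_mm / sl$voxel_mm)
  offs <- as.matrix(expand.grid(-ri[1]:ri[1], -ri[2]:ri[2]))
  keep <- (offs[, 1] * sl$voxel_mm[1])^2 + (offs[, 2] * sl$voxel_mm[2])^2 <= ball_mm^2
  offs <- offs[keep, , drop = FALSE]
  score <- vapply(seq_len(nrow(cand)), function(q) {
    ii <- cand[q, 1] + offs[, 1]; jj <- cand[q, 2] + offs[, 2]
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
    mean(gl[cbind(ii[ok], jj[ok])])
  }, 1)
  # among solidly gland-embedded candidates, stay close to the nominal spot
  good <- score >= min(0.85, max(score)) - 1e-12
  k <- which(good)[which.min(D2[cand[good, , drop = FALSE]])]
  c(xs[cand[k, 1]], nominal_mm[2], zs[cand[k, 2]])
}

# phantom -> segmented 2D medium on the simulation lattice
case_medium <- function(case, setup) {
  lat <- sim_lattice(setup, case$target_mm[c(1, 3)])
  if (is.null(case$recipe))
    return(water_medium(lat$dim, lat$dx, lat$origin,
                        frequency_hz = setup$config$frequency_hz,
                        props = setup$props))
  lab3 <- segmented_phantom(case$recipe)
  lab2 <- slice_xz(lab3, case$target_mm[2])
  lab2s <- resample_to_grid(lab2, lat$dx, origin_mm = lat$origin,
                            dim_out = lat$dim, fill = tissue_code("WATER"))
  if (case$ablate_gland) {
    l <- lab2s$labels
    l[l == tissue_code("GLAND")] <- tissue_code("FAT")
    lab2s <- tissue_labels(l, lab2s$voxel_mm, lab2s$origin_mm)
  }
  assign_properties(lab2s, setup$props, setup$config$frequency_hz)
}

#' Run one treatment-simulation case
#'
#' Executes the full chain for one case: phantom synthesis, segmentation,
#' slicing and resampling onto the simulation grid, free-field reference
#' (cached), forward run and time-reversal drive estimation when
#' requested, the treatment run, and all focal metrics.
#'
#' @param case a [case_spec()].
#' @param setup a [study_setup()].
#' @return list with `metrics` (beta, phi, Phi, peak, distance), `inhom`
#'   (chi), the `drive` used, and a reproducibility `manifest`.
#' @export
run_case <- function(case, setup = study_setup()) {
  stage <- "phantom/segmentation"
  res <- tryCatch({
    med <- case_medium(case, setup)
    target2 <- case$target_mm[c(1, 3)]
    pose <- case$pose_deg * pi / 180
    stage <- "free-field reference"
    ff <- free_field_reference(setup)
    stage <- "drive estimation"
    drive <- geometric_drive(setup$arc)
    if (case$drive == "time_reversal") {
      fwd_src <- list(point_source(target2, med))
      recv <- arc_receivers_2d(setup$arc, med, target2, pose)
      fwd <- fdtd_run(setup$config, med, fwd_src, receivers = recv,
                      min_travel_mm = setup$arc$focal_distance_mm)
      drive <- time_reversal_drive(element_recordings(fwd), fwd$dt,
                                   setup$config$frequency_hz)
    }
    stage <- "treatment run"
    src <- array_source_2d(setup$arc, med, target2, drive, pose)
    run <- fdtd_run(setup$config, med, src,
                    min_travel_mm = setup$arc$focal_distance_mm)
    stage <- "metrics"
    reg <- metric_regions(target2, setup$r_mm, setup$R_mm)
    Q <- heat_deposition(run, med)
    beta <- localized_heating_ratio(Q, med$voxel_mm, med$origin_mm, reg)
    phi <- focusing_ratio(run$psq, med, med$voxel_mm, med$origin_mm, reg)
    # peak search restricted to the focal neighbourhood (2.5 R, the scaled
    # analogue of a 20 mm rendering box at the full geometry): the additive
    # source cells sit inside the domain and their near field is not part
    # of the insonified-tissue map
    roi <- dist2_map(dim(run$pmax), med$voxel_mm, med$origin_mm, target2) <=
      (2.5 * setup$R_mm)^2
    pmax_roi <- run$pmax
    pmax_roi[!roi] <- 0
    pk <- primary_peak(pmax_roi, med$voxel_mm, med$origin_mm, target2,
                       reference = ff$peak)
    region <- beam_path_region(med, setup$arc, target2, pose)
    inhom <- if (any(region))
      local_acoustic_inhomogeneity(med, region)
    else list(chi = 0, n_voxels = 0L)
    list(metrics = list(beta = beta, phi = phi, phi0 = ff$phi0,
                        Phi = phi / ff$phi0,
                        peak_normalized = pk$normalized,
                        peak_distance_mm = pk$distance_mm,
                        peak_location_mm = pk$location_mm),
         inhom = inhom, drive = drive, result = run, medium = med,
         manifest = list(case = unclass(case),
                         recipe_seed = if (is.null(case$recipe)) NA else case$recipe$seed,
                         dx_mm = setup$config$dx_mm,
                         cycles = setup$config$cycles,
                         frequency_hz = setup$config$frequency_hz,
                         package_version = as.character(utils::packageVersion("hifubreast"))))
  }, error = function(e) {
    stop("case '", case$label, "' failed at stage [", stage, "]: ",
         conditionMessage(e), call. = FALSE)
  })
  res
}

#' Default synthetic ensemble plan
#'
#' Twenty-four cases: twelve phantom morphologies, each treated at two
#' target positions, mirroring the 12-model x 2-target design of the
#' emulated study. Every phantom keeps the same 66.5 % fat fraction
#' (gland fraction 0.335), as the study fixes it for all patients; the
#' structural diversity comes from the gland feature scale (fine 0.8 mm,
#' wavelength-scale 1.5 mm, coarse 3 mm), the gland position (near chest
#' wall / toward nipple) and independent network realizations. Targets
#' are tumour-like (inside solid gland, [gland_target()]) at a fixed
#' depth, so the beam-path region is comparable across cases and the
#' inhomogeneity indicator responds to the fibroglandular structure
#' rather than to the path length.
#'
#' @param seed base seed; phantom k uses `seed + k`.
#' @param breast_radius_mm,nipple_height_mm phantom scale (mm).
#' @param depth_mm target height above the chest plane (mm).
#' @param target_offsets_mm lateral offsets of the two nominal target
#'   positions from the breast axis (mm).
#' @return list of [case_spec()]s.
#' @export
default_ensemble_plan <- function(seed = 2026L, breast_radius_mm = 35,
                                  nipple_height_mm = 30, depth_mm = 12,
                                  target_offsets_mm = c(-8, 8)) {
  grid <- expand.grid(corr = c(0.8, 1.5, 3.0),
                      realization = c(1L, 2L),
                      center = c(0.35, 0.70))
  base <- rep(c(-20, 0, 20), length.out = nrow(grid))
  dom <- c(2.2 * breast_radius_mm, 2.2 * breast_radius_mm,
           1.35 * nipple_height_mm)
  out <- list()
  for (k in seq_len(nrow(grid))) {
    rec <- phantom_recipe(domain_size_mm = dom,
                          breast_radius_mm = breast_radius_mm,
                          nipple_height_mm = nipple_height_mm,
                          gland_correlation_mm = grid$corr[k],
                          gland_center_frac = grid$center[k],
                          seed = seed + k)
    for (ti in seq_along(target_offsets_mm)) {
      target <- gland_target(rec, c(dom[1] / 2 + target_offsets_mm[ti],
                                    dom[2] / 2, depth_mm))
      out[[length(out) + 1]] <-
        case_spec(rec, target_mm = target,
                  pose_deg = base[k],
                  label = sprintf("s%.1f_r%d_c%.2f_t%d", grid$corr[k],
                                  grid$realization[k], grid$center[k], ti))
    }
  }
  out
}

#' Fixture treatment cases from the reference phantom morphologies
#'
#' One case per reference morphology (gland near the chest wall, gland
#' reaching the nipple, sparse gland, dense gland) at the desk-study
#' scale, with tumour-like targets at a fixed depth. Used for the
#' time-reversal and ablation comparisons.
#'
#' @param breast_radius_mm,nipple_height_mm phantom scale (mm).
#' @param depth_mm target height above the chest plane (mm).
#' @param seed base seed passed to [reference_phantoms()].
#' @return list of [case_spec()]s.
#' @export
fixture_cases <- function(breast_radius_mm = 35, nipple_height_mm = 30,
                          depth_mm = 12, seed = 100L) {
  refs <- reference_phantoms(breast_radius_mm, nipple_height_mm, seed = seed)
  lapply(refs, function(r) {
    dom <- r$recipe$domain_size_mm
    target <- gland_target(r$recipe, c(dom[1] / 2, dom[2] / 2, depth_mm))
    case_spec(r$recipe, target_mm = target, pose_deg = 0,
              label = r$description)
  })
}

#' Run an ensemble of cases
#'
#' Runs every case and assembles the per-case scatter table (Phi, chi,
#' normalized peak, peak distance, beta, phi) with the Pearson
#' correlations that summarize how focal quality relates to the local
#' acoustic inhomogeneity.
#'
#' @param plan list of [case_spec()]s (>= 3).
#' @param setup a [study_setup()].
#' @param out_csv,out_json optional output paths for the table and the
#'   correlation summary.
#' @return list with `table` (data.frame) and `correlations`.
#' @export
run_ensemble <- function(plan, setup = study_setup(), out_csv = NULL,
                         out_json = NULL) {
  if (length(plan) < 3) stop("ensemble requires at least 3 cases")
  rows <- lapply(seq_along(plan), function(k) {
    r <- run_case(plan[[k]], setup)
    data.frame(case = if (nzchar(plan[[k]]$label)) plan[[k]]$label else paste0("case", k),
               drive = plan[[k]]$drive,
               beta = r$metrics$beta, phi = r$metrics$phi,
               Phi = r$metrics$Phi, chi = r$inhom$chi,
               peak_normalized = r$metrics$peak_normalized,
               peak_distance_mm = r$metrics$peak_distance_mm,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  cors <- list(Phi_chi = pearson_correlation(tab$Phi, tab$chi),
               peak_chi = pearson_correlation(tab$peak_normalized, tab$chi),
               beta_phi = pearson_correlation(tab$beta, tab$phi))
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  if (!is.null(out_json))
    jsonlite::write_json(cors, out_json, auto_unbox = TRUE, digits = NA)
  list(table = tab, correlations = cors)
}
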