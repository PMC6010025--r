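#' Simulation configuration
#'
#' Parameters of a monochromatic FDTD run. The solver uses a staggered
#' pressure-velocity leapfrog, 6th-order central differences in space and
#' a split-field perfectly matched layer. Defaults are desk-scale; the grid
#' must resolve at least 6 points per wavelength in the slowest medium.
#'
#' @param ndim 1, 2 or 3.
#' @param dx_mm grid spacing (mm); defaults 0.075 (2D) / 0.1 (3D).
#' @param frequency_hz drive frequency (Hz), default 2 MHz.
#' @param cfl Courant number; defaults 0.4 (1D/2D) / 0.3 (3D).
#' @param amplitude source amplitude scale (Pa-equivalent; the solver is
#'   linear by default so only ratios matter).
#' @param cycles total drive cycles simulated; `NULL` lets the runner size
#'   it from the propagation distance.
#' @param avg_cycles steady-state averaging window (cycles), default 5.
#' @param ramp_cycles cosine source ramp length (cycles), default 3.
#' @param pml_cells absorbing-layer thickness (cells), default 20.
#' @param pml_r0 PML theoretical reflection coefficient, default 1e-6.
#' @param nonlinear enable the quadratic (B/A) correction; default FALSE.
#' @param ba_values per-tissue B/A in code order (water, skin, fat, gland);
#'   literature placeholder defaults.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(ndim = 2, dx_mm = NULL, frequency_hz = 2e6, cfl = NULL,
                       amplitude = 1, cycles = NULL, avg_cycles = 5,
                       ramp_cycles = 3, pml_cells = 20, pml_r0 = 1e-6,
                       nonlinear = FALSE,
                       ba_values = c(WATER = 5.2, SKIN = 7.9, FAT = 9.9, GLAND = 7.0)) {
  if (!ndim %in% 1:3) stop("ndim must be 1, 2 or 3")
  if (is.null(dx_mm)) dx_mm <- if (ndim == 3) 0.1 else 0.075
  if (is.null(cfl)) cfl <- if (ndim == 3) 0.3 else 0.4
  structure(list(ndim = ndim, dx_mm = dx_mm, frequency_hz = frequency_hz,
                 cfl = cfl, amplitude = amplitude, cycles = cycles,
                 avg_cycles = avg_cycles, ramp_cycles = ramp_cycles,
                 pml_cells = pml_cells, pml_r0 = pml_r0,
                 nonlinear = nonlinear, ba_values = ba_values),
            class = "sim_config")
}

#' Grid points per wavelength
#'
#' @param wavelength_mm acoustic wavelength (mm).
#' @param dx_mm grid spacing (mm).
#' @export
points_per_wavelength <- function(wavelength_mm, dx_mm) wavelength_mm / dx_mm

#' Stable time step
#'
#' `dt = CFL * dx / c_max` with the configured Courant number.
#'
#' @param config a [sim_config()].
#' @param medium a `medium_field` (its voxel spacing defines dx).
#' @return dt in seconds.
#' @export
stable_timestep <- function(config, medium) {
  dx <- medium$voxel_mm[1] * 1e-3
  cmax <- max(medium$c)
  if (cmax <= 0) stop("sound-speed map must be positive")
  config$cfl * dx / cmax
}

check_medium_grid <- function(config, medium) {
  if (length(unique(signif(medium$voxel_mm, 10))) != 1L)
    stop("FDTD requires an isotropic grid; resample the medium first")
  lam_min_mm <- min(medium$c) / config$frequency_hz * 1e3
  ppw <- lam_min_mm / medium$voxel_mm[1]
  if (ppw < 6 - 1e-9)
    stop(sprintf("grid resolves only %.2f points per wavelength (< 6)", ppw))
  invisible(ppw)
}

#' Run an FDTD simulation
#'
#' Time-steps the heterogeneous first-order pressure-velocity system until
#' the configured number of drive cycles has elapsed, accumulating the
#' mean-square pressure and peak |p| maps over the final averaging window
#' and recording per-element signals.
#'
#' @param config a [sim_config()].
#' @param medium a `medium_field`; its lattice is the simulation grid.
#' @param sources list of source specs, each
#'   `list(idx = <linear cell indices>, amp = <per-cell amplitude>,
#'   phase = <per-cell phase, rad>)` (see [array_source_2d()],
#'   [point_source()]).
#' @param receivers optional receiver spec
#'   `list(idx =, elem =, n_elem =)` mapping cells to element ids
#'   (see [arc_receivers_2d()]).
#' @param energy_every record the interior acoustic energy every this many
#'   steps (0 = off; 2D only).
#' @param min_travel_mm when given, warn if the simulated time does not
#'   cover this propagation distance plus ramp and averaging window.
#' @param source_stop_cycles switch the sources off after this many drive
#'   cycles (2D only; `NULL` = drive for the whole run). Used by the
#'   energy-conservation diagnostics.
#' @return object of class `sim_result` with `psq` (mean-square pressure),
#'   `pmax` (peak |p|), `rec` (steps x elements matrix), `energy`, `dt`,
#'   `nsteps`, lattice geometry and a config echo.
#' @export
fdtd_run <- function(config, medium, sources, receivers = NULL,
                     energy_every = 0, min_travel_mm = NULL,
                     source_stop_cycles = NULL) {
  check_medium_grid(config, medium)
  dt <- stable_timestep(config, medium)
  f0 <- config$frequency_hz
  cycles <- config$cycles
  if (is.null(cycles)) stop("config$cycles must be set (or use run_case)")
  nsteps <- ceiling(cycles / (f0 * dt))
  steps_per_cycle <- 1 / (f0 * dt)
  avg_start <- max(0L, nsteps - as.integer(round(config$avg_cycles * steps_per_cycle)))
  if (!is.null(min_travel_mm)) {
    need <- min_travel_mm * 1e-3 / min(medium$c) +
      (config$ramp_cycles + config$avg_cycles) / f0
    if (nsteps * dt < need)
      warning("simulated time ", signif(nsteps * dt * 1e6, 3),
              " us does not cover the propagation distance plus settling (",
              signif(need * 1e6, 3), " us): focus may not be insonified")
  }
  src_idx <- integer(0); src_amp <- numeric(0); src_phase <- numeric(0)
  for (s in sources) {
    src_idx <- c(src_idx, as.integer(s$idx) - 1L)
    src_amp <- c(src_amp, rep_len(s$amp, length(s$idx)))
    src_phase <- c(src_phase, rep_len(s$phase, length(s$idx)))
  }
  if (is.null(receivers)) receivers <- list(idx = integer(0), elem = integer(0), n_elem = 0L)
  if (is.null(receivers$w)) receivers$w <- rep(1, length(receivers$idx))
  dx <- medium$voxel_mm[1] * 1e-3
  alpha <- medium$alpha_np
  beta_map <- NULL
  if (config$nonlinear) {
    ba <- config$ba_values[medium$labels + 1L]
    beta_map <- array(1 + ba / 2, dim(medium$rho))
  }
  nd <- if (is.null(dim(medium$rho))) 1L else length(dim(medium$rho))
  if (nd != config$ndim)
    stop("medium dimensionality does not match config$ndim")
  if (nd == 1) {
    res <- fdtd1d_cpp(as.numeric(medium$rho), as.numeric(medium$c), as.numeric(alpha),
                      dx, dt, nsteps, f0, src_idx, src_amp, src_phase,
                      config$amplitude, config$ramp_cycles,
                      as.integer(receivers$idx) - 1L, avg_start,
                      config$pml_cells, config$pml_r0)
  } else if (nd == 2) {
    res <- fdtd2d_cpp(medium$rho, medium$c, alpha, dx, dt, nsteps, f0,
                      src_idx, src_amp, src_phase,
                      config$amplitude, config$ramp_cycles,
                      as.integer(receivers$idx) - 1L, as.integer(receivers$elem) - 1L,
                      as.numeric(receivers$w),
                      as.integer(receivers$n_elem), avg_start,
                      config$pml_cells, config$pml_r0,
                      config$nonlinear,
                      if (is.null(beta_map)) matrix(0, 1, 1) else beta_map,
                      as.integer(energy_every),
                      if (is.null(source_stop_cycles)) 0L
                      else as.integer(round(source_stop_cycles * steps_per_cycle)))
  } else {
    res <- fdtd3d_cpp(as.numeric(medium$rho), as.numeric(medium$c), as.numeric(alpha),
                      as.integer(dim(medium$rho)), dx, dt, nsteps, f0,
                      src_idx, src_amp, src_phase,
                      config$amplitude, config$ramp_cycles,
                      as.integer(receivers$idx) - 1L, as.integer(receivers$elem) - 1L,
                      as.numeric(receivers$w),
                      as.integer(receivers$n_elem), avg_start,
                      config$pml_cells, config$pml_r0,
                      config$nonlinear,
                      if (is.null(beta_map)) numeric(1) else as.numeric(beta_map))
  }
  structure(list(psq = res$psq, pmax = res$pmax, rec = res$rec,
                 energy = res$energy, navg = res$navg, dt = dt, nsteps = nsteps,
                 voxel_mm = medium$voxel_mm, origin_mm = medium$origin_mm,
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> ", paste(dim(x$psq), collapse = " x "), " cells, ",
      x$nsteps, " steps (dt = ", signif(x$dt * 1e9, 4), " ns), <p^2> over ",
      x$navg, " steps\n", sep = "")
  invisible(x)
}

#' Per-element recordings of a run
#'
#' Element signals are the area-weighted (cell-averaged) pressure over each
#' element footprint, sampled every time step.
#'
#' @param result a `sim_result` from a run with receivers.
#' @return matrix (time steps x elements).
#' @export
element_recordings <- function(result) {
  if (is.null(result$rec) || ncol(result$rec) == 0)
    stop("run was performed without element recording")
  result$rec
}

#' Heat deposition map
#'
#' `Q(x) = alpha(x) * 2 <p^2>(x) / (rho(x) c(x))` in W/m^3, with `<p^2>`
#' the time-averaged squared pressure, so `2 <p^2>` is the squared
#' amplitude of the monochromatic wave. The sphere-ratio metrics are
#' invariant to this convention.
#'
#' @param result a `sim_result` (or a mean-square pressure array).
#' @param medium the `medium_field` of the run.
#' @return array Q on the simulation lattice.
#' @export
heat_deposition <- function(result, medium) {
  psq <- if (inherits(result, "sim_result")) result$psq else result
  medium$alpha_np * 2 * psq / (medium$rho * medium$c)
}

#' Point source specification
#'
#' The source is spread over the `2^ndim` neighbouring cells with
#' multilinear weights so its effective position is sub-cell exact (a
#' rounded source would bias arrival phases across a surrounding array).
#'
#' @param position_mm world position (mm).
#' @param medium the `medium_field` providing the lattice.
#' @param amp,phase amplitude scale and phase (rad).
#' @export
point_source <- function(position_mm, medium, amp = 1, phase = 0) {
  d <- dim(medium$rho)
  if (is.null(d)) d <- length(medium$rho)
  nd <- length(d)
  fi <- vapply(seq_len(nd), function(a)
    (position_mm[a] - medium$origin_mm[a]) / medium$voxel_mm[a] + 1, 1)
  lo <- pmin(pmax(floor(fi), 1), d - 1)
  fr <- pmin(pmax(fi - lo, 0), 1)
  strides <- cumprod(c(1, d[-nd]))
  idx <- integer(0); w <- numeric(0)
  for (corner in 0:(2^nd - 1)) {
    bits <- as.integer(intToBits(corner))[seq_len(nd)]
    ii <- lo + bits
    idx <- c(idx, as.integer((ii - 1) %*% strides + 1))
    w <- c(w, prod(ifelse(bits == 1, fr, 1 - fr)))
  }
  keep <- w > 0
  list(idx = idx[keep], amp = amp * w[keep], phase = phase)
}
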