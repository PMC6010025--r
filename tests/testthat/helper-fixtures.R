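# Shared lazily-computed fixtures; heavyweight objects are built once per
# test session and reused across files.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# compact phantom recipe used throughout the unit tests
small_recipe <- function(seed = 7L, ...) {
  phantom_recipe(domain_size_mm = c(34, 34, 20), breast_radius_mm = 13,
                 nipple_height_mm = 12, seed = seed, ...)
}

# 1D medium helper: a labelled strip with tissue properties collapsed to
# vectors for the 1D solver
medium_1d <- function(codes, dx_mm, frequency_hz = 2e6, lossless = FALSE,
                      props = tissue_properties()) {
  n <- length(codes)
  lab <- tissue_labels(array(as.integer(codes), c(n, 1)), c(dx_mm, dx_mm))
  m <- assign_properties(lab, props, frequency_hz)
  m$rho <- as.numeric(m$rho); m$c <- as.numeric(m$c)
  m$alpha_np <- if (lossless) rep(0, n) else as.numeric(m$alpha_np)
  m$labels <- as.integer(codes)
  m$voxel_mm <- dx_mm; m$origin_mm <- 0
  m
}

# complex quadrature demodulation of the tail of a recorded signal
demod_phasor <- function(sig, dt, f0, tail_frac = 0.1) {
  ns <- length(sig)
  i0 <- floor(ns * (1 - tail_frac)):ns
  tt <- (i0 - 1) * dt
  s <- sig[i0]
  complex(real = 2 * mean(s * cos(2 * pi * f0 * tt)),
          imaginary = -2 * mean(s * sin(2 * pi * f0 * tt)))
}

# free-field 2D run at 15 points per wavelength (used by several checks)
freefield_15ppw <- function() memo("ff15", {
  f0 <- 2e6; cw <- 1482
  dx <- cw / f0 * 1e3 / 15
  org <- c(-31, -10)
  nd <- c(round(62 / dx) + 1, round(37 / dx) + 1)
  med <- water_medium(nd, dx, org, f0)
  arc <- build_arc_2d(25, 30, 8.75, n_elements = 32L, frequency_hz = f0)
  cfg <- sim_config(ndim = 2, dx_mm = dx, frequency_hz = f0,
                    cycles = ceiling(f0 * 31e-3 / cw) + 12)
  res <- fdtd_run(cfg, med, array_source_2d(arc, med, c(0, 0)),
                  min_travel_mm = 25)
  list(res = res, med = med, arc = arc, cfg = cfg, dx = dx)
})

study <- function() memo("study", study_setup())

ff_study <- function() memo("ff_study", free_field_reference(study()))

ensemble_table <- function() memo("ensemble", {
  suppressMessages(run_ensemble(default_ensemble_plan(), study()))
})

fixture_results <- function() memo("fixtures", {
  setup <- study()
  lapply(fixture_cases(), function(case) {
    geom <- suppressMessages(run_case(case, setup))
    tr_case <- case; tr_case$drive <- "time_reversal"
    tr <- suppressMessages(run_case(tr_case, setup))
    ab_case <- case; ab_case$ablate_gland <- TRUE
    ab <- suppressMessages(run_case(ab_case, setup))
    list(label = case$label, geom = geom, tr = tr, ablate = ab)
  })
})

# ---- memoised 1D solver validations (shared with the acceptance suite) ----

# numerical phase speed of a 1D plane wave in water at 15 points per
# wavelength; CFL 0.2 isolates the spatial scheme from the second-order
# temporal dispersion of the leapfrog
speed_1d <- function() memo("speed1d", {
  dx <- 1482 / 2e6 * 1e3 / 15
  med <- medium_1d(rep(0L, 1600), dx, lossless = TRUE)
  cfg <- sim_config(ndim = 1, dx_mm = dx, cfl = 0.2, cycles = 80)
  res <- fdtd_run(cfg, med, list(list(idx = 300L, amp = 1, phase = 0)),
                  receivers = list(idx = c(500L, 1100L), elem = 1:2, n_elem = 2L))
  phA <- Arg(demod_phasor(res$rec[, 1], res$dt, 2e6))
  phB <- Arg(demod_phasor(res$rec[, 2], res$dt, 2e6))
  dist_m <- 600 * dx * 1e-3
  k_true <- 2 * pi * 2e6 / 1482
  dphi <- phA - phB
  nwrap <- round((k_true * dist_m - dphi) / (2 * pi))
  2 * pi * 2e6 / ((dphi + 2 * pi * nwrap) / dist_m)
})

# measured amplitude decay of a 2 MHz wave over 10 mm of fat
atten_1d <- function() memo("atten1d", {
  dx <- 1465 / 2e6 * 1e3 / 15
  med <- medium_1d(rep(2L, 1600), dx)
  cfg <- sim_config(ndim = 1, dx_mm = dx, cycles = 80)
  res <- fdtd_run(cfg, med, list(list(idx = 300L, amp = 1, phase = 0)),
                  receivers = list(idx = c(500L, 1100L), elem = 1:2, n_elem = 2L))
  aA <- Mod(demod_phasor(res$rec[, 1], res$dt, 2e6))
  aB <- Mod(demod_phasor(res$rec[, 2], res$dt, 2e6))
  (aB / aA)^(10 / (600 * dx))
})

# measured reflection coefficient of a flat water/fat interface at normal
# incidence, via two-run (with/without interface) subtraction
fresnel_1d <- function() memo("fresnel1d", {
  dx <- 1482 / 2e6 * 1e3 / 15
  codes <- rep(0L, 1600); codes_int <- codes; codes_int[1200:1600] <- 2L
  m_ref <- medium_1d(codes, dx, lossless = TRUE)
  m_int <- medium_1d(codes_int, dx, lossless = TRUE)
  probes <- seq(500L, 900L, by = 10L)
  recv <- list(idx = probes, elem = seq_along(probes), n_elem = length(probes))
  cfg <- sim_config(ndim = 1, dx_mm = dx, cycles = 140)
  r_ref <- fdtd_run(cfg, m_ref, list(list(idx = 300L, amp = 1, phase = 0)), receivers = recv)
  r_int <- fdtd_run(cfg, m_int, list(list(idx = 300L, amp = 1, phase = 0)), receivers = recv)
  inc <- vapply(seq_along(probes), function(q)
    Mod(demod_phasor(r_ref$rec[, q], r_ref$dt, 2e6)), 1)
  refl <- vapply(seq_along(probes), function(q)
    Mod(demod_phasor(r_int$rec[, q] - r_ref$rec[, q], r_int$dt, 2e6)), 1)
  mean(refl) / mean(inc)
})

# worst relative on-axis disagreement between the Rayleigh quadrature and
# the concave-radiator closed form (full cap and holed cap)
oneil_err <- function() memo("oneil", {
  z <- c(-8, -4, -1, 0.5, 2, 6, 10)
  worst <- 0
  for (hole in c(1e-6, 35)) {
    num <- linear_focus_oracle(0, z, hole_mm = hole)
    cf <- oneil_axis(z, hole_mm = hole)
    worst <- max(worst, max(abs(abs(num) - abs(cf)) / abs(cf)))
  }
  worst
})

# point source at the focus of the 2D arc in water, with arc recordings
# (15 points per wavelength)
point_recordings <- function() memo("pointrec", {
  f0 <- 2e6
  dx <- 1482 / f0 * 1e3 / 15
  arc <- build_arc_2d(25, 30, 8.75, n_elements = 32L, frequency_hz = f0)
  org <- c(-31, -10)
  nd <- c(round(62 / dx) + 1, round(37 / dx) + 1)
  med <- water_medium(nd, dx, org, f0)
  cfg <- sim_config(ndim = 2, dx_mm = dx, frequency_hz = f0,
                    cycles = ceiling(f0 * 31e-3 / 1482) + 12)
  res <- fdtd_run(cfg, med, list(point_source(c(0, 0), med)),
                  receivers = arc_receivers_2d(arc, med, c(0, 0)),
                  min_travel_mm = 25)
  list(res = res, med = med, arc = arc, dx = dx)
})
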