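test_that("default cap geometry closes: f-number, radii, equal areas", {
  arr <- build_array()
  expect_identical(arr$f_number, 100 / 120)
  expect_equal(arr$f_number, 5 / 6, tolerance = 1e-12)
  d <- sqrt(rowSums(arr$position^2))
  expect_true(all(abs(d - 100) < 0.01))
  expect_lt(diff(range(arr$area_mm2)) / mean(arr$area_mm2), 0.01)
  # analytic cap-minus-hole area 2 pi R (h_outer - h_hole)
  h_outer <- 100 - sqrt(100^2 - 60^2)
  h_hole <- 100 * (1 - cos(asin(17.5 / 100)))
  A <- 2 * pi * 100 * (h_outer - h_hole)
  expect_equal(A, 1.160e4, tolerance = 1e-3)
  expect_lt(abs(sum(arr$area_mm2) - A) / A, 0.01)
  expect_error(build_array(hole_mm = 130), "hole")
  expect_error(build_array(focal_distance_mm = 50), "focal distance")
})

test_that("geometric drive is uniform and in phase", {
  d <- geometric_drive(build_array())
  expect_true(all(d$phase == 0))
  expect_true(all(d$amp == 1))
})

test_that("elements record identical signals for a source at the focus", {
  pr <- point_recordings()
  rec <- element_recordings(pr$res)
  tail <- floor(0.8 * nrow(rec)):nrow(rec)
  ref <- rec[tail, 1]
  rel <- apply(rec[tail, , drop = FALSE], 2, function(x)
    sqrt(mean((x - ref)^2)) / sqrt(mean(ref^2)))
  expect_lt(max(rel), 0.02)

  expect_equal(dim(rec), c(pr$res$nsteps, 32L))
})

test_that("recording without receivers errors; zero field records zero", {
  med <- water_medium(c(60, 60), 0.12, c(0, 0))
  cfg <- sim_config(ndim = 2, dx_mm = 0.12, cycles = 4)
  silent <- fdtd_run(cfg, med, list(),
                     receivers = list(idx = c(10L, 20L), elem = c(1L, 2L), n_elem = 2L))
  expect_true(all(silent$rec == 0))
  none <- fdtd_run(cfg, med, list())
  expect_error(element_recordings(none), "without element recording")
})

test_that("time reversal recovers zero lags in uniform water", {
  pr <- point_recordings()
  dr <- time_reversal_drive(element_recordings(pr$res), pr$res$dt, 2e6)
  expect_true(all(abs(dr$phase) < 0.05))
  expect_true(all(abs(dr$amp - 1) < 0.05))
})

test_that("time reversal recovers the ray delay of a slow slab", {
  f0 <- 2e6
  dx <- 1482 / f0 * 1e3 / 15
  arc <- build_arc_2d(25, 30, 8.75, n_elements = 32L, frequency_hz = f0)
  org <- c(-31, -10)
  nd <- c(round(62 / dx) + 1, round(37 / dx) + 1)
  med <- water_medium(nd, dx, org, f0)
  # 3 mm slab with c = 1400 m/s covering the x < 0 half of the aperture
  # (thin enough that the slowest oblique ray delay stays well inside the
  # half-period lag search window)
  zi <- org[2] + (seq_len(nd[2]) - 1) * dx
  xi <- org[1] + (seq_len(nd[1]) - 1) * dx
  w_mm <- 3
  slab <- outer(xi < 0, zi >= 10 & zi < 10 + w_mm, "&")
  med$c[slab] <- 1400
  med$alpha_np <- med$alpha_np * 0
  cfg <- sim_config(ndim = 2, dx_mm = dx, frequency_hz = f0,
                    cycles = ceiling(f0 * 31e-3 / 1400) + 12)
  res <- fdtd_run(cfg, med, list(point_source(c(0, 0), med)),
                  receivers = arc_receivers_2d(arc, med, c(0, 0)),
                  min_travel_mm = 25)
  dr <- time_reversal_drive(element_recordings(res), res$dt, f0)
  # ray-delay closed form per element: the ray to an element at angle
  # theta crosses the slab obliquely, path w / cos(theta)
  left <- 4:13; right <- 20:29
  exp_left <- w_mm * 1e-3 / cos(arc$angle[left]) * (1 / 1400 - 1 / 1482)
  lag_diff <- mean(dr$lag_s[left]) - mean(dr$lag_s[right])
  expect_lt(abs(lag_diff - mean(exp_left)), res$dt)
})

test_that("drive phases are invariant to a global time shift", {
  pr <- point_recordings()
  rec <- element_recordings(pr$res)
  n <- nrow(rec); k <- 37L
  d1 <- time_reversal_drive(rec[1:(n - k), ], pr$res$dt, 2e6)
  d2 <- time_reversal_drive(rec[(k + 1):n, ], pr$res$dt, 2e6)
  expect_lt(max(abs(d1$phase - d2$phase)), 0.02)
})

test_that("amplitude modes compensate, match, and handle dead channels", {
  dt <- 1e-8; t <- (0:4999) * dt
  ref <- sin(2 * pi * 2e6 * t)
  weak <- 0.1 * sin(2 * pi * 2e6 * t)
  dead <- rep(0, length(t))
  rec <- cbind(ref, weak, ref)
  inv <- time_reversal_drive(rec, dt, 2e6, reference = 1L, amp_mode = "rms_ratio")
  expect_equal(inv$amp[2], 4)  # 1/0.1 capped at 4
  expect_equal(inv$amp[1], 1)
  mat <- time_reversal_drive(rec, dt, 2e6, reference = 1L, amp_mode = "matched")
  expect_equal(mat$amp[2] / mat$amp[1], 0.1, tolerance = 1e-6)
  expect_warning(
    z <- time_reversal_drive(cbind(ref, dead), dt, 2e6, reference = 1L),
    "no signal")
  expect_equal(z$amp[2], 0)
  uni <- time_reversal_drive(rec, dt, 2e6, reference = 1L, amp_mode = "uniform")
  expect_true(all(uni$amp == 1))
})
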