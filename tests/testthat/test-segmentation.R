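test_that("median filter removes impulses and preserves flats and ramps", {
  const <- brightness_volume(array(7, c(6, 6, 6)), c(1, 1, 1))
  expect_equal(median_filter3(const)$values, const$values)

  imp <- array(0, c(7, 7, 7)); imp[4, 4, 4] <- 100
  out <- median_filter3(brightness_volume(imp, c(1, 1, 1)))
  expect_equal(out$values[4, 4, 4], 0)
  expect_true(all(out$values == 0))

  ramp <- array(rep(1:8, times = 64), c(8, 8, 8))  # linear in x
  outr <- median_filter3(brightness_volume(ramp, c(1, 1, 1)))
  expect_equal(outr$values[2:7, 2:7, 2:7], ramp[2:7, 2:7, 2:7])
})

test_that("air/breast threshold finds the histogram valley", {
  set.seed(1)
  vals <- c(rnorm(4000, 0, 5), rnorm(4000, 300, 5))
  vol <- brightness_volume(array(pmax(vals, 0), c(20, 20, 20)), c(1, 1, 1))
  thr <- air_breast_threshold(vol)
  # strictly between the modes; ties in the flat valley break toward the
  # lower bin, so the threshold sits just above the air mode's support
  expect_gt(thr, 15); expect_lt(thr, 285)

  # Gaussian mixture, against an independent brute-force scan of the same
  # smoothed histogram; the analytic valley of this mixture sits near 94
  set.seed(99)
  gm <- c(rnorm(3e5, 50, 10), rnorm(7e5, 300, 60))
  gvol <- brightness_volume(array(gm, c(100, 100, 100)), c(1, 1, 1))
  gthr <- air_breast_threshold(gvol)
  expect_gt(gthr, 85); expect_lt(gthr, 250)
  # brute force: explicit loops over smoothed bins (mode pair = global
  # maximum plus highest maximum across a genuine valley, then the valley)
  h <- attr(gthr, "histogram")
  s <- h$smoothed
  pk <- integer(0)
  for (i in seq_along(s)) {
    left <- if (i == 1) -Inf else s[i - 1]
    right <- if (i == length(s)) -Inf else s[i + 1]
    if (s[i] > left && s[i] >= right) pk <- c(pk, i)
  }
  pk <- pk[order(s[pk], decreasing = TRUE)]
  A <- pk[1]; B <- NA
  for (m in pk[-1]) {
    rng <- sort(c(A, m))
    if (rng[2] - rng[1] < 2) next
    if (min(s[(rng[1] + 1):(rng[2] - 1)]) < 0.5 * min(s[A], s[m])) { B <- m; break }
  }
  vi <- (min(A, B) + 1):(max(A, B) - 1)
  expect_equal(as.numeric(gthr), h$mids[vi[which.min(s[vi])]])

  expect_error(air_breast_threshold(
    brightness_volume(array(5, c(4, 4, 4)), c(1, 1, 1))), "air/breast")
})

test_that("air mask zeroes exactly the sub-threshold voxels", {
  v <- brightness_volume(array(c(1, 2, 3, 4), c(4, 4, 4)), c(1, 1, 1))
  expect_true(all(apply_air_mask(v, 10)$values == 0))
  expect_equal(apply_air_mask(v, 0.5)$values, v$values)
  set.seed(2)
  toy <- brightness_volume(array(runif(64, 0, 10), c(4, 4, 4)), c(1, 1, 1))
  masked <- apply_air_mask(toy, 5)
  expect_equal(sum(masked$values == 0), sum(toy$values < 5))
})

test_that("interface detection marks the breast surface only where reachable", {
  # half-space slab: constant brightness for z >= 11
  arr <- array(0, c(20, 20, 20)); arr[, , 11:20] <- 100
  iface <- detect_interface(brightness_volume(arr, c(1, 1, 1)))
  expect_equal(iface$threshold, 50)
  ind <- arrayInd(iface$indices, c(20, 20, 20))
  # scans along +/-x, +/-y graze the slab face; the true interface plane
  # z = 11 must be fully marked and nothing below it
  expect_true(all(ind[, 3] >= 11))
  expect_true(all(iface$volume$values[, , 11][cbind(1:20, 1)] == -1))
  # interior lines: the z-scans mark the true interface plane z = 11 from
  # below and the domain-boundary face z = 20 from above
  plane <- ind[ind[, 1] > 1 & ind[, 1] < 20 & ind[, 2] > 1 & ind[, 2] < 20, ]
  expect_true(all(plane[, 3] %in% c(11, 20)))
  expect_true(any(plane[, 3] == 11))

  # hemisphere: marked voxels lie within one voxel of the analytic surface
  n <- 41; h <- 1
  co <- (1:n - 21)
  d2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  hemi <- array(0, c(n, n, n)); hemi[d2 <= 15^2] <- 100
  ih <- detect_interface(brightness_volume(hemi, c(h, h, h)))
  rind <- arrayInd(ih$indices, c(n, n, n))
  rad <- sqrt(rowSums((rind - 21)^2))
  expect_true(all(abs(rad - 15) <= 1.5))

  # interior hole not reachable from the boundary stays unmarked
  slab <- array(100, c(15, 15, 15)); slab[8, 8, 8] <- 0
  is <- detect_interface(brightness_volume(slab, c(1, 1, 1)))
  hole_lin <- 8 + 15 * (7 + 15 * 7)
  expect_false(hole_lin %in% is$indices)

  expect_error(detect_interface(
    brightness_volume(array(0, c(4, 4, 4)), c(1, 1, 1))), "empty breast")
})

test_that("skin layer is an outward shell of the requested thickness", {
  # flat slab, 0.5 mm voxels, 1.5 mm skin -> exactly 3 air-side layers
  arr <- array(0, c(12, 12, 24)); arr[, , 13:24] <- 100
  vol <- brightness_volume(arr, c(0.5, 0.5, 0.5))
  iface <- detect_interface(vol)
  sk <- add_skin(vol, iface, 1.5)
  mid <- sk$values[6, 6, ]
  expect_equal(which(mid == -1), 10:12)
  expect_equal(sk$values[6, 6, 13], 100)  # interface voxel restored

  # hemispherical cap: skin voxel count within 5 % of the analytic shell
  n <- 101; h <- 0.5
  co <- (1:n - 51) * h
  d2xy <- outer(co^2, co^2, "+")
  hemi <- array(0, c(n, n, 45))
  for (k in 1:45) {
    z <- (k - 1) * h
    hemi[, , k][d2xy <= 20^2 - z^2] <- 100
  }
  hv <- brightness_volume(hemi, c(h, h, h))
  ifh <- detect_interface(hv)
  skh <- add_skin(hv, ifh, 1.5)
  n_skin <- sum(skh$values == -1)
  shell <- 2 * pi * 20^2 * 1.5 / h^3
  expect_lt(abs(n_skin - shell) / shell, 0.05)

  # sub-voxel thickness still marks one air layer
  thin <- add_skin(vol, iface, 0.4)
  expect_equal(which(thin$values[6, 6, ] == -1), 12L)
  expect_error(add_skin(vol, iface, 0), "positive")
})

test_that("fat/gland threshold hits the requested fat fraction", {
  set.seed(3)
  u <- brightness_volume(array(runif(30^3, 0, 1000), c(30, 30, 30)), c(1, 1, 1))
  thr <- fat_gland_threshold(u, 0.665)
  expect_lt(abs(thr - 665), 15)
  expect_lt(abs(attr(thr, "achieved_fraction") - 0.665), 0.005)

  # fraction -> 1 on a volume with a unique maximum
  vals <- c(runif(999, 0, 10), 99)
  vv <- brightness_volume(array(vals, c(10, 10, 10)), c(1, 1, 1))
  t1 <- fat_gland_threshold(vv, 0.999)
  expect_equal(as.numeric(t1), 99)

  # three-valued interior: equals the exhaustively best cut
  three <- c(rep(100, 200), rep(300, 500), rep(500, 300))
  tv <- brightness_volume(array(three, c(10, 10, 10)), c(1, 1, 1))
  frac <- 0.4
  cuts <- c(100, 300, 500)
  achieved <- c(0, 200, 700) / 1000
  best <- cuts[which.min(abs(achieved - frac))]
  expect_equal(as.numeric(fat_gland_threshold(tv, frac)), best)

  expect_error(fat_gland_threshold(u, 1.2), "fat_fraction")
})

test_that("segmentation is a total partition and monotone in the threshold", {
  set.seed(4)
  v <- array(runif(6^3, 0, 400), c(6, 6, 6))
  v[1:2, , ] <- 0; v[3, , ] <- -1
  vol <- brightness_volume(v, c(1, 1, 1))
  lab <- segment_tissues(vol, fat_thr = 200)
  expect_true(all(lab$labels %in% 0:3))
  expect_equal(sum(lab$labels == 0), sum(v == 0))
  expect_equal(sum(lab$labels == 1), sum(v == -1))
  expect_equal(sum(lab$labels == 2), sum(v > 0 & v < 200))
  expect_equal(sum(lab$labels == 3), sum(v >= 200))

  # hand-computed toy table
  toy <- array(0, c(2, 2, 2))
  toy[1, 1, 1] <- 0; toy[2, 1, 1] <- -1; toy[1, 2, 1] <- 50
  toy[2, 2, 1] <- 150; toy[1, 1, 2] <- 99; toy[2, 1, 2] <- 100
  toy[1, 2, 2] <- 0; toy[2, 2, 2] <- 300
  tl <- segment_tissues(brightness_volume(toy, c(1, 1, 1)), fat_thr = 100)
  expect_equal(as.integer(tl$labels),
               c(0L, 1L, 2L, 3L, 2L, 3L, 0L, 3L))

  # raising the threshold never converts FAT to GLAND
  l1 <- segment_tissues(vol, fat_thr = 150)$labels
  l2 <- segment_tissues(vol, fat_thr = 250)$labels
  expect_false(any(l1 == 2 & l2 == 3))
})

test_that("resampling: identity, midpoint mean, label preservation", {
  set.seed(5)
  v <- brightness_volume(array(runif(8^3), c(8, 8, 8)), c(1, 1, 1))
  same <- resample_to_grid(v, 1)
  expect_equal(same$values, v$values, tolerance = 1e-12)

  # query midpoints along x: fine grid at half spacing
  fine <- resample_to_grid(v, c(0.5, 1, 1))
  expect_equal(fine$values[2, , ], (v$values[1, , ] + v$values[2, , ]) / 2,
               tolerance = 1e-12)

  lab <- tissue_labels(array(sample(0:3, 6^3, TRUE), c(6, 6, 6)), c(1, 1, 1))
  rl <- resample_to_grid(lab, 0.7)
  expect_true(all(rl$labels %in% 0:3))
})

test_that("tissue properties reproduce the impedance table and unit conversions", {
  props <- tissue_properties()
  med <- assign_properties(
    tissue_labels(array(0L, c(2, 2, 2)), c(1, 1, 1)), props, 2e6)
  expect_equal(med$rho[1], 998.2)
  expect_equal(med$c[1], 1482)
  expect_equal(med$alpha0[1], 0.22)

  expect_equal(props["SKIN", "impedance"] / 1e6, 1.760, tolerance = 5e-4)
  expect_equal(props["GLAND", "impedance"] / 1e6, 1.597, tolerance = 5e-4)
  expect_equal(props["FAT", "impedance"] / 1e6, 1.443, tolerance = 5e-4)
  expect_equal(props["WATER", "impedance"] / 1e6, 1.479, tolerance = 5e-4)

  # fat at 2 MHz: 80 dB/m -> 9.21 Np/m
  expect_equal(attenuation_np_per_m(40, 2e6), 9.21, tolerance = 1e-3)
  fatmed <- assign_properties(
    tissue_labels(array(2L, c(2, 2, 2)), c(1, 1, 1)), props, 2e6)
  expect_equal(fatmed$alpha_np[1], 9.21, tolerance = 1e-3)

  bad <- tissue_labels(array(0L, c(2, 2, 2)), c(1, 1, 1))
  bad$labels[1] <- 7L
  expect_error(assign_properties(bad), "unknown label")
})

test_that("full segmentation chain is deterministic and hits the fat fraction", {
  # the fat-fraction tolerance is an asymptotic statement; use a phantom
  # with > 1e5 interior voxels
  v <- synthesize_breast_mri(
    phantom_recipe(domain_size_mm = c(56, 56, 30), breast_radius_mm = 26,
                   nipple_height_mm = 24, seed = 51L))
  lab1 <- segment_pipeline(v)
  lab2 <- segment_pipeline(v)
  expect_identical(lab1$labels, lab2$labels)
  interior <- sum(lab1$labels %in% 2:3)
  expect_gt(interior, 1e5)
  fat_frac <- sum(lab1$labels == 2) / interior
  expect_lt(abs(fat_frac - 0.665), 0.005)
})
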