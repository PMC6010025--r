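test_that("heating ratio matches an exhaustive sphere-sum oracle", {
  set.seed(8)
  n <- 41; h <- 0.5
  Q <- array(runif(n^3), c(n, n, n))
  org <- rep(-10, 3)
  reg <- metric_regions(c(0, 0, 0), 2.5, 10)
  beta <- localized_heating_ratio(Q, rep(h, 3), org, reg)
  # brute force over explicitly enumerated voxels
  num <- 0; den <- 0
  for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    d2 <- sum((org + (c(i, j, k) - 1) * h)^2)
    if (d2 <= 100) den <- den + Q[i, j, k]
    if (d2 <= 6.25) num <- num + Q[i, j, k]
  }
  expect_equal(beta, num / den, tolerance = 1e-12)

  # all heat inside the small sphere -> ratio 1
  Qin <- array(0, c(n, n, n))
  Qin[19:23, 19:23, 19:23] <- 1
  expect_equal(localized_heating_ratio(Qin, rep(h, 3), org, reg), 1)

  expect_error(localized_heating_ratio(array(0, c(n, n, n)), rep(h, 3), org, reg),
               "no heat")
})

test_that("focusing ratio matches closed-form Gaussian shell integrals", {
  h <- 0.25; co <- seq(-10.5, 10.5, by = h)
  sig <- 1.5
  d2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  psq <- exp(-d2 / (2 * sig^2))
  reg <- metric_regions(c(0, 0, 0), 2.5, 10)
  phi <- focusing_ratio(psq, NULL, rep(h, 3), rep(-10.5, 3), reg)
  shell <- function(r) stats::integrate(function(x) x^2 * exp(-x^2 / (2 * sig^2)),
                                        0, r, rel.tol = 1e-10)$value
  expect_lt(abs(phi - shell(2.5) / shell(10)) / (shell(2.5) / shell(10)), 0.01)
})

test_that("beta equals phi when alpha/(rho c) is spatially uniform", {
  set.seed(9)
  psq <- array(runif(30^2), c(30, 30))
  med <- assign_properties(tissue_labels(array(2L, c(30, 30)), c(1, 1)))
  Q <- heat_deposition(psq, med)
  reg <- metric_regions(c(15, 15), 3, 10)
  beta <- localized_heating_ratio(Q, c(1, 1), c(0, 0), reg)
  phi <- focusing_ratio(psq, med, c(1, 1), c(0, 0), reg)
  expect_equal(beta, phi, tolerance = 1e-12)
})

test_that("primary peak reports location, distance and tie-breaks", {
  f <- array(0, c(21, 21)); f[15, 9] <- 3
  pk <- primary_peak(f, c(1, 1), c(0, 0), target_mm = c(10, 10))
  expect_equal(pk$location_mm, c(14, 8))
  expect_equal(pk$distance_mm, sqrt(16 + 4))
  expect_equal(pk$value, 3)
  expect_equal(primary_peak(f, c(1, 1), c(0, 0), c(10, 10), reference = 6)$normalized, 0.5)

  # two equal maxima: the one nearer the target wins
  f2 <- array(0, c(21, 21)); f2[3, 3] <- 5; f2[11, 12] <- 5
  pk2 <- primary_peak(f2, c(1, 1), c(0, 0), target_mm = c(10, 10))
  expect_equal(pk2$location_mm, c(10, 11))
  expect_error(primary_peak(array(0, c(4, 4)), c(1, 1), c(0, 0), c(1, 1)), "empty field")
})

test_that("acoustic inhomogeneity: null, homogeneity, and step oracles", {
  uni <- assign_properties(tissue_labels(array(2L, c(40, 20)), c(0.5, 0.5)))
  reg <- array(TRUE, c(40, 20))
  expect_equal(local_acoustic_inhomogeneity(uni, reg, 2e6)$chi, 0)

  # synthetic impedance step: hand-enumerated central-difference oracle
  h_mm <- 0.5; h <- h_mm * 1e-3
  L_cols <- 40
  Zlo <- 1.4e6; Delta <- 2e5
  med <- list(impedance = matrix(Zlo, L_cols, 9), voxel_mm = c(h_mm, h_mm),
              frequency_hz = 2e6)
  med$impedance[21:L_cols, ] <- Zlo + Delta
  reg <- matrix(TRUE, L_cols, 9)
  chi <- local_acoustic_inhomogeneity(med, reg, 2e6)$chi
  # central differences spread the jump over the two flanking columns at
  # Delta/(2h) each; interior rows only (top/bottom rows see no y-gradient)
  norm <- 998.2 * 1482 / (1482 / 2e6)
  chi_hand <- sqrt(2 * (Delta / (2 * h))^2 / L_cols) / norm
  expect_equal(chi, chi_hand, tolerance = 1e-12)

  # doubling the contrast doubles chi
  med2 <- med; med2$impedance <- Zlo + 2 * (med$impedance - Zlo)
  expect_equal(local_acoustic_inhomogeneity(med2, reg, 2e6)$chi, 2 * chi,
               tolerance = 1e-12)

  # resolved linear ramp: continuum closed form sqrt(W/L) * Delta/W
  M <- 8
  ramp <- matrix(Zlo, 80, 9)
  for (i in 1:M) ramp[40 + i, ] <- Zlo + Delta * i / M
  ramp[(41 + M):80, ] <- Zlo + Delta
  med3 <- list(impedance = ramp, voxel_mm = c(h_mm, h_mm), frequency_hz = 2e6)
  chi3 <- local_acoustic_inhomogeneity(med3, matrix(TRUE, 80, 9), 2e6)$chi
  W <- M * h; L <- 80 * h
  chi_cont <- (Delta / W) * sqrt(W / L) / norm
  expect_lt(abs(chi3 - chi_cont) / chi_cont, 0.05)

  expect_error(local_acoustic_inhomogeneity(uni, reg & FALSE, 2e6), "empty")
})

test_that("beam-path region is a tissue-restricted triangle", {
  lab <- array(tissue_code("WATER"), c(100, 100))
  lab[30:70, 10:40] <- tissue_code("FAT")
  med <- assign_properties(tissue_labels(lab, c(0.5, 0.5)))
  arc <- build_arc_2d(30, 36, 10.5)
  reg <- beam_path_region(med, arc, target_mm = c(25, 5), pose_rad = 0)
  expect_true(any(reg))
  expect_true(all(med$labels[reg] != tissue_code("WATER")))
  # apex at the target: cells below the target are outside
  expect_false(any(reg[, 1:9]))
})

test_that("pearson correlation handles exact and degenerate cases", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 3), 1)
  expect_equal(pearson_correlation(1:10, -(1:10)), -1)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(pearson_correlation(1:5, rep(1, 5)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})
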