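test_that("orientation bins partition [0,180) with the half-open convention", {
  ba <- assign_bin(c(30, 100, 45, 90, 135, 0, 179.999))
  expect_identical(ba$bin, c(1L, 3L, 2L, 3L, 4L, 1L, 4L))
  expect_identical(ba$axis_class, c("ML", "AP", "AP", "AP", "ML", "ML", "ML"))
  expect_error(assign_bin(180), "0, 180")
  expect_error(assign_bin(-1), "0, 180")
  expect_error(assign_bin(NA_real_), "NA")
  # partition property: every angle lands in exactly one bin
  set.seed(8)
  th <- runif(500, 0, 180 - 1e-9)
  ba <- assign_bin(th)
  expect_identical(sum(table(ba$bin)), 500L)
  expect_identical(sum(ba$axis_class == "ML") + sum(ba$axis_class == "AP"), 500L)
})

test_that("junction intensity is the plain mean over the pixel set", {
  ch <- matrix(7, 10, 10)
  expect_identical(measure_junction_intensity(c(1L, 5L, 99L), ch), 7)
  ch[1] <- 10; ch[5] <- 20
  expect_identical(measure_junction_intensity(c(1L, 5L), ch), 15)
  expect_error(measure_junction_intensity(1L, ch, dim = c(5L, 5L)), "shape")
  expect_error(measure_junction_intensity(integer(0), ch), "empty")
})

test_that("equal intensities give t = 0 and identical axis means", {
  j <- data.frame(theta_deg = c(10, 20, 70, 100, 150, 80), mean_intensity = 5)
  ps <- polarity_summary(j)
  expect_identical(ps$t_statistic, 0)
  expect_identical(ps$p_value, 1)
  expect_identical(ps$ml_ap_ratio, 1)
  expect_error(
    polarity_summary(data.frame(theta_deg = c(10, 20, 30), mean_intensity = 1:3)),
    "axis class"
  )
})

test_that("polarity statistics scale correctly and respect ML reflection", {
  tis <- polarized_tissue(rho = 1.5, rng_seed = 41L)
  ps <- polarity_summary(tis$junctions)
  # scaling equivariance: channel x 3 scales means, leaves t and p alone
  j3 <- tis$junctions
  j3$mean_intensity <- 3 * j3$mean_intensity
  ps3 <- polarity_summary(j3)
  expect_equal(ps3$axes$mean, 3 * ps$axes$mean)
  expect_equal(ps3$t_statistic, ps$t_statistic)
  expect_equal(ps3$p_value, ps$p_value)
  expect_equal(ps3$ml_ap_ratio, ps$ml_ap_ratio)
  # reflection about the ML axis: bins swap 1<->4 and 2<->3, axis means fixed.
  # Junctions sitting exactly on a bin boundary (0/45/90/135 degrees) are
  # dropped first: an exact half-open partition necessarily reassigns them.
  jb <- tis$junctions
  jb <- jb[jb$analyzable, , drop = FALSE]
  jb <- jb[jb$theta_deg %% 45 >= 1e-9, , drop = FALSE]
  ps <- polarity_summary(jb)
  jr <- jb
  jr$theta_deg <- (180 - jr$theta_deg) %% 180
  pr <- polarity_summary(jr)
  expect_equal(pr$bins$mean[1], ps$bins$mean[4])
  expect_equal(pr$bins$mean[2], ps$bins$mean[3])
  expect_equal(pr$axes$mean, ps$axes$mean)
  expect_equal(pr$t_statistic, ps$t_statistic)
})

test_that("the ML:AP estimator recovers the simulated anisotropy", {
  for (rho in c(1, 1.5, 2)) {
    tis <- polarized_tissue(rho = rho, rng_seed = 900L + round(10 * rho))
    ps <- polarity_summary(tis$junctions)
    expect_gte(ps$n_ml + ps$n_ap, 200L)
    expect_equal(ps$ml_ap_ratio, rho, tolerance = 0.1)
    if (rho == 2) expect_lt(ps$p_value, 0.001)
    if (rho == 1) expect_gt(ps$p_value, 0.001)
  }
})

test_that("the junctional/medial partition matches hand-counted zones", {
  # 12x12 two-cell image: boundary pixels are columns 6-7, the junctional
  # band columns 5-8 (48 px); at margin 2 the medial zones are columns 1-4
  # and 9-12 (96 px); no guard pixels remain
  lab <- two_cell_vertical()
  ch <- matrix(3, 12, 12)
  pt <- partition_fluorescence(lab, ch, margin = 2)
  expect_identical(pt$junctional_mean, 3)
  expect_identical(pt$medial_mean, 3)
  expect_equal(pt$junctional_fraction, 48 / (48 + 96))
  expect_identical(pt$excluded_pixels, 0L)
  # all signal on the band
  ch2 <- matrix(0, 12, 12)
  ch2[, 5:8] <- 10
  pt2 <- partition_fluorescence(lab, ch2, margin = 2)
  expect_identical(pt2$junctional_fraction, 1)
  # a cell too small to keep a medial zone is excluded with a warning
  lab3 <- matrix(1L, 9, 9)
  lab3[, 5] <- 2L
  lab3[, 6:9] <- 3L
  expect_warning(partition_fluorescence(lab3, matrix(1, 9, 9), margin = 2), "excluded")
})

test_that("the partition recovers the rendered junctional fraction", {
  tis <- polarized_tissue(rho = 2, rng_seed = 43L, noise_sd = 5,
                          junctional_fraction = 0.9)
  pt <- partition_fluorescence(tis$tess$label, tis$channel, margin = 2)
  expect_equal(pt$junctional_fraction, 0.9, tolerance = 0.05)
})
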