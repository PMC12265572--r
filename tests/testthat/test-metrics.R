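test_that("PSNR matches closed forms and caps at zero error", {
  z <- array(0, c(4, 4, 4))
  t1 <- z; t1[1] <- 1 # dynamic range 1
  # MSE exactly 1 -> 0 dB
  p <- t1 + 1
  expect_equal(as.numeric(psnr(t1, p)), 0)
  # MSE 0.01 -> 20 dB
  p2 <- t1 + 0.1
  expect_equal(as.numeric(psnr(t1, p2)), 20, tolerance = 1e-10)
  capped <- psnr(t1, t1)
  expect_equal(as.numeric(capped), 100)
  expect_true(attr(capped, "capped"))
  # all-ones mask equals the whole-volume value exactly
  ones <- array(1, dim(t1))
  expect_equal(as.numeric(psnr(t1, p2, ones)), as.numeric(psnr(t1, p2)))
  expect_error(psnr(t1, p2, array(0, dim(t1))), class = "empty_foreground_error")
  expect_error(psnr(z, p2), class = "validation_error") # constant target
})

test_that("3D SSIM is 1 on identity, negative on anti-correlation, and matches the luminance closed form", {
  y <- make_blocky_volume(8, seed = 41)
  expect_equal(ssim3d(y, y, window = 5), 1, tolerance = 1e-12)
  # anticorrelation shows as a negative score when local means vanish
  # (otherwise the negative luminance and structure terms multiply to a
  # positive value); use a zero-local-mean oscillatory pattern
  idx <- expand.grid(z = 1:10, y = 1:10, x = 1:10)
  osc <- array(sin(2 * pi * (idx$z + idx$y + idx$x) / 5), c(10, 10, 10))
  expect_lt(ssim3d(osc, -osc, window = 5, dynamic_range = 2), 0)

  # constant volumes: only the luminance term survives
  a <- array(0.2, c(6, 6, 6))
  b <- array(0.6, c(6, 6, 6))
  r <- 1
  c1 <- (0.01 * r)^2
  c2 <- (0.03 * r)^2
  lum <- (2 * 0.2 * 0.6 + c1) / (0.2^2 + 0.6^2 + c1)
  expect_equal(ssim3d(a, b, window = 3, dynamic_range = r), lum,
               tolerance = 1e-12)

  expect_error(ssim3d(y, y, window = 4), class = "validation_error")
  expect_error(ssim3d(y, y, window = 9), class = "validation_error")

  # masked variant averages the same local map over the mask
  set.seed(42)
  p <- y + array(rnorm(length(y), 0, 0.05), dim(y))
  m <- foreground_mask(y, otsu_threshold(y))
  s_fg <- ssim3d(y, p, window = 5, mask = m)
  expect_true(is.finite(s_fg) && s_fg >= -1 && s_fg <= 1)
})

test_that("shell correlations match the brute-force frequency-bin oracle", {
  set.seed(43)
  a <- array(rnorm(16^3), c(16, 16, 16))
  b <- a + array(rnorm(16^3, 0, 0.5), c(16, 16, 16))
  sh <- frc_shell_correlation(a, b, n_shells = 8)
  orc <- oracle_fsc(a, b, 8)
  expect_equal(sh$correlation, orc, tolerance = 1e-10)
  expect_true(all(abs(sh$correlation[!is.na(sh$correlation)]) <= 1 + 1e-12))
})

test_that("FSC resolution: self-correlation hits the Nyquist floor, noise pairs the coarsest shells", {
  y <- make_blocky_volume(16, seed = 44)
  res_self <- frc_resolution(y, y)
  expect_equal(as.numeric(res_self), 2.0)
  expect_true(attr(res_self, "at_nyquist"))
  sh <- frc_shell_correlation(y, y, 8)
  expect_true(all(abs(sh$correlation[sh$n_bins > 0] - 1) < 1e-10))

  set.seed(45)
  n1 <- array(rnorm(16^3), c(16, 16, 16))
  n2 <- array(rnorm(16^3), c(16, 16, 16))
  res_noise <- frc_resolution(n1, n2, n_shells = 8)
  expect_false(attr(res_noise, "at_nyquist"))
  expect_gt(as.numeric(res_noise), 4) # resolved only at the coarsest scales

  # smoothing the prediction degrades (enlarges) the resolution estimate
  blurred <- gaussian_blur3d(y, c(2, 2, 2))
  res_blur <- frc_resolution(y, pmax(blurred, 0) +
                               array(rnorm(16^3, 0, 0.05), c(16, 16, 16)))
  expect_gt(as.numeric(res_blur), 2)
})

test_that("the metrics report assembles all fields with a target-derived mask", {
  s <- generate_sample(tiny_synth_config(seed = 46))
  tn <- normalize_volume(s$target_volume)$data
  set.seed(47)
  pred <- array(pmin(1, pmax(0, tn + rnorm(length(tn), 0, 0.05))), dim(tn))
  rep <- metrics_report(tn, pred)
  expect_named(rep, c("psnr_whole", "psnr_fg", "ssim3d_whole", "ssim3d_fg",
                      "frc_resolution", "mask_fraction"))
  expect_true(all(is.finite(unlist(rep))))
  expect_gt(rep$mask_fraction, 0)
  expect_lt(rep$mask_fraction, 0.5)
  expect_gte(rep$frc_resolution, 2)
})
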