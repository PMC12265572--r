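test_that("Otsu threshold separates a two-class volume and matches brute force", {
  v <- array(0, c(10, 10, 10))
  v[1:10, 1:10, 1] <- 1 # 10% bright voxels
  t <- otsu_threshold(v)
  expect_gt(t, 0)
  expect_lte(t, 1)
  m <- foreground_mask(v, t)
  expect_equal(m$mask, array(as.numeric(v == 1), dim(v)))

  set.seed(42)
  for (i in 1:5) {
    r <- array(runif(16^3), c(16, 16, 16))
    expect_equal(otsu_threshold(r), oracle_otsu(r))
  }
})

test_that("Otsu errors on degenerate input with a typed condition", {
  expect_error(otsu_threshold(array(0.5, c(4, 4, 4))),
               class = "degenerate_histogram_error")
  expect_error(otsu_threshold(array(c(NA, 1, 2, 3), c(2, 2, 1))),
               class = "validation_error")
  expect_error(otsu_threshold(array(1:8, c(2, 2, 2)), n_bins = 1),
               class = "validation_error")
})

test_that("foreground mask uses an inclusive >= comparison", {
  v <- array(c(0.2, 0.8), c(1, 2, 1))
  m <- foreground_mask(v, 0.5)
  expect_equal(as.numeric(m$mask), c(0, 1))
  # threshold exactly at a voxel value: that voxel is foreground
  m2 <- foreground_mask(v, 0.8)
  expect_equal(as.numeric(m2$mask), c(0, 1))
  # threshold below the minimum: all foreground
  m3 <- foreground_mask(v, 0.1)
  expect_equal(as.numeric(m3$mask), c(1, 1))
  expect_equal(m$threshold, 0.5)
})

test_that("masked MSE matches hand evaluation and reduces to plain MSE", {
  y <- array(c(1, 2), c(1, 2, 1))
  yh <- array(c(0, 0), c(1, 2, 1))
  m <- array(c(0, 1), c(1, 2, 1))
  expect_equal(masked_mse(y, yh, m), 4.0, tolerance = 1e-12)

  set.seed(7)
  a <- array(runif(27), c(3, 3, 3))
  b <- array(runif(27), c(3, 3, 3))
  ones <- array(1, c(3, 3, 3))
  expect_equal(masked_mse(a, b, ones), mean((a - b)^2), tolerance = 1e-12)
  expect_equal(masked_mse(a, a, ones), 0)
  expect_error(masked_mse(a, b, array(0, c(3, 3, 3))),
               class = "empty_foreground_error")
  expect_error(masked_mse(a, array(runif(8), c(2, 2, 2)), ones),
               class = "validation_error")
})

test_that("tunable sigmoid has its fixed points, odd symmetry and monotonicity", {
  ks <- c(-0.99, -0.9, -0.5, 0, 0.5)
  for (k in ks) {
    expect_equal(tunable_sigmoid(0, k), 0)
    expect_equal(tunable_sigmoid(1, k), 1)
    expect_equal(tunable_sigmoid(-1, k), -1)
  }
  x <- seq(-1, 1, length.out = 41)
  expect_equal(tunable_sigmoid(x, 0), x) # k = 0 is the identity
  for (k in c(-0.9, -0.3, 0.4)) {
    s <- tunable_sigmoid(x, k)
    expect_equal(tunable_sigmoid(-x, k), -s, tolerance = 1e-12)
    expect_true(all(diff(s) >= -1e-12))
    expect_true(all(abs(s) <= 1 + 1e-12))
  }
  expect_error(tunable_sigmoid(0.5, 1), class = "validation_error")
})

test_that("soft foreground is 0.5 at the transition and sharpens as k -> -1", {
  cfg0 <- spotlight_config(sigmoid_k = 0)
  thr <- 0.37
  p <- array(c(thr, 0.1, 0.9), c(1, 3, 1))
  s0 <- soft_foreground(p, cfg0, thr)
  expect_equal(s0[1, 1, 1], 0.5)
  # k = 0: affine recentring only
  scale <- max(thr, 1 - thr)
  expect_equal(as.numeric(s0),
               (pmin(1, pmax(-1, (as.numeric(p) - thr) / scale)) + 1) / 2)
  # a voxel 0.1 above the transition approaches 1 monotonically as k -> -1
  above <- array(thr + 0.1, c(1, 1, 1))
  vals <- vapply(c(-0.9, -0.99, -0.999), function(k)
    soft_foreground(above, spotlight_config(sigmoid_k = k), thr)[1], 0)
  expect_true(all(diff(vals) > 0))
  expect_gt(vals[3], 0.99)
})

test_that("Dice loss matches hand evaluation and stays in [0, 1]", {
  s <- array(c(0.5, 0.5), c(1, 2, 1))
  m <- array(c(1, 0), c(1, 2, 1))
  expect_equal(dice_loss(s, m, eps = 1), 1 - (2 * 0.5) / (1 + 1 + 1),
               tolerance = 1e-12)
  # perfect overlap: bounded by eps / (2S + eps)
  mm <- array(c(1, 0, 1, 0, 0, 0, 1, 1), c(2, 2, 2))
  eps <- 1e-6
  S <- sum(mm)
  expect_equal(dice_loss(mm, mm, eps), 1 - 2 * S / (2 * S + eps))
  expect_lte(dice_loss(mm, mm, eps), eps / (2 * S + eps))
  # disjoint nonempty supports: loss exactly 1 in the eps -> contribution
  a <- array(c(1, 0, 0, 0), c(1, 4, 1))
  b <- array(c(0, 0, 1, 1), c(1, 4, 1))
  expect_equal(dice_loss(a, b, 1e-9), 1, tolerance = 1e-8)
  # dice_loss(M, M, eps) -> 0 as eps -> 0
  expect_lt(dice_loss(mm, mm, 1e-12), 1e-12)
  set.seed(11)
  for (i in 1:10) {
    sp <- array(runif(27), c(3, 3, 3))
    mk <- array(rbinom(27, 1, 0.4), c(3, 3, 3))
    d <- dice_loss(sp, mk)
    expect_gte(d, 0)
    expect_lte(d, 1)
  }
})

test_that("combined loss is the stated convex combination with a target-derived mask", {
  y <- make_blocky_volume(8, seed = 3)
  set.seed(4)
  yh <- array(pmin(1, pmax(0, y + rnorm(length(y), 0, 0.1))), dim(y))

  l1 <- spotlight_loss(y, yh, spotlight_config(lambda_weight = 1))
  expect_equal(l1$value, unname(l1$components["mmse"]))
  l0 <- spotlight_loss(y, yh, spotlight_config(lambda_weight = 0))
  expect_equal(l0$value, unname(l0$components["dice"]))

  # half-weight equals the independently recomputed standalone components
  cfg <- spotlight_config(lambda_weight = 0.5)
  l <- spotlight_loss(y, yh, cfg)
  thr <- otsu_threshold(y)
  m <- foreground_mask(y, thr)
  mmse <- masked_mse(y, yh, m)
  dce <- dice_loss(soft_foreground(yh, cfg, thr), m, cfg$dice_eps)
  expect_equal(l$value, 0.5 * mmse + 0.5 * dce, tolerance = 1e-12)
  expect_equal(unname(l$components), c(mmse, dce), tolerance = 1e-12)

  # value always reconstructs from components
  for (lam in c(0.2, 0.7)) {
    ll <- spotlight_loss(y, yh, spotlight_config(lambda_weight = lam))
    expect_equal(ll$value,
                 lam * ll$components[["mmse"]] + (1 - lam) * ll$components[["dice"]],
                 tolerance = 1e-12)
  }

  # self-prediction: mmse exactly 0; dice is the soft-threshold residual
  ls <- spotlight_loss(y, y, cfg)
  expect_equal(unname(ls$components["mmse"]), 0)
  expect_gte(unname(ls$components["dice"]), 0)
  expect_lte(unname(ls$components["dice"]), 1)

  expect_error(spotlight_loss(array(0.3, dim(y)), y),
               class = "degenerate_histogram_error")
})

test_that("loss configuration validates its domain", {
  expect_error(spotlight_config(lambda_weight = 1.2), class = "validation_error")
  expect_error(spotlight_config(sigmoid_k = 1), class = "validation_error")
  expect_error(spotlight_config(sigmoid_k = -1), class = "validation_error")
  expect_error(spotlight_config(dice_eps = 0), class = "validation_error")
  cfg <- spotlight_config()
  expect_equal(cfg$lambda_weight, 0.8)
  expect_equal(cfg$sigmoid_k, -0.9)
  expect_equal(cfg$center_policy, "otsu_center")
})
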