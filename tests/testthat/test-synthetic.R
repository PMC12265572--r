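test_that("generation is bit-identical under one seed and distinct across seeds", {
  cfg <- tiny_synth_config(seed = 5)
  a <- generate_sample(cfg)
  b <- generate_sample(cfg)
  expect_identical(a$target_volume, b$target_volume)
  expect_identical(a$input_volume, b$input_volume)
  expect_identical(a$labels, b$labels)
  c2 <- generate_sample(tiny_synth_config(seed = 6))
  expect_false(identical(a$target_volume, c2$target_volume))
})

test_that("background-only volumes sit at the background offset", {
  cfg <- synth_config(shape = c(32, 32, 32), n_nuclei = 0, seed = 9)
  s <- generate_sample(cfg)
  expect_true(all(s$labels == 0))
  se <- cfg$background_noise_sd / sqrt(prod(cfg$shape))
  expect_lt(abs(mean(s$target_volume) - cfg$background_offset), 5 * se + 1e-4)
})

test_that("labels are consecutive, background dominates, and the clean volume is exact", {
  s <- generate_sample(synth_config(seed = 2))
  ids <- sort(unique(as.vector(s$labels[s$labels > 0])))
  expect_equal(ids, seq_along(ids))
  expect_lte(length(ids), s$config$n_nuclei)
  expect_gt(sum(s$labels == 0), sum(s$labels > 0)) # background dominates
  expect_true(all(s$clean_volume[s$labels == 0] == 0))
  expect_true(all(s$clean_volume[s$labels > 0] >=
                    s$config$foreground_intensity_range[1]))

  # with all degradation switched off the target equals the clean volume
  cfg0 <- synth_config(shape = c(32, 32, 32), n_nuclei = 2,
                       radius_range = c(4, 6),
                       axial_elongation_sigma = c(0, 0, 0),
                       background_noise_sd = 0, background_offset = 0,
                       gradient_artifact_amplitude = 0, seed = 4)
  s0 <- generate_sample(cfg0)
  expect_equal(s0$target_volume, s0$clean_volume)
})

test_that("the target's Otsu mask recovers the true nuclear foreground", {
  s <- generate_sample(synth_config(seed = 11))
  tn <- normalize_volume(s$target_volume)$data
  m <- tn >= otsu_threshold(tn)
  truth <- s$labels > 0
  f1 <- 2 * sum(m & truth) / (sum(m) + sum(truth))
  expect_gte(f1, 0.7)
})

test_that("the axial halo is present: nuclei elongated along z in the target", {
  s <- generate_sample(synth_config(seed = 13))
  sig <- s$config$axial_elongation_sigma
  for (id in seq_len(max(s$labels))) {
    # isolate the nucleus before blurring so neighbours cannot contaminate
    # the second-moment measurement
    solo <- s$clean_volume * (s$labels == id)
    blurred <- gaussian_blur3d(solo, sig)
    w <- as.vector(blurred / sum(blurred))
    co <- arrayInd(seq_along(blurred), dim(blurred))
    mu <- colSums(co * w)
    sds <- sqrt(colSums((co - matrix(mu, nrow(co), 3, byrow = TRUE))^2 * w))
    ratio <- sds[1] / mean(sds[2:3])
    # analytic spread of a blurred solid ellipsoid: sqrt(r^2/5 + sigma^2)
    r <- s$nuclei[[id]]$radius
    expected <- sqrt(r[1]^2 / 5 + sig[1]^2) /
      mean(c(sqrt(r[2]^2 / 5 + sig[2]^2), sqrt(r[3]^2 / 5 + sig[3]^2)))
    expect_gt(ratio, 1)
    expect_gte(ratio, 0.85 * expected)
  }
})

test_that("datasets carry a manifest that regenerates them bit-identically", {
  ds <- generate_dataset(tiny_synth_config(), n_samples = 3, seed_base = 70)
  expect_length(ds$samples, 3)
  expect_equal(length(unique(ds$manifest$seeds)), 3)
  again <- regenerate_dataset(ds$manifest)
  for (i in 1:3) {
    expect_identical(again[[i]]$target_volume, ds$samples[[i]]$target_volume)
    expect_identical(again[[i]]$labels, ds$samples[[i]]$labels)
  }
  # disjoint seed ranges give distinct samples
  expect_false(identical(ds$samples[[1]]$target_volume,
                         ds$samples[[2]]$target_volume))
})

test_that("TIFF round trip preserves volumes and 16-bit labels", {
  s <- generate_sample(tiny_synth_config(seed = 21))
  dir <- tempfile("tiffio")
  paths <- write_sample_tiff(s, dir, "s1")
  tgt <- read_volume_tiff(paths["target"])
  expect_equal(dim(tgt), dim(s$target_volume))
  expect_lt(max(abs(tgt - s$target_volume)), 1e-6) # 32-bit float pages
  lab <- read_volume_tiff(paths["labels"], integer_labels = TRUE)
  expect_identical(array(as.integer(lab), dim(lab)), s$labels)
  unlink(dir, recursive = TRUE)
})
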