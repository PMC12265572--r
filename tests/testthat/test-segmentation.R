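test_that("watershed finds isolated bright spheres and tolerates empty input", {
  expect_warning(lab0 <- watershed_segment(array(0, c(8, 8, 8))))
  expect_true(all(lab0 == 0))

  one <- make_sphere_volume(24, c(12, 12, 12), 6)
  lab1 <- watershed_segment(one)
  expect_equal(max(lab1), 1)
  inter <- sum(lab1 == 1 & one > 0)
  union <- sum(lab1 == 1 | one > 0)
  expect_gte(inter / union, 0.8)

  two <- make_sphere_volume(32, c(9, 9, 9), 4) +
    make_sphere_volume(32, c(24, 24, 24), 4)
  lab2 <- watershed_segment(two)
  expect_equal(max(lab2), 2)
})

test_that("IoU matrix matches hand-counted set sizes", {
  gt <- array(0L, c(5, 5, 8))
  gt[1:5, 1:5, 1:4] <- 1L # 100 voxels
  pred <- array(0L, c(5, 5, 8))
  pred[1:5, 1:4, 2:4] <- 7L # 60 inside gt
  pred[1:5, 1:4, 5] <- 7L   # 20 outside
  m <- iou_matrix(gt, pred)
  expect_equal(dim(m), c(1L, 1L))
  # |gt| = 100, |pred| = 80, intersection 60 -> union 120
  expect_equal(m[1, 1], 60 / 120)

  expect_equal(unname(iou_matrix(gt, gt)[1, 1]), 1.0)
  disj <- array(0L, dim(gt))
  disj[1:2, 1:2, 7:8] <- 1L
  expect_equal(max(iou_matrix(gt, disj)), 0)
})

test_that("average precision reproduces hand-enumerated matchings", {
  side <- 16
  gt <- make_box_labels(side, list(
    list(lo = c(1, 1, 1), hi = c(5, 5, 5)),
    list(lo = c(10, 10, 10), hi = c(14, 14, 14))))
  expect_true(all(average_precision(gt, gt)$AP == 1))

  empty <- array(0L, dim(gt))
  expect_true(all(average_precision(gt, empty)$AP == 0))

  # one prediction overlapping one of two gt instances at IoU 0.6:
  # AP@0.5 = 1/(1+0+1) = 0.5; AP@0.75: TP=0, FP=1, FN=2 -> 0
  pred <- array(0L, dim(gt))
  pred[1:5, 1:5, 1:4] <- 1L # 100/125 inside the first cube
  iou <- iou_matrix(gt, pred)[1, 1]
  expect_equal(iou, 100 / 125)
  pred2 <- array(0L, dim(gt))
  pred2[1:5, 1:5, 2:5] <- 1L
  pred2[1:5, 1:5, 6:7] <- 1L # 100 voxels inside gt, 50 outside
  iou2 <- iou_matrix(gt, pred2)[1, 1]
  expect_equal(iou2, 100 / 175) # |gt|=125, |pred|=150, inter=100
  ap <- average_precision(gt, pred2, c(0.3, 0.75))
  expect_equal(ap$AP[1], 0.5) # TP 1, FP 0, FN 1
  expect_equal(ap$AP[2], 0)   # TP 0, FP 1, FN 2
})

test_that("AP is antitone in the IoU threshold and symmetric in counts", {
  set.seed(55)
  grid <- c(0.3, 0.5, 0.7, 0.9)
  for (i in 1:20) {
    side <- 20
    n <- sample(2:4, 1)
    boxes <- lapply(seq_len(n), function(j) {
      lo <- c(sample(1:12, 1), sample(1:12, 1), sample(1:12, 1))
      list(lo = lo, hi = pmin(lo + sample(3:6, 3, TRUE), side))
    })
    gt <- make_box_labels(side, boxes)
    shift <- sample(0:3, 3, TRUE)
    predboxes <- lapply(boxes, function(b)
      list(lo = pmin(side, b$lo + shift), hi = pmin(side, b$hi + shift)))
    pred <- make_box_labels(side, predboxes)
    ap <- average_precision(gt, pred, grid)
    expect_true(all(diff(ap$AP) <= 1e-12))
    mr <- match_instances(iou_matrix(gt, pred), 0.5)
    ms <- match_instances(iou_matrix(pred, gt), 0.5)
    expect_equal(mr$TP, ms$TP)
    expect_equal(mr$FP, ms$FN)
    expect_equal(mr$FN, ms$FP)
  }
})

test_that("greedy matching equals optimal matching on generator fixtures", {
  for (sd in c(101, 202, 303, 404)) {
    s <- generate_sample(tiny_synth_config(seed = sd))
    tn <- normalize_volume(s$target_volume)$data
    pred <- suppressWarnings(watershed_segment(tn))
    iou <- iou_matrix(s$labels, pred)
    for (t in c(0.3, 0.5, 0.75)) {
      g <- match_instances(iou, t, "greedy")
      o <- match_instances(iou, t, "optimal")
      expect_equal(g$TP, o$TP)
      expect_equal(g$FP, o$FP)
      expect_equal(g$FN, o$FN)
    }
  }
})

test_that("watershed recovers the planted instance count on nearly all seeded fixtures", {
  seeds <- 1:50
  hits <- vapply(seeds, function(sd) {
    s <- generate_sample(tiny_synth_config(seed = sd))
    tn <- normalize_volume(s$target_volume)$data
    lab <- suppressWarnings(watershed_segment(tn))
    max(lab) == max(s$labels)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("threshold sweep rows agree with standalone per-threshold calls", {
  s <- generate_sample(tiny_synth_config(seed = 77))
  tn <- normalize_volume(s$target_volume)$data
  sw <- threshold_sweep(tn, s$labels, thresholds = c(-1, 0.3, 2),
                        iou_thresholds = 0.5)
  # below-minimum threshold row equals the unthresholded evaluation
  lab <- suppressWarnings(watershed_segment(tn))
  ap0 <- average_precision(s$labels, lab, 0.5)
  expect_equal(sw$AP[sw$threshold == -1], ap0$AP[1])
  # above-maximum threshold removes everything
  expect_equal(sw$AP[sw$threshold == 2], 0)
  # interior threshold consistent with a standalone call
  v <- tn
  v[v < 0.3] <- 0
  lab3 <- suppressWarnings(watershed_segment(v))
  expect_equal(sw$AP[sw$threshold == 0.3],
               average_precision(s$labels, lab3, 0.5)$AP[1])
})

test_that("the external-segmenter adapter enforces the label contract", {
  seg <- segmenter_adapter(function(v) {
    lab <- array(0L, dim(v))
    lab[v > 0.5] <- 5L # one instance, non-consecutive id
    lab
  })
  v <- make_sphere_volume(10, c(5, 5, 5), 3)
  out <- seg(v)
  expect_equal(max(out), 1L)
  bad <- segmenter_adapter(function(v) array(-1L, dim(v)))
  expect_error(bad(v), class = "validation_error")
})
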