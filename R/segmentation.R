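# Instance-segmentation evaluation: Otsu threshold + Euclidean distance
# transform + seeded watershed to extract instances, IoU-based one-to-one
# matching against ground truth, and average precision AP = TP/(TP+FP+FN)
# at a grid of IoU levels (the cell-segmentation convention, not the
# ranked-detection PR-curve AP).

relabel_consecutive <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) return(array(0L, dim(labels)))
  out <- array(match(labels, ids, nomatch = 0L), dim(labels))
  storage.mode(out) <- "integer"
  out
}

#' Watershed instance segmentation of an intensity volume
#'
#' Pipeline: Otsu binary mask (inclusive `>=`), exact 3D Euclidean distance
#' transform inside the mask, Gaussian smoothing of the distance map, seeds
#' at its local maxima (greedily suppressed to a minimum separation),
#' priority-flood watershed of the negative distance map restricted to the
#' mask, and removal of instances below `min_object_voxels`.
#'
#' A constant volume has no Otsu threshold; an empty label volume is then
#' returned with a warning rather than an error, so that evaluating an
#' all-background prediction cannot crash a pipeline.
#'
#' @param volume 3D numeric array (Z, Y, X).
#' @param min_object_voxels minimum instance size kept (default 27 = 3^3).
#' @param smoothing_sigma Gaussian sd (voxels) for the distance map.
#' @param min_seed_separation minimum seed distance in voxels; defaults to
#'   the expected nucleus radius scale (4).
#' @param n_bins Otsu histogram bins.
#' @return Integer 3D label array; 0 is background, instances are numbered
#'   consecutively from 1.
#' @export
watershed_segment <- function(volume, min_object_voxels = 27L,
                              smoothing_sigma = 1, min_seed_separation = 4L,
                              n_bins = 256L) {
  check_volume(volume)
  thr <- tryCatch(otsu_threshold(volume, n_bins),
                  degenerate_histogram_error = function(e) NULL)
  if (is.null(thr)) {
    warning("constant volume: no foreground to segment, returning empty labels")
    return(array(0L, dim(volume)))
  }
  mask <- array(as.numeric(volume >= thr), dim(volume))
  if (sum(mask) == 0) return(array(0L, dim(volume)))
  dist <- edt3d(mask)
  sm <- if (smoothing_sigma > 0) gaussian_blur3d(dist, smoothing_sigma) else dist
  r <- max(1L, as.integer(min_seed_separation))
  mx <- maxfilter3d(sm, r)
  cand <- which(mask > 0 & sm >= mx - 1e-9 & dist > 0.5)
  if (length(cand) == 0L) cand <- which(mask > 0 & dist == max(dist))[1]
  # greedy suppression: strongest maxima first, enforce minimum separation
  ord <- cand[order(-sm[cand], cand)]
  coords <- arrayInd(ord, dim(volume))
  keep <- integer(0)
  kept_xyz <- matrix(0, 0, 3)
  for (i in seq_along(ord)) {
    p <- coords[i, ]
    if (nrow(kept_xyz) > 0) {
      d2 <- rowSums((kept_xyz - matrix(p, nrow(kept_xyz), 3, byrow = TRUE))^2)
      if (min(d2) < r^2) next
    }
    keep <- c(keep, ord[i])
    kept_xyz <- rbind(kept_xyz, p)
  }
  seeds <- array(0L, dim(volume))
  seeds[keep] <- seq_along(keep)
  lab <- watershed3d(-sm, seeds, mask)
  if (min_object_voxels > 0L) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    small <- which(sizes < min_object_voxels)
    if (length(small) > 0) lab[lab %in% small] <- 0L
  }
  relabel_consecutive(lab)
}

check_labels <- function(x, name = "labels") {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop_validation(sprintf("%s must be a 3D array", name))
  if (any(x < 0) || any(x != round(x)))
    stop_validation(sprintf("%s must contain non-negative integers", name))
  invisible(x)
}

#' Pairwise IoU matrix between two label volumes
#'
#' IoU(g, p) = |g intersect p| / |g union p| over voxels, background (0)
#' excluded from every set. Instance ids are relabeled consecutively on
#' ingest.
#'
#' @param gt,pred 3D integer label arrays, same shape.
#' @return `n_gt x n_pred` matrix with attributes `gt_sizes`, `pred_sizes`.
#' @export
iou_matrix <- function(gt, pred) {
  check_labels(gt, "gt")
  check_labels(pred, "pred")
  check_same_shape(gt, pred, "gt", "pred")
  gt <- relabel_consecutive(gt)
  pred <- relabel_consecutive(pred)
  ng <- max(gt)
  np <- max(pred)
  gs <- if (ng > 0) tabulate(gt[gt > 0], ng) else integer(0)
  ps <- if (np > 0) tabulate(pred[pred > 0], np) else integer(0)
  m <- matrix(0, ng, np)
  both <- gt > 0 & pred > 0
  if (any(both) && ng > 0 && np > 0) {
    enc <- (gt[both] - 1) * np + pred[both]
    cnt <- tabulate(enc, ng * np)
    hit <- which(cnt > 0)
    for (e in hit) {
      g <- (e - 1) %/% np + 1
      p <- (e - 1) %% np + 1
      inter <- cnt[e]
      m[g, p] <- inter / (gs[g] + ps[p] - inter)
    }
  }
  attr(m, "gt_sizes") <- gs
  attr(m, "pred_sizes") <- ps
  m
}

#' One-to-one instance matching at an IoU threshold
#'
#' Candidate pairs are those with IoU >= `threshold`. `"greedy"` accepts
#' pairs in descending IoU order (ties broken by gt id then pred id);
#' `"optimal"` computes a maximum-cardinality bipartite matching over the
#' candidate pairs.
#'
#' @param iou IoU matrix from [iou_matrix()].
#' @param threshold minimum IoU for a valid match, in (0, 1).
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return Object of class `match_result`: list with `matches` (data frame
#'   gt, pred, iou), `TP`, `FP`, `FN`.
#' @export
match_instances <- function(iou, threshold, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  ng <- nrow(iou)
  np <- ncol(iou)
  cand <- which(iou >= threshold, arr.ind = TRUE)
  matches <- data.frame(gt = integer(0), pred = integer(0), iou = numeric(0))
  if (nrow(cand) > 0) {
    if (method == "greedy") {
      v <- iou[cand]
      ord <- order(-v, cand[, 1], cand[, 2])
      used_g <- logical(ng)
      used_p <- logical(np)
      for (i in ord) {
        g <- cand[i, 1]
        p <- cand[i, 2]
        if (!used_g[g] && !used_p[p]) {
          used_g[g] <- TRUE
          used_p[p] <- TRUE
          matches <- rbind(matches,
                           data.frame(gt = g, pred = p, iou = iou[g, p]))
        }
      }
    } else {
      el <- cbind(cand[, 1], ng + cand[, 2])
      gr <- igraph::graph_from_edgelist(el, directed = FALSE)
      gr <- igraph::add_vertices(gr, max(0, ng + np - igraph::vcount(gr)))
      igraph::V(gr)$type <- seq_len(igraph::vcount(gr)) > ng
      mm <- igraph::max_bipartite_match(gr)$matching
      for (g in seq_len(ng)) {
        p <- mm[g]
        if (!is.na(p)) {
          matches <- rbind(matches,
                           data.frame(gt = g, pred = p - ng,
                                      iou = iou[g, p - ng]))
        }
      }
    }
    if (nrow(matches) > 0) matches <- matches[order(matches$gt), , drop = FALSE]
    rownames(matches) <- NULL
  }
  tp <- nrow(matches)
  structure(list(matches = matches, TP = tp, FP = np - tp, FN = ng - tp,
                 threshold = threshold, method = method),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result @ IoU >= %.2f (%s): TP %d, FP %d, FN %d\n",
              x$threshold, x$method, x$TP, x$FP, x$FN))
  invisible(x)
}

#' Average precision at a grid of IoU thresholds
#'
#' At each IoU level, predicted and ground-truth instances are matched
#' one-to-one and AP = TP / (TP + FP + FN). With no instances in either
#' volume the score is defined as 1 (nothing to find, nothing hallucinated).
#'
#' @param gt,pred 3D integer label arrays, same shape.
#' @param iou_thresholds IoU levels in (0, 1).
#' @param method matching method, see [match_instances()].
#' @return Object of class `ap_report`: data frame with columns
#'   `iou_threshold`, `TP`, `FP`, `FN`, `AP`, plus attribute `mean_ap`.
#' @export
average_precision <- function(gt, pred,
                              iou_thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9),
                              method = "greedy") {
  if (any(iou_thresholds <= 0 | iou_thresholds >= 1))
    stop_validation("iou_thresholds must lie in (0, 1)")
  iou <- iou_matrix(gt, pred)
  rows <- lapply(iou_thresholds, function(t) {
    mr <- match_instances(iou, t, method)
    denom <- mr$TP + mr$FP + mr$FN
    data.frame(iou_threshold = t, TP = mr$TP, FP = mr$FP, FN = mr$FN,
               AP = if (denom == 0) 1 else mr$TP / denom)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_ap") <- mean(out$AP)
  class(out) <- c("ap_report", "data.frame")
  out
}

#' @export
print.ap_report <- function(x, ...) {
  print.data.frame(x)
  cat(sprintf("mean AP: %.4f\n", attr(x, "mean_ap")))
  invisible(x)
}

#' Intensity-threshold sweep of a prediction's segmentability
#'
#' For each intensity cutoff `t`, voxels below `t` are zeroed, the volume is
#' re-segmented with [watershed_segment()] and scored with
#' [average_precision()]; optionally image-quality metrics against `target`
#' are appended. Sweeping cutoffs across the background/foreground modes
#' shows how sensitive a model's segmentation scores are to post-hoc
#' background removal.
#'
#' @param prediction 3D numeric array.
#' @param gt 3D integer label array (ground-truth instances).
#' @param thresholds intensity cutoffs.
#' @param iou_thresholds IoU levels for AP.
#' @param target optional target volume; adds `psnr` and `ssim` columns.
#' @param ... passed to [watershed_segment()].
#' @return Data frame with one row per (threshold, iou_threshold).
#' @export
threshold_sweep <- function(prediction, gt, thresholds,
                            iou_thresholds = 0.5, target = NULL, ...) {
  check_volume(prediction, "prediction")
  check_labels(gt, "gt")
  rows <- lapply(thresholds, function(t) {
    v <- prediction
    v[v < t] <- 0
    lab <- suppressWarnings(watershed_segment(v, ...))
    ap <- average_precision(gt, lab, iou_thresholds)
    df <- data.frame(threshold = t, ap)
    if (!is.null(target)) {
      df$psnr <- as.numeric(psnr(target, v))
      df$ssim <- ssim3d(target, v)
    }
    df
  })
  do.call(rbind, rows)
}

#' Plug in an external instance segmenter
#'
#' Adapter hook for segmentation backends beyond the built-in watershed
#' (e.g. a pretrained deep segmenter run out-of-process): any function
#' mapping a 3D intensity array to an integer label array of the same shape
#' can be wrapped and used wherever [watershed_segment()] is.
#'
#' @param fn function(volume, ...) returning a 3D integer label array.
#' @return Function with the same signature that validates the contract and
#'   relabels instances consecutively.
#' @export
segmenter_adapter <- function(fn) {
  force(fn)
  function(volume, ...) {
    lab <- fn(volume, ...)
    check_labels(lab, "segmenter output")
    check_same_shape(volume, lab, "volume", "segmenter output")
    relabel_consecutive(lab)
  }
}
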