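# Pixel-level image-quality metrics, whole-image and foreground-restricted:
# PSNR, 3D structural similarity (a standard SSIM over 3D box windows,
# standing in for microscopy-specific structural similarity variants), and a
# Fourier shell correlation resolution estimate.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(R^2 / MSE)` with the dynamic range `R = max - min` taken from
#' the *target* volume (deterministic and prediction-independent). With a
#' mask, the MSE is averaged over mask voxels only. Identical volumes have
#' infinite PSNR; the returned value is capped (default 100 dB) and flagged
#' via the `"capped"` attribute.
#'
#' @param target,prediction 3D numeric arrays, same shape.
#' @param mask optional `foreground_mask` or 0/1 array; must select at least
#'   one voxel.
#' @param cap value reported for a zero-error pair (dB).
#' @return Scalar PSNR in dB with logical attribute `capped`.
#' @export
psnr <- function(target, prediction, mask = NULL, cap = 100) {
  check_volume(target, "target")
  check_volume(prediction, "prediction")
  check_same_shape(target, prediction, "target", "prediction")
  r <- max(target) - min(target)
  if (r <= 0) stop_validation("target volume is constant: PSNR dynamic range is 0")
  err <- (target - prediction)^2
  if (is.null(mask)) {
    mse <- mean(err)
  } else {
    m <- as_mask_array(mask, dim(target))
    sm <- sum(m)
    if (sm == 0) stop_empty_foreground("mask selects no voxels: masked PSNR is undefined")
    mse <- sum(m * err) / sm
  }
  if (mse == 0) return(structure(cap, capped = TRUE))
  v <- 10 * log10(r^2 / mse)
  structure(min(v, cap), capped = v > cap)
}

#' 3D structural similarity
#'
#' Standard SSIM computed with 3D box windows: local means, variances and
#' covariance from a `window^3` uniform filter (edge-renormalized), combined
#' with the usual stabilization constants `C1 = (K1*R)^2`, `C2 = (K2*R)^2`
#' where `R` is the target's dynamic range. The score is the mean of the
#' local SSIM map over all voxels, or over mask voxels when a mask is given.
#'
#' @param target,prediction 3D numeric arrays, same shape.
#' @param window odd window edge length >= 3, at most the smallest volume
#'   dimension.
#' @param mask optional `foreground_mask` or 0/1 array.
#' @param K1,K2 stabilization constants.
#' @param dynamic_range override for `R` (needed when the target is
#'   constant).
#' @return Scalar in \[-1, 1\].
#' @export
ssim3d <- function(target, prediction, window = 7L, mask = NULL,
                   K1 = 0.01, K2 = 0.03, dynamic_range = NULL) {
  check_volume(target, "target")
  check_volume(prediction, "prediction")
  check_same_shape(target, prediction, "target", "prediction")
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop_validation("window must be an odd integer >= 3")
  if (any(dim(target) < window))
    stop_validation("volume dimensions must be >= window")
  r <- if (is.null(dynamic_range)) max(target) - min(target) else dynamic_range
  if (r <= 0)
    stop_validation("dynamic range is 0; pass dynamic_range explicitly for constant targets")
  c1 <- (K1 * r)^2
  c2 <- (K2 * r)^2
  k <- rep(1, window)
  box <- function(x) sepconv3d(x, k, k, k)
  mass <- box(array(1, dim(target)))
  mu_t <- box(target) / mass
  mu_p <- box(prediction) / mass
  var_t <- pmax(box(target^2) / mass - mu_t^2, 0)
  var_p <- pmax(box(prediction^2) / mass - mu_p^2, 0)
  cov_tp <- box(target * prediction) / mass - mu_t * mu_p
  map <- ((2 * mu_t * mu_p + c1) * (2 * cov_tp + c2)) /
    ((mu_t^2 + mu_p^2 + c1) * (var_t + var_p + c2))
  if (is.null(mask)) return(mean(map))
  m <- as_mask_array(mask, dim(target))
  sm <- sum(m)
  if (sm == 0) stop_empty_foreground("mask selects no voxels: masked SSIM is undefined")
  sum(map * m) / sm
}

fft_freqs <- function(n) {
  k <- c(0:floor(n / 2), if (n > 1) -(ceiling(n / 2) - 1):-1)
  k[seq_len(n)] / n
}

#' Fourier shell correlation between two volumes
#'
#' Normalized cross-correlation of the two volumes' Fourier transforms
#' averaged over concentric spherical frequency shells (the 3D analogue of
#' Fourier ring correlation); `mode = "ring"` computes 2D rings per Z slice
#' and accumulates across slices.
#'
#' @param target,prediction 3D numeric arrays, same shape.
#' @param n_shells number of shells between 0 and the Nyquist frequency 0.5
#'   (>= 4).
#' @param mode `"shell"` (3D, default) or `"ring"` (2D per slice).
#' @return Data frame with `shell`, `freq_lo`, `freq_hi`, `freq_center`,
#'   `correlation`, `n_bins`.
#' @export
frc_shell_correlation <- function(target, prediction, n_shells = 16L,
                                  mode = c("shell", "ring")) {
  check_volume(target, "target")
  check_volume(prediction, "prediction")
  check_same_shape(target, prediction, "target", "prediction")
  mode <- match.arg(mode)
  if (n_shells < 4L) stop_validation("n_shells must be >= 4")
  edges <- seq(0, 0.5, length.out = n_shells + 1L)
  num <- den1 <- den2 <- cnt <- numeric(n_shells)
  sums_by_bin <- function(values, bin) {
    out <- numeric(n_shells)
    agg <- rowsum(values, bin)
    out[as.integer(rownames(agg))] <- agg
    out
  }
  accumulate <- function(f1, f2, radius) {
    keep <- radius <= 0.5
    bin <- pmin(findInterval(radius[keep], edges, rightmost.closed = TRUE),
                n_shells)
    x1 <- f1[keep]
    x2 <- f2[keep]
    num <<- num + sums_by_bin(Re(x1 * Conj(x2)), bin)
    den1 <<- den1 + sums_by_bin(abs(x1)^2, bin)
    den2 <<- den2 + sums_by_bin(abs(x2)^2, bin)
    cnt <<- cnt + sums_by_bin(rep(1, length(x1)), bin)
  }
  d <- dim(target)
  if (mode == "shell") {
    f1 <- fft(target)
    f2 <- fft(prediction)
    fz <- fft_freqs(d[1]); fy <- fft_freqs(d[2]); fx <- fft_freqs(d[3])
    radius <- sqrt(outer(outer(fz^2, fy^2, `+`), fx^2, `+`))
    accumulate(f1, f2, radius)
  } else {
    fy <- fft_freqs(d[2]); fx <- fft_freqs(d[3])
    radius <- sqrt(outer(fy^2, fx^2, `+`))
    for (z in seq_len(d[1])) {
      accumulate(fft(target[z, , ]), fft(prediction[z, , ]), radius)
    }
  }
  corr <- ifelse(den1 > 0 & den2 > 0, num / sqrt(den1 * den2), NA_real_)
  data.frame(shell = seq_len(n_shells),
             freq_lo = edges[-(n_shells + 1L)],
             freq_hi = edges[-1L],
             freq_center = (edges[-(n_shells + 1L)] + edges[-1L]) / 2,
             correlation = corr,
             n_bins = cnt)
}

#' FRC/FSC-based resolution estimate
#'
#' Returns the real-space distance (in voxels) at which the shell
#' correlation between the two volumes first drops below `criterion`
#' (default 1/7), linearly interpolated between shell centers. The DC shell
#' is excluded from the crossing search. If the correlation never drops
#' below the criterion, the Nyquist floor of 2 voxels is returned with
#' attribute `at_nyquist = TRUE`.
#'
#' @inheritParams frc_shell_correlation
#' @param criterion correlation cutoff in (0, 1).
#' @return Scalar resolution in voxels (>= 2), with attribute `at_nyquist`.
#' @export
frc_resolution <- function(target, prediction, n_shells = 16L,
                           criterion = 1 / 7, mode = c("shell", "ring")) {
  if (criterion <= 0 || criterion >= 1)
    stop_validation("criterion must lie in (0, 1)")
  sh <- frc_shell_correlation(target, prediction, n_shells, mode)
  sh <- sh[!is.na(sh$correlation) & sh$n_bins > 0, , drop = FALSE]
  f <- sh$freq_center
  corr <- sh$correlation
  # DC shell anchors interpolation but cannot itself be the crossing
  below <- which(corr < criterion & sh$shell > 1L)
  if (length(below) == 0L) return(structure(2.0, at_nyquist = TRUE))
  i <- below[1]
  if (i == 1L) {
    f_cross <- f[1]
  } else {
    c0 <- corr[i - 1]; c1 <- corr[i]
    w <- (c0 - criterion) / (c0 - c1)
    f_cross <- f[i - 1] + w * (f[i] - f[i - 1])
  }
  structure(max(1 / f_cross, 2.0), at_nyquist = FALSE)
}

#' Full image-quality report for one prediction/target pair
#'
#' Whole-image and foreground-restricted PSNR and 3D SSIM, the FSC
#' resolution estimate, and the foreground fraction. The mask defaults to
#' the Otsu foreground of the target, mirroring how the training mask is
#' defined.
#'
#' @param target,prediction 3D numeric arrays, same shape.
#' @param mask optional `foreground_mask`; computed from the target when
#'   `NULL`.
#' @param window SSIM window.
#' @param n_shells FSC shells.
#' @return One-row data frame: `psnr_whole`, `psnr_fg`, `ssim3d_whole`,
#'   `ssim3d_fg`, `frc_resolution`, `mask_fraction`.
#' @export
metrics_report <- function(target, prediction, mask = NULL, window = 7L,
                           n_shells = 16L) {
  if (is.null(mask)) {
    mask <- foreground_mask(target, otsu_threshold(target))
  }
  m <- as_mask_array(mask, dim(target))
  data.frame(
    psnr_whole = as.numeric(psnr(target, prediction)),
    psnr_fg = as.numeric(psnr(target, prediction, mask)),
    ssim3d_whole = ssim3d(target, prediction, window),
    ssim3d_fg = ssim3d(target, prediction, window, mask),
    frc_resolution = as.numeric(frc_resolution(target, prediction, n_shells)),
    mask_fraction = mean(m)
  )
}
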