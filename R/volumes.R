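# Volumes are plain 3D numeric arrays in (Z, Y, X) axis order. Helpers here
# validate that contract at module boundaries and handle intensity
# normalization.

check_volume <- function(x, name = "volume") {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop_validation(sprintf("%s must be a 3D array in (Z, Y, X) order", name))
  if (!is.numeric(x))
    stop_validation(sprintf("%s must be numeric", name))
  if (any(!is.finite(x)))
    stop_validation(sprintf("%s contains non-finite values", name))
  invisible(x)
}

check_same_shape <- function(a, b, name_a = "first", name_b = "second") {
  if (!identical(dim(a), dim(b)))
    stop_validation(sprintf(
      "%s (%s) and %s (%s) volumes must have identical shapes",
      name_a, paste(dim(a), collapse = "x"),
      name_b, paste(dim(b), collapse = "x")
    ))
  invisible(NULL)
}

#' Min-max normalize a volume to \[0, 1\]
#'
#' Losses are defined on intensities in \[0, 1\]; volumes are rescaled
#' per volume and the original range recorded so predictions can be mapped
#' back to raw intensity units.
#'
#' @param x 3D numeric array (Z, Y, X).
#' @return A list with `data` (the rescaled array), `min` and `max` (the
#'   original range). A constant volume maps to all zeros with `max == min`.
#' @export
normalize_volume <- function(x) {
  check_volume(x)
  mn <- min(x)
  mx <- max(x)
  d <- if (mx > mn) (x - mn) / (mx - mn) else array(0, dim(x))
  list(data = d, min = mn, max = mx)
}

#' Invert [normalize_volume()]
#'
#' @param x normalized 3D array.
#' @param norm list with `min` and `max` as returned by [normalize_volume()].
#' @return Array on the original intensity scale.
#' @export
denormalize_volume <- function(x, norm) {
  x * (norm$max - norm$min) + norm$min
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Anisotropic Gaussian blur of a 3D volume
#'
#' Separable Gaussian filtering with per-axis standard deviations, used both
#' by the synthetic-data generator (axial-elongation point-spread emulation)
#' and by the watershed seeding step.
#'
#' @param x 3D numeric array (Z, Y, X).
#' @param sigma length-3 numeric, standard deviations (voxels) per axis
#'   `(sigma_z, sigma_y, sigma_x)`; a scalar is recycled. Zeros skip the axis.
#' @return Blurred array, same shape.
#' @export
gaussian_blur3d <- function(x, sigma) {
  check_volume(x)
  sigma <- rep(as.numeric(sigma), length.out = 3L)
  if (any(sigma < 0)) stop_validation("blur sigma must be non-negative")
  sepconv3d(x,
            gaussian_kernel_1d(sigma[1]),
            gaussian_kernel_1d(sigma[2]),
            gaussian_kernel_1d(sigma[3]))
}

#' Read a multi-page TIFF as a (Z, Y, X) volume
#'
#' Continuous volumes written by [write_volume_tiff()] carry a JSON sidecar
#' (`<path>.json`) with the original intensity range; when present, the
#' volume is restored to that range on read.
#'
#' @param path file path; pages become Z slices.
#' @param integer_labels if `TRUE`, round to integers (for label volumes
#'   stored as 16-bit TIFF, where intensities are label / 65535).
#' @return 3D array (Z, Y, X).
#' @export
read_volume_tiff <- function(path, integer_labels = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = integer_labels)
  if (!is.list(pages)) pages <- list(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  out <- array(0, c(length(pages), ny, nx))
  for (i in seq_along(pages)) out[i, , ] <- pages[[i]]
  if (integer_labels) {
    return(array(as.integer(round(out)), dim(out)))
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    rng <- jsonlite::read_json(sidecar)
    out <- out * (rng$max - rng$min) + rng$min
  }
  out
}

#' Write a (Z, Y, X) volume as a multi-page TIFF
#'
#' Continuous volumes are min-max scaled into the writable \[0, 1\] range,
#' stored as 32-bit float pages, and accompanied by a `<path>.json` sidecar
#' recording the original range (TIFF stores no float metadata); label
#' volumes are stored as 16-bit unsigned integers.
#'
#' @param x 3D array (Z, Y, X).
#' @param path output file path.
#' @param labels if `TRUE`, treat `x` as integer instance labels.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(x, path, labels = FALSE) {
  check_dim <- dim(x)
  if (length(check_dim) != 3L) stop_validation("expected a 3D (Z, Y, X) array")
  if (labels) {
    if (max(x) > 65535) stop_validation("labels exceed 16-bit range")
    pages <- lapply(seq_len(check_dim[1]), function(z) {
      m <- matrix(as.integer(x[z, , ]), check_dim[2], check_dim[3])
      m / 65535
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    mn <- min(x)
    mx <- max(x)
    xs <- if (mx > mn) (x - mn) / (mx - mn) else array(0, check_dim)
    pages <- lapply(seq_len(check_dim[1]), function(z) {
      matrix(xs[z, , ], check_dim[2], check_dim[3])
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    jsonlite::write_json(list(min = mn, max = mx), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
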