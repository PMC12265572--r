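# A small 3D encoder-decoder regression backbone: conv(3^3) + ReLU blocks,
# 2x average pooling down, nearest-neighbour upsampling with additive skip
# connections back up, and a linear 3^3 output convolution. The architecture
# is deliberately plain - the training objective, not the network, is the
# subject of this package - but it is a genuinely differentiable 3D
# image-to-image map with a hand-written reverse-mode pass (src/ops.cpp).

#' Backbone architecture configuration
#'
#' @param depth number of down/up-sampling levels (>= 1). Every spatial
#'   dimension of a processed patch must be divisible by `2^depth`.
#' @param base_channels channels of the first encoder level; level `i` uses
#'   `base_channels * 2^(i-1)`.
#' @param input_channels,output_channels volume channels (default 1/1).
#' @return Object of class `backbone_config`.
#' @export
backbone_config <- function(depth = 2L, base_channels = 8L,
                            input_channels = 1L, output_channels = 1L) {
  if (depth < 1L) stop_validation("depth must be >= 1")
  if (base_channels < 1L) stop_validation("base_channels must be >= 1")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 input_channels = as.integer(input_channels),
                 output_channels = as.integer(output_channels)),
            class = "backbone_config")
}

check_patch_shape <- function(shape, depth) {
  div <- 2^depth
  if (any(shape %% div != 0))
    stop_validation(sprintf(
      "patch shape %s incompatible with depth %d: every spatial dimension must be divisible by %d",
      paste(shape, collapse = "x"), depth, div))
  invisible(NULL)
}

he_init <- function(kz, ky, kx, cin, cout) {
  sd <- sqrt(2 / (kz * ky * kx * cin))
  array(rnorm(kz * ky * kx * cin * cout, 0, sd), c(kz, ky, kx, cin, cout))
}

#' Build a backbone model
#'
#' Initializes all convolution kernels (He-scaled Gaussian) from `seed`, so
#' two builds with the same seed have identical parameters.
#'
#' @param config [backbone_config()].
#' @param seed integer RNG seed for the initialization.
#' @return Object of class `backbone`: configuration plus a named list of
#'   parameter arrays.
#' @export
build_backbone <- function(config = backbone_config(), seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  d <- config$depth
  c0 <- config$base_channels
  params <- list()
  cin <- config$input_channels
  for (i in seq_len(d)) {
    cout <- c0 * 2^(i - 1)
    params[[paste0("enc", i)]] <- list(w = he_init(3, 3, 3, cin, cout),
                                       b = numeric(cout))
    cin <- cout
  }
  cb <- c0 * 2^d
  params[["bott"]] <- list(w = he_init(3, 3, 3, cin, cb), b = numeric(cb))
  cin <- cb
  for (i in rev(seq_len(d))) {
    cout <- c0 * 2^(i - 1)
    params[[paste0("dec", i)]] <- list(w = he_init(3, 3, 3, cin, cout),
                                       b = numeric(cout))
    cin <- cout
  }
  params[["out"]] <- list(w = he_init(3, 3, 3, cin, config$output_channels),
                          b = numeric(config$output_channels))
  structure(list(config = config, params = params, seed = seed),
            class = "backbone")
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.backbone <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(p) length(p$w) + length(p$b), 0))
  cat(sprintf("3D encoder-decoder backbone: depth %d, base channels %d, %d parameters\n",
              x$config$depth, x$config$base_channels, n_par))
  invisible(x)
}

as_feature_map <- function(x, channels = 1L) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), channels)
  x
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Forward pass; with cache = TRUE also returns every intermediate needed by
# backbone_backward.
backbone_forward <- function(model, x, cache = FALSE) {
  cfg <- model$config
  p <- model$params
  x <- as_feature_map(x, cfg$input_channels)
  check_patch_shape(dim(x)[1:3], cfg$depth)
  d <- cfg$depth
  cc <- list(inputs = list(), pre = list(), skips = list())
  a <- x
  for (i in seq_len(d)) {
    nm <- paste0("enc", i)
    if (cache) cc$inputs[[nm]] <- a
    z <- conv3d_fwd(a, p[[nm]]$w, p[[nm]]$b)
    if (cache) cc$pre[[nm]] <- z
    r <- relu(z)
    cc$skips[[i]] <- r
    a <- avgpool3d(r)
  }
  if (cache) cc$inputs[["bott"]] <- a
  z <- conv3d_fwd(a, p$bott$w, p$bott$b)
  if (cache) cc$pre[["bott"]] <- z
  a <- relu(z)
  for (i in rev(seq_len(d))) {
    nm <- paste0("dec", i)
    u <- upsample3d(a)
    if (cache) cc$inputs[[nm]] <- u
    z <- conv3d_fwd(u, p[[nm]]$w, p[[nm]]$b)
    if (cache) cc$pre[[nm]] <- z
    a <- relu(z) + cc$skips[[i]]
  }
  if (cache) cc$inputs[["out"]] <- a
  z <- conv3d_fwd(a, p$out$w, p$out$b)
  # bounded intensity output: targets live on the normalized [0, 1] scale,
  # and a bounded prediction keeps the soft-threshold sigmoid inside its
  # domain, so the Dice gradient can never die on runaway voxels
  out <- 1 / (1 + exp(-z))
  if (cache) {
    cc$out_act <- out
    list(output = out, cache = cc)
  } else {
    out
  }
}

# Reverse-mode pass: returns the gradient of a scalar loss with respect to
# every parameter, given dL/doutput. Skip connections add gradients at the
# matching encoder level.
backbone_backward <- function(model, fw, gout) {
  cfg <- model$config
  p <- model$params
  cc <- fw$cache
  d <- cfg$depth
  grads <- list()
  gout <- gout * cc$out_act * (1 - cc$out_act) # logistic output
  bk <- conv3d_bwd(cc$inputs[["out"]], p$out$w, gout)
  grads[["out"]] <- list(w = bk$gw, b = bk$gb)
  ga <- bk$gx
  gskip <- vector("list", d)
  for (i in seq_len(d)) {
    nm <- paste0("dec", i)
    gskip[[i]] <- ga
    gz <- ga * (cc$pre[[nm]] > 0)
    bk <- conv3d_bwd(cc$inputs[[nm]], p[[nm]]$w, gz)
    grads[[nm]] <- list(w = bk$gw, b = bk$gb)
    ga <- upsample3d_bwd(bk$gx)
  }
  gz <- ga * (cc$pre[["bott"]] > 0)
  bk <- conv3d_bwd(cc$inputs[["bott"]], p$bott$w, gz)
  grads[["bott"]] <- list(w = bk$gw, b = bk$gb)
  ga <- bk$gx
  for (i in rev(seq_len(d))) {
    nm <- paste0("enc", i)
    gr <- avgpool3d_bwd(ga, dim(cc$skips[[i]])) + gskip[[i]]
    gz <- gr * (cc$pre[[nm]] > 0)
    bk <- conv3d_bwd(cc$inputs[[nm]], p[[nm]]$w, gz)
    grads[[nm]] <- list(w = bk$gw, b = bk$gb)
    ga <- bk$gx
  }
  grads
}

#' Full-volume prediction by overlapping tiles
#'
#' Volumes larger than one patch are processed as overlapping tiles blended
#' with separable triangular weights, so tiling introduces no seams.
#'
#' @param model a `backbone` object.
#' @param input 3D numeric array (Z, Y, X).
#' @param patch_size tile edge length (scalar or length 3); must be
#'   divisible by `2^depth`. Defaults to the whole volume when that is
#'   compatible.
#' @param overlap tile overlap in voxels (`< patch_size`).
#' @return Predicted 3D array, same shape as `input`.
#' @export
predict_volume <- function(model, input, patch_size = NULL, overlap = 8L) {
  check_volume(input, "input")
  shape <- dim(input)
  d <- model$config$depth
  if (is.null(patch_size)) {
    check_patch_shape(shape, d)
    out <- backbone_forward(model, input)
    return(array(out, shape))
  }
  patch <- rep(as.integer(patch_size), length.out = 3L)
  overlap <- rep(as.integer(overlap), length.out = 3L)
  check_patch_shape(patch, d)
  if (any(overlap >= patch))
    stop_validation("overlap must be smaller than patch_size")
  if (any(patch > shape))
    stop_validation("patch_size exceeds the volume shape")
  stride <- patch - overlap
  starts <- lapply(1:3, function(a) {
    s <- unique(pmin(seq(1L, shape[a], by = stride[a]), shape[a] - patch[a] + 1L))
    s[c(TRUE, diff(s) > 0)]
  })
  # separable triangular blending window
  win1 <- function(n) {
    w <- pmin(seq_len(n), rev(seq_len(n)))
    w / max(w)
  }
  wz <- win1(patch[1]); wy <- win1(patch[2]); wx <- win1(patch[3])
  w3 <- outer(outer(wz, wy), wx)
  acc <- array(0, shape)
  wacc <- array(0, shape)
  for (z0 in starts[[1]]) for (y0 in starts[[2]]) for (x0 in starts[[3]]) {
    iz <- z0:(z0 + patch[1] - 1L)
    iy <- y0:(y0 + patch[2] - 1L)
    ix <- x0:(x0 + patch[3] - 1L)
    tile <- input[iz, iy, ix, drop = FALSE]
    pred <- array(backbone_forward(model, tile), patch)
    acc[iz, iy, ix] <- acc[iz, iy, ix] + pred * w3
    wacc[iz, iy, ix] <- wacc[iz, iy, ix] + w3
  }
  acc / wacc
}

flatten_params <- function(params) {
  out <- list()
  for (nm in names(params)) {
    out[[paste0(nm, ".w")]] <- params[[nm]]$w
    out[[paste0(nm, ".b")]] <- params[[nm]]$b
  }
  out
}

#' Extract backbone parameters as a numeric vector
#'
#' @param object a `backbone` object.
#' @param ... unused.
#' @return Named numeric vector of all kernel weights and biases.
#' @export
coef.backbone <- function(object, ...) {
  fl <- flatten_params(object$params)
  unlist(fl)
}

#' Save a fitted model or backbone checkpoint
#'
#' Single-file checkpoint holding the architecture configuration, all
#' parameters, normalization policy and training history, with a schema
#' version for forward compatibility.
#'
#' @param object a `backbone` or `virtual_stain_fit` object.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(list(schema = 1L, class = class(object)[1], object = object), path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @return The stored object.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (is.null(x$schema) || x$schema != 1L)
    stop_validation("unrecognized checkpoint schema")
  x$object
}
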