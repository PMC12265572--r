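# Shared fixtures and independent oracles. Oracles deliberately use naive
# explicit loops so they stay independent of the vectorized implementation
# paths they check.

# Brute-force Otsu: exhaustively score every histogram cut by explicitly
# summing class masses and means.
oracle_otsu <- function(volume, n_bins = 256L) {
  mn <- min(volume)
  mx <- max(volume)
  width <- (mx - mn) / n_bins
  bin <- pmin(floor((volume - mn) / width) + 1L, n_bins)
  h <- tabulate(bin, nbins = n_bins)
  mid <- mn + (seq_len(n_bins) - 0.5) * width
  n <- sum(h)
  best <- -Inf
  best_cut <- NA_integer_
  for (cut in seq_len(n_bins - 1L)) {
    n0 <- sum(h[1:cut])
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(h[1:cut] * mid[1:cut]) / n0
    mu1 <- sum(h[(cut + 1):n_bins] * mid[(cut + 1):n_bins]) / n1
    s <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (s > best + 1e-15) {
      best <- s
      best_cut <- cut
    }
  }
  mn + best_cut * width
}

# Brute-force shell accumulation: visit every frequency voxel once,
# compute its radius and bin explicitly, and accumulate scalar sums.
oracle_fsc <- function(target, prediction, n_shells) {
  d <- dim(target)
  f1 <- fft(target)
  f2 <- fft(prediction)
  freqs <- function(n) {
    k <- 0:(n - 1)
    k[k > n / 2] <- k[k > n / 2] - n
    k / n
  }
  fz <- freqs(d[1]); fy <- freqs(d[2]); fx <- freqs(d[3])
  edges <- seq(0, 0.5, length.out = n_shells + 1L)
  num <- den1 <- den2 <- numeric(n_shells)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    r <- sqrt(fz[i]^2 + fy[j]^2 + fx[k]^2)
    if (r > 0.5) next
    b <- min(max(findInterval(r, edges, rightmost.closed = TRUE), 1L), n_shells)
    a <- f1[i, j, k]
    bb <- f2[i, j, k]
    num[b] <- num[b] + Re(a * Conj(bb))
    den1[b] <- den1[b] + Mod(a)^2
    den2[b] <- den2[b] + Mod(bb)^2
  }
  ifelse(den1 > 0 & den2 > 0, num / sqrt(den1 * den2), NA_real_)
}

# A small volume with an unambiguous foreground block, for loss tests.
make_blocky_volume <- function(side = 8L, seed = 1L) {
  set.seed(seed)
  v <- array(runif(side^3, 0, 0.2), rep(side, 3))
  h <- max(2L, side %/% 3L)
  v[1:h, 1:h, 1:h] <- runif(h^3, 0.7, 1)
  v
}

# Paint a sphere of radius r centred at ctr into a zero volume.
make_sphere_volume <- function(side, ctr, r, intensity = 1) {
  v <- array(0, rep(side, 3))
  for (z in 1:side) for (y in 1:side) for (x in 1:side) {
    if ((z - ctr[1])^2 + (y - ctr[2])^2 + (x - ctr[3])^2 <= r^2)
      v[z, y, x] <- intensity
  }
  v
}

# Label volume of axis-aligned boxes; boxes is a list of list(lo, hi).
make_box_labels <- function(side, boxes) {
  lab <- array(0L, rep(side, 3))
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    lab[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]] <- i
  }
  lab
}

# Central finite differences of a scalar function at x (an array).
finite_diff_grad <- function(f, x, h = 1e-6) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b) / pmax(1e-6, abs(a) + abs(b)))
}

tiny_synth_config <- function(seed = 1L, shape = 32L) {
  synth_config(shape = rep(shape, 3), n_nuclei = 3L, radius_range = c(4, 6),
               seed = seed)
}
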