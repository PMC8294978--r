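# Small-grid generator parameters used throughout the suite; noise off by
# default so image-path oracles are exact.
small_params <- function(..., seed = 7L) {
  args <- utils::modifyList(
    list(nx = 96, ny = 96, nz = 48, depth = 4,
         speckle = 0, flow_noise = 0, seed = seed),
    list(...))
  do.call(synth_params, args)
}

# Brute-force Phansalkar oracle: per-pixel sliding circular window over a
# mirror-padded image, recomputing m, s and t literally from the formula.
phansalkar_oracle <- function(v, radius, k = 0.25, r = 0.5, p = 2, q = 10) {
  nr <- nrow(v); nc <- ncol(v)
  refl <- function(i, n) {
    per <- (i - 1) %% (2 * n - 2)
    ifelse(per < n, per + 1, 2 * n - 1 - per)
  }
  out <- matrix(FALSE, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    vals <- c()
    for (dy in -radius:radius) for (dx in -radius:radius) {
      if (dy * dy + dx * dx <= radius * radius) {
        vals <- c(vals, v[refl(y + dy, nr), refl(x + dx, nc)])
      }
    }
    m <- mean(vals)
    s <- sqrt(mean((vals - m)^2))
    t <- m * (1 + p * exp(-q * m) + k * (s / r - 1))
    out[y, x] <- v[y, x] > t
  }
  out
}

# Independent point-in-polygon oracle: angle-summation (winding by ray
# casting written differently from the implementation) per pixel center.
ray_cast_oracle <- function(vertices, shape) {
  n <- nrow(vertices)
  out <- matrix(FALSE, shape[1], shape[2])
  for (row in seq_len(shape[1])) for (col in seq_len(shape[2])) {
    px <- col - 1; py <- row - 1
    crossings <- 0
    on_edge <- FALSE
    for (e in seq_len(n)) {
      a <- vertices[e, ]; b <- vertices[if (e == n) 1 else e + 1, ]
      # point-on-segment check
      cross <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
      if (abs(cross) < 1e-9 &&
          px >= min(a[1], b[1]) - 1e-9 && px <= max(a[1], b[1]) + 1e-9 &&
          py >= min(a[2], b[2]) - 1e-9 && py <= max(a[2], b[2]) + 1e-9)
        on_edge <- TRUE
      if ((a[2] > py) != (b[2] > py)) {
        xint <- a[1] + (py - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
        if (px < xint) crossings <- crossings + 1
      }
    }
    out[row, col] <- on_edge || (crossings %% 2 == 1)
  }
  out
}
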