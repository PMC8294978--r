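#' Phansalkar thresholding parameters
#'
#' Parameters of the Phansalkar auto-local threshold
#' \deqn{t = m (1 + p e^{-q m} + k (s/r - 1))}
#' where m and s are the local mean and standard deviation of the normalized
#' intensities over a circular window. Defaults are the Fiji
#' "Auto Local Threshold > Phansalkar" plugin defaults (radius 15 px,
#' k = 0.25, r = 0.5, p = 2, q = 10), appropriate for low-contrast
#' angiographic images.
#'
#' @param radius window radius in pixels (>= 1).
#' @param k weight of the normalized-deviation term.
#' @param r dynamic range of the standard deviation (> 0).
#' @param p,q parameters of the exponential mean-dependent term.
#' @return An object of class `phansalkar_params`.
#' @export
phansalkar_params <- function(radius = 15, k = 0.25, r = 0.5, p = 2, q = 10) {
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L)
    stop("phansalkar_params: radius must be >= 1", call. = FALSE)
  if (r <= 0) stop("phansalkar_params: r must be > 0", call. = FALSE)
  structure(list(radius = radius, k = k, r = r, p = p, q = q),
            class = "phansalkar_params")
}

# Offsets (dy, dx) of the circular window of given radius, centre included.
circular_offsets <- function(radius) {
  d <- -radius:radius
  g <- expand.grid(dy = d, dx = d)
  g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

# Fold out-of-range indices back into [1, n] by mirror reflection (period
# 2n - 2, edge row not repeated); handles padding wider than the image.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * n - 2L)
  ifelse(p < n, p + 1L, 2L * n - 1L - p)
}

# Mirror-pad a matrix by `pad` pixels on every side.
mirror_pad <- function(m, pad) {
  nr <- nrow(m); nc <- ncol(m)
  m[reflect_index((1L - pad):(nr + pad), nr),
    reflect_index((1L - pad):(nc + pad), nc), drop = FALSE]
}

#' Phansalkar auto-local threshold
#'
#' Binarizes a grayscale image with the Phansalkar local threshold: a pixel is
#' foreground iff its normalized intensity strictly exceeds
#' `t = m * (1 + p*exp(-q*m) + k*((s/r) - 1))`, with m and s the mean and
#' standard deviation of the normalized image over a circular window centred
#' on the pixel. Intensities are first normalized to \[0,1\] by the image's
#' declared bit-depth maximum; the window uses mirror padding at the borders
#' and the population (1/n) standard deviation. Ties (value equal to t) go to
#' background. The computation is deterministic.
#'
#' @param image a [gray_image()] (or bare numeric matrix, taken as already in
#'   \[0,1\]).
#' @param params a [phansalkar_params()].
#' @return A [binary_image()] of the same shape, `TRUE` = foreground.
#' @examples
#' img <- gray_image(matrix(0.5, 16, 16), bit_depth = 1)
#' sum(phansalkar_threshold(img)$data)  # constant 0.5 image: all foreground
#' @export
phansalkar_threshold <- function(image, params = phansalkar_params()) {
  if (is.matrix(image)) image <- gray_image(image, bit_depth = 1)
  stopifnot(inherits(image, "gray_image"),
            inherits(params, "phansalkar_params"))
  v <- image$data / bit_depth_max(image$bit_depth)
  rad <- params$radius
  if (rad >= nrow(v) && rad >= ncol(v))
    stop("phansalkar_threshold: window radius exceeds both image dimensions",
         call. = FALSE)
  vp <- mirror_pad(v, rad)
  off <- circular_offsets(rad)
  nr <- nrow(v); nc <- ncol(v)
  pr <- rad; pc <- rad
  s1 <- matrix(0, nr, nc); s2 <- matrix(0, nr, nc)
  for (i in seq_len(nrow(off))) {
    w <- vp[(1 + pr + off$dy[i]):(nr + pr + off$dy[i]),
            (1 + pc + off$dx[i]):(nc + pc + off$dx[i]), drop = FALSE]
    s1 <- s1 + w
    s2 <- s2 + w * w
  }
  n <- nrow(off)
  m <- s1 / n
  s <- sqrt(pmax(s2 / n - m * m, 0))
  t <- m * (1 + params$p * exp(-params$q * m) + params$k * (s / params$r - 1))
  binary_image(v > t)
}

#' Flow density inside a region of interest
#'
#' Flow density (FD) is the percentage of foreground (white) pixels of a
#' binarized image inside a mask: `100 * sum(binary & mask) / sum(mask)`.
#'
#' @param binary a [binary_image()] (or logical matrix): the binarized image.
#' @param mask a [binary_image()] (or logical matrix) of the same shape with
#'   at least one `TRUE` pixel.
#' @return Flow density in percent, in \[0, 100\].
#' @export
flow_density <- function(binary, mask) {
  b <- as_mask_matrix(binary, "binary")
  m <- as_mask_matrix(mask, "mask")
  if (!identical(dim(b), dim(m)))
    stop("flow_density: binary and mask shapes differ", call. = FALSE)
  n <- sum(m)
  if (n == 0L)
    stop("flow_density: empty mask (degenerate ROI)", call. = FALSE)
  100 * sum(b & m) / n
}
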