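#' Grayscale image container
#'
#' A 2-D intensity image together with its declared intensity range (bit
#' depth) and optional lateral pixel spacing. Intensities are kept in their
#' native integer units (0..255 for 8-bit, 0..65535 for 16-bit) or already in
#' \[0,1\] when `bit_depth = 1`; normalization to \[0,1\] happens inside the
#' operations that require it.
#'
#' @param data numeric matrix of intensities (rows = y, columns = x).
#' @param bit_depth declared bit depth: 8, 16, or 1 for images already scaled
#'   to \[0,1\].
#' @param spacing_mm lateral pixel spacing in mm/px, or `NA` when unknown.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(data, bit_depth = 8, spacing_mm = NA_real_) {
  if (!is.matrix(data) || length(data) == 0L)
    stop("gray_image: 'data' must be a non-empty matrix", call. = FALSE)
  if (!bit_depth %in% c(1, 8, 16))
    stop("gray_image: bit_depth must be 1, 8 or 16", call. = FALSE)
  mx <- bit_depth_max(bit_depth)
  rng <- range(data, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > mx)
    stop(sprintf("gray_image: intensities outside declared range [0, %s]", mx),
         call. = FALSE)
  structure(list(data = data, bit_depth = bit_depth, spacing_mm = spacing_mm),
            class = "gray_image")
}

bit_depth_max <- function(bit_depth) {
  if (bit_depth == 1) 1 else 2^bit_depth - 1
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("gray_image: %d x %d px, %s-bit, spacing %s mm/px\n",
              nrow(x$data), ncol(x$data), x$bit_depth,
              ifelse(is.na(x$spacing_mm), "unknown", format(x$spacing_mm))))
  invisible(x)
}

#' Binary image container
#'
#' A 2-D logical mask with the same shape as the image it was derived from.
#'
#' @param data logical matrix.
#' @return An object of class `binary_image`.
#' @export
binary_image <- function(data) {
  if (!is.matrix(data) || !is.logical(data) || length(data) == 0L)
    stop("binary_image: 'data' must be a non-empty logical matrix",
         call. = FALSE)
  structure(list(data = data), class = "binary_image")
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("binary_image: %d x %d px, %d foreground\n",
              nrow(x$data), ncol(x$data), sum(x$data)))
  invisible(x)
}

# Accept either a binary_image or a bare logical matrix; return the matrix.
as_mask_matrix <- function(x, arg = "mask") {
  if (inherits(x, "binary_image")) return(x$data)
  if (is.matrix(x) && is.logical(x)) return(x)
  stop(sprintf("'%s' must be a binary_image or logical matrix", arg),
       call. = FALSE)
}
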