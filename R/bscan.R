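#' B-scan with red flow overlay
#'
#' A cross-sectional OCT structural image rendered in gray with the OCTA
#' flow signal overlaid in red, as exported by the device review software:
#' an 8-bit RGB image (rows = axial, row 0 at the top = vitreous; columns =
#' lateral) plus the ILM polyline as a per-column axial row coordinate
#' (0-based, like all pixel coordinates).
#'
#' @param rgb numeric array `(rows, cols, 3)` with integer values 0..255.
#' @param axial_um_px axial pixel spacing, um/px (`NA` if unknown).
#' @param lateral_mm_px lateral pixel spacing, mm/px (`NA` if unknown).
#' @param ilm_row numeric vector of length `ncol`: 0-based axial row of the
#'   ILM in each column.
#' @return An object of class `bscan_rgb`.
#' @export
bscan_rgb <- function(rgb, axial_um_px = NA_real_, lateral_mm_px = NA_real_,
                      ilm_row = NULL) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L)
    stop("bscan_rgb: need an RGB array with exactly 3 channels (format error)",
         call. = FALSE)
  if (min(rgb) < 0 || max(rgb) > 255)
    stop("bscan_rgb: 8-bit RGB expected (values 0..255)", call. = FALSE)
  if (!is.null(ilm_row)) {
    if (length(ilm_row) != d[2])
      stop("bscan_rgb: ILM polyline length must equal image width",
           call. = FALSE)
    if (any(ilm_row < 0 | ilm_row > d[1] - 1))
      stop("bscan_rgb: ILM polyline outside image bounds", call. = FALSE)
  }
  structure(list(rgb = rgb, axial_um_px = axial_um_px,
                 lateral_mm_px = lateral_mm_px, ilm_row = ilm_row),
            class = "bscan_rgb")
}

#' Isolate the flow overlay from a B-scan
#'
#' Color-splits the RGB B-scan and subtracts the blue from the red channel
#' (clamped at 0), which removes the achromatic structural gray exactly and
#' leaves the red flow overlay as a grayscale image.
#'
#' @param bscan a [bscan_rgb()].
#' @return A [gray_image()] (8-bit) of `max(R - B, 0)`.
#' @export
isolate_flow <- function(bscan) {
  if (!inherits(bscan, "bscan_rgb"))
    stop("isolate_flow: input is not an RGB B-scan (format error)",
         call. = FALSE)
  gray_image(pmax(bscan$rgb[, , 1] - bscan$rgb[, , 3], 0), bit_depth = 8,
             spacing_mm = bscan$lateral_mm_px)
}

#' Measure a neovascularization on a B-scan
#'
#' The NV is delineated on the B-scan by a polygon bounded below by the ILM
#' and above by the vitreous. The isolated flow overlay is binarized with
#' the Phansalkar threshold over the full image and masked by the ROI
#' afterwards (the same order as the en face path). Heights are maximum
#' protrusions from the ILM toward the vitreous (decreasing row index),
#' taken over single columns, in um: `height_structure` uses the topmost ROI
#' pixel, `height_flow` the topmost binarized-flow pixel inside the ROI.
#'
#' @param bscan a [bscan_rgb()] with an ILM polyline.
#' @param roi an [roi_polygon()] on the B-scan pixel grid.
#' @param params [phansalkar_params()] for the binarization.
#' @return A list of class `bscan_measurement` with `nv_area` (mm^2 when
#'   both spacings are known, px^2 otherwise, see `area_unit`), `fd_pct`,
#'   `height_structure_um`, `height_flow_um` (heights in px when the axial
#'   spacing is unknown, see `height_unit`).
#' @export
measure_bscan <- function(bscan, roi, params = phansalkar_params()) {
  stopifnot(inherits(bscan, "bscan_rgb"))
  if (is.null(bscan$ilm_row))
    stop("measure_bscan: B-scan has no ILM polyline", call. = FALSE)
  d <- dim(bscan$rgb)
  mask <- polygon_to_mask(roi, d[1:2])$data
  if (sum(mask) == 0L)
    stop("measure_bscan: empty ROI mask (degenerate ROI)", call. = FALSE)
  # ROI must not extend below the ILM (row index > ilm_row)
  cols <- which(colSums(mask) > 0L)
  for (cc in cols) {
    if (max(which(mask[, cc])) - 1L > bscan$ilm_row[cc] + 0.5)
      stop("measure_bscan: ROI extends below the ILM (geometry error)",
           call. = FALSE)
  }
  axial <- bscan$axial_um_px
  lateral <- bscan$lateral_mm_px
  have_spacing <- !is.na(axial) && !is.na(lateral)
  nv_area <- if (have_spacing)
    sum(mask) * (axial / 1000) * lateral else sum(mask)
  bin <- phansalkar_threshold(isolate_flow(bscan), params)$data
  fd <- flow_density(binary_image(bin), binary_image(mask))
  ax <- if (is.na(axial)) 1 else axial
  hs <- max(vapply(cols, function(cc)
    bscan$ilm_row[cc] - (min(which(mask[, cc])) - 1L), numeric(1))) * ax
  flowpix <- bin & mask
  if (!any(flowpix)) {
    warning("measure_bscan: no flow inside ROI; height_flow set to 0")
    hf <- 0
  } else {
    fcols <- which(colSums(flowpix) > 0L)
    hf <- max(vapply(fcols, function(cc)
      bscan$ilm_row[cc] - (min(which(flowpix[, cc])) - 1L), numeric(1))) * ax
    hf <- max(hf, 0)
  }
  structure(list(nv_area = nv_area,
                 area_unit = if (have_spacing) "mm2" else "px2",
                 fd_pct = fd,
                 height_structure_um = max(hs, 0), height_flow_um = hf,
                 height_unit = if (is.na(axial)) "px" else "um"),
            class = "bscan_measurement")
}

#' @export
print.bscan_measurement <- function(x, ...) {
  cat(sprintf("bscan_measurement: area %.4f %s, FD %.1f%%, heights %0.1f/%0.1f %s (structure/flow)\n",
              x$nv_area, x$area_unit, x$fd_pct,
              x$height_structure_um, x$height_flow_um, x$height_unit))
  invisible(x)
}

# Render the B-scan RGB image of one lateral slice (fixed y row) of a
# volume: structural gray with saturated red where the flow channel exceeds
# `flow_thresh`. Returns a bscan_rgb with the ILM polyline of that slice.
render_bscan <- function(volume, y = NULL, flow_thresh = 0.3) {
  d <- volume$dim
  if (is.null(y)) y <- round(d[1] / 2)
  gray <- t(volume$structure[y, , ])  # (nz rows, nx cols)
  fl <- t(volume$flow[y, , ]) > flow_thresh
  g8 <- round(255 * clamp01(gray))
  r <- g8; g <- g8; b <- g8
  r[fl] <- 255; g[fl] <- 0; b[fl] <- 0
  bscan_rgb(array(c(r, g, b), c(nrow(g8), ncol(g8), 3)),
            axial_um_px = volume$axial_um_px,
            lateral_mm_px = volume$lateral_mm_px,
            ilm_row = volume$ilm_z[y, ] - 1)
}
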