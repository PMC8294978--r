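#' Read a TIFF image
#'
#' Reads an 8- or 16-bit grayscale TIFF as a [gray_image()] (intensities kept
#' in native integer units, bit depth recorded) or an 8-bit 3-channel TIFF
#' as a [bscan_rgb()] (without ILM polyline; attach it separately).
#'
#' @param path TIFF file path.
#' @param spacing_mm optional lateral pixel spacing to attach.
#' @param axial_um_px optional axial spacing (B-scans).
#' @return A `gray_image` or `bscan_rgb`.
#' @export
read_tiff <- function(path, spacing_mm = NA_real_, axial_um_px = NA_real_) {
  if (!file.exists(path)) stop(sprintf("read_tiff: no such file: %s", path),
                               call. = FALSE)
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  bits <- attr(img, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(img) > 255) 16L else 8L
  d <- dim(img)
  if (length(d) == 2L) {
    if (!bits %in% c(8L, 16L))
      stop(sprintf("read_tiff: unsupported grayscale bit depth %d", bits),
           call. = FALSE)
    gray_image(img[, , drop = TRUE] + 0, bit_depth = bits,
               spacing_mm = spacing_mm)
  } else if (length(d) == 3L && d[3] == 3L && bits == 8L) {
    a <- img[, , , drop = FALSE] + 0
    # multi-channel images come back rescaled to [0,1]; restore 8-bit units
    if (max(a) <= 1) a <- round(a * 255)
    bscan_rgb(a, axial_um_px = axial_um_px, lateral_mm_px = spacing_mm)
  } else {
    stop(sprintf(
      "read_tiff: unsupported TIFF layout (%s, %d bits per sample)",
      paste(d, collapse = "x"), bits), call. = FALSE)
  }
}

# Write a gray_image as a grayscale TIFF with the given bit depth.
write_gray_tiff <- function(img, path, bits = NULL) {
  stopifnot(inherits(img, "gray_image"))
  if (is.null(bits)) bits <- if (img$bit_depth == 1) 16L else img$bit_depth
  tiff::writeTIFF(img$data / bit_depth_max(img$bit_depth), path,
                  bits.per.sample = bits)
  invisible(path)
}

#' Read an NV delineation (ROI) file
#'
#' Supports the JSON polygon dialect
#' `{"plane": "angio", "vertices": [[x, y], ...]}` and ImageJ `.roi` files of
#' the polygon subtype (the byte layout written by ImageJ/Fiji, big-endian).
#' For `.roi` files the plane tag is taken from the `plane` argument or
#' guessed from the filename (`angio`/`structure`/`bscan` substring).
#'
#' @param path file ending in `.json` or `.roi`.
#' @param plane optional explicit plane tag overriding file/filename.
#' @return An [roi_polygon()].
#' @export
read_roi <- function(path, plane = NULL) {
  if (!file.exists(path)) stop(sprintf("read_roi: no such file: %s", path),
                               call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$vertices))
      stop("read_roi: JSON ROI lacks 'vertices'", call. = FALSE)
    v <- matrix(as.numeric(as.matrix(obj$vertices)), ncol = 2)
    roi_polygon(v, plane %||% obj$plane %||% "angio")
  } else if (grepl("\\.roi$", path, ignore.case = TRUE)) {
    read_imagej_roi(path, plane = plane %||% plane_from_name(path))
  } else {
    stop("read_roi: unsupported ROI file type (want .json or .roi)",
         call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

plane_from_name <- function(path) {
  nm <- tolower(basename(path))
  if (grepl("structure", nm)) "structure"
  else if (grepl("bscan", nm)) "bscan"
  else "angio"
}

# ImageJ .roi reader, polygon subtype. Layout (big-endian): bytes 0-3 magic
# "Iout", 4-5 version, 6 roi type (0 = polygon, 7 = freehand), 8-15
# top/left/bottom/right shorts, 16-17 n coordinates, 64.. n x-shorts
# relative to left then n y-shorts relative to top.
read_imagej_roi <- function(path, plane = "angio") {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    stop("read_roi: not an ImageJ .roi file", call. = FALSE)
  type <- as.integer(raw[7])
  type_names <- c("polygon", "rect", "oval", "line", "freeline", "polyline",
                  "noRoi", "freehand", "traced", "angle", "point")
  if (!type %in% c(0L, 7L))
    stop(sprintf("read_roi: unsupported ROI type '%s' (only polygon ROIs)",
                 type_names[min(type + 1L, length(type_names))]),
         call. = FALSE)
  short_at <- function(off)  # 0-based byte offset, big-endian signed short
    readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "big")
  top <- short_at(8); left <- short_at(10)
  n <- short_at(16)
  if (n < 3) stop("read_roi: polygon needs >= 3 vertices", call. = FALSE)
  xs <- readBin(raw[65:(64 + 2 * n)], "integer", n = n, size = 2,
                endian = "big")
  ys <- readBin(raw[(65 + 2 * n):(64 + 4 * n)], "integer", n = n, size = 2,
                endian = "big")
  roi_polygon(cbind(xs + left, ys + top), plane)
}

#' Write an ROI in the JSON polygon dialect
#'
#' @param roi an [roi_polygon()].
#' @param path output path.
#' @export
write_roi_json <- function(roi, path) {
  stopifnot(inherits(roi, "roi_polygon"))
  jsonlite::write_json(
    list(plane = roi$plane,
         vertices = unname(lapply(seq_len(nrow(roi$vertices)),
                                  function(i) roi$vertices[i, ]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an ROI as an ImageJ .roi polygon file
#'
#' Vertices are rounded to integer pixel coordinates (the format stores
#' shorts).
#'
#' @param roi an [roi_polygon()].
#' @param path output path.
#' @export
write_imagej_roi <- function(roi, path) {
  stopifnot(inherits(roi, "roi_polygon"))
  v <- round(roi$vertices)
  left <- min(v[, 1]); top <- min(v[, 2])
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("Iout"), con)
  writeBin(c(228L, 0L), con, size = 2, endian = "big")  # version, type=0
  writeBin(as.integer(c(top, left, max(v[, 2]), max(v[, 1]), nrow(v))), con,
           size = 2, endian = "big")
  writeBin(raw(64 - 18), con)  # rest of the fixed 64-byte header
  writeBin(as.integer(v[, 1] - left), con, size = 2, endian = "big")
  writeBin(as.integer(v[, 2] - top), con, size = 2, endian = "big")
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the scan-pattern spacing table (pattern name to mm/px), the
#' Phansalkar parameters, the posttreatment endpoint window, output
#' directory, seed, and log level. Read from YAML with [read_config()].
#'
#' @param spacing_table named numeric vector, mm/px per scan pattern.
#' @param phansalkar a [phansalkar_params()].
#' @param endpoint_window length-2 numeric, weeks after the last
#'   initial-block injection (low < high).
#' @param output_dir output directory.
#' @param seed integer seed.
#' @param log_level one of "quiet", "info", "debug".
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(spacing_table = c("3x3" = 3 / 256,
                                              "6x6" = 6 / 512,
                                              "12x12" = 12 / 1024,
                                              "9x15" = 15 / 1024),
                            phansalkar = phansalkar_params(),
                            endpoint_window = c(4, 6),
                            output_dir = ".", seed = 1L,
                            log_level = "info") {
  if (any(spacing_table <= 0))
    stop("pipeline_config: spacings must be > 0", call. = FALSE)
  if (length(endpoint_window) != 2L ||
      endpoint_window[1] >= endpoint_window[2])
    stop("pipeline_config: endpoint window must satisfy low < high",
         call. = FALSE)
  structure(list(spacing_table = spacing_table, phansalkar = phansalkar,
                 endpoint_window = endpoint_window, output_dir = output_dir,
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any field missing from the file keeps its [pipeline_config()] default.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  ph <- defaults$phansalkar
  if (!is.null(y$phansalkar))
    ph <- do.call(phansalkar_params,
                  utils::modifyList(unclass(ph)[c("radius", "k", "r", "p", "q")],
                                    y$phansalkar))
  pipeline_config(
    spacing_table = if (is.null(y$spacing_table)) defaults$spacing_table
                    else unlist(y$spacing_table),
    phansalkar = ph,
    endpoint_window = y$endpoint_window %||% defaults$endpoint_window,
    output_dir = y$output_dir %||% defaults$output_dir,
    seed = y$seed %||% defaults$seed,
    log_level = y$log_level %||% defaults$log_level)
}
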