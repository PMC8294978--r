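#' Simulate a longitudinal synthetic OCTA case
#'
#' Generates the vessel scaffold once, then renders one volume per scheduled
#' visit after applying the treatment schedule, so flow regresses (and may
#' recur) within a constant structural scaffold — the ground-truth analogue
#' of an NV followed under anti-VEGF.
#'
#' @param params a [synth_params()].
#' @return An object of class `octa_case`: list with `params`, `tree`
#'   (baseline), and `visits`, a list of `list(week, tree, volume)`.
#' @export
simulate_case <- function(params = synth_params()) {
  tree <- generate_vessel_tree(params)
  visits <- lapply(params$schedule$week, function(w) {
    tw <- apply_treatment_schedule(tree, params, w)
    list(week = w, tree = tw, volume = render_volume(tw, params))
  })
  structure(list(params = params, tree = tree, visits = visits),
            class = "octa_case")
}

#' @export
print.octa_case <- function(x, ...) {
  cat(sprintf("octa_case: %d visits (weeks %s), seed %d\n",
              length(x$visits),
              paste(x$params$schedule$week, collapse = ", "),
              x$params$seed))
  invisible(x)
}

# Convex-hull delineation polygon of a logical en face footprint, in
# 0-based pixel coordinates. Pads collinear/small footprints to a valid
# polygon.
footprint_polygon <- function(fp, plane) {
  pix <- which(fp, arr.ind = TRUE)
  if (nrow(pix) == 0L)
    stop("footprint_polygon: empty footprint", call. = FALSE)
  x <- pix[, 2] - 1; y <- pix[, 1] - 1
  if (length(unique(paste(x, y))) < 3L || length(unique(x)) == 1L ||
      length(unique(y)) == 1L) {
    # degenerate footprint: surround it with a half-pixel box
    x <- c(min(x) - 0.5, max(x) + 0.5, max(x) + 0.5, min(x) - 0.5)
    y <- c(min(y) - 0.5, min(y) - 0.5, max(y) + 0.5, max(y) + 0.5)
    return(roi_polygon(cbind(x, y), plane))
  }
  h <- grDevices::chull(x, y)
  roi_polygon(cbind(x[h], y[h]), plane)
}

#' Export a synthetic case to analysis-ready files
#'
#' Writes, per visit: the en face angio/structure pair as 16-bit grayscale
#' TIFFs, the B-scan with red flow overlay as an 8-bit RGB TIFF, ground-truth
#' delineation polygons (JSON dialect) for the angio, structure and B-scan
#' planes, and the ILM polyline CSV; plus `truth.csv` (header
#' `visit_week,true_structure_area_mm2,true_angio_area_mm2,true_perfused_fraction`),
#' `injections.csv` and a `case.json` with grid and spacing metadata. Truth
#' areas are shoelace areas of the exported polygons in mm^2;
#' `true_perfused_fraction` is the fraction (0-1) of structure-ROI pixels
#' covered by the en face perfused footprint — the ground-truth counterpart
#' of FD-structure. Identical parameters (including seed) give bit-identical
#' files.
#'
#' @param case an [simulate_case()] result.
#' @param dir output directory (created if missing).
#' @param nv_id identifier written into the CSVs.
#' @return Invisibly, a character vector of the files written.
#' @export
export_case <- function(case, dir, nv_id = "SYN1") {
  stopifnot(inherits(case, "octa_case"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("export_case: cannot create output directory (filesystem error)",
         call. = FALSE)
  p <- case$params
  by <- round(p$ny / 2)  # B-scan slice through the root anchor
  files <- character(0)
  truth <- NULL
  for (v in case$visits) {
    w <- v$week
    tag <- sprintf("w%03d", w)
    pair <- mip_projection(v$volume)
    fa <- file.path(dir, sprintf("enface_angio_%s.tif", tag))
    fs <- file.path(dir, sprintf("enface_structure_%s.tif", tag))
    write_gray_tiff(pair$angio, fa, bits = 16)
    write_gray_tiff(pair$structure, fs, bits = 16)
    bs <- render_bscan(v$volume, y = by)
    fb <- file.path(dir, sprintf("bscan_%s.tif", tag))
    tiff::writeTIFF(bs$rgb / 255, fb, bits.per.sample = 8)
    tr <- enface_truth(v$volume)
    roi_a <- footprint_polygon(tr$flow_fp, "angio")
    roi_s <- footprint_polygon(tr$structure_fp, "structure")
    fra <- file.path(dir, sprintf("roi_angio_%s.json", tag))
    frs <- file.path(dir, sprintf("roi_structure_%s.json", tag))
    write_roi_json(roi_a, fra)
    write_roi_json(roi_s, frs)
    # B-scan delineation: hull of the scaffold pixels in the exported slice,
    # clipped at the ILM (the delineation is bounded below by the ILM even
    # though the rasterized root capsule dips slightly under it)
    slice_fp <- t(v$volume$structure_mask[by, , ])
    if (p$ilm_z < p$nz) slice_fp[(p$ilm_z + 1):p$nz, ] <- FALSE
    roi_b <- footprint_polygon(slice_fp, "bscan")
    frb <- file.path(dir, sprintf("roi_bscan_%s.json", tag))
    write_roi_json(roi_b, frb)
    fi <- file.path(dir, sprintf("ilm_%s.csv", tag))
    utils::write.csv(data.frame(column_index = seq_len(p$nx) - 1L,
                                axial_row = bs$ilm_row),
                     fi, row.names = FALSE, quote = FALSE)
    mask_s <- polygon_to_mask(roi_s, dim(tr$structure_fp))$data
    truth <- rbind(truth, data.frame(
      visit_week = w,
      true_structure_area_mm2 = abs(polygon_area(roi_s)) * p$lateral_mm_px^2,
      true_angio_area_mm2 = abs(polygon_area(roi_a)) * p$lateral_mm_px^2,
      true_perfused_fraction = sum(tr$flow_fp & mask_s) / sum(mask_s)))
    files <- c(files, fa, fs, fb, fra, frs, frb, fi)
  }
  ft <- file.path(dir, "truth.csv")
  utils::write.csv(truth, ft, row.names = FALSE, quote = FALSE)
  fj <- file.path(dir, "injections.csv")
  utils::write.csv(data.frame(nv_id = nv_id,
                              injection_week = p$injection_weeks),
                   fj, row.names = FALSE, quote = FALSE)
  fc <- file.path(dir, "case.json")
  jsonlite::write_json(list(
    nv_id = nv_id, nx = p$nx, ny = p$ny, nz = p$nz,
    lateral_mm_px = p$lateral_mm_px, axial_um_px = p$axial_um_px,
    weeks = p$schedule$week, bscan_y = by, seed = p$seed),
    fc, auto_unbox = TRUE, digits = NA)
  invisible(c(files, ft, fj, fc))
}
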