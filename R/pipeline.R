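#' Measure every visit of an exported case (en face path)
#'
#' Reads the en face TIFF pairs and the per-plane delineations of a case
#' directory (the layout written by [export_case()], which is also the
#' layout expected for cases exported from the device software), runs
#' [measure_enface()] per visit, and returns one measurement row per visit
#' with the standard columns
#' `nv_id, visit_week, nv_structure_area_mm2, nv_angio_area_mm2,
#' fd_structure_pct, fd_angio_pct`.
#'
#' @param dir case directory containing `case.json`.
#' @param params [phansalkar_params()] for the binarization.
#' @return A data.frame, one row per visit.
#' @export
measure_case_enface <- function(dir, params = phansalkar_params()) {
  meta <- read_case_meta(dir)
  rows <- lapply(meta$weeks, function(w) {
    tag <- sprintf("w%03d", w)
    angio <- read_tiff(file.path(dir, sprintf("enface_angio_%s.tif", tag)),
                       spacing_mm = meta$lateral_mm_px)
    struct <- read_tiff(file.path(dir, sprintf("enface_structure_%s.tif", tag)),
                        spacing_mm = meta$lateral_mm_px)
    roi_a <- read_roi(file.path(dir, sprintf("roi_angio_%s.json", tag)))
    roi_s <- read_roi(file.path(dir, sprintf("roi_structure_%s.json", tag)))
    m <- measure_enface(en_face_pair(angio, struct), roi_a, roi_s, params)
    data.frame(nv_id = meta$nv_id, visit_week = w,
               nv_structure_area_mm2 = m$nv_structure_area_mm2,
               nv_angio_area_mm2 = m$nv_angio_area_mm2,
               fd_structure_pct = m$fd_structure_pct,
               fd_angio_pct = m$fd_angio_pct)
  })
  do.call(rbind, rows)
}

#' Measure every visit of an exported case (B-scan path)
#'
#' Reads the RGB B-scans, ILM polylines and B-scan delineations of a case
#' directory and runs [measure_bscan()] per visit.
#'
#' @param dir case directory containing `case.json`.
#' @param params [phansalkar_params()] for the binarization.
#' @return A data.frame with columns `nv_id, visit_week, bscan_area,
#'   bscan_fd_pct, height_structure_um, height_flow_um`.
#' @export
measure_case_bscan <- function(dir, params = phansalkar_params()) {
  meta <- read_case_meta(dir)
  rows <- lapply(meta$weeks, function(w) {
    tag <- sprintf("w%03d", w)
    bs <- read_tiff(file.path(dir, sprintf("bscan_%s.tif", tag)),
                    spacing_mm = meta$lateral_mm_px,
                    axial_um_px = meta$axial_um_px)
    ilm <- utils::read.csv(file.path(dir, sprintf("ilm_%s.csv", tag)))
    bs$ilm_row <- ilm$axial_row[order(ilm$column_index)]
    roi <- read_roi(file.path(dir, sprintf("roi_bscan_%s.json", tag)))
    m <- measure_bscan(bs, roi, params)
    data.frame(nv_id = meta$nv_id, visit_week = w, bscan_area = m$nv_area,
               bscan_fd_pct = m$fd_pct,
               height_structure_um = m$height_structure_um,
               height_flow_um = m$height_flow_um)
  })
  do.call(rbind, rows)
}

read_case_meta <- function(dir) {
  f <- file.path(dir, "case.json")
  if (!file.exists(f))
    stop(sprintf("no case.json in %s", dir), call. = FALSE)
  jsonlite::read_json(f, simplifyVector = TRUE)
}

#' Build a per-NV series from measurement rows and an injections table
#'
#' @param enface_rows data.frame from [measure_case_enface()] (one NV).
#' @param injections data.frame with columns `nv_id, injection_week`.
#' @return An [nv_series()].
#' @export
series_from_measurements <- function(enface_rows, injections) {
  nv <- unique(enface_rows$nv_id)
  if (length(nv) != 1L)
    stop("series_from_measurements: rows must belong to one NV",
         call. = FALSE)
  v <- enface_rows[order(enface_rows$visit_week), ]
  nv_series(nv,
            data.frame(week = v$visit_week,
                       nv_structure_area_mm2 = v$nv_structure_area_mm2,
                       nv_angio_area_mm2 = v$nv_angio_area_mm2,
                       fd_structure_pct = v$fd_structure_pct,
                       fd_angio_pct = v$fd_angio_pct),
            injections$injection_week[injections$nv_id == nv])
}
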