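#' Relative change of an area from baseline
#'
#' `100 * (visit - baseline) / baseline`: negative values are regression,
#' positive growth; the result is bounded below by -100 (complete
#' regression) and unbounded above. This is the sign convention of the
#' per-NV change columns ("change from baseline (=100%)").
#'
#' @param baseline_area baseline area (> 0), any consistent unit.
#' @param visit_area area at the visit (>= 0), same unit.
#' @return Relative change in percent.
#' @examples
#' relative_change(1.00, 0.49)  # -51: the NV regressed by 51%
#' @export
relative_change <- function(baseline_area, visit_area) {
  if (any(baseline_area <= 0))
    stop("relative_change: zero or negative baseline (degenerate baseline)",
         call. = FALSE)
  100 * (visit_area - baseline_area) / baseline_area
}

#' Flow-density change from baseline
#'
#' `baseline_fd - visit_fd` in percentage points, decrease-positive (the
#' convention used for reporting FD decreases from baseline).
#'
#' @param baseline_fd,visit_fd flow densities in percent, each in \[0, 100\].
#' @return The decrease in percentage points (negative = FD increased).
#' @export
fd_change <- function(baseline_fd, visit_fd) {
  if (any(baseline_fd < 0 | baseline_fd > 100 |
          visit_fd < 0 | visit_fd > 100))
    stop("fd_change: flow densities must lie in [0, 100]", call. = FALSE)
  baseline_fd - visit_fd
}

#' Per-NV longitudinal series
#'
#' One NV's timeline: per-visit en face measurements (weeks strictly
#' increasing, baseline at week 0), optional B-scan measurements, and the
#' injection weeks. Areas must be measured at one constant pixel spacing
#' across the series; mixing scan patterns within a series is rejected
#' upstream.
#'
#' @param nv_id identifier.
#' @param visits data.frame with columns `week`, `nv_structure_area_mm2`,
#'   `nv_angio_area_mm2`, `fd_structure_pct`, `fd_angio_pct` (optionally
#'   B-scan columns; `NA` permitted there).
#' @param injection_weeks numeric vector of injection weeks.
#' @return An object of class `nv_series`.
#' @export
nv_series <- function(nv_id, visits, injection_weeks) {
  need <- c("week", "nv_structure_area_mm2", "nv_angio_area_mm2",
            "fd_structure_pct", "fd_angio_pct")
  if (!all(need %in% names(visits)))
    stop(sprintf("nv_series: visits need columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  visits <- visits[order(visits$week), , drop = FALSE]
  if (anyDuplicated(visits$week))
    stop("nv_series: visit weeks must be strictly increasing", call. = FALSE)
  if (visits$week[1] != 0)
    stop("nv_series: baseline visit must be at week 0", call. = FALSE)
  structure(list(nv_id = nv_id, visits = visits,
                 injection_weeks = sort(injection_weeks)),
            class = "nv_series")
}

#' @export
print.nv_series <- function(x, ...) {
  cat(sprintf("nv_series %s: %d visits (weeks %s), injections at %s\n",
              x$nv_id, nrow(x$visits),
              paste(x$visits$week, collapse = ", "),
              paste(x$injection_weeks, collapse = ", ")))
  invisible(x)
}

# Last injection of the initial treatment block: the maximal prefix of the
# sorted injection weeks with successive gaps <= 6 weeks (monthly dosing);
# later retreatments are separated by longer treatment-free intervals.
initial_block_end <- function(injection_weeks) {
  w <- sort(injection_weeks)
  if (length(w) == 0L)
    stop("initial_block_end: no injections", call. = FALSE)
  end <- w[1]
  for (i in seq_along(w)[-1]) {
    if (w[i] - w[i - 1] <= 6) end <- w[i] else break
  }
  end
}

#' Select the posttreatment and last-follow-up endpoints of a series
#'
#' The posttreatment visit is the one falling 5 +/- 1 weeks after the last
#' injection of the initial treatment block (window `[low, high]` weeks
#' after it); if several visits fall inside the window the one closest to
#' 5 weeks wins, ties resolved toward the earlier visit. The last endpoint
#' is the final visit of the series, which must lie after the posttreatment
#' visit.
#'
#' @param series an [nv_series()].
#' @param window length-2 numeric: the window bounds in weeks after the last
#'   initial-block injection (default `c(4, 6)`).
#' @return A one-row data.frame of class `endpoint_row` with the change and
#'   FD columns at posttreatment and last follow-up, plus the selected
#'   weeks.
#' @export
select_endpoints <- function(series, window = c(4, 6)) {
  stopifnot(inherits(series, "nv_series"))
  v <- series$visits
  block_end <- initial_block_end(series$injection_weeks)
  target <- block_end + mean(window)
  lo <- block_end + window[1]; hi <- block_end + window[2]
  cand <- which(v$week >= lo & v$week <= hi)
  if (length(cand) == 0L)
    stop(sprintf(
      "select_endpoints: no visit in the posttreatment window [%g, %g] weeks; visit weeks: %s",
      lo, hi, paste(v$week, collapse = ", ")), call. = FALSE)
  dist <- abs(v$week[cand] - target)
  post <- cand[order(dist, v$week[cand])][1]
  last <- nrow(v)
  if (last <= post)
    stop("select_endpoints: series has no visit after the posttreatment visit",
         call. = FALSE)
  base <- 1L
  row <- data.frame(
    nv_id = series$nv_id,
    week_post = v$week[post], week_last = v$week[last],
    change_structure_post_pct = relative_change(
      v$nv_structure_area_mm2[base], v$nv_structure_area_mm2[post]),
    change_structure_last_pct = relative_change(
      v$nv_structure_area_mm2[base], v$nv_structure_area_mm2[last]),
    change_angio_post_pct = relative_change(
      v$nv_angio_area_mm2[base], v$nv_angio_area_mm2[post]),
    change_angio_last_pct = relative_change(
      v$nv_angio_area_mm2[base], v$nv_angio_area_mm2[last]),
    fd_structure_baseline_pct = v$fd_structure_pct[base],
    fd_structure_post_pct = v$fd_structure_pct[post],
    fd_structure_last_pct = v$fd_structure_pct[last],
    fd_angio_baseline_pct = v$fd_angio_pct[base],
    fd_angio_post_pct = v$fd_angio_pct[post],
    fd_angio_last_pct = v$fd_angio_pct[last])
  class(row) <- c("endpoint_row", class(row))
  row
}
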