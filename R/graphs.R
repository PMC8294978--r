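#' Render cohort box plots and per-NV longitudinal graphs
#'
#' Produces the standard cohort figures: two box-plot panels (area changes
#' from baseline at posttreatment/last follow-up; FD levels at
#' baseline/posttreatment/last follow-up) and four longitudinal panels (one
#' per endpoint family), with the area curves normalized to baseline = 1,
#' FD curves in raw percent, and injection weeks marked. Output is
#' deterministic for fixed input.
#'
#' @param rows endpoint rows (one per NV), as from [select_endpoints()] or
#'   the packaged fixture.
#' @param series optional list of [nv_series()] for the longitudinal
#'   panels; when `NULL`, three-point series (baseline/post/last) are
#'   reconstructed from `rows` (using `week_post`/`week_last` when present,
#'   otherwise nominal weeks 0/17/45).
#' @param dir output directory.
#' @param format `"png"` or `"svg"`.
#' @return Character vector of the files written.
#' @export
render_graphs <- function(rows, series = NULL, dir = ".", format = "png") {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("render_graphs: cannot create output directory (filesystem error)",
         call. = FALSE)
  if (is.null(series)) series <- series_from_rows(rows)
  if (length(series) == 0L) stop("render_graphs: no series", call. = FALSE)
  files <- character(0)
  save_plot <- function(plt, name) {
    f <- file.path(dir, paste0(name, ".", format))
    ggplot2::ggsave(f, plt, width = 6, height = 4.5, dpi = 150)
    f
  }
  # box plots of changes from baseline
  chg <- data.frame(
    value = c(rows$change_structure_post_pct, rows$change_structure_last_pct,
              rows$change_angio_post_pct, rows$change_angio_last_pct),
    endpoint = rep(c("NV-structure\npost", "NV-structure\nlast",
                     "NV-angio\npost", "NV-angio\nlast"),
                   each = nrow(rows)))
  chg$endpoint <- factor(chg$endpoint, levels = unique(chg$endpoint))
  p1 <- ggplot2::ggplot(chg, ggplot2::aes(x = endpoint, y = value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(y = "Change from baseline (%)", x = NULL,
                  title = "NV size change from baseline") +
    ggplot2::theme_minimal()
  files <- c(files, save_plot(p1, "box_area_change"))
  fd <- data.frame(
    value = c(rows$fd_structure_baseline_pct, rows$fd_structure_post_pct,
              rows$fd_structure_last_pct, rows$fd_angio_baseline_pct,
              rows$fd_angio_post_pct, rows$fd_angio_last_pct),
    endpoint = rep(c("FD-structure\nbaseline", "FD-structure\npost",
                     "FD-structure\nlast", "FD-angio\nbaseline",
                     "FD-angio\npost", "FD-angio\nlast"),
                   each = nrow(rows)))
  fd$endpoint <- factor(fd$endpoint, levels = unique(fd$endpoint))
  p2 <- ggplot2::ggplot(fd, ggplot2::aes(x = endpoint, y = value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(y = "Flow density (%)", x = NULL,
                  title = "Flow density within NV areas") +
    ggplot2::theme_minimal()
  files <- c(files, save_plot(p2, "box_fd"))
  # longitudinal panels
  long <- do.call(rbind, lapply(series, function(s) {
    v <- s$visits
    data.frame(nv_id = s$nv_id, week = v$week,
               norm_structure = v$nv_structure_area_mm2 /
                 v$nv_structure_area_mm2[1],
               norm_angio = v$nv_angio_area_mm2 / v$nv_angio_area_mm2[1],
               fd_structure = v$fd_structure_pct,
               fd_angio = v$fd_angio_pct)
  }))
  inj <- do.call(rbind, lapply(series, function(s)
    if (length(s$injection_weeks) > 0)
      data.frame(nv_id = s$nv_id, week = s$injection_weeks) else NULL))
  panel <- function(ycol, ylab, title, hline = NULL) {
    p <- ggplot2::ggplot(long, ggplot2::aes(x = week, y = .data[[ycol]],
                                            colour = nv_id,
                                            group = nv_id)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 1)
    if (!is.null(inj))
      p <- p + ggplot2::geom_vline(data = inj,
                                   ggplot2::aes(xintercept = week),
                                   linetype = 3, colour = "grey60")
    if (!is.null(hline))
      p <- p + ggplot2::geom_hline(yintercept = hline, linetype = 2,
                                   colour = "grey50")
    p + ggplot2::labs(x = "Weeks from baseline", y = ylab, title = title) +
      ggplot2::theme_minimal()
  }
  files <- c(files,
             save_plot(panel("norm_structure", "NV-structure area (baseline = 1)",
                             "NV-structure area over time", 1),
                       "long_nv_structure"),
             save_plot(panel("norm_angio", "NV-angio area (baseline = 1)",
                             "NV-angio area over time", 1),
                       "long_nv_angio"),
             save_plot(panel("fd_structure", "FD-structure (%)",
                             "Flow density within the structural area"),
                       "long_fd_structure"),
             save_plot(panel("fd_angio", "FD-angio (%)",
                             "Flow density within the angio area"),
                       "long_fd_angio"))
  files
}

# Reconstruct minimal 3-visit series (baseline/post/last) from endpoint rows.
series_from_rows <- function(rows) {
  lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    wp <- if ("week_post" %in% names(r)) r$week_post else 17
    wl <- if ("week_last" %in% names(r)) r$week_last
          else if ("last_octa_week" %in% names(r)) r$last_octa_week else 45
    nv_series(r$nv_id, data.frame(
      week = c(0, wp, wl),
      nv_structure_area_mm2 = c(1, 1 + r$change_structure_post_pct / 100,
                                1 + r$change_structure_last_pct / 100),
      nv_angio_area_mm2 = c(1, 1 + r$change_angio_post_pct / 100,
                            1 + r$change_angio_last_pct / 100),
      fd_structure_pct = c(r$fd_structure_baseline_pct,
                           r$fd_structure_post_pct, r$fd_structure_last_pct),
      fd_angio_pct = c(r$fd_angio_baseline_pct, r$fd_angio_post_pct,
                       r$fd_angio_last_pct)),
      injection_weeks = numeric(0))
  })
}
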