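#' Generate a branching neovascular vessel tree
#'
#' Grows a fan-like binary branching tree anchored on the ILM plane and
#' spreading into the vitreous (decreasing axial index z), the morphology of
#' an active retinal NV: a trunk that fans out into progressively thinner,
#' shorter, more numerous segments. All endpoints stay at or above the ILM
#' plane and inside the voxel grid (with a safety margin equal to the
#' segment radius). The result is deterministic for a fixed seed.
#'
#' @param params a [synth_params()].
#' @return An object of class `vessel_tree`: a list with `segments` (a
#'   data.frame with columns `tier, x0, y0, z0, x1, y1, z1, radius,
#'   perfused`, coordinates in 1-based voxel units), `root_anchor`
#'   (x, y, z on the ILM plane) and `depth`.
#' @export
generate_vessel_tree <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  with_seed(params$seed, {
    cx <- params$nx / 2; cy <- params$ny / 2; z0 <- params$ilm_z
    spread <- params$spread_deg * pi / 180
    len0 <- 0.09 * min(params$nx, params$ny)
    rad0 <- max(1.5, 0.012 * min(params$nx, params$ny))
    zmin <- 3
    clamp <- function(v, lo, hi) pmin(hi, pmax(lo, v))
    segs <- vector("list", 2^params$depth - 1)
    k <- 0L
    # frontier rows: x, y, z (tip), azimuth, elevation, length, radius
    az0 <- stats::runif(1, 0, 2 * pi)
    frontier <- data.frame(x = cx, y = cy, z = z0, az = az0,
                           el = 50 * pi / 180, len = len0, rad = rad0)
    for (tier in seq_len(params$depth)) {
      nxt <- vector("list", nrow(frontier) * 2)
      for (i in seq_len(nrow(frontier))) {
        f <- frontier[i, ]
        x1 <- clamp(f$x + f$len * cos(f$el) * cos(f$az),
                    f$rad + 2, params$nx - f$rad - 1)
        y1 <- clamp(f$y + f$len * cos(f$el) * sin(f$az),
                    f$rad + 2, params$ny - f$rad - 1)
        z1 <- clamp(f$z - f$len * sin(f$el), zmin + f$rad, params$ilm_z)
        k <- k + 1L
        segs[[k]] <- data.frame(tier = tier, x0 = f$x, y0 = f$y, z0 = f$z,
                                x1 = x1, y1 = y1, z1 = z1, radius = f$rad)
        if (tier < params$depth) {
          for (s in c(-1, 1)) {
            jit <- stats::runif(1, 0.7, 1.3)
            nxt[[2 * (i - 1) + (s + 3) / 2]] <- data.frame(
              x = x1, y = y1, z = z1,
              az = f$az + s * jit * spread / 2,
              el = f$el * 0.55, len = f$len * 0.85,
              rad = max(0.8, f$rad * 0.72))
          }
        }
      }
      if (tier < params$depth) frontier <- do.call(rbind, nxt)
    }
    segments <- do.call(rbind, segs[seq_len(k)])
    segments$perfused <- TRUE
    structure(list(segments = segments,
                   root_anchor = c(x = cx, y = cy, z = z0),
                   depth = params$depth),
              class = "vessel_tree")
  })
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("vessel_tree: %d segments, depth %d, %d perfused\n",
              nrow(x$segments), x$depth, sum(x$segments$perfused)))
  invisible(x)
}

#' Apply the anti-VEGF treatment schedule to a vessel tree
#'
#' Updates the per-segment perfusion flags for one imaged visit. The
#' perfusion fraction for the visit is looked up in the schedule; distal
#' generation tiers lose perfusion first, emulating regression to residual
#' truncated main arcs, and structural segments are never deleted. The root
#' tier stays perfused even at fraction 0 (the residual arc). If the
#' recurrence flag is set and the visit is at or after the recurrence week,
#' the perfusion fraction rises again to at least `recurrence_fraction`.
#'
#' @param tree a [generate_vessel_tree()] result.
#' @param params the [synth_params()] holding the schedule.
#' @param visit_week a week present in `params$schedule$week`.
#' @return A copy of `tree` with updated `perfused` flags.
#' @export
apply_treatment_schedule <- function(tree, params, visit_week) {
  stopifnot(inherits(tree, "vessel_tree"), inherits(params, "synth_params"))
  idx <- match(visit_week, params$schedule$week)
  if (is.na(idx))
    stop(sprintf(
      "apply_treatment_schedule: week %s not in schedule (weeks: %s)",
      visit_week, paste(params$schedule$week, collapse = ", ")),
      call. = FALSE)
  f <- params$schedule$fraction[idx]
  if (params$recurrence && visit_week >= params$recurrence_week)
    f <- max(f, params$recurrence_fraction)
  n_tiers <- 1L + floor(f * (tree$depth - 1) + 1e-9)
  tree$segments$perfused <- tree$segments$tier <= n_tiers
  tree
}
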