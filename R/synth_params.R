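#' Parameters of the synthetic OCTA case generator
#'
#' Defines the voxel grid, optics-like spacings, NV morphology, noise levels,
#' and the per-visit perfusion schedule that emulates the response of a
#' retinal neovascularization to an initial block of monthly anti-VEGF
#' injections, with optional recurrence after a treatment-free interval.
#'
#' The default grid is 256 x 256 x 128 voxels at 11.7 um/px laterally
#' (about a 3 x 3 mm scan pattern) and 6.3 um/px axially. The default
#' schedule images the lesion at weeks 0, 4, 8, 12 (injection visits),
#' 17 (about five weeks after the last injection of the initial block) and
#' 45, with tierwise perfusion fractions 1.0, 0.8, 0.5, 0.3, 0.25, 0.2.
#'
#' @param nx,ny,nz voxel grid dimensions (x, y lateral; z axial).
#' @param lateral_mm_px lateral pixel spacing, mm/px.
#' @param axial_um_px axial pixel spacing, um/px.
#' @param depth branching depth of the vessel tree (>= 1).
#' @param spread_deg branch azimuthal angle spread, degrees.
#' @param speckle multiplicative Rayleigh speckle level on the structure
#'   channel, in \[0, 1\] (0 disables noise).
#' @param flow_noise additive Gaussian noise sd on the flow channel
#'   (0 disables).
#' @param schedule data.frame with columns `week` and `fraction`: the
#'   perfusion fraction (0-1, applied over segment-generation tiers) at each
#'   imaged visit.
#' @param injection_weeks weeks of anti-VEGF injections (initial block).
#' @param recurrence logical: does perfusion rise again after
#'   `recurrence_week`?
#' @param recurrence_week,recurrence_fraction recurrence onset (weeks from
#'   baseline) and the perfusion fraction it rises to.
#' @param ilm_frac axial position of the internal limiting membrane (ILM)
#'   plane as a fraction of `nz`; the NV grows from the ILM toward the
#'   vitreous (decreasing z).
#' @param seed single global random seed governing tree, noise, and jitter.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(nx = 256, ny = 256, nz = 128,
                         lateral_mm_px = 0.0117, axial_um_px = 6.3,
                         depth = 5, spread_deg = 40,
                         speckle = 0.15, flow_noise = 0.05,
                         schedule = data.frame(
                           week = c(0, 4, 8, 12, 17, 45),
                           fraction = c(1, 0.8, 0.5, 0.3, 0.25, 0.2)),
                         injection_weeks = c(0, 4, 8, 12),
                         recurrence = FALSE, recurrence_week = 32,
                         recurrence_fraction = 0.9,
                         ilm_frac = 0.75, seed = 1L) {
  if (any(c(nx, ny, nz) < 8))
    stop("synth_params: grid dimensions must be >= 8 voxels", call. = FALSE)
  if (depth < 1) stop("synth_params: branching depth must be >= 1",
                      call. = FALSE)
  if (lateral_mm_px <= 0 || axial_um_px <= 0)
    stop("synth_params: pixel spacings must be > 0", call. = FALSE)
  if (!all(c("week", "fraction") %in% names(schedule)))
    stop("synth_params: schedule needs 'week' and 'fraction' columns",
         call. = FALSE)
  if (any(schedule$fraction < 0 | schedule$fraction > 1))
    stop("synth_params: perfusion fractions must lie in [0, 1]",
         call. = FALSE)
  if (recurrence_fraction < 0 || recurrence_fraction > 1)
    stop("synth_params: recurrence_fraction must lie in [0, 1]",
         call. = FALSE)
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
    lateral_mm_px = lateral_mm_px, axial_um_px = axial_um_px,
    depth = as.integer(depth), spread_deg = spread_deg,
    speckle = speckle, flow_noise = flow_noise,
    schedule = schedule, injection_weeks = injection_weeks,
    recurrence = isTRUE(recurrence), recurrence_week = recurrence_week,
    recurrence_fraction = recurrence_fraction,
    ilm_z = as.integer(round(ilm_frac * nz)), seed = as.integer(seed)
  ), class = "synth_params")
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
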