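#' OCTA volume container
#'
#' Paired 3-D structure (reflectivity) and flow (decorrelation) channels in
#' \[0,1\] on a common voxel grid, stored as arrays with dimensions
#' `(ny, nx, nz)` (rows = y, columns = x, slices = z; z increases from the
#' vitreous toward the deep retina). `ilm_z` gives the per-(x,y) axial index
#' of the internal limiting membrane. Rendered volumes also carry exact
#' ground-truth voxel masks of the vessel scaffold and of the currently
#' perfused segments.
#'
#' @param structure,flow numeric arrays in \[0,1\], same dimensions.
#' @param ilm_z integer matrix `(ny, nx)` (or scalar) of ILM axial indices.
#' @param lateral_mm_px,axial_um_px pixel spacings.
#' @param structure_mask,flow_mask optional logical ground-truth arrays.
#' @return An object of class `octa_volume`.
#' @export
octa_volume <- function(structure, flow, ilm_z, lateral_mm_px, axial_um_px,
                        structure_mask = NULL, flow_mask = NULL) {
  if (!identical(dim(structure), dim(flow)))
    stop("octa_volume: channel shapes differ", call. = FALSE)
  d <- dim(structure)
  if (length(d) != 3L) stop("octa_volume: channels must be 3-D arrays",
                            call. = FALSE)
  if (length(ilm_z) == 1L) ilm_z <- matrix(as.integer(ilm_z), d[1], d[2])
  if (any(ilm_z < 1L | ilm_z > d[3]))
    stop("octa_volume: ilm_z outside axial range", call. = FALSE)
  structure(list(structure = structure, flow = flow, ilm_z = ilm_z,
                 lateral_mm_px = lateral_mm_px, axial_um_px = axial_um_px,
                 structure_mask = structure_mask, flow_mask = flow_mask,
                 dim = d), class = "octa_volume")
}

#' @export
print.octa_volume <- function(x, ...) {
  cat(sprintf("octa_volume: %d x %d x %d voxels, %.4f mm/px lateral, %.1f um/px axial\n",
              x$dim[2], x$dim[1], x$dim[3], x$lateral_mm_px, x$axial_um_px))
  invisible(x)
}

# Clamp to [0, 1] preserving dim attributes.
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Rasterize capsule segments (line + radius) onto the voxel grid; returns a
# logical (ny, nx, nz) array. Voxel centers sit at integer 1-based coords.
rasterize_segments <- function(segments, nx, ny, nz) {
  m <- array(FALSE, c(ny, nx, nz))
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    r <- s$radius
    xr <- max(1L, floor(min(s$x0, s$x1) - r)):min(nx, ceiling(max(s$x0, s$x1) + r))
    yr <- max(1L, floor(min(s$y0, s$y1) - r)):min(ny, ceiling(max(s$y0, s$y1) + r))
    zr <- max(1L, floor(min(s$z0, s$z1) - r)):min(nz, ceiling(max(s$z0, s$z1) + r))
    g <- expand.grid(y = yr, x = xr, z = zr)
    ax <- s$x1 - s$x0; ay <- s$y1 - s$y0; az <- s$z1 - s$z0
    len2 <- ax * ax + ay * ay + az * az
    if (len2 == 0) {
      d2 <- (g$x - s$x0)^2 + (g$y - s$y0)^2 + (g$z - s$z0)^2
    } else {
      tt <- pmin(1, pmax(0, ((g$x - s$x0) * ax + (g$y - s$y0) * ay +
                               (g$z - s$z0) * az) / len2))
      d2 <- (g$x - (s$x0 + tt * ax))^2 + (g$y - (s$y0 + tt * ay))^2 +
        (g$z - (s$z0 + tt * az))^2
    }
    hit <- d2 <= r * r
    if (any(hit)) m[cbind(g$y[hit], g$x[hit], g$z[hit])] <- TRUE
  }
  m
}

#' Render an OCTA volume from a vessel tree
#'
#' Produces the paired structure/flow channels: the structure (reflectivity)
#' channel is raised along ALL segments of the scaffold over a two-layer
#' background (dim vitreous above the ILM, brighter retinal tissue below);
#' the flow (decorrelation) channel is raised only along currently perfused
#' segments. Multiplicative Rayleigh speckle is applied to the structure
#' channel and additive clipped Gaussian noise to the flow channel, both
#' driven by the single global seed; noise levels of 0 disable the RNG
#' entirely. Exact ground-truth voxel masks are kept on the volume.
#'
#' @param tree a [generate_vessel_tree()] result (possibly after
#'   [apply_treatment_schedule()]).
#' @param params the [synth_params()].
#' @return An [octa_volume()].
#' @export
render_volume <- function(tree, params) {
  stopifnot(inherits(tree, "vessel_tree"), inherits(params, "synth_params"))
  seg <- tree$segments
  if (any(seg$x1 - seg$radius < 0.5 | seg$x1 + seg$radius > params$nx + 0.5 |
          seg$y1 - seg$radius < 0.5 | seg$y1 + seg$radius > params$ny + 0.5 |
          seg$z1 - seg$radius < 0.5 | seg$z1 + seg$radius > params$nz + 0.5))
    stop("render_volume: tree outside grid", call. = FALSE)
  ny <- params$ny; nx <- params$nx; nz <- params$nz
  smask <- rasterize_segments(seg, nx, ny, nz)
  fmask <- rasterize_segments(seg[seg$perfused, , drop = FALSE], nx, ny, nz)
  zslab <- array(rep(seq_len(nz), each = ny * nx), c(ny, nx, nz))
  structure_ch <- array(0.02, c(ny, nx, nz))
  structure_ch[zslab > params$ilm_z] <- 0.35
  structure_ch[smask] <- 0.85
  flow_ch <- array(0, c(ny, nx, nz))
  flow_ch[fmask] <- 0.9
  if (params$speckle > 0 || params$flow_noise > 0) {
    with_seed(params$seed + 1L, {
      if (params$speckle > 0) {
        # Rayleigh factor with unit mean: sigma * sqrt(-2 log U)
        u <- stats::runif(length(structure_ch))
        ray <- sqrt(2 / pi) * sqrt(-2 * log(u))
        fac <- (1 - params$speckle) + params$speckle * ray
        structure_ch <- clamp01(structure_ch * array(fac, dim(structure_ch)))
      }
      if (params$flow_noise > 0) {
        flow_ch <- clamp01(flow_ch +
          array(stats::rnorm(length(flow_ch), 0, params$flow_noise),
                dim(flow_ch)))
      }
    })
  }
  octa_volume(structure_ch, flow_ch, params$ilm_z,
              params$lateral_mm_px, params$axial_um_px,
              structure_mask = smask, flow_mask = fmask)
}

#' Vitreoretinal-interface (VRI) slab
#'
#' The axial slab used for en face projection: it starts at the ILM and
#' includes the vitreous cavity as far as the NV reaches. `ilm` is the
#' inclusive deep bound (the ILM surface itself is projected) and `top` the
#' exclusive vitreous-side bound, so a voxel at axial index z is inside iff
#' `top < z <= ilm`.
#'
#' @param volume an [octa_volume()].
#' @param top exclusive vitreous-side bound (scalar or `(ny, nx)` matrix);
#'   0 includes everything above the ILM.
#' @return A list with matrices `ilm` and `top`.
#' @export
vri_slab <- function(volume, top = 0) {
  d <- volume$dim
  if (length(top) == 1L) top <- matrix(top, d[1], d[2])
  list(ilm = volume$ilm_z, top = top)
}

#' Maximum intensity projection of an axial slab
#'
#' Projects both channels of a volume to an en face image pair: each en face
#' pixel is the maximum of the respective channel over the axial slab range
#' (`top < z <= ilm`). Pixels with an empty slab project to 0.
#'
#' @param volume an [octa_volume()].
#' @param slab a [vri_slab()]-style list with per-pixel bounds.
#' @return An [en_face_pair()].
#' @export
mip_projection <- function(volume, slab = vri_slab(volume)) {
  d <- volume$dim
  ilm <- slab$ilm; top <- slab$top
  if (length(ilm) == 1L) ilm <- matrix(ilm, d[1], d[2])
  if (length(top) == 1L) top <- matrix(top, d[1], d[2])
  if (any(ilm < top))
    stop("mip_projection: slab upper bound below lower bound", call. = FALSE)
  if (any(ilm > d[3]) || any(top < 0))
    stop("mip_projection: slab outside volume", call. = FALSE)
  proj <- function(ch) {
    out <- matrix(0, d[1], d[2])
    for (k in seq_len(d[3])) {
      inside <- k > top & k <= ilm
      if (!any(inside)) next
      sl <- ch[, , k]
      sl[!inside] <- 0
      out <- pmax(out, sl)
    }
    out
  }
  en_face_pair(gray_image(proj(volume$flow), bit_depth = 1,
                          spacing_mm = volume$lateral_mm_px),
               gray_image(proj(volume$structure), bit_depth = 1,
                          spacing_mm = volume$lateral_mm_px))
}

# En face ground-truth footprints of the scaffold and the perfused subset
# (MIP of the exact voxel masks over the same slab).
enface_truth <- function(volume, slab = vri_slab(volume)) {
  d <- volume$dim
  ilm <- slab$ilm; top <- slab$top
  fp <- function(mask) {
    out <- matrix(FALSE, d[1], d[2])
    for (k in seq_len(d[3])) {
      inside <- k > top & k <= ilm
      sl <- mask[, , k] & inside
      out <- out | sl
    }
    out
  }
  list(structure_fp = fp(volume$structure_mask),
       flow_fp = fp(volume$flow_mask))
}
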