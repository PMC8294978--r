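test_that("tree generation: size, determinism, geometry above the ILM", {
  p1 <- small_params(depth = 1)
  t1 <- generate_vessel_tree(p1)
  expect_equal(nrow(t1$segments), 1)
  expect_true(all(t1$segments$perfused))
  p4 <- small_params()
  ta <- generate_vessel_tree(p4)
  tb <- generate_vessel_tree(p4)
  expect_identical(ta, tb)                       # fixed seed -> identical
  expect_gte(nrow(ta$segments), 2^(p4$depth - 1))
  # exhaustive scan: every endpoint at or above (toward vitreous) the ILM
  seg <- ta$segments
  expect_true(all(seg$z0 <= p4$ilm_z + 1e-9))
  expect_true(all(seg$z1 <= p4$ilm_z + 1e-9))
  expect_true(all(seg$z1 >= 1))
  expect_true(all(seg$radius > 0))
  # connectivity through the root: every non-root segment starts where some
  # previous-tier segment ends
  for (tier in 2:p4$depth) {
    starts <- seg[seg$tier == tier, c("x0", "y0", "z0")]
    ends <- seg[seg$tier == tier - 1, c("x1", "y1", "z1")]
    key <- function(d) paste(round(d[[1]], 6), round(d[[2]], 6),
                             round(d[[3]], 6))
    expect_true(all(key(starts) %in% key(ends)))
  }
  expect_error(synth_params(depth = 0), "depth")
  expect_error(synth_params(nx = -4), "dimensions")
})

test_that("treatment schedule prunes distal tiers first and can recur", {
  p <- small_params(schedule = data.frame(week = c(0, 6, 12),
                                          fraction = c(1, 0.4, 0.9)))
  tree <- generate_vessel_tree(p)
  n_perf <- vapply(c(0, 6, 12), function(w)
    sum(apply_treatment_schedule(tree, p, w)$segments$perfused), numeric(1))
  expect_equal(n_perf[1], nrow(tree$segments))     # fraction 1 -> all
  expect_lt(n_perf[2], n_perf[1])                  # regression
  expect_gt(n_perf[3], n_perf[2])                  # recurrence
  # fraction 0: only the root tier (residual truncated arc) stays perfused
  p0 <- small_params(schedule = data.frame(week = 0, fraction = 0))
  t0 <- apply_treatment_schedule(generate_vessel_tree(p0), p0, 0)
  expect_identical(which(t0$segments$perfused),
                   which(t0$segments$tier == 1))
  # structure never shrinks: same segment list, only flags change
  expect_identical(t0$segments[names(t0$segments) != "perfused"],
                   generate_vessel_tree(p0)$segments[
                     names(t0$segments) != "perfused"])
  expect_error(apply_treatment_schedule(tree, p, 99), "not in schedule")
})

test_that("with recurrence disabled, perfused voxels only shrink and stay inside the scaffold", {
  p <- small_params()   # fractions 1, .8, .5, .3, .25, .2 (no recurrence)
  case <- simulate_case(p)
  counts <- vapply(case$visits, function(v) sum(v$volume$flow_mask),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  smask0 <- case$visits[[1]]$volume$structure_mask
  for (v in case$visits) {
    expect_identical(v$volume$structure_mask, smask0)  # scaffold constant
    expect_true(all(v$volume$flow_mask[v$volume$flow_mask] &
                      smask0[v$volume$flow_mask]))     # perfused subset
  }
})

test_that("rendering: flow confined to perfused voxels, reproducible, bounded", {
  p <- small_params()
  tree <- generate_vessel_tree(p)
  vol <- render_volume(tree, p)
  # noise off: flow nonzero exactly on the perfused rasterized voxels
  expect_identical(vol$flow > 0, vol$flow_mask)
  expect_true(all(vol$structure[vol$structure_mask] == 0.85))
  # independent rasterization of a single segment
  seg <- tree$segments[1, ]
  d <- c(p$ny, p$nx, p$nz)
  oracle <- array(FALSE, d)
  for (x in 1:d[2]) for (y in 1:d[1]) for (z in 1:d[3]) {
    ax <- seg$x1 - seg$x0; ay <- seg$y1 - seg$y0; az <- seg$z1 - seg$z0
    tt <- ((x - seg$x0) * ax + (y - seg$y0) * ay + (z - seg$z0) * az) /
      (ax^2 + ay^2 + az^2)
    tt <- min(1, max(0, tt))
    d2 <- (x - (seg$x0 + tt * ax))^2 + (y - (seg$y0 + tt * ay))^2 +
      (z - (seg$z0 + tt * az))^2
    if (d2 <= seg$radius^2) oracle[y, x, z] <- TRUE
  }
  one <- tree; one$segments <- tree$segments[1, ]
  expect_identical(render_volume(one, p)$structure_mask, oracle)
  # all flags false -> flow all zero before noise
  none <- tree; none$segments$perfused <- FALSE
  expect_true(all(render_volume(none, p)$flow == 0))
  # determinism with noise on
  pn <- small_params(speckle = 0.15, flow_noise = 0.05)
  expect_identical(render_volume(tree, pn), render_volume(tree, pn))
})

test_that("export writes the full file set, round-trips, and truth areas are shoelace areas", {
  skip_if_not_installed("pracma")
  p <- small_params(schedule = data.frame(week = c(0, 5, 10),
                                          fraction = c(1, 0.5, 0.2)),
                    injection_weeks = c(0, 4, 8))
  case <- simulate_case(p)
  d <- withr::local_tempdir()
  files <- export_case(case, d)
  expect_length(list.files(d, pattern = "^enface_angio_.*tif$"), 3)
  expect_length(list.files(d, pattern = "^enface_structure_.*tif$"), 3)
  expect_length(list.files(d, pattern = "^bscan_.*tif$"), 3)
  expect_true(file.exists(file.path(d, "truth.csv")))
  # 16-bit round trip equals the in-memory projection up to quantization
  pair <- mip_projection(case$visits[[1]]$volume)
  back <- read_tiff(file.path(d, "enface_angio_w000.tif"))
  expect_equal(back$bit_depth, 16)
  expect_equal(back$data / 65535, pair$angio$data, tolerance = 1 / 65535)
  # truth areas equal an independent shoelace computation on the ROI files
  tr <- utils::read.csv(file.path(d, "truth.csv"))
  for (i in seq_len(3)) {
    w <- c(0, 5, 10)[i]
    roi <- read_roi(file.path(d, sprintf("roi_structure_w%03d.json", w)))
    a <- abs(pracma::polyarea(roi$vertices[, 1], roi$vertices[, 2]))
    expect_equal(tr$true_structure_area_mm2[i], a * p$lateral_mm_px^2)
    roi_a <- read_roi(file.path(d, sprintf("roi_angio_w%03d.json", w)))
    aa <- abs(pracma::polyarea(roi_a$vertices[, 1], roi_a$vertices[, 2]))
    expect_equal(tr$true_angio_area_mm2[i], aa * p$lateral_mm_px^2)
  }
  # bit-reproducibility of the whole export
  d2 <- withr::local_tempdir()
  export_case(simulate_case(p), d2)
  for (f in basename(files)) {
    expect_identical(readBin(file.path(d, f), "raw", file.size(file.path(d, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})
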