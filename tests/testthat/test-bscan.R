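test_that("flow isolation: red minus blue, achromatic removal, green invariance", {
  rgb <- array(0, c(4, 4, 3))
  rgb[1, 1, ] <- c(255, 0, 0)      # pure red
  rgb[2, 2, ] <- c(120, 80, 60)    # mixed
  rgb[3, 3, ] <- c(90, 90, 90)     # achromatic
  bs <- bscan_rgb(rgb)
  fl <- isolate_flow(bs)
  expect_equal(fl$data[1, 1], 255)
  expect_equal(fl$data[2, 2], 60)
  expect_equal(fl$data[3, 3], 0)
  # any achromatic image vanishes entirely
  for (v in c(0, 17, 255)) {
    gr <- array(v, c(3, 3, 3))
    expect_true(all(isolate_flow(bscan_rgb(gr))$data == 0))
  }
  # blue exceeding red clamps at zero, and green never matters
  set.seed(8)
  rgb2 <- array(sample(0:255, 5 * 5 * 3, replace = TRUE), c(5, 5, 3))
  rgb3 <- rgb2
  rgb3[, , 2] <- sample(0:255, 25, replace = TRUE)
  expect_identical(isolate_flow(bscan_rgb(rgb2))$data,
                   isolate_flow(bscan_rgb(rgb3))$data)
  expect_true(all(isolate_flow(bscan_rgb(rgb2))$data >= 0))
  expect_error(isolate_flow("not an image"), "format error")
  expect_error(bscan_rgb(array(0, c(4, 4, 2))), "3 channels")
})

test_that("B-scan measurement: heights, FD, and geometry checks", {
  # flat ILM at row 100 (0-based), ROI reaching up to row 50, 2 um/px axial
  h <- 120; w <- 40
  rgb <- array(60, c(h, w, 3))  # gray structure everywhere
  ilm <- rep(100, w)
  # saturated red overlay filling rows 60..100 in columns 10..30
  rgb[61:101, 11:31, 1] <- 255
  rgb[61:101, 11:31, 2] <- 0
  rgb[61:101, 11:31, 3] <- 0
  bs <- bscan_rgb(rgb, axial_um_px = 2, lateral_mm_px = 0.01, ilm_row = ilm)
  roi <- roi_polygon(rbind(c(10, 50), c(30, 50), c(30, 100), c(10, 100)),
                     "bscan")
  m <- measure_bscan(bs, roi, phansalkar_params(radius = 5))
  expect_equal(m$height_structure_um, (100 - 50) * 2)
  # flow reaches row 60 -> height_flow = (100 - 60) * 2; never above structure
  expect_equal(m$height_flow_um, (100 - 60) * 2)
  expect_lte(m$height_flow_um, m$height_structure_um)
  # area in mm2: 21 x 51 px * (2/1000 mm) * 0.01 mm
  expect_equal(m$nv_area, 21 * 51 * 0.002 * 0.01)
  expect_equal(m$area_unit, "mm2")
  # no red overlay anywhere: fd = 0 and height_flow = 0 (with warning)
  gray_only <- bscan_rgb(array(60, c(h, w, 3)), axial_um_px = 2,
                         lateral_mm_px = 0.01, ilm_row = ilm)
  expect_warning(m0 <- measure_bscan(gray_only, roi,
                                     phansalkar_params(radius = 5)),
                 "no flow")
  expect_equal(m0$fd_pct, 0)
  expect_equal(m0$height_flow_um, 0)
  # ROI dipping below the ILM is a geometry error
  bad <- roi_polygon(rbind(c(10, 80), c(30, 80), c(30, 110), c(10, 110)),
                     "bscan")
  expect_error(measure_bscan(bs, bad, phansalkar_params(radius = 5)),
               "below the ILM")
})

test_that("saturated red overlay covering the whole ROI yields FD = 100%", {
  rgb <- array(0, c(30, 30, 3))
  rgb[6:25, 6:25, 1] <- 255
  bs <- bscan_rgb(rgb, axial_um_px = 2, lateral_mm_px = 0.01,
                  ilm_row = rep(27, 30))
  roi <- roi_polygon(rbind(c(7, 7), c(24, 7), c(24, 24), c(7, 24)), "bscan")
  m <- measure_bscan(bs, roi, phansalkar_params(radius = 4))
  expect_equal(m$fd_pct, 100)
})

test_that("height_flow <= height_structure on generated B-scans across visits", {
  p <- small_params()
  case <- simulate_case(p)
  d <- withr::local_tempdir()
  export_case(case, d)
  rows <- measure_case_bscan(d)
  expect_equal(nrow(rows), nrow(p$schedule))
  expect_true(all(rows$height_flow_um <= rows$height_structure_um + 1e-9))
  expect_true(all(rows$bscan_fd_pct >= 0 & rows$bscan_fd_pct <= 100))
  # flow regresses within a constant structural outline
  expect_true(all(diff(rows$height_flow_um) <= 1e-9))
  expect_equal(length(unique(rows$height_structure_um)), 1)
})

test_that("B-scan FD tracks the rendered perfused pixels within the ROI", {
  p <- small_params()
  tree <- generate_vessel_tree(p)
  vol <- render_volume(tree, p)
  by <- round(p$ny / 2)
  bs <- render_bscan(vol, y = by)
  # counting oracle on the rendered overlay pixels inside the ROI
  slice_fp <- t(vol$structure_mask[by, , ])
  if (p$ilm_z < p$nz) slice_fp[(p$ilm_z + 1):p$nz, ] <- FALSE
  flow_fp <- t(vol$flow_mask[by, , ])
  pix <- which(slice_fp, arr.ind = TRUE)
  hull <- grDevices::chull(pix[, 2] - 1, pix[, 1] - 1)
  roi <- roi_polygon(cbind(pix[hull, 2] - 1, pix[hull, 1] - 1), "bscan")
  mask <- polygon_to_mask(roi, dim(slice_fp))$data
  truth_fd <- 100 * sum(flow_fp & mask) / sum(mask)
  m <- measure_bscan(bs, roi)
  expect_lt(abs(m$fd_pct - truth_fd), 5)
})
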