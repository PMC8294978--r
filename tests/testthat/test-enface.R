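test_that("polygon rasterization: rectangles, oracle agreement, errors", {
  # axis-aligned rectangle through pixel centers (0,0)-(9,9): 100 pixels,
  # boundary centers count as inside
  rect <- roi_polygon(rbind(c(0, 0), c(9, 0), c(9, 9), c(0, 9)), "angio")
  m <- polygon_to_mask(rect, c(12, 12))
  expect_equal(sum(m$data), 100)
  expect_true(all(m$data[1:10, 1:10]))
  # triangle vs an independently written per-pixel ray-casting oracle
  tri <- roi_polygon(rbind(c(1, 1), c(10.5, 2.2), c(4, 9.7)), "structure")
  expect_identical(polygon_to_mask(tri, c(12, 12))$data,
                   ray_cast_oracle(tri$vertices, c(12, 12)))
  # irregular pentagon
  pent <- roi_polygon(rbind(c(0.5, 3), c(5, 0.2), c(11, 4), c(8, 11),
                            c(2, 9.5)), "angio")
  expect_identical(polygon_to_mask(pent, c(13, 13))$data,
                   ray_cast_oracle(pent$vertices, c(13, 13)))
  expect_error(roi_polygon(rbind(c(0, 0), c(5, 5)), "angio"), ">= 3")
  expect_error(polygon_to_mask(roi_polygon(rbind(c(0, 0), c(50, 0), c(0, 50)),
                                           "angio"), c(12, 12)),
               "outside image bounds")
})

test_that("shoelace area matches an independent implementation", {
  skip_if_not_installed("pracma")
  set.seed(5)
  for (i in 1:10) {
    ang <- sort(runif(6, 0, 2 * pi))
    rr <- runif(6, 2, 10)
    v <- cbind(10 + rr * cos(ang), 10 + rr * sin(ang))  # star-convex: simple
    expect_equal(abs(polygon_area(v)), abs(pracma::polyarea(v[, 1], v[, 2])))
  }
  sq <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))
  expect_equal(abs(polygon_area(sq)), 16)
})

test_that("maximum intensity projection matches a brute-force loop", {
  set.seed(9)
  st <- array(runif(16 * 16 * 8), c(16, 16, 8))
  fl <- array(runif(16 * 16 * 8), c(16, 16, 8))
  ilm <- matrix(sample(3:8, 256, replace = TRUE), 16, 16)
  vol <- octa_volume(st, fl, ilm, 0.01, 5)
  pair <- mip_projection(vol)
  exp_a <- matrix(0, 16, 16); exp_s <- matrix(0, 16, 16)
  for (r in 1:16) for (cc in 1:16) {
    zz <- seq_len(ilm[r, cc])  # slab: 0 < z <= ilm
    exp_a[r, cc] <- max(fl[r, cc, zz])
    exp_s[r, cc] <- max(st[r, cc, zz])
  }
  expect_equal(pair$angio$data, exp_a)
  expect_equal(pair$structure$data, exp_s)
})

test_that("slab semantics: voxels below the ILM are excluded", {
  st <- array(0, c(8, 8, 8)); fl <- array(0, c(8, 8, 8))
  fl[4, 4, 3] <- 0.7   # inside slab (z = 3 <= ilm = 5)
  fl[5, 5, 7] <- 0.9   # strictly below the ILM -> excluded
  vol <- octa_volume(st, fl, 5, 0.01, 5)
  pair <- mip_projection(vol)
  expect_equal(pair$angio$data[4, 4], 0.7)
  expect_equal(pair$angio$data[5, 5], 0)
  # slab bounds validation
  expect_error(mip_projection(vol, list(ilm = 2, top = 4)), "below lower")
  expect_error(mip_projection(vol, list(ilm = 9, top = 0)), "outside")
})

test_that("en face measurement: areas, FD source image, and degenerate input", {
  # 10x10-pixel rectangle at 0.01 mm/px -> 100 px * 1e-4 mm2 = 0.01 mm2
  ang <- gray_image(matrix(0, 20, 20), bit_depth = 1, spacing_mm = 0.01)
  str <- gray_image(matrix(0.2, 20, 20), bit_depth = 1, spacing_mm = 0.01)
  pair <- en_face_pair(ang, str)
  roi <- roi_polygon(rbind(c(3, 3), c(12, 3), c(12, 12), c(3, 12)), "angio")
  roi_s <- roi_polygon(rbind(c(3, 3), c(12, 3), c(12, 12), c(3, 12)),
                       "structure")
  m <- measure_enface(pair, roi, roi_s, phansalkar_params(radius = 3))
  expect_equal(m$nv_angio_area_mm2, 0.01)
  expect_equal(m$nv_structure_area_mm2, 0.01)
  # angio image all-zero -> both FD are 0 regardless of ROIs
  expect_equal(m$fd_angio_pct, 0)
  expect_equal(m$fd_structure_pct, 0)
})

test_that("identical ROIs give identical FDs; areas scale with spacing^2", {
  set.seed(21)
  img <- matrix(runif(900), 30, 30)
  mk_pair <- function(sp) en_face_pair(
    gray_image(img, bit_depth = 1, spacing_mm = sp),
    gray_image(img / 2, bit_depth = 1, spacing_mm = sp))
  roi <- roi_polygon(rbind(c(4, 5), c(25, 3), c(27, 26), c(6, 24)), "angio")
  roi_s <- roi_polygon(roi$vertices, "structure")
  pp <- phansalkar_params(radius = 4)
  m1 <- measure_enface(mk_pair(0.01), roi, roi_s, pp)
  expect_identical(m1$fd_angio_pct, m1$fd_structure_pct)
  m2 <- measure_enface(mk_pair(0.02), roi, roi_s, pp)
  expect_equal(m2$nv_angio_area_mm2, 4 * m1$nv_angio_area_mm2)
  expect_equal(m2$nv_structure_area_mm2, 4 * m1$nv_structure_area_mm2)
  expect_equal(m2$fd_angio_pct, m1$fd_angio_pct)  # FD is unit-free
})

test_that("FD-structure <= FD-angio when the angio ROI isolates all foreground", {
  # foreground confined to a bright block; angio ROI = that block,
  # structure ROI = a strictly larger region
  img <- matrix(0, 24, 24)
  img[9:14, 9:14] <- 1
  pair <- en_face_pair(gray_image(img, bit_depth = 1, spacing_mm = 0.01),
                       gray_image(img, bit_depth = 1, spacing_mm = 0.01))
  roi_a <- roi_polygon(rbind(c(8, 8), c(13, 8), c(13, 13), c(8, 13)), "angio")
  roi_s <- roi_polygon(rbind(c(2, 2), c(21, 2), c(21, 21), c(2, 21)),
                       "structure")
  m <- measure_enface(pair, roi_a, roi_s, phansalkar_params(radius = 5))
  expect_lte(m$fd_structure_pct, m$fd_angio_pct)
})
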