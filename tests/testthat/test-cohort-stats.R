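test_that("summarize_values reproduces the reference cohort summary", {
  # NV-angio posttreatment regressions of the nine NVs
  x <- c(76, 78, 100, 11, 65, 24, 32, 33, 48)
  s <- summarize_values(x)
  expect_equal(round(s$mean, 1), 51.9)
  expect_equal(round(s$sd, 1), 29.5)
  expect_equal(round(s$ci_low, 1), 32.6)
  expect_equal(round(s$ci_high, 1), 71.2)
  expect_equal(s$median, 48)
  expect_equal(c(s$range_low, s$range_high), c(11, 100))
  # constant list
  s0 <- summarize_values(c(5, 5, 5))
  expect_equal(s0$sd, 0)
  expect_equal(c(s0$ci_low, s0$ci_high, s0$median), c(5, 5, 5))
  expect_error(summarize_values(3), "insufficient data")
})

test_that("summarize_values matches direct textbook formulas on random data", {
  set.seed(99)
  x <- rnorm(50, 10, 4)
  s <- summarize_values(x)
  m <- sum(x) / 50
  sd_direct <- sqrt(sum((x - m)^2) / 49)
  xs <- sort(x)
  expect_equal(s$mean, m, tolerance = 1e-12)
  expect_equal(s$sd, sd_direct, tolerance = 1e-12)
  expect_equal(s$median, (xs[25] + xs[26]) / 2, tolerance = 1e-12)
  expect_equal(s$ci_low, m - 1.96 * sd_direct / sqrt(50), tolerance = 1e-12)
  expect_equal(s$ci_high, m + 1.96 * sd_direct / sqrt(50), tolerance = 1e-12)
  # permutation invariance and shift equivariance
  s2 <- summarize_values(sample(x))
  expect_equal(s2$mean, s$mean)
  expect_equal(s2$sd, s$sd)
  s3 <- summarize_values(x + 7)
  expect_equal(s3$median, s$median + 7)
  expect_equal(s3$sd, s$sd)
  expect_equal(s3$ci_high - s3$ci_low, s$ci_high - s$ci_low)
})

test_that("Wilcoxon variant: all-positive n = 9 and the symmetric pair", {
  # nine all-positive differences: W+ = n(n+1)/2 = 45, z ~ 2.666, p ~ 0.0077
  d <- c(26, 37, 61, 39, 30, 53, 14, 3, 7)
  w <- wilcoxon_signed_rank(d)
  expect_equal(w$w_plus, 45)
  expect_equal(w$z, 2.666, tolerance = 5e-4)
  expect_equal(round(w$p, 4), 0.0077)
  expect_warning(w2 <- wilcoxon_signed_rank(c(1, -1)), "n < 5")
  expect_equal(w2$w_plus, 1.5)
  expect_equal(w2$z, 0)
  expect_equal(w2$p, 1)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "all differences are zero")
})

test_that("Wilcoxon agrees with the stats oracle and the exact enumeration", {
  set.seed(123)
  for (i in 1:5) {
    d <- round(rnorm(9, 1, 2), 1)
    d <- d[d != 0]
    w <- wilcoxon_signed_rank(d)
    ref <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                               correct = FALSE))
    expect_equal(w$p, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(w$w_plus, unname(ref$statistic))
  }
  # rank machinery vs exhaustive sign enumeration at n = 8
  set.seed(7)
  d8 <- round(rnorm(8, 0.5, 1.5), 2)
  d8 <- d8[d8 != 0]
  w <- wilcoxon_signed_rank(d8, method = "exact")
  r <- rank(abs(d8)); n <- length(d8); mu <- n * (n + 1) / 4
  bits <- as.integer(2^(0:(n - 1)))
  ws <- vapply(0:(2^n - 1), function(mask)
    sum(r[bitwAnd(mask, bits) > 0]), numeric(1))
  p_exact <- mean(abs(ws - mu) >= abs(w$w_plus - mu) - 1e-12)
  expect_equal(w$p, p_exact, tolerance = 1e-12)
  # p is invariant under monotone transforms of |d| preserving signs/order
  w1 <- wilcoxon_signed_rank(d8)
  w2 <- wilcoxon_signed_rank(sign(d8) * exp(abs(d8)))
  expect_equal(w1$p, w2$p, tolerance = 1e-12)
})

test_that("endpoint_table reproduces the cohort statistics from the fixture", {
  et <- endpoint_table(load_table1_fixture())
  g <- function(ep) et[et$endpoint == ep, ]
  sp <- g("nv_structure_regression_post")
  expect_equal(sp$median, 15)
  expect_equal(round(sp$mean, 1), 18.7)
  expect_equal(round(sp$sd, 1), 39.0)
  expect_equal(round(sp$p, 2), 0.26)
  # scale invariance: doubling all areas leaves relative changes unchanged
  fx <- load_table1_fixture()
  fx2 <- fx
  for (cc in grep("^area_", names(fx2))) fx2[[cc]] <- 2 * fx2[[cc]]
  for (side in c("structure", "angio")) for (when in c("post", "last")) {
    fx2[[sprintf("change_%s_%s_pct", side, when)]] <- relative_change(
      fx2[[sprintf("area_%s_baseline", side)]],
      fx2[[sprintf("area_%s_%s", side, when)]])
  }
  et2 <- endpoint_table(fx2)
  expect_equal(et2$mean, et$mean, tolerance = 1e-12)
  expect_equal(et2$p, et$p, tolerance = 1e-12)
  # single-row input: medians equal the row's own values, p omitted
  et1 <- endpoint_table(load_table1_fixture()[4, ])
  expect_equal(et1$median[et1$endpoint == "fd_structure_baseline"], 81)
  expect_true(all(is.na(et1$p)))
})

test_that("all-positive differences give W+ = n(n+1)/2 exactly", {
  set.seed(31)
  for (n in c(5, 9, 14)) {
    d <- abs(rnorm(n)) + 0.01
    expect_equal(wilcoxon_signed_rank(d)$w_plus, n * (n + 1) / 2)
  }
})

test_that("graph rendering writes the six deterministic panels", {
  fx <- load_table1_fixture()
  d <- withr::local_tempdir()
  files <- render_graphs(fx, dir = d)
  expect_length(files, 6)
  expect_true(all(file.exists(files)))
  expect_length(list.files(d, pattern = "^box_.*png$"), 2)
  expect_length(list.files(d, pattern = "^long_.*png$"), 4)
  # normalized curves equal raw areas divided by baseline, pointwise
  s <- octanv:::series_from_rows(fx)[[5]]   # NV5
  v <- s$visits
  expect_equal(v$nv_structure_area_mm2 / v$nv_structure_area_mm2[1],
               c(1, 1.28, 2.96), tolerance = 1e-12)
})
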