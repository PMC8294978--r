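#' Median/range/mean/SD/CI summary of one endpoint
#'
#' Cohort descriptive summary: median (midpoint rule for even n), range,
#' mean, sample standard deviation (n - 1 denominator), and the normal 95%
#' confidence interval of the mean, `mean +/- 1.96 * sd / sqrt(n)`. The
#' 1.96 normal multiplier (rather than Student t) is the variant that
#' back-solves the reference cohort's printed intervals exactly.
#'
#' @param values numeric vector, length >= 2.
#' @return A list of class `stat_summary` with fields `n`, `median`,
#'   `range_low`, `range_high`, `mean`, `sd`, `ci_low`, `ci_high`.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L)
    stop("summarize_values: need at least 2 values (insufficient data)",
         call. = FALSE)
  m <- mean(values); s <- stats::sd(values)
  half <- 1.96 * s / sqrt(n)
  structure(list(n = n, median = stats::median(values),
                 range_low = min(values), range_high = max(values),
                 mean = m, sd = s, ci_low = m - half, ci_high = m + half),
            class = "stat_summary")
}

#' @export
print.stat_summary <- function(x, ...) {
  cat(sprintf(
    "n=%d  median %g (range %g to %g)  mean %.1f +/- %.1f (95%% CI %.1f to %.1f)\n",
    x$n, x$median, x$range_low, x$range_high, x$mean, x$sd,
    x$ci_low, x$ci_high))
  invisible(x)
}

#' Wilcoxon signed-rank test (normal approximation, no continuity correction)
#'
#' Tests paired differences against zero. Zero differences are dropped;
#' absolute differences are ranked with average ranks for ties; W+ is the
#' sum of the ranks of the positive differences. The default normal
#' approximation uses the tie-corrected variance
#' `n(n+1)(2n+1)/24 - sum(t^3 - t)/48` and NO continuity correction, the
#' variant that reproduces the reference cohort's printed p-values; the
#' two-sided p comes from the normal distribution. `method = "exact"`
#' instead enumerates all 2^n sign assignments of the observed ranks
#' (n <= 20) and returns the exact two-sided tail probability
#' `P(|W - mu| >= |W+ - mu|)`.
#'
#' @param differences numeric vector of paired differences.
#' @param method `"normal"` (default) or `"exact"`.
#' @return A list of class `wilcoxon_result`: `n` (nonzero differences),
#'   `w_plus`, `z` (`NA` for exact), `p`, `method`.
#' @export
wilcoxon_signed_rank <- function(differences, method = c("normal", "exact")) {
  method <- match.arg(method)
  d <- differences[differences != 0]
  if (length(d) == 0L)
    stop("wilcoxon_signed_rank: all differences are zero (undefined test)",
         call. = FALSE)
  n <- length(d)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (method == "normal") {
    if (n < 5)
      warning("wilcoxon_signed_rank: normal approximation with n < 5 nonzero differences")
    ties <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- if (sigma2 > 0) (w_plus - mu) / sqrt(sigma2) else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    structure(list(n = n, w_plus = w_plus, z = z, p = p, method = method),
              class = "wilcoxon_result")
  } else {
    if (n > 20)
      stop("wilcoxon_signed_rank: exact enumeration limited to n <= 20",
           call. = FALSE)
    signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
    w_all <- as.matrix(signs) %*% r
    p <- mean(abs(w_all - mu) >= abs(w_plus - mu) - 1e-12)
    structure(list(n = n, w_plus = w_plus, z = NA_real_, p = p,
                   method = method),
              class = "wilcoxon_result")
  }
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): n=%d, W+=%g, z=%s, p=%.4g\n",
              x$method, x$n, x$w_plus,
              ifelse(is.na(x$z), "-", sprintf("%.3f", x$z)), x$p))
  invisible(x)
}

# The eight treatment-response endpoints (values oriented so that positive
# means regression/decrease, the reporting convention) plus the raw FD
# levels at each timepoint.
endpoint_definitions <- function() {
  list(
    nv_structure_regression_post = function(r) -r$change_structure_post_pct,
    nv_structure_regression_last = function(r) -r$change_structure_last_pct,
    nv_angio_regression_post = function(r) -r$change_angio_post_pct,
    nv_angio_regression_last = function(r) -r$change_angio_last_pct,
    fd_structure_decrease_post = function(r)
      fd_change(r$fd_structure_baseline_pct, r$fd_structure_post_pct),
    fd_structure_decrease_last = function(r)
      fd_change(r$fd_structure_baseline_pct, r$fd_structure_last_pct),
    fd_angio_decrease_post = function(r)
      fd_change(r$fd_angio_baseline_pct, r$fd_angio_post_pct),
    fd_angio_decrease_last = function(r)
      fd_change(r$fd_angio_baseline_pct, r$fd_angio_last_pct))
}

fd_level_definitions <- function() {
  list(
    fd_structure_baseline = function(r) r$fd_structure_baseline_pct,
    fd_structure_post = function(r) r$fd_structure_post_pct,
    fd_structure_last = function(r) r$fd_structure_last_pct,
    fd_angio_baseline = function(r) r$fd_angio_baseline_pct,
    fd_angio_post = function(r) r$fd_angio_post_pct,
    fd_angio_last = function(r) r$fd_angio_last_pct)
}

#' Cohort endpoint table
#'
#' Summarizes every treatment-response endpoint over the cohort: area
#' regressions (positive = regression) and FD decreases (positive =
#' decrease) at posttreatment and last follow-up, each with median/range,
#' mean/SD, normal 95% CI, and the Wilcoxon signed-rank p-value versus zero
#' change; plus the raw FD levels at baseline/posttreatment/last follow-up
#' (descriptive only, no test). With a single row, medians/means equal the
#' row's own values and SD/CI/p are `NA`.
#'
#' @param rows a data.frame of endpoint rows ([select_endpoints()] output or
#'   the packaged reference fixture), one row per NV.
#' @return A data.frame, one row per endpoint, columns `endpoint, n, median,
#'   range_low, range_high, mean, sd, ci_low, ci_high, w_plus, z, p`.
#' @export
endpoint_table <- function(rows) {
  if (nrow(rows) < 1L) stop("endpoint_table: no rows", call. = FALSE)
  defs <- c(endpoint_definitions(), fd_level_definitions())
  tested <- names(endpoint_definitions())
  out <- lapply(names(defs), function(nm) {
    vals <- defs[[nm]](rows)
    if (length(vals) >= 2L) {
      s <- summarize_values(vals)
      wres <- if (nm %in% tested && any(vals != 0))
        wilcoxon_signed_rank(vals) else NULL
      data.frame(endpoint = nm, n = s$n, median = s$median,
                 range_low = s$range_low, range_high = s$range_high,
                 mean = s$mean, sd = s$sd,
                 ci_low = s$ci_low, ci_high = s$ci_high,
                 w_plus = if (is.null(wres)) NA_real_ else wres$w_plus,
                 z = if (is.null(wres)) NA_real_ else wres$z,
                 p = if (is.null(wres)) NA_real_ else wres$p)
    } else {
      data.frame(endpoint = nm, n = 1L, median = vals, range_low = vals,
                 range_high = vals, mean = vals, sd = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, w_plus = NA_real_,
                 z = NA_real_, p = NA_real_)
    }
  })
  do.call(rbind, out)
}
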