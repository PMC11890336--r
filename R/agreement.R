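#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of mid-ranks (average ranks for ties).
#' The two-sided p-value uses exact permutation enumeration for n <= 9 and
#' the t approximation with n - 2 degrees of freedom otherwise.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return List with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_sp("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop_sp("need n >= 3 observations, got %d", n)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_sp("x and y must be finite")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop_sp("rho undefined: at least one vector is constant")
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    s_obs <- sum(rx * ry)
    center <- n * mean(rx) * mean(ry)
    P <- all_perms(n - 1L)
    exceed <- 0; total <- 0
    for (i in seq_len(n)) {
      rest <- ry[-i]
      s_all <- rx[1] * ry[i] + as.vector(matrix(rest[P], nrow(P)) %*% rx[-1])
      exceed <- exceed + sum(abs(s_all - center) >= abs(s_obs - center) - 1e-9)
      total <- total + length(s_all)
    }
    p <- exceed / total
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

# All permutations of 1..n as an n! x n integer matrix (n <= 8 in practice).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- all_perms(n - 1L)
  m <- nrow(p)
  out <- matrix(0L, n * m, n)
  for (i in seq_len(n)) {
    out[((i - 1L) * m + 1L):(i * m), ] <- cbind(i, matrix((seq_len(n)[-i])[p], m))
  }
  out
}

#' Bland-Altman agreement
#'
#' Mean difference between two measurement methods with 95% limits of
#' agreement at mean +/- 1.96 x SD of the differences (sample SD, n - 1
#' denominator). The 1.96 multiplier is fixed; no small-sample t correction
#' is applied.
#'
#' @param us_mm,wsi_mm paired measurements (mm). Alternatively pass the
#'   differences directly as `us_mm` and omit `wsi_mm`.
#' @return List with `n`, `mean_diff_mm`, `sd_diff_mm`, `loa_lower_mm`,
#'   `loa_upper_mm`. Differences are `us - wsi`.
#' @export
bland_altman <- function(us_mm, wsi_mm = NULL) {
  d <- if (is.null(wsi_mm)) as.numeric(us_mm) else {
    if (length(us_mm) != length(wsi_mm)) stop_sp("paired vectors must have equal length")
    as.numeric(us_mm) - as.numeric(wsi_mm)
  }
  if (length(d) < 2L) stop_sp("need at least 2 paired measurements, got %d", length(d))
  m <- mean(d); s <- stats::sd(d)
  list(n = length(d), mean_diff_mm = m, sd_diff_mm = s,
       loa_lower_mm = m - 1.96 * s, loa_upper_mm = m + 1.96 * s)
}

#' Pair US and WSI measurements
#'
#' Joins one ultrasound source's measurements to the WSI measurements by
#' slide and region, computing the per-pair mean, difference (us - wsi) and
#' magnitude category.
#'
#' @param measurements data.frame as from [measure_all()] (columns
#'   `slide_id`, `source`, `region`, `value_mm`).
#' @param us_source `"US_M"` or `"US_Reg"`.
#' @return data.frame with `slide_id`, `region`, `us_mm`, `wsi_mm`,
#'   `mean_mm`, `diff_mm`, `category`.
#' @export
paired_measurements <- function(measurements, us_source = c("US_Reg", "US_M")) {
  us_source <- match.arg(us_source)
  wsi <- measurements[measurements$source == "WSI", ]
  us <- measurements[measurements$source == us_source, ]
  if (!nrow(wsi)) stop_sp("no WSI measurements to pair against")
  if (!nrow(us)) stop_sp("no %s measurements present", us_source)
  merged <- merge(us[, c("slide_id", "region", "value_mm")],
                  wsi[, c("slide_id", "region", "value_mm")],
                  by = c("slide_id", "region"), suffixes = c("_us", "_wsi"))
  merged <- merged[order(merged$slide_id, merged$region), ]
  out <- data.frame(slide_id = merged$slide_id, region = merged$region,
                    us_mm = merged$value_mm_us, wsi_mm = merged$value_mm_wsi,
                    stringsAsFactors = FALSE)
  out$mean_mm <- (out$us_mm + out$wsi_mm) / 2
  out$diff_mm <- out$us_mm - out$wsi_mm
  out$category <- categorize_mean(out$mean_mm)
  rownames(out) <- NULL
  out
}

categorize_mean <- function(mean_mm) {
  if (any(mean_mm < 0)) stop_sp("negative mean measurement; categories are defined on [0, Inf)")
  as.character(cut(mean_mm, breaks = c(0, 5, 10, Inf),
                   labels = c("<5", "5<10", ">10"),
                   right = FALSE, include.lowest = TRUE))
}

#' Split paired measurements into magnitude categories
#'
#' Partitions by the mean of the two modalities into `<5` ([0, 5) mm),
#' `5<10` ([5, 10) mm) and `>10` ([10, Inf) mm). Boundaries are left-closed
#' (5.0 falls in `5<10`, 10.0 in `>10`); the partition is exhaustive and
#' disjoint.
#'
#' @param pairs data.frame from [paired_measurements()] (needs `mean_mm`).
#' @return Named list of data.frames, one per category (possibly empty).
#' @export
split_categories <- function(pairs) {
  cats <- c("<5", "5<10", ">10")
  if (!nrow(pairs)) return(stats::setNames(lapply(cats, function(x) pairs), cats))
  cat_col <- categorize_mean(pairs$mean_mm)
  stats::setNames(lapply(cats, function(cc) pairs[cat_col == cc, , drop = FALSE]), cats)
}

#' Agreement and correlation report
#'
#' For each ultrasound annotation source present (US_M, US_Reg) and each
#' stratum (All plus the three magnitude categories), computes the Spearman
#' correlation and Bland-Altman agreement against the WSI measurements.
#' Strata with fewer than 3 pairs are flagged as not computed. Measurements
#' from multiple slides of one patient are pooled without clustering
#' adjustment; the `pooled_slides` attribute flags this limitation.
#'
#' @param measurements data.frame as from [measure_all()] rows bound over
#'   slides.
#' @return data.frame with columns `us_source`, `stratum`, `n`, `rho`, `p`,
#'   `mean_diff_mm`, `loa_lower_mm`, `loa_upper_mm`, `computed`.
#' @export
agreement_report <- function(measurements) {
  if (!any(measurements$source == "WSI"))
    stop_sp("agreement_report: no WSI measurements present")
  srcs <- intersect(c("US_M", "US_Reg"), unique(measurements$source))
  if (!length(srcs)) stop_sp("agreement_report: no ultrasound measurements present")
  rows <- list()
  for (src in srcs) {
    pairs <- paired_measurements(measurements, src)
    strata <- c(list(All = pairs), split_categories(pairs))
    for (st in names(strata)) {
      d <- strata[[st]]
      if (nrow(d) >= 3L && stats::sd(d$us_mm) > 0 && stats::sd(d$wsi_mm) > 0) {
        sc <- spearman_correlation(d$wsi_mm, d$us_mm)
        ba <- bland_altman(d$us_mm, d$wsi_mm)
        rows[[length(rows) + 1L]] <- data.frame(
          us_source = src, stratum = st, n = nrow(d), rho = sc$rho, p = sc$p_value,
          mean_diff_mm = ba$mean_diff_mm, loa_lower_mm = ba$loa_lower_mm,
          loa_upper_mm = ba$loa_upper_mm, computed = TRUE, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          us_source = src, stratum = st, n = nrow(d), rho = NA_real_, p = NA_real_,
          mean_diff_mm = NA_real_, loa_lower_mm = NA_real_, loa_upper_mm = NA_real_,
          computed = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pooled_slides") <- TRUE
  out
}

#' Bland-Altman plot
#'
#' Difference against mean of the paired measurements, with the mean
#' difference and 95% limits of agreement as horizontal lines and points
#' colored by magnitude category. Requires ggplot2.
#'
#' @param pairs data.frame from [paired_measurements()].
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(pairs, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_sp("plot_bland_altman requires the ggplot2 package")
  ba <- bland_altman(pairs$us_mm, pairs$wsi_mm)
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$mean_mm, y = .data$diff_mm,
                                      color = .data$category)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = ba$mean_diff_mm, color = "blue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower_mm, ba$loa_upper_mm),
                        color = "red", linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(5, 10), linetype = "dotted") +
    ggplot2::labs(x = "mean of US and WSI (mm)", y = "US - WSI (mm)",
                  title = title, color = "category") +
    ggplot2::theme_minimal()
}
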