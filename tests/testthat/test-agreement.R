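test_that("spearman rho hits the monotone extremes", {
  x <- c(1, 3, 4, 7, 9, 12)
  expect_equal(spearman_correlation(x, exp(x))$rho, 1.0)
  expect_equal(spearman_correlation(x, rev(x))$rho, -1.0)
  expect_error(spearman_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("rho equals the rank-then-Pearson oracle and cor.test", {
  set.seed(77)
  for (k in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    res <- spearman_correlation(x, y)
    oracle <- cor(rank(x), rank(y))
    expect_equal(res$rho, oracle, tolerance = 1e-12)
    expect_equal(res$rho,
                 unname(suppressWarnings(
                   cor.test(x, y, method = "spearman")$estimate)),
                 tolerance = 1e-12)
  }
})

test_that("the n = 7 permutation p-value equals full enumeration", {
  set.seed(5)
  x <- rnorm(7); y <- 0.8 * x + rnorm(7, 0, 0.6)
  res <- spearman_correlation(x, y)
  expect_equal(res$method, "exact permutation")
  # independent oracle: recursive enumeration of all 7! rank permutations
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  count <- 0L; total <- 0L
  recurse <- function(prefix, remaining) {
    if (!length(remaining)) {
      r <- cor(rx, ry[prefix])
      if (abs(r) >= abs(rho_obs) - 1e-12) count <<- count + 1L
      total <<- total + 1L
      return(invisible())
    }
    for (i in seq_along(remaining))
      recurse(c(prefix, remaining[i]), remaining[-i])
  }
  recurse(integer(0), 1:7)
  expect_equal(total, factorial(7))
  expect_equal(res$p_value, count / total, tolerance = 1e-12)
  # cor.test's exact p (AS 89) must agree for tie-free data
  expect_equal(res$p_value,
               cor.test(x, y, method = "spearman", exact = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("large-n p-value uses the t approximation consistently", {
  set.seed(8)
  x <- rnorm(30); y <- 0.4 * x + rnorm(30)
  res <- spearman_correlation(x, y)
  expect_equal(res$method, "t approximation")
  tt <- res$rho * sqrt((30 - 2) / (1 - res$rho^2))
  expect_equal(res$p_value, 2 * pt(-abs(tt), 28), tolerance = 1e-12)
})

test_that("Bland-Altman limits follow mean +/- 1.96 sd exactly", {
  ba <- bland_altman(rep(2.5, 6))
  expect_equal(ba$mean_diff_mm, 2.5)
  expect_equal(ba$loa_upper_mm - ba$loa_lower_mm, 0)

  ba2 <- bland_altman(c(-1, 1))
  expect_equal(ba2$mean_diff_mm, 0)
  expect_equal(ba2$sd_diff_mm, sqrt(2), tolerance = 1e-12)
  expect_equal(ba2$loa_upper_mm, 1.96 * sqrt(2), tolerance = 1e-12)

  set.seed(9)
  us <- runif(25, 0, 15); wsi <- us * 0.9 + rnorm(25, 0, 0.5)
  ba3 <- bland_altman(us, wsi)
  d <- us - wsi
  expect_equal(ba3$mean_diff_mm, mean(d), tolerance = 1e-12)
  expect_equal(ba3$sd_diff_mm, sd(d), tolerance = 1e-12)
  expect_equal(ba3$loa_lower_mm, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_error(bland_altman(1.2), "at least 2")
})

test_that("category boundaries are left-closed on the mean of the modalities", {
  pairs <- data.frame(slide_id = "s", region = "deep",
                      us_mm = c(4.9, 5.0, 10.0), wsi_mm = c(4.9, 5.0, 10.0))
  pairs$mean_mm <- (pairs$us_mm + pairs$wsi_mm) / 2
  pairs$diff_mm <- 0
  sp <- split_categories(pairs)
  expect_equal(nrow(sp[["<5"]]), 1L)
  expect_equal(nrow(sp[["5<10"]]), 1L)
  expect_equal(nrow(sp[[">10"]]), 1L)
  expect_equal(sp[["<5"]]$mean_mm, 4.9)
  expect_equal(sp[[">10"]]$mean_mm, 10.0)

  empty <- split_categories(pairs[0, ])
  expect_true(all(vapply(empty, nrow, 1L) == 0L))
  neg <- pairs; neg$mean_mm[1] <- -1
  expect_error(split_categories(neg), "negative")
})

test_that("category split matches a brute-force filter on random data", {
  set.seed(10)
  pairs <- data.frame(slide_id = "s", region = "deep",
                      us_mm = runif(200, 0, 20), wsi_mm = runif(200, 0, 20))
  pairs$mean_mm <- (pairs$us_mm + pairs$wsi_mm) / 2
  pairs$diff_mm <- pairs$us_mm - pairs$wsi_mm
  sp <- split_categories(pairs)
  expect_equal(nrow(sp[["<5"]]), sum(pairs$mean_mm < 5))
  expect_equal(nrow(sp[["5<10"]]), sum(pairs$mean_mm >= 5 & pairs$mean_mm < 10))
  expect_equal(nrow(sp[[">10"]]), sum(pairs$mean_mm >= 10))
  expect_equal(sum(vapply(sp, nrow, 1L)), 200L)
})

test_that("identical sources give rho 1 and zero mean difference in all strata", {
  set.seed(11)
  vals <- runif(40, 1, 18)
  meas <- rbind(
    data.frame(slide_id = rep(sprintf("s%02d", 1:10), each = 4),
               source = "US_Reg", region = rep(c("cranial", "deep", "caudal", "thickness"), 10),
               value_mm = vals),
    data.frame(slide_id = rep(sprintf("s%02d", 1:10), each = 4),
               source = "WSI", region = rep(c("cranial", "deep", "caudal", "thickness"), 10),
               value_mm = vals))
  rep_tab <- agreement_report(meas)
  done <- rep_tab[rep_tab$computed, ]
  expect_true(all(abs(done$rho - 1) < 1e-12))
  expect_true(all(abs(done$mean_diff_mm) < 1e-12))
  expect_true(all(abs(done$loa_upper_mm - done$loa_lower_mm) < 1e-12))
  expect_setequal(rep_tab$stratum, c("All", "<5", "5<10", ">10"))
})

test_that("the agreement report is a pure, order-independent function of the table", {
  set.seed(12)
  n <- 30
  meas <- rbind(
    data.frame(slide_id = rep(sprintf("s%02d", 1:n), 1), source = "US_M",
               region = "deep", value_mm = runif(n, 0, 15)),
    data.frame(slide_id = rep(sprintf("s%02d", 1:n), 1), source = "US_Reg",
               region = "deep", value_mm = runif(n, 0, 15)),
    data.frame(slide_id = rep(sprintf("s%02d", 1:n), 1), source = "WSI",
               region = "deep", value_mm = runif(n, 0, 15)))
  r1 <- agreement_report(meas)
  shuffled <- meas[sample(nrow(meas)), ]
  r2 <- agreement_report(shuffled)
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2)
  expect_error(agreement_report(meas[meas$source != "WSI", ]), "WSI")
})

test_that("small strata are flagged as not computed", {
  meas <- rbind(
    data.frame(slide_id = c("a", "b"), source = "US_Reg", region = "deep",
               value_mm = c(1, 2)),
    data.frame(slide_id = c("a", "b"), source = "WSI", region = "deep",
               value_mm = c(1.1, 2.2)))
  rep_tab <- agreement_report(meas)
  expect_false(any(rep_tab$computed))
  expect_true(all(is.na(rep_tab$rho)))
})
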