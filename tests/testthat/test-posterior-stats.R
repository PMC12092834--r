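test_that("marginal KS comparison separates shifted posteriors with direction", {
  model <- toy_model()
  lo <- posterior_for(tibble::tibble(x1 = 0.05), model, id = "pre",
                      batch = "B1")
  hi <- posterior_for(tibble::tibble(x1 = 0.95), model, id = "post",
                      batch = "B1")
  cmp <- compare_marginals(lo, hi, n = 50, seed = 3)
  expect_lt(cmp$p_value, 1e-10)
  expect_identical(cmp$direction, 1)
  expect_identical(cmp$id_a, "pre")
  # statistic lives on the 1/50 lattice for equal sample sizes
  expect_equal(cmp$statistic * 50, round(cmp$statistic * 50),
               tolerance = 1e-9)
  # symmetry up to direction
  rev <- compare_marginals(hi, lo, n = 50, seed = 3)
  expect_identical(rev$direction, -1)
})

test_that("KS comparison of a posterior with itself is calibrated", {
  model <- toy_model()
  post <- posterior_for(tibble::tibble(x1 = 0.5), model)
  ps <- vapply(1:100, function(s) {
    compare_marginals(post, post, n = 50, seed = s)$p_value
  }, numeric(1))
  rate <- mean(ps < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("cross-batch comparisons are refused unless overridden", {
  model <- toy_model()
  a <- posterior_for(tibble::tibble(x1 = 0.4), model, batch = "MEA-1")
  b <- posterior_for(tibble::tibble(x1 = 0.6), model, batch = "MEA-2")
  expect_error(compare_marginals(a, b), "different MEA batches")
  expect_s3_class(compare_marginals(a, b, allow_cross_batch = TRUE),
                  "tbl_df")
  # same batch passes
  b1 <- posterior_for(tibble::tibble(x1 = 0.6), model, batch = "MEA-1")
  expect_s3_class(compare_marginals(a, b1), "tbl_df")
})

test_that("feature comparison uses the exact Mann-Whitney distribution", {
  set.seed(7)
  ga <- tibble::tibble(MFR = rnorm(8, 5), NBR = rnorm(8, 2))
  gb <- ga
  gb$MFR <- gb$MFR + 100   # complete separation on one feature
  res <- compare_features(ga, gb)
  # smallest two-sided p for complete separation at n = m = 8
  expect_equal(res$p_value[res$feature == "MFR"], 2 / choose(16, 8),
               tolerance = 1e-12)
  expect_gt(res$p_value[res$feature == "NBR"], 0.05)
  expect_error(compare_features(ga[1:2, ], gb), "at least 3")
  # identical groups: full ties give p = 1
  res_id <- compare_features(ga, ga)
  expect_true(all(res_id$p_value == 1))
  # an all-tied (constant) feature warns and yields p = 1
  ca <- tibble::tibble(f = rep(2, 5))
  expect_warning(res_c <- compare_features(ca, ca), "identical")
  expect_equal(res_c$p_value, 1)
})

test_that("Mann-Whitney null rejections stay near the nominal level", {
  set.seed(11)
  ps <- vapply(1:200, function(i) {
    a <- tibble::tibble(f = rnorm(8))
    b <- tibble::tibble(f = rnorm(8))
    compare_features(a, b)$p_value
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("correlation-vs-zero t-test behaves across regimes", {
  set.seed(13)
  null_r <- c(rnorm(25, 0, 0.1), -rnorm(25, 0, 0.1))
  expect_gt(corr_vs_zero(null_r)$p_value, 0.05)
  strong <- 0.9 + rnorm(50, 0, 0.001)
  expect_lt(corr_vs_zero(strong)$p_value, 1e-10)
  # mean 0.1, sd 0.1, n = 50: t = 0.1 / (0.1 / sqrt(50)) ~ 7.07
  z <- rnorm(50); z <- (z - mean(z)) / sd(z)
  r <- 0.1 + 0.1 * z
  res <- corr_vs_zero(r)
  expect_equal(res$t, 0.1 / (0.1 / sqrt(50)), tolerance = 1e-9)
  expect_lt(res$p_value, 1e-8)
  # degenerate zero-variance sets decide from the sign
  expect_equal(corr_vs_zero(rep(0.5, 10))$p_value, 0)
  expect_equal(corr_vs_zero(rep(0, 10))$p_value, 1)
  expect_error(corr_vs_zero(c(0.1, 0.2)), "at least 3")
})

test_that("prior-sd normalization is an exact element-wise division", {
  fv <- tibble::tibble(MFR = c(2, 4), NBR = c(3, 0))
  sds <- c(MFR = 2, NBR = 3)
  out <- normalize_features(fv, sds)
  expect_equal(out$MFR, c(1, 2))
  expect_equal(out$NBR, c(1, 0))
  # homogeneity
  out2 <- normalize_features(dplyr::mutate(fv, MFR = 2 * MFR), sds)
  expect_equal(out2$MFR, 2 * out$MFR)
  expect_error(normalize_features(fv, c(MFR = 0, NBR = 3)), "MFR")
})

test_that("per-line per-MEA aggregation averages wells correctly", {
  tb <- tibble::tibble(
    line = c("ctrl", "ctrl", "ctrl", "pat"),
    mea = c("M1", "M1", "M2", "M1"),
    MFR = c(1, 3, 5, 7))
  agg <- aggregate_by_line(tb)
  expect_identical(nrow(agg), 3L)
  expect_equal(agg$MFR[agg$line == "ctrl" & agg$mea == "M1"], 2)  # (1+3)/2
  expect_equal(agg$MFR[agg$line == "ctrl" & agg$mea == "M2"], 5)
  expect_equal(agg$n_wells, c(2L, 1L, 1L))
  expect_error(aggregate_by_line(tb[, -1]), "line")
})
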