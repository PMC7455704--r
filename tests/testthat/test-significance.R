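test_that("count levels are log-spaced, deduplicated, and span the range", {
  lv <- choose_count_levels(6000, c(10, 500, 5000), n_levels = 20)
  expect_identical(lv[1], 10L)
  expect_identical(lv[length(lv)], 5000L)
  expect_identical(lv, sort(unique(lv)))
  expect_length(lv, 20L)
  expect_identical(choose_count_levels(100, rep(50L, 5)), 50L)
})

test_that("randomized divergences are reproducible with positive spread", {
  coords <- make_blobs(250, rbind(c(0, 0), c(5, 5)), seed = 13)
  g <- select_grid_highd(coords, 15, seed = 3)
  g$bandwidth <- default_bandwidth(coords, g)
  dm <- kernel_weights(coords, g)
  q <- reference_distribution(dm)
  a <- randomized_divergences(50, dm, q, n_randomizations = 50, seed = 7)
  b <- randomized_divergences(50, dm, q, n_randomizations = 50, seed = 7)
  expect_identical(a, b)
  for (lv in c(10, 100, 250)) {
    r <- randomized_divergences(lv, dm, q, n_randomizations = 50, seed = 1)
    expect_gt(r["sd"], 0)
  }
  expect_error(randomized_divergences(500, dm, q), "level")
})

test_that("uniform weights reproduce the unweighted sampling distribution", {
  # selection frequencies under weighted sampling with uniform weights must
  # be indistinguishable from uniform (chi-square over 1000 draws)
  n_cells <- 40
  set.seed(123)
  counts <- numeric(n_cells)
  for (i in 1:1000) {
    idx <- sample.int(n_cells, 10, prob = rep(1 / n_cells, n_cells))
    counts[idx] <- counts[idx] + 1
  }
  expected <- sum(counts) / n_cells
  chi <- sum((counts - expected)^2 / expected)
  expect_gt(pchisq(chi, df = n_cells - 1, lower.tail = FALSE), 0.01)
})

test_that("spline null interpolates saturated fits and clamps extrapolation", {
  levels <- c(10, 20, 40, 80, 160, 320, 640)
  means <- log(1 / levels) + rnorm(7, sd = 0.01)
  sds <- rep(0.3, 7)
  m <- fit_null_model(levels, means, sds, spline_df = 6)   # df + 1 = n points
  expect_equal(m$mean_fun(levels), means, tolerance = 1e-8)
  expect_equal(m$sd_fun(levels), sds, tolerance = 1e-8)
  # clamped outside the fitted range
  expect_equal(m$mean_fun(1), m$mean_fun(10))
  expect_equal(m$mean_fun(10000), m$mean_fun(640))
  expect_true(all(m$sd_fun(c(1, 50, 1e5)) > 0))
  # constant means give a flat curve
  mc <- fit_null_model(levels, rep(-5, 7), sds, spline_df = 4)
  expect_equal(mc$mean_fun(c(15, 100, 500)), rep(-5, 3), tolerance = 1e-8)
  # too few levels fall back to the global constants
  m3 <- fit_null_model(c(10, 20, 30), c(-1, -2, -3), c(0.1, 0.2, 0.3))
  expect_equal(m3$mean_fun(15), -2)
  expect_error(fit_null_model(levels, c(means[-7], NA), sds), "finite")
  # with n_cells, the curve is symmetric in k vs n_cells - k
  ms <- fit_null_model(levels, means, sds, spline_df = 5, n_cells = 1000)
  expect_equal(ms$mean_fun(c(100, 250)), ms$mean_fun(c(900, 750)),
               tolerance = 1e-10)
})

test_that("null spline tracks held-out randomization means", {
  coords <- make_blobs(200, rbind(c(0, 0), c(4, 4)), seed = 14)
  g <- select_grid_highd(coords, 12, seed = 5)
  g$bandwidth <- default_bandwidth(coords, g)
  dm <- kernel_weights(coords, g)
  q <- reference_distribution(dm)
  levels <- choose_count_levels(400, c(10, 390), n_levels = 16)
  pts <- vapply(levels, function(lv)
    randomized_divergences(lv, dm, q, n_randomizations = 100, seed = lv),
    numeric(2))
  hold <- seq(2, length(levels) - 1, by = 3)
  m <- fit_null_model(levels[-hold], pts["mean", -hold], pts["sd", -hold],
                      n_cells = 400)
  pred <- m$mean_fun(levels[hold])
  tol <- 2 * pts["sd", hold] / sqrt(100)
  expect_gte(mean(abs(pred - pts["mean", hold]) < tol), 0.9)
})

test_that("z-scores convert to the expected log10 p-values", {
  model <- fit_null_model(c(10, 20, 40, 80), rep(0, 4), rep(1, 4))
  mk <- function(lnd) data.frame(gene = "g", d_kl = exp(lnd), n_detected = 20L)
  expect_equal(p_values(mk(0), model)$log10_pval, log10(0.5), tolerance = 1e-6)
  expect_equal(p_values(mk(1.6449), model)$log10_pval, -1.30103,
               tolerance = 1e-3)
  expect_equal(p_values(mk(-3), model)$log10_pval, log10(pnorm(3)),
               tolerance = 1e-6)
})

test_that("ranking is monotone in divergence at fixed detection count", {
  model <- fit_null_model(c(10, 20, 40, 80), -(1:4), rep(0.5, 4))
  scores <- data.frame(gene = paste0("g", 1:4),
                       d_kl = c(0.01, 0.5, 0.05, 0.5),
                       n_detected = c(20L, 20L, 20L, 40L))
  res <- p_values(scores, model)
  expect_lt(res$log10_pval[2], res$log10_pval[3])   # larger d_kl, same count
  expect_identical(res$rank[order(res$log10_pval, -res$d_kl)], 1:4)
  expect_true(all(res$log10_pval_adj >= res$log10_pval))
})

test_that("BH adjustment in log space matches the step-up rule", {
  expect_equal(10^adjust_bh(log10(c(0.01, 0.02, 0.03, 0.04))),
               rep(0.04, 4), tolerance = 1e-12)
  expect_equal(adjust_bh(log10(0.37)), log10(0.37))
  expect_equal(adjust_bh(rep(0, 5)), rep(0, 5))
  p <- c(0.001, 0.01, 0.02, 0.2, 0.9)
  expect_equal(10^adjust_bh(log10(p)), p.adjust(p, "BH"), tolerance = 1e-12)
})
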