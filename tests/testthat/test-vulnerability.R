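test_that("SDI evaluates the circularity formula", {
  r <- c(0.3, 1, 7)
  expect_equal(sdi(2 * pi * r, pi * r^2), rep(1, 3))        # circles
  expect_equal(sdi(4, 1), 2 / sqrt(pi))                     # unit square
  expect_equal(sdi(100, 100), 2.8209, tolerance = 1e-4)
  expect_error(sdi(-1, 1), "positive")
  expect_error(sdi(1, 0), "positive")
})

test_that("magnitude of change is the median absolute driver change", {
  fake <- function(x) structure(list(samples = data.frame(
    delta_driver = x)), class = "driver_assessment")
  expect_equal(magnitude_of_change(fake(c(-1, -2, -3, 1))), 1.5)
  expect_equal(magnitude_of_change(fake(rep(-2.5, 10))), 2.5)
  expect_equal(magnitude_of_change(fake(rep(2.5, 10))), 2.5)  # sign flip
  set.seed(20)
  x <- rnorm(101)
  expect_equal(magnitude_of_change(fake(x)), magnitude_of_change(fake(-x)))
  expect_error(magnitude_of_change(fake(numeric(0))), "empty")
})

test_that("correlation test matches the t formula and known cases", {
  x <- 1:20
  ct <- correlation_test(x, 2 * x)
  expect_equal(ct$r, 1)
  expect_lt(ct$p, 1e-12)
  expect_equal(unname(ct$line["slope"]), 2)

  # reported significances at n = 31: r = 0.56 -> p < 0.01,
  # r = -0.39 -> p ~ 0.03
  r_to_p <- function(r, n) {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * pt(-abs(t), n - 2)
  }
  expect_lt(r_to_p(0.56, 31), 0.01)
  expect_equal(r_to_p(-0.39, 31), 0.03, tolerance = 0.005 / 0.03)

  # symmetry in the arguments
  set.seed(11)
  a <- rnorm(31); b <- 0.5 * a + rnorm(31)
  expect_equal(correlation_test(a, b)$r, correlation_test(b, a)$r)
  expect_equal(correlation_test(a, b)$p, correlation_test(b, a)$p)
  expect_error(correlation_test(a, rep(1, 31)), "zero variance")
})

test_that("correlation test agrees with stats::cor.test", {
  set.seed(12)
  x <- rnorm(31); y <- 0.4 * x + rnorm(31)
  ours <- correlation_test(x, y)
  ref <- cor.test(x, y)
  expect_equal(ours$r, unname(ref$estimate))
  expect_equal(ours$p, ref$p.value)
  expect_equal(ours$t, unname(ref$statistic))
})

test_that("a planted characteristic-vulnerability correlation of 0.9 is
           detected in at least 95% of replicates at n = 31", {
  hits <- 0
  for (r in 1:100) {
    sc <- generate_scenario(31, 45, seed = 5000 + r)
    ch <- generate_characteristics(sc, planted_r = 0.9, seed = 6000 + r)
    ct <- correlation_test(ch$access_clean_water, true_vulnerability(sc))
    hits <- hits + (ct$significant && ct$r > 0)
  }
  expect_gte(hits, 95)
})

test_that("vulnerability_correlations tests every characteristic within
           driver", {
  set.seed(13)
  mags <- expand.grid(lake_id = sprintf("L%02d", 1:10),
                      driver = c("AT", "PRE"), stringsAsFactors = FALSE)
  mags$magnitude <- runif(20, 0.5, 3)
  chars <- data.frame(lake_id = sprintf("L%02d", 1:10),
                      access_clean_water = runif(10),
                      shoreline_pop_density = rlnorm(10, 4),
                      avg_depth = rlnorm(10, 2), SDI = runif(10, 1, 5))
  ct <- vulnerability_correlations(mags, chars)
  expect_equal(nrow(ct), 8)  # 2 drivers x 4 characteristics
  expect_true(all(ct$n == 10))
  expect_true(all(abs(ct$r) <= 1))
})
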