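make_wt_panel <- function(AT, WT, id = "A") {
  df <- data.frame(lake_id = id, year = seq_along(AT), AT = AT, WT = WT)
  lake_panel(df)
}

test_that("least squares recovers an exact line with zero residuals", {
  AT <- c(3, 7, 11, 2, 9, 5)
  p <- make_wt_panel(AT, 2 + 3 * AT)
  fit <- least_squares_fit(p, "WT")
  expect_equal(unname(fit$coef), c(2, 3))
  expect_equal(fit$sigma2, 0)
  expect_equal(fit$n_used, 6)
})

test_that("constant predictor raises a named rank-deficiency error", {
  p <- make_wt_panel(rep(4, 8), rnorm(8))
  expect_error(least_squares_fit(p, "WT"), "collinear.*AT")
})

test_that("too few usable years is an explicit error", {
  p <- make_wt_panel(c(1, 2), c(1, 2))
  expect_error(least_squares_fit(p, "WT"), "usable years")
})

test_that("unscaled covariance matches the hand-computed normal equations", {
  # X = [1 1; 1 2; 1 3]: X'X = [3 6; 6 14], det = 6,
  # (X'X)^-1 = [14 -6; -6 3] / 6
  p <- make_wt_panel(c(1, 2, 3), c(1, 4, 9))
  fit <- least_squares_fit(p, "WT")
  expect_equal(fit$cov_unscaled,
               matrix(c(14, -6, -6, 3) / 6, 2, 2,
                      dimnames = list(c("Intercept", "AT"),
                                      c("Intercept", "AT"))))
})

test_that("LS fit ignores row order and rows with missing response", {
  sc <- generate_scenario(1, 30, seed = 21)
  panel <- forward_simulate(sc, seed = 22)
  f1 <- least_squares_fit(panel, "CHL")
  shuffled <- lake_panel(as.data.frame(panel)[sample(nrow(panel)), ])
  f2 <- least_squares_fit(shuffled, "CHL")
  expect_equal(f1$coef, f2$coef)
  # adding rows with missing CHL changes nothing
  extra <- as.data.frame(panel)[1:5, ]
  extra$year <- 3001:3005
  extra$CHL <- NA
  f3 <- least_squares_fit(lake_panel(rbind(as.data.frame(panel), extra)),
                          "CHL")
  expect_equal(f1$coef, f3$coef)
})

test_that("prior covariance scales proportionally with g and identical
           data give identical priors", {
  sc <- generate_scenario(2, 25, seed = 23)
  panel <- forward_simulate(sc, seed = 24)
  pri <- build_priors(panel, stocking = scenario_stocking(sc))
  v1 <- prior_covariance(pri, "WT", "L01", g = 1)
  expect_equal(v1, pri$submodels$WT$L01$cov_unscaled)
  expect_equal(prior_covariance(pri, "WT", "L01", g = 4), 4 * v1)
  expect_error(prior_covariance(pri, "WT", "L01", g = 0), "positive")
  # duplicate lake: same data -> same prior
  dup <- as.data.frame(panel[panel$lake_id == "L01", ])
  dup$lake_id <- "L99"
  pri2 <- build_priors(lake_panel(rbind(as.data.frame(panel), dup)),
                       stocking = c(scenario_stocking(sc), L99 = FALSE))
  expect_equal(pri2$submodels$WT$L99$mean, pri2$submodels$WT$L01$mean)
  expect_equal(pri2$submodels$WT$L99$cov_unscaled,
               pri2$submodels$WT$L01$cov_unscaled)
})

test_that("prior covariance is symmetric positive definite across
           submodels", {
  sc <- generate_scenario(3, 45, seed = 25)
  panel <- forward_simulate(sc, seed = 26)
  pri <- build_priors(panel, stocking = scenario_stocking(sc))
  for (sm in c("WT", "dWL", "CHL", "CATCH"))
    for (lk in pri$lakes) {
      V <- pri$submodels[[sm]][[lk]]$cov_unscaled
      expect_equal(V, t(V))
      expect_true(all(eigen(V, symmetric = TRUE)$values > 0))
      expect_gte(pri$submodels[[sm]][[lk]]$n_used,
                 length(pri$submodels[[sm]][[lk]]$mean) + 1)
    }
})
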