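# degenerate point-mass "posterior": only the AT -> WT -> CATCH channel
point_mass_draws <- function(w1 = 0.8, k1 = -0.5, n = 500) {
  list(WT = matrix(rep(c(10, w1), each = n), n, 2,
                   dimnames = list(NULL, c("Intercept", "AT"))),
       dWL = matrix(rep(c(0, 0, 0, 0), each = n), n, 4,
                    dimnames = list(NULL, c("Intercept", "PRE", "PE",
                                            "PE.LUag"))),
       CHL = matrix(rep(c(2, 0, 0, 0, 0), each = n), n, 5,
                    dimnames = list(NULL, c("Intercept", "logPRE",
                                            "logLUag", "muDWL", "muWT"))),
       CATCH = matrix(rep(c(4, k1, 0, 0, 0), each = n), n, 5,
                      dimnames = list(NULL, c("Intercept", "muWT", "muDWL",
                                              "muCHL", "logEFF"))),
       stocking = FALSE)
}

flat_panel <- function(n = 45, at_sd = 2) {
  set.seed(99)
  lake_panel(data.frame(
    lake_id = "L01", year = seq_len(n) + 1969,
    AT = rnorm(n, 15, at_sd), PRE = exp(rnorm(n, 0, 0.15)),
    PE = 1 + 0.02 * rnorm(n, 15, at_sd), LUag = rnorm(n, 40, 3),
    WT = rnorm(n, 20, 1), WL = cumsum(rnorm(n, 0, 0.1)) + 100,
    CHL = exp(rnorm(n, 2, 0.3)), CATCH = exp(rnorm(n, 4, 0.3)),
    ST = exp(rnorm(n, 4, 0.3)), EFF = exp(rnorm(n, 0, 0.2))))
}

test_that("importance cutoffs reproduce the equal-share arithmetic", {
  expect_equal(importance_cutoff(3), (1 - 0.75^(1 / 3)) * 100)
  expect_equal(sprintf("%.1f", importance_cutoff(3)), "9.1")
  expect_equal(sprintf("%.1f", importance_cutoff(2)), "13.4")
  expect_equal(importance_cutoff(1), 25)
  # (1 - c_k/100)^k = 0.75 exactly
  for (k in 1:6)
    expect_equal((1 - importance_cutoff(k) / 100)^k, 0.75)
  expect_error(importance_cutoff(0), "positive integer")
})

test_that("acceptance window is closed at both ends", {
  expect_true(accept_sample(log(0.75), 0))
  expect_true(accept_sample(log(0.76), 0))
  expect_true(accept_sample(log(0.74), 0))
  expect_false(accept_sample(log(0.739), 0))
  expect_false(accept_sample(log(0.761), 0))
})

test_that("change metrics follow the per-variable reporting conventions", {
  expect_equal(change_metric("AT", 15.2, 14.1), 1.1)
  expect_equal(change_metric("LUag", 42, 38), 4)
  expect_equal(change_metric("PRE", 1.1, 1.0), 10)
  expect_equal(change_metric("CHL", 0.0953, 0), (exp(0.0953) - 1) * 100,
               tolerance = 1e-12)
  expect_equal(change_metric("CHL", 0.0953, 0), 10, tolerance = 1e-3)
  expect_error(change_metric("PRE", 1, 0), "zero baseline")
  expect_error(change_metric("XX", 1, 1), "unknown variable")
})

test_that("mediator effects evaluate the exponential formula", {
  expect_equal(mediator_catch_effect(0, 3, 1), 0)
  expect_equal(mediator_catch_effect(-0.3, 2, 2), 0)
  expect_equal(mediator_catch_effect(-0.1, 3, 1), (exp(-0.2) - 1) * 100)
  expect_equal(mediator_catch_effect(-0.1, 3, 1), -18.13, tolerance = 1e-3)
})

test_that("degenerate posterior concentrates at the analytic root", {
  w1 <- 0.8; k1 <- -0.5
  pan <- flat_panel()
  a <- run_driver_assessment(point_mass_draws(w1, k1), pan, "L01", "AT",
                             n_accepted = 300, seed = 1, batch = 20000)
  # exp(k1 * w1 * dAT) = ratio -> dAT = log(ratio) / (k1 w1)
  root <- log(0.75) / (k1 * w1)
  expect_lt(abs(median(a$samples$delta_driver) - root), 0.05)
  expect_true(all(abs(a$samples$delta_driver -
                        log(a$samples$ratio) / (k1 * w1)) < 1e-10))
})

test_that("all accepted ratios lie inside the window; reruns are
           identical", {
  pan <- flat_panel()
  a1 <- run_driver_assessment(point_mass_draws(), pan, "L01", "AT",
                              n_accepted = 10, seed = 5, batch = 5000)
  expect_equal(nrow(a1$samples), 10)
  expect_true(all(a1$samples$ratio >= 0.74 & a1$samples$ratio <= 0.76))
  a2 <- run_driver_assessment(point_mass_draws(), pan, "L01", "AT",
                              n_accepted = 10, seed = 5, batch = 5000)
  expect_identical(a1$samples, a2$samples)
})

test_that("PRE and LUag assessments hold AT (and PE) at medians", {
  fit <- small_fit()
  a <- run_driver_assessment(fit$draws, fit$panel, "L01", "PRE",
                             n_accepted = 200, seed = 6)
  expect_equal(a$k, 2)
  expect_true(all(is.na(a$samples$delta_WT)))
  s <- summary(a)
  expect_true(is.na(s$mediator_important[["WT"]]))
  expect_type(s$association, "character")
})

test_that("mediator effects multiply to the catch ratio exactly", {
  fit <- small_fit()
  for (dr in c("AT", "PRE")) {
    a <- run_driver_assessment(fit$draws, fit$panel, "L01", dr,
                               n_accepted = 300, seed = 7)
    s <- a$samples
    prod_f <- (1 + s$effect_WL / 100) * (1 + s$effect_CHL / 100)
    if (dr == "AT") prod_f <- prod_f * (1 + s$effect_WT / 100)
    expect_equal(prod_f, s$ratio, tolerance = 1e-10)
  }
})

test_that("association classification mirrors the labeling convention
           and is antisymmetric", {
  expect_equal(classify_association(rep(-1, 50)), "positive")
  expect_equal(classify_association(rep(1, 50)), "negative")
  expect_equal(classify_association(c(rep(-1, 30), rep(1, 70))), "mixed")
  set.seed(8)
  for (mu in c(-1, 0, 1)) {
    x <- rnorm(2000, mu)
    a <- classify_association(x)
    b <- classify_association(-x)
    expect_equal(b, switch(a, positive = "negative",
                           negative = "positive", mixed = "mixed"))
  }
  expect_error(classify_association(numeric(0)), "no accepted")
})

test_that("importance flag uses the 0.75 quantile against the cutoff", {
  expect_true(flag_importance(rep(-20, 100), 3))
  expect_false(flag_importance(rep(-5, 100), 3))
  # boundary: Normal(-13.4, 0.01) has q75 ~ -13.393, above -13.4035
  set.seed(9)
  expect_false(flag_importance(rnorm(20000, -13.4, 0.01), 2))
  expect_true(flag_importance(rnorm(20000, -13.5, 0.01), 2))
  expect_error(flag_importance(numeric(0), 2), "no effects")
})

test_that("proposals with nonpositive PRE/LUag are resampled", {
  set.seed(10)
  x <- propose_driver(5000, "PRE", 0.3, 0.5)
  expect_true(all(x > 0))
  y <- propose_driver(5000, "AT", 0, 1)  # AT may be negative
  expect_true(any(y < 0))
})
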