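test_that("same seed reproduces draws exactly", {
  sc <- generate_scenario(2, 30, seed = 61)
  panel <- forward_simulate(sc, seed = 62)
  pri <- build_priors(panel, stocking = scenario_stocking(sc))
  cfg <- bnm_config(chains = 2, burnin = 50, retained = 100, seed = 63)
  d1 <- run_mcmc(panel, pri, cfg)
  d2 <- run_mcmc(panel, pri, cfg)
  expect_identical(d1$draws, d2$draws)
})

test_that("single-lake WT-only posterior matches the conjugate closed
           form with fixed sigma and g", {
  sc <- generate_scenario(1, 45, seed = 64)
  panel <- forward_simulate(sc, seed = 65)
  pri <- build_priors(panel)
  sig <- 0.08; gfix <- 0.002
  dr <- run_mcmc(panel, pri,
                 bnm_config(chains = 2, burnin = 200, retained = 2500,
                            seed = 66, submodels = "WT",
                            fix_sigma = c(WT = sig), fix_g = c(WT = gfix)))
  m <- as_draw_matrix(dr)[, 1:2]
  d <- lakebnm:::.design_prior(panel, "WT")
  XtX <- crossprod(d$X)
  P <- XtX / gfix + XtX / sig^2
  mu <- solve(P, XtX %*% pri$submodels$WT$L01$mean / gfix +
                crossprod(d$X, d$y) / sig^2)
  V <- solve(P)
  for (i in 1:2) {
    se <- sd(m[, i]) / sqrt(200)   # conservative effective sample size
    expect_lt(abs(mean(m[, i]) - mu[i]), 3 * se)
    expect_lt(abs(sd(m[, i]) - sqrt(V[i, i])) / sqrt(V[i, i]), 0.1)
  }
})

test_that("a huge prior scale recovers the pure-likelihood (LS)
           solution", {
  sc <- generate_scenario(1, 45, seed = 67)
  panel <- forward_simulate(sc, seed = 68)
  pri <- build_priors(panel)
  dr <- run_mcmc(panel, pri,
                 bnm_config(chains = 2, burnin = 200, retained = 1500,
                            seed = 69, submodels = "WT",
                            fix_sigma = c(WT = 0.1), fix_g = c(WT = 1e6)))
  m <- as_draw_matrix(dr)
  ls <- least_squares_fit(panel, "WT")
  for (i in 1:2)
    expect_lt(abs(mean(m[, i]) - ls$coef[i]), 2 * sd(m[, i]))
})

test_that("posterior sd contracts as the panel grows", {
  # same lakes and coefficients; fit the full 80-year panel vs its first
  # 20 years
  sc <- generate_scenario(2, 80, seed = 70)
  full <- forward_simulate(sc, seed = 71)
  mean_sd <- function(panel) {
    pri <- build_priors(panel, stocking = scenario_stocking(sc))
    dr <- run_mcmc(panel, pri,
                   bnm_config(chains = 2, burnin = 200, retained = 600,
                              seed = 72))
    ps <- posterior_summary(dr)
    # compare on the WT slope, same scale across runs
    mean(ps$sd[ps$type == "beta" & ps$submodel == "WT" & ps$term == "AT"])
  }
  short <- lake_panel(as.data.frame(full)[full$year < min(full$year) + 20, ])
  expect_lt(mean_sd(full), mean_sd(short))
})

test_that("submodel subsets are validated", {
  expect_error(bnm_config(submodels = "CHL"), "requires WT")
  expect_error(bnm_config(submodels = c("WT", "CATCH")), "requires")
  expect_silent(bnm_config(submodels = c("WT", "dWL")))
})
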