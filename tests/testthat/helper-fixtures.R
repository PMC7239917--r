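# Shared fixtures: one small fitted model, built lazily and cached for the
# whole test run so several test files can reuse it.

.fixture_env <- new.env(parent = emptyenv())

small_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  sc <- generate_scenario(3, 45, seed = 42)
  panel <- forward_simulate(sc, seed = 43)
  priors <- build_priors(panel, stocking = scenario_stocking(sc))
  draws <- run_mcmc(panel, priors,
                    bnm_config(chains = 2, burnin = 300, retained = 1200,
                               seed = 44))
  .fixture_env$fit <- list(scenario = sc, panel = panel, priors = priors,
                           draws = draws)
  .fixture_env$fit
}

# coefficient list of lake `id` from a scenario, for predicted_means etc.
scenario_coef <- function(scenario, id) scenario$lakes[[id]]$coef
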