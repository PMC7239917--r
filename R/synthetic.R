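#' Generate a ground-truth multi-lake scenario
#'
#' Draws, per lake, the driver-generating parameters (annual air temperature,
#' precipitation, agricultural land use, a deterministic linear PE--AT map
#' with positive slope, stocking and effort levels), the true coefficients of
#' the four conditional submodels (water temperature, water-level change,
#' chlorophyll-a, catch) and the shared noise scales, then generates the
#' driver series themselves. Defaults emulate a 31-lake, 45-year (1970--2014)
#' study: drivers are independent across years, the AT -> WT slope is
#' positive in every lake while the remaining links carry mixed signs across
#' lakes, and a configurable fraction of lakes is stocking-eligible (the
#' catch submodel then carries a log-stocking term).
#'
#' Submodel intercepts are set so that simulated levels are realistic
#' (water temperature tracking air temperature, chlorophyll-a around 8 ug/l,
#' catches around 50 kg/ha, stationary water levels). Noise scales default to
#' `sigma_frac` (10%) of the pooled *within-lake* standard deviation of each
#' submodel's linear predictor (between-lake level differences are excluded:
#' the model is fitted per lake, so they carry no information about the
#' noise a lake's submodel must overcome) — moderate noise under which
#' coefficients are recoverable.
#'
#' @param n_lakes number of lakes (>= 1).
#' @param n_years panel length in years (>= 10); years start at 1970.
#' @param seed integer seed; the scenario is reproducible given the seed.
#' @param sign_plan `"table"` (default: AT->WT always positive, other links
#'   mixed), `"all_positive_WT"` (synonym for the WT rule with otherwise
#'   mixed signs) or `"mixed"` (every slope sign random).
#' @param sigma_frac noise scale as a fraction of each linear predictor's
#'   pooled sd; 0 gives a noiseless scenario.
#' @param prop_eligible proportion of stocking-eligible lakes (default 8/31).
#' @param ar1_rho optional AR(1) correlation for driver series (default 0:
#'   independent years, the model's own assumption).
#' @return a `bnm_scenario`: true coefficients and noise scales per lake,
#'   driver-generating parameters, eligibility flags, and the generated
#'   driver series in `$drivers_data`.
#' @export
generate_scenario <- function(n_lakes, n_years, seed,
                              sign_plan = c("table", "all_positive_WT",
                                            "mixed"),
                              sigma_frac = 0.1,
                              prop_eligible = 8 / 31,
                              ar1_rho = 0) {
  sign_plan <- match.arg(sign_plan)
  if (n_lakes < 1) stop("n_lakes must be >= 1")
  if (n_years < 10) stop("n_years must be >= 10")
  set.seed(as.integer(seed))
  years <- seq(1970L, length.out = n_years)
  ids <- sprintf("L%02d", seq_len(n_lakes))
  n_elig <- round(prop_eligible * n_lakes)
  eligible <- ids %in% sample(ids, n_elig)

  # sign of a slope: P(positive) per link, echoing the mixed directions the
  # four-level model typically shows across lakes
  p_pos <- c(PRE = 0.93, PE = 0.25, PE.LUag = 0.5,
             logPRE = 0.55, logLUag = 0.65, muDWL.CHL = 0.55, muWT.CHL = 0.3,
             muWT = 0.5, muDWL = 0.6, muCHL = 0.55, logST = 0.7,
             logEFF = 0.97)
  if (sign_plan == "mixed") p_pos[] <- 0.5
  draw_sign <- function(link) if (runif(1) < p_pos[[link]]) 1 else -1

  ar1 <- function(n, mean, sd) {
    if (ar1_rho == 0) return(rnorm(n, mean, sd))
    e <- rnorm(n, 0, sd * sqrt(1 - ar1_rho^2))
    x <- numeric(n)
    x[1] <- rnorm(1, 0, sd)
    for (t in 2:n) x[t] <- ar1_rho * x[t - 1] + e[t]
    mean + x
  }

  lakes <- list()
  drivers_data <- NULL
  mus <- list(WT = NULL, dWL = NULL, CHL = NULL, CATCH = NULL)
  for (j in seq_len(n_lakes)) {
    dr <- list(
      AT_mean = runif(1, 4, 22),  AT_sd = runif(1, 0.5, 1.0),
      PRE_meanlog = log(runif(1, 0.5, 1.6)), PRE_sdlog = runif(1, 0.1, 0.25),
      LUag_mean = runif(1, 10, 60), LUag_sd = runif(1, 2, 6),
      PE_b = runif(1, 0.015, 0.045),
      ST_meanlog = log(runif(1, 20, 200)), ST_sdlog = 0.3,
      EFF_meanlog = 0, EFF_sdlog = 0.2,
      WL0 = runif(1, 50, 300))
    dr$PE_a <- runif(1, 0.6, 1.3) - dr$PE_b * dr$AT_mean

    AT <- ar1(n_years, dr$AT_mean, dr$AT_sd)
    PRE <- exp(ar1(n_years, dr$PRE_meanlog, dr$PRE_sdlog))
    LUag <- pmin(pmax(ar1(n_years, dr$LUag_mean, dr$LUag_sd), 0.5), 99.5)
    PE <- dr$PE_a + dr$PE_b * AT
    ST <- rlnorm(n_years, dr$ST_meanlog, dr$ST_sdlog)
    EFF <- rlnorm(n_years, dr$EFF_meanlog, dr$EFF_sdlog)

    b_WT <- c(Intercept = 0,
              AT = (if (sign_plan == "mixed") draw_sign("muWT") else 1) *
                runif(1, 0.5, 1.1))
    b_WT["Intercept"] <- (0.75 * dr$AT_mean + 5) - mean(b_WT["AT"] * AT)
    mu_WT <- b_WT["Intercept"] + b_WT["AT"] * AT

    b_dWL <- c(Intercept = 0,
               PRE = draw_sign("PRE") * runif(1, 0.5, 2.0),
               PE = draw_sign("PE") * runif(1, 0.5, 2.0),
               PE.LUag = draw_sign("PE.LUag") * runif(1, 0.005, 0.02))
    lp <- b_dWL["PRE"] * PRE + b_dWL["PE"] * PE +
      b_dWL["PE.LUag"] * PE * LUag
    b_dWL["Intercept"] <- -mean(lp)
    mu_dWL <- b_dWL["Intercept"] + lp

    b_CHL <- c(Intercept = 0,
               logPRE = draw_sign("logPRE") * runif(1, 0.3, 1.0),
               logLUag = draw_sign("logLUag") * runif(1, 0.3, 1.0),
               muDWL = draw_sign("muDWL.CHL") * runif(1, 0.2, 0.8),
               muWT = draw_sign("muWT.CHL") * runif(1, 0.05, 0.2))
    lp <- b_CHL["logPRE"] * log(PRE) + b_CHL["logLUag"] * log(LUag) +
      b_CHL["muDWL"] * mu_dWL + b_CHL["muWT"] * mu_WT
    b_CHL["Intercept"] <- log(8) - mean(lp)
    mu_CHL <- b_CHL["Intercept"] + lp

    b_CATCH <- c(Intercept = 0,
                 muWT = draw_sign("muWT") * runif(1, 0.05, 0.2),
                 muDWL = draw_sign("muDWL") * runif(1, 0.2, 0.8),
                 muCHL = draw_sign("muCHL") * runif(1, 0.2, 0.6),
                 logST = draw_sign("logST") * runif(1, 0.1, 0.4),
                 logEFF = draw_sign("logEFF") * runif(1, 0.5, 1.0))
    if (!eligible[j]) b_CATCH <- b_CATCH[names(b_CATCH) != "logST"]
    lp <- b_CATCH["muWT"] * mu_WT + b_CATCH["muDWL"] * mu_dWL +
      b_CATCH["muCHL"] * mu_CHL + b_CATCH["logEFF"] * log(EFF)
    if (eligible[j]) lp <- lp + b_CATCH["logST"] * log(ST)
    b_CATCH["Intercept"] <- log(50) - mean(lp)
    mu_CATCH <- b_CATCH["Intercept"] + lp

    # center per lake: sigma is set relative to *within-lake* signal, which
    # is what each lake's submodel actually has to resolve
    mus$WT <- c(mus$WT, mu_WT - mean(mu_WT))
    mus$dWL <- c(mus$dWL, mu_dWL - mean(mu_dWL))
    mus$CHL <- c(mus$CHL, mu_CHL - mean(mu_CHL))
    mus$CATCH <- c(mus$CATCH, mu_CATCH - mean(mu_CATCH))

    lakes[[ids[j]]] <- list(
      lake_id = ids[j], stocking = eligible[j], drivers = dr,
      coef = list(WT = b_WT, dWL = b_dWL, CHL = b_CHL, CATCH = b_CATCH))
    drivers_data <- rbind(drivers_data, data.frame(
      lake_id = ids[j], year = years, AT = AT, PRE = PRE, PE = PE,
      LUag = LUag, ST = ST, EFF = EFF, stringsAsFactors = FALSE))
  }

  sigma <- vapply(mus, function(m) sigma_frac * sd(m), numeric(1))
  sigma[!is.finite(sigma) | sigma < 0] <- 0
  for (id in ids) lakes[[id]]$sigma <- sigma

  structure(list(n_lakes = n_lakes, n_years = n_years, years = years,
                 seed = as.integer(seed), sign_plan = sign_plan,
                 sigma_frac = sigma_frac, sigma = sigma, lakes = lakes,
                 drivers_data = drivers_data),
            class = "bnm_scenario")
}

#' @export
print.bnm_scenario <- function(x, ...) {
  cat(sprintf("bnm_scenario: %d lakes x %d years (seed %d), sigma = %s\n",
              x$n_lakes, x$n_years, x$seed,
              paste(sprintf("%s %.3g", names(x$sigma), x$sigma),
                    collapse = ", ")))
  invisible(x)
}

#' True coefficients of a scenario
#'
#' @param scenario a `bnm_scenario`.
#' @return data frame `lake_id, submodel, term, value` of ground-truth
#'   coefficients (for recovery checks).
#' @export
truth_coefficients <- function(scenario) {
  out <- NULL
  for (lk in scenario$lakes)
    for (sm in .bnm_submodels)
      out <- rbind(out, data.frame(
        lake_id = lk$lake_id, submodel = sm, term = names(lk$coef[[sm]]),
        value = unname(lk$coef[[sm]]), stringsAsFactors = FALSE))
  out
}

#' Simulate panels forward from a scenario
#'
#' Reads the model generatively: `WT ~ N(mu_WT, sigma_WT)` with
#' `mu_WT = b0 + b1 AT`; `dWL ~ N(mu_dWL, sigma_dWL)` with precipitation,
#' potential-evaporation and PE x LUag terms; `log CHL ~ N(mu_CHL,
#' sigma_CHL)` using log-precipitation, log-land-use and the *predicted
#' means* of dWL and WT; `log CATCH ~ N(mu_CATCH, sigma_CATCH)` using the
#' predicted means of WT, dWL and CHL plus log-stocking (eligible lakes
#' only) and log-effort. Water level is integrated from the drawn changes
#' starting at the lake's initial level, so the derived first difference of
#' the written WL series reproduces the drawn changes.
#'
#' @param scenario a `bnm_scenario`.
#' @param seed integer seed for the observation noise.
#' @return a [lake_panel()] covering all lakes.
#' @export
forward_simulate <- function(scenario, seed) {
  stopifnot(inherits(scenario, "bnm_scenario"))
  set.seed(as.integer(seed))
  sg <- scenario$sigma
  out <- NULL
  for (lk in scenario$lakes) {
    d <- scenario$drivers_data[scenario$drivers_data$lake_id == lk$lake_id, ]
    n <- nrow(d)
    mu_WT <- lk$coef$WT["Intercept"] + lk$coef$WT["AT"] * d$AT
    WT <- rnorm(n, mu_WT, sg["WT"])
    b <- lk$coef$dWL
    mu_dWL <- b["Intercept"] + b["PRE"] * d$PRE + b["PE"] * d$PE +
      b["PE.LUag"] * d$PE * d$LUag
    dWL <- rnorm(n, mu_dWL, sg["dWL"])
    WL <- lk$drivers$WL0 + c(0, cumsum(dWL[-1]))
    b <- lk$coef$CHL
    mu_CHL <- b["Intercept"] + b["logPRE"] * log(d$PRE) +
      b["logLUag"] * log(d$LUag) + b["muDWL"] * mu_dWL + b["muWT"] * mu_WT
    CHL <- exp(rnorm(n, mu_CHL, sg["CHL"]))
    b <- lk$coef$CATCH
    mu_CATCH <- b["Intercept"] + b["muWT"] * mu_WT + b["muDWL"] * mu_dWL +
      b["muCHL"] * mu_CHL + b["logEFF"] * log(d$EFF)
    if (lk$stocking) mu_CATCH <- mu_CATCH + b["logST"] * log(d$ST)
    CATCH <- exp(rnorm(n, mu_CATCH, sg["CATCH"]))
    out <- rbind(out, data.frame(
      lake_id = lk$lake_id, year = d$year, AT = d$AT, PRE = d$PRE,
      PE = d$PE, LUag = d$LUag, WT = WT, WL = WL, CHL = CHL, CATCH = CATCH,
      ST = d$ST, EFF = d$EFF, stringsAsFactors = FALSE))
  }
  lake_panel(out)
}

#' Knock out observations while keeping the 9-year floor
#'
#' Removes a per-variable fraction of each lake's observations (random or
#' contiguous gaps). Raises an error if the request would leave fewer than
#' `min_years` observed years for any variable in any lake, the floor the
#' prior-construction stage requires.
#'
#' @param panel a [lake_panel()].
#' @param fractions single number or named vector (per model variable) of
#'   missing fractions in \[0, 1).
#' @param seed integer seed (gap pattern is reproducible).
#' @param pattern `"random"` scattered gaps or `"contiguous"` one block.
#' @param min_years observed-year floor (default 9).
#' @return the panel with `NA` gaps; passes [validate_panel()].
#' @export
apply_missingness <- function(panel, fractions, seed, pattern = c("random",
                              "contiguous"), min_years = 9) {
  pattern <- match.arg(pattern)
  panel <- lake_panel(panel)
  set.seed(as.integer(seed))
  if (is.null(names(fractions)))
    fractions <- setNames(rep(fractions[1], length(.bnm_variables)),
                          .bnm_variables)
  for (id in unique(panel$lake_id)) {
    rows <- which(panel$lake_id == id)
    n <- length(rows)
    for (v in intersect(names(fractions), .bnm_variables)) {
      n_miss <- round(fractions[[v]] * n)
      if (n_miss == 0) next
      if (n - n_miss < min_years)
        stop(sprintf(
          "missing fraction %.2f for %s leaves %d < %d observed years (lake %s)",
          fractions[[v]], v, n - n_miss, min_years, id))
      drop <- if (pattern == "random") sample(n, n_miss)
              else seq_len(n_miss) + sample(n - n_miss + 1, 1) - 1
      panel[rows[drop], v] <- NA_real_
    }
  }
  panel
}

# dlogCATCH/dAT at median inputs under the true coefficients, chained
# through WT, dWL (via the PE--AT map) and CHL
.at_sensitivity <- function(scenario) {
  vapply(scenario$lakes, function(lk) {
    d <- scenario$drivers_data[scenario$drivers_data$lake_id == lk$lake_id, ]
    lu_med <- median(d$LUag)
    dWT <- unname(lk$coef$WT["AT"])
    dDW <- unname((lk$coef$dWL["PE"] + lk$coef$dWL["PE.LUag"] * lu_med) *
                    lk$drivers$PE_b)
    dCHL <- unname(lk$coef$CHL["muDWL"] * dDW + lk$coef$CHL["muWT"] * dWT)
    unname(lk$coef$CATCH["muWT"] * dWT + lk$coef$CATCH["muDWL"] * dDW +
             lk$coef$CATCH["muCHL"] * dCHL)
  }, numeric(1))
}

#' Ground-truth air-temperature vulnerability magnitude
#'
#' The AT change that produces a 25% catch decrease under the true
#' coefficients: `|log 0.75| / |dlogCATCH/dAT|` at median inputs. Smaller
#' magnitude = more vulnerable lake. Used to validate the correlation stage
#' without MCMC.
#'
#' @param scenario a `bnm_scenario`.
#' @return named numeric vector (degC per lake).
#' @export
true_vulnerability <- function(scenario) {
  abs(log(0.75)) / abs(.at_sensitivity(scenario))
}

#' Generate lake characteristics with a plantable correlation
#'
#' Draws socio-economic and hydrogeomorphological lake characteristics.
#' `access_clean_water` is constructed so that its expected Pearson
#' correlation with the lakes' true AT vulnerability magnitude (see
#' [true_vulnerability()]) equals `planted_r`; shoreline length and lake
#' area are drawn so the shoreline development index spans roughly 1--8.
#' Vulnerability magnitudes are winsorized at three times their 90th
#' percentile before planting, so a near-zero-sensitivity lake cannot
#' dominate the correlation.
#'
#' @param scenario a `bnm_scenario`.
#' @param planted_r target correlation in \[-1, 1\] (default 0).
#' @param seed integer seed.
#' @return data frame: `lake_id`, `access_clean_water`,
#'   `shoreline_pop_density`, `avg_depth`, `shoreline_length_km`,
#'   `lake_area_km2`, `SDI`.
#' @export
generate_characteristics <- function(scenario, planted_r = 0, seed) {
  if (abs(planted_r) > 1) stop("planted_r must be in [-1, 1]")
  set.seed(as.integer(seed))
  n <- scenario$n_lakes
  v <- true_vulnerability(scenario)
  v <- pmin(v, 3 * quantile(v, 0.9))
  z <- if (sd(v) > 0) as.numeric(scale(v)) else rnorm(n)
  lat <- planted_r * z + sqrt(1 - planted_r^2) * rnorm(n)
  access <- if (diff(range(lat)) > 0)
    0.05 + 0.9 * (lat - min(lat)) / diff(range(lat)) else rep(0.5, n)
  area <- rlnorm(n, log(50), 1.2)
  sdi_target <- runif(n, 1.05, 8)
  data.frame(
    lake_id = names(scenario$lakes),
    access_clean_water = access,
    shoreline_pop_density = rlnorm(n, log(100), 1),
    avg_depth = rlnorm(n, log(10), 0.7),
    shoreline_length_km = sdi_target * 2 * sqrt(pi * area),
    lake_area_km2 = area,
    SDI = sdi_target,
    stringsAsFactors = FALSE)
}
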