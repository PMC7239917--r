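## Monte-Carlo acceptance sampling of scenarios associated with a 25% catch
## decrease, mediator effect propagation, change metrics and importance
## cutoffs.

#' Importance cutoff for k mediators sharing a 25% decrease
#'
#' `(1 - 0.75^(1/k)) x 100`: the per-mediator percent decrease if `k`
#' mediators contribute equally to a 25% total catch decrease. k = 3 gives
#' 9.1% (air-temperature assessments: water temperature, water level and
#' chlorophyll-a all mediate), k = 2 gives 13.4% (precipitation and
#' land-use assessments, where water temperature is not a mediator),
#' k = 1 gives 25%.
#'
#' @param k integer number of mediators (>= 1).
#' @return cutoff in percent.
#' @export
importance_cutoff <- function(k) {
  if (any(k < 1) || any(k != round(k))) stop("k must be a positive integer")
  (1 - 0.75^(1 / k)) * 100
}

#' Acceptance rule for the 25% catch decrease window
#'
#' A proposed scenario is kept when the ratio of predicted catch to the
#' predicted baseline catch, `exp(mu_CATCH - mu0_CATCH)`, falls in the
#' closed window (default \[0.74, 0.76\]).
#'
#' @param mu_catch predicted log-catch under the perturbed driver.
#' @param mu0_catch predicted log-catch at median inputs (same coefficient
#'   draw).
#' @param window closed acceptance interval for the catch ratio.
#' @return logical (vectorized).
#' @export
accept_sample <- function(mu_catch, mu0_catch, window = c(0.74, 0.76)) {
  ratio <- exp(mu_catch - mu0_catch)
  ratio >= window[1] & ratio <= window[2]
}

#' Change in a variable's reporting convention
#'
#' Actual difference from the baseline median for `AT`, `WT` and `WL`
#' (and `dWL`); percent difference for `PRE`; percentage-point difference
#' (of catchment area) for `LUag`. For `CHL` the inputs are log-scale
#' predicted means and the metric is the percent difference
#' `(exp(mu - mu0) - 1) x 100`.
#'
#' @param variable one of `"AT"`, `"WT"`, `"WL"`, `"dWL"`, `"PRE"`,
#'   `"LUag"`, `"CHL"`.
#' @param value sampled or predicted value (log-scale for `CHL`).
#' @param baseline the 1970--2014 median (log-scale predicted mean for
#'   `CHL`).
#' @return the change in the variable's metric (vectorized).
#' @export
change_metric <- function(variable, value, baseline) {
  switch(variable,
    AT = , WT = , WL = , dWL = , LUag = value - baseline,
    PRE = {
      if (any(baseline == 0)) stop("zero baseline for a percent metric")
      (value / baseline - 1) * 100
    },
    CHL = (exp(value - baseline) - 1) * 100,
    stop("unknown variable: ", variable))
}

#' Mediator effect on catch
#'
#' Percent change in predicted catch attributable to one mediator:
#' `(exp(beta x (mu - mu0)) - 1) x 100`, where `beta` is the mediator's
#' catch coefficient and `mu`, `mu0` its predicted means under the
#' perturbed and baseline inputs (same coefficient draw).
#'
#' @param beta catch-submodel coefficient of the mediator.
#' @param mu,mu0 predicted mediator means (log scale for chlorophyll-a).
#' @return percent catch change (vectorized).
#' @export
mediator_catch_effect <- function(beta, mu, mu0) {
  (exp(beta * (mu - mu0)) - 1) * 100
}

#' Baseline prediction at median inputs
#'
#' @param coef coefficient list as in [predicted_means()].
#' @param medians one-row data frame (or named list) of per-lake medians of
#'   all model inputs (see [compute_medians()]).
#' @param stocking stocking-eligibility flag.
#' @return list `muWT`, `muDWL`, `muCHL`, `muCATCH` at the medians.
#' @export
baseline_prediction <- function(coef, medians, stocking = FALSE) {
  predicted_means(coef, as.data.frame(as.list(medians))[
    c("AT", "PRE", "PE", "LUag", "ST", "EFF")], stocking)
}

#' Propose driver values
#'
#' Samples a driver from a normal distribution fitted to the lake's
#' observed series; nonpositive precipitation or land-use proposals are
#' resampled (their logs enter the model).
#'
#' @param n number of proposals.
#' @param driver `"AT"`, `"PRE"` or `"LUag"`.
#' @param mean,sd proposal distribution parameters.
#' @return numeric vector of length `n`.
#' @export
propose_driver <- function(n, driver, mean, sd) {
  x <- rnorm(n, mean, sd)
  if (driver %in% c("PRE", "LUag")) {
    bad <- which(x <= 0)
    while (length(bad)) {
      x[bad] <- rnorm(length(bad), mean, sd)
      bad <- bad[x[bad] <= 0]
    }
  }
  x
}

# vectorized mu chain over rows of coefficient draw matrices
.mu_vec <- function(cd, idx, AT, PRE, PE, LUag, logST, logEFF) {
  W <- cd$WT[idx, , drop = FALSE]
  D <- cd$dWL[idx, , drop = FALSE]
  C <- cd$CHL[idx, , drop = FALSE]
  K <- cd$CATCH[idx, , drop = FALSE]
  muWT <- W[, "Intercept"] + W[, "AT"] * AT
  muDWL <- D[, "Intercept"] + D[, "PRE"] * PRE + D[, "PE"] * PE +
    D[, "PE.LUag"] * PE * LUag
  muCHL <- C[, "Intercept"] + C[, "logPRE"] * log(PRE) +
    C[, "logLUag"] * log(LUag) + C[, "muDWL"] * muDWL + C[, "muWT"] * muWT
  muCATCH <- K[, "Intercept"] + K[, "muWT"] * muWT +
    K[, "muDWL"] * muDWL + K[, "muCHL"] * muCHL + K[, "logEFF"] * logEFF
  if (cd$stocking) muCATCH <- muCATCH + K[, "logST"] * logST
  list(muWT = muWT, muDWL = muDWL, muCHL = muCHL, muCATCH = muCATCH)
}

#' Monte-Carlo assessment of one driver in one lake
#'
#' Three-step acceptance sampler. Step 1 draws a coefficient set from the
#' posterior and computes the baseline predictions at the lake's study-window
#' median inputs. Step 2 proposes the assessed driver from a normal
#' distribution fitted to its observed series (non-assessed drivers stay at
#' their medians; for air-temperature assessments, potential evaporation is
#' recomputed from the proposed AT through the lake's fitted linear PE--AT
#' map). Step 3 keeps the proposal if the predicted catch ratio
#' `exp(mu_CATCH - mu0_CATCH)` falls in the acceptance window. Sampling
#' repeats until `n_accepted` samples are collected; each accepted sample
#' records the driver change, the mediator changes and the mediator-to-catch
#' effects in their reporting metrics.
#'
#' @param draws a `bnm_draws` (or a list of coefficient matrices as
#'   returned by [coefficient_draws()]).
#' @param panel the [lake_panel()] the model was fitted to.
#' @param lake lake id.
#' @param driver `"AT"`, `"PRE"` or `"LUag"`.
#' @param n_accepted accepted-sample target (default from config).
#' @param seed integer seed.
#' @param window acceptance window for the catch ratio.
#' @param batch proposals per vectorized batch.
#' @param min_rate abort threshold for the acceptance rate.
#' @return a `driver_assessment`: `samples` data frame (one row per
#'   accepted sample: coefficient-draw index, driver value, driver change,
#'   mediator changes, mediator effects in percent, catch ratio), counts,
#'   the proposal distribution, PE--AT map, mediator count `k` and its
#'   importance cutoff.
#' @export
run_driver_assessment <- function(draws, panel, lake,
                                  driver = c("AT", "PRE", "LUag"),
                                  n_accepted = 10000, seed = 1,
                                  window = c(0.74, 0.76), batch = 50000,
                                  min_rate = 1e-5) {
  driver <- match.arg(driver)
  cd <- if (inherits(draws, "bnm_draws")) coefficient_draws(draws, lake)
        else draws
  panel <- lake_panel(panel)
  sub <- panel[panel$lake_id == lake, ]
  med <- compute_medians(sub)
  obs <- sub[[driver]][!is.na(sub[[driver]])]
  dist <- list(mean = mean(obs), sd = sd(obs))
  peo <- complete.cases(sub$AT, sub$PE)
  pe_fit <- least_squares_line(sub$AT[peo], sub$PE[peo])
  if (driver == "AT" && pe_fit["slope"] <= 0)
    warning("fitted PE-AT slope is not positive for lake ", lake)

  set.seed(as.integer(seed))
  ndraws <- nrow(cd$WT)
  k_med <- if (driver == "AT") 3L else 2L
  acc <- list()
  n_prop <- 0L; n_acc <- 0L
  logSTm <- log(med$ST); logEFFm <- log(med$EFF)
  while (n_acc < n_accepted) {
    B <- batch
    idx <- sample.int(ndraws, B, replace = TRUE)
    x <- propose_driver(B, driver, dist$mean, dist$sd)
    AT <- if (driver == "AT") x else med$AT
    PRE <- if (driver == "PRE") x else med$PRE
    LUag <- if (driver == "LUag") x else med$LUag
    PE <- if (driver == "AT")
      pe_fit["intercept"] + pe_fit["slope"] * x else med$PE
    mu0 <- .mu_vec(cd, idx, med$AT, med$PRE, med$PE, med$LUag,
                   logSTm, logEFFm)
    mu <- .mu_vec(cd, idx, AT, PRE, PE, LUag, logSTm, logEFFm)
    keep <- which(accept_sample(mu$muCATCH, mu0$muCATCH, window))
    n_prop <- n_prop + B
    if (length(keep)) {
      K <- cd$CATCH[idx[keep], , drop = FALSE]
      dWT <- mu$muWT[keep] - mu0$muWT[keep]
      dWL <- mu$muDWL[keep] - mu0$muDWL[keep]
      dCHL <- change_metric("CHL", mu$muCHL[keep], mu0$muCHL[keep])
      acc[[length(acc) + 1L]] <- data.frame(
        draw = idx[keep],
        driver_value = x[keep],
        delta_driver = change_metric(driver, x[keep], med[[driver]]),
        delta_WT = if (driver == "AT") dWT else NA_real_,
        delta_WL = dWL,
        delta_CHL = dCHL,
        effect_WT = if (driver == "AT")
          mediator_catch_effect(K[, "muWT"], mu$muWT[keep],
                                mu0$muWT[keep]) else NA_real_,
        effect_WL = mediator_catch_effect(K[, "muDWL"], mu$muDWL[keep],
                                          mu0$muDWL[keep]),
        effect_CHL = mediator_catch_effect(K[, "muCHL"], mu$muCHL[keep],
                                           mu0$muCHL[keep]),
        ratio = exp(mu$muCATCH[keep] - mu0$muCATCH[keep]))
      n_acc <- n_acc + length(keep)
    }
    if (n_prop >= 20 * batch && n_acc / n_prop < min_rate)
      stop(sprintf(
        "acceptance rate %.2g below %g after %d proposals for lake %s/%s;
widen the proposal distribution or check the posterior",
        n_acc / n_prop, min_rate, n_prop, lake, driver))
  }
  samples <- do.call(rbind, acc)[seq_len(n_accepted), ]
  rownames(samples) <- NULL
  structure(list(lake = lake, driver = driver, samples = samples,
                 n_accepted = n_accepted, n_proposed = n_prop,
                 window = window, medians = med, proposal = dist,
                 pe_map = pe_fit, k = k_med,
                 cutoff = importance_cutoff(k_med)),
            class = "driver_assessment")
}

#' @export
print.driver_assessment <- function(x, ...) {
  cat(sprintf(
    "driver_assessment %s/%s: %d accepted of %d proposals (rate %.3g)\n",
    x$lake, x$driver, x$n_accepted, x$n_proposed,
    x$n_accepted / x$n_proposed))
  cat(sprintf("  delta %s: median %.3g [q25 %.3g, q75 %.3g] -> %s\n",
              x$driver, median(x$samples$delta_driver),
              quantile(x$samples$delta_driver, 0.25),
              quantile(x$samples$delta_driver, 0.75),
              classify_association(x$samples$delta_driver)))
  invisible(x)
}

#' Classify the driver association with a catch decrease
#'
#' Positive when the catch decrease is associated with a *decrease* in the
#' driver (the 0.75 quantile of the accepted driver changes is below 0),
#' negative when with an increase (0.25 quantile above 0), mixed otherwise
#' — the labeling convention of the one-tailed 75% credible-interval rule.
#'
#' @param delta_driver accepted driver changes (in the driver's metric).
#' @param level credibility level (default 0.75).
#' @return `"positive"`, `"negative"` or `"mixed"`.
#' @export
classify_association <- function(delta_driver, level = 0.75) {
  if (length(delta_driver) == 0) stop("no accepted samples")
  if (quantile(delta_driver, level, names = FALSE) < 0) "positive"
  else if (quantile(delta_driver, 1 - level, names = FALSE) > 0) "negative"
  else "mixed"
}

#' Importance flag for a mediator's catch effect
#'
#' A mediator is important when at least 75% of the accepted samples show a
#' catch decrease exceeding the equal-share cutoff: the 0.75 quantile of
#' its percent effects is at or below `-importance_cutoff(k)`.
#'
#' @param effects percent catch changes (negative = decrease).
#' @param k number of mediators sharing the decrease (see
#'   [importance_cutoff()]).
#' @param level credibility level (default 0.75).
#' @return logical flag.
#' @export
flag_importance <- function(effects, k, level = 0.75) {
  if (length(effects) == 0) stop("no effects to flag")
  quantile(effects, level, names = FALSE) <= -importance_cutoff(k)
}

#' Summary of a driver assessment
#'
#' @param object a `driver_assessment`.
#' @param ... unused.
#' @return list with quartiles of the driver change, its association class,
#'   and per-mediator medians and importance flags.
#' @export
summary.driver_assessment <- function(object, ...) {
  s <- object$samples
  meds <- c(WT = if (object$driver == "AT") median(s$effect_WT) else NA,
            WL = median(s$effect_WL), CHL = median(s$effect_CHL))
  imp <- c(WT = if (object$driver == "AT")
             flag_importance(s$effect_WT, object$k) else NA,
           WL = flag_importance(s$effect_WL, object$k),
           CHL = flag_importance(s$effect_CHL, object$k))
  list(lake = object$lake, driver = object$driver,
       delta_quartiles = quantile(s$delta_driver, c(0.25, 0.5, 0.75)),
       association = classify_association(s$delta_driver),
       mediator_median_effect = meds, mediator_important = imp,
       acceptance_rate = object$n_accepted / object$n_proposed)
}
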