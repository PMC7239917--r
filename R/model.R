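## The four-level conditional model: predicted means and joint log density.

# vectorized evaluation of the four predicted means over a data frame of
# inputs (AT, PRE, PE, LUag, ST, EFF); coef is a list of named vectors
.mu_chain <- function(coef, d, stocking = FALSE) {
  if (any(d$PRE <= 0, na.rm = TRUE) || any(d$LUag <= 0, na.rm = TRUE))
    stop("PRE and LUag must be positive (log terms)")
  if (any(d$EFF <= 0, na.rm = TRUE)) stop("EFF must be positive (log term)")
  if (stocking && any(d$ST <= 0, na.rm = TRUE))
    stop("ST must be positive (log term)")
  b <- coef$WT
  muWT <- b["Intercept"] + b["AT"] * d$AT
  b <- coef$dWL
  muDWL <- b["Intercept"] + b["PRE"] * d$PRE + b["PE"] * d$PE +
    b["PE.LUag"] * d$PE * d$LUag
  b <- coef$CHL
  muCHL <- b["Intercept"] + b["logPRE"] * log(d$PRE) +
    b["logLUag"] * log(d$LUag) + b["muDWL"] * muDWL + b["muWT"] * muWT
  b <- coef$CATCH
  muCATCH <- b["Intercept"] + b["muWT"] * muWT + b["muDWL"] * muDWL +
    b["muCHL"] * muCHL + b["logEFF"] * log(d$EFF)
  if (stocking) muCATCH <- muCATCH + b["logST"] * log(d$ST)
  list(muWT = unname(muWT), muDWL = unname(muDWL), muCHL = unname(muCHL),
       muCATCH = unname(muCATCH))
}

#' Predicted means of the four submodels
#'
#' Evaluates the recursive chain of predicted means at a set of inputs:
#' `mu_WT = b0 + b1 AT`; `mu_dWL = b0 + b1 PRE + b2 PE + b3 PE x LUag`;
#' `mu_CHL = b0 + b1 log PRE + b2 log LUag + b3 mu_dWL + b4 mu_WT`;
#' `mu_CATCH = b0 + b1 mu_WT + b2 mu_dWL + b3 mu_CHL (+ b4 log ST) +
#' b5 log EFF`. Downstream submodels consume upstream *predicted* means,
#' never the noisy observations.
#'
#' @param coef list of named coefficient vectors `WT`, `dWL`, `CHL`,
#'   `CATCH` (terms as in the design matrices).
#' @param record one row (or data frame of rows) with `AT`, `PRE`, `PE`,
#'   `LUag`, `EFF` and, for stocking-eligible lakes, `ST`.
#' @param stocking include the log-stocking term in the catch submodel?
#' @return list `muWT`, `muDWL`, `muCHL`, `muCATCH` (vectors if `record`
#'   has several rows).
#' @export
predicted_means <- function(coef, record, stocking = FALSE) {
  record <- as.data.frame(record)
  .mu_chain(coef, record, stocking)
}

# likelihood row sets: years usable by each submodel under plug-in means
.rows_likelihood <- function(sub, submodel, stocking = FALSE) {
  drivers <- is.finite(sub$AT) & is.finite(sub$PRE) & sub$PRE > 0 &
    is.finite(sub$PE) & is.finite(sub$LUag) & sub$LUag > 0
  switch(submodel,
    WT = is.finite(sub$WT) & is.finite(sub$AT),
    dWL = is.finite(sub$dWL) & is.finite(sub$PRE) & is.finite(sub$PE) &
      is.finite(sub$LUag),
    CHL = is.finite(sub$CHL) & sub$CHL > 0 & drivers,
    CATCH = is.finite(sub$CATCH) & sub$CATCH > 0 & is.finite(sub$EFF) &
      sub$EFF > 0 & drivers &
      (if (stocking) is.finite(sub$ST) & sub$ST > 0 else TRUE))
}

#' Joint log density of the model
#'
#' Gaussian log-likelihood summed over lakes, submodels and usable years
#' (a year enters a submodel's term only when that submodel's response and
#' all required inputs are observed), plus — when `priors` is supplied —
#' the MVN log-priors on the coefficient blocks and the inverse-gamma terms
#' on the noise variances and scale hyperparameters.
#'
#' @param coef named list (per lake) of coefficient lists as in
#'   [predicted_means()]; a bare coefficient list is accepted for a
#'   single-lake panel.
#' @param panel a [lake_panel()].
#' @param sigma named vector of noise SDs per submodel.
#' @param priors optional `bnm_priors` (flat priors when `NULL`).
#' @param g named vector of prior scales per submodel (required with
#'   `priors`).
#' @param submodels subset of submodels to include.
#' @param stocking named logical per lake (defaults to the priors' flags,
#'   else none).
#' @return scalar log density (`-Inf` if any `sigma <= 0`).
#' @export
log_joint <- function(coef, panel, sigma, priors = NULL, g = NULL,
                      submodels = .bnm_submodels, stocking = NULL) {
  panel <- add_delta_wl(lake_panel(panel))
  lakes <- unique(panel$lake_id)
  if (!is.null(coef$WT) && !is.null(names(coef$WT))) {
    stopifnot(length(lakes) == 1)
    coef <- setNames(list(coef), lakes)
  }
  if (is.null(stocking))
    stocking <- if (!is.null(priors)) priors$stocking
                else setNames(rep(FALSE, length(lakes)), lakes)
  if (any(sigma[submodels] <= 0)) return(-Inf)
  ll <- 0
  for (id in lakes) {
    sub <- panel[panel$lake_id == id, ]
    mu <- .mu_chain(coef[[id]], sub, stocking[[id]])
    resp <- list(WT = sub$WT, dWL = sub$dWL, CHL = log(pmax(sub$CHL, 1e-300)),
                 CATCH = log(pmax(sub$CATCH, 1e-300)))
    mus <- list(WT = mu$muWT, dWL = mu$muDWL, CHL = mu$muCHL,
                CATCH = mu$muCATCH)
    for (sm in submodels) {
      ok <- .rows_likelihood(sub, sm, stocking[[id]])
      r <- resp[[sm]][ok] - mus[[sm]][ok]
      ll <- ll + sum(dnorm(r, 0, sigma[[sm]], log = TRUE))
    }
  }
  if (!is.null(priors)) {
    stopifnot(!is.null(g))
    h <- priors$hyper
    for (sm in submodels) {
      for (id in lakes) {
        pr <- priors$submodels[[sm]][[id]]
        dev <- coef[[id]][[sm]][pr$terms] - pr$mean
        P <- pr$XtX / g[[sm]]
        ll <- ll + 0.5 * determinant(P, logarithm = TRUE)$modulus -
          0.5 * drop(t(dev) %*% P %*% dev) -
          0.5 * length(dev) * log(2 * pi)
      }
      # inverse-gamma densities on sigma^2 and g
      ll <- ll + .dinvgamma_log(sigma[[sm]]^2, h$sigma_shape, h$sigma_rate) +
        .dinvgamma_log(g[[sm]], h$g_shape, h$g_rate)
    }
  }
  as.numeric(ll)
}

.dinvgamma_log <- function(x, shape, rate) {
  if (x <= 0) return(-Inf)
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

#' @importFrom stats dnorm
NULL
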