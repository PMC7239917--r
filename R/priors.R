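## Prior construction: per-lake least-squares anchors and MVN priors with a
## shared scale hyperparameter per submodel.

# Design matrix for the *prior* least-squares fit of one submodel in one
# lake. Unlike the likelihood (which plugs in predicted means), the prior
# stage uses the observed upstream variables, since predicted means do not
# exist before estimation.
.design_prior <- function(sub, submodel, stocking = FALSE) {
  sub <- add_delta_wl(sub)
  if (submodel == "WT") {
    X <- cbind(Intercept = 1, AT = sub$AT)
    y <- sub$WT
  } else if (submodel == "dWL") {
    X <- cbind(Intercept = 1, PRE = sub$PRE, PE = sub$PE,
               PE.LUag = sub$PE * sub$LUag)
    y <- sub$dWL
  } else if (submodel == "CHL") {
    X <- cbind(Intercept = 1, logPRE = log(sub$PRE),
               logLUag = log(sub$LUag), muDWL = sub$dWL, muWT = sub$WT)
    y <- log(sub$CHL)
  } else if (submodel == "CATCH") {
    X <- cbind(Intercept = 1, muWT = sub$WT, muDWL = sub$dWL,
               muCHL = log(sub$CHL),
               logST = if (stocking) log(sub$ST) else NULL,
               logEFF = log(sub$EFF))
    y <- log(sub$CATCH)
  } else stop("unknown submodel: ", submodel)
  ok <- is.finite(y) & apply(is.finite(X), 1, all)
  list(X = X[ok, , drop = FALSE], y = y[ok], years = sub$year[ok])
}

#' Per-lake least-squares fit of one submodel
#'
#' Ordinary least squares for one submodel in one lake, using only years in
#' which the response and all predictors are observed. The returned
#' covariance is the *unscaled* `(X'X)^-1` — no residual-variance
#' multiplier; the scale is carried by the prior hyperparameter instead.
#'
#' @param panel a [lake_panel()] (single lake, or give `lake`).
#' @param submodel one of `"WT"`, `"dWL"`, `"CHL"`, `"CATCH"`.
#' @param lake lake id if the panel holds several lakes.
#' @param stocking does the catch submodel include the log-stocking term?
#' @return list with `coef`, `cov_unscaled` (`(X'X)^-1`), `XtX`, `sigma2`
#'   (residual variance), `n_used`, `terms`, `submodel`, `lake_id`.
#' @export
least_squares_fit <- function(panel, submodel, lake = NULL,
                              stocking = FALSE) {
  panel <- lake_panel(panel)
  if (is.null(lake)) {
    lake <- unique(panel$lake_id)
    if (length(lake) > 1) stop("give 'lake' for a multi-lake panel")
  }
  sub <- panel[panel$lake_id == lake, , drop = FALSE]
  d <- .design_prior(sub, submodel, stocking)
  p <- ncol(d$X)
  if (nrow(d$X) < p + 1)
    stop(sprintf("lake %s, %s submodel: %d usable years for %d coefficients",
                 lake, submodel, nrow(d$X), p))
  qx <- qr(d$X)
  if (qx$rank < p) {
    bad <- colnames(d$X)[qx$pivot[(qx$rank + 1):p]]
    stop(sprintf("lake %s, %s submodel: rank-deficient design (collinear: %s)",
                 lake, submodel, paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qx, d$y)
  res <- d$y - drop(d$X %*% beta)
  XtX <- crossprod(d$X)
  cov_unscaled <- chol2inv(chol(XtX))
  dimnames(cov_unscaled) <- dimnames(XtX)
  list(coef = beta, cov_unscaled = cov_unscaled, XtX = XtX,
       sigma2 = sum(res^2) / (nrow(d$X) - p), n_used = nrow(d$X),
       terms = colnames(d$X), submodel = submodel, lake_id = lake)
}

#' Build MVN priors from per-lake least-squares fits
#'
#' For each submodel and lake, the prior on the coefficient vector is
#' multivariate normal with mean equal to the lake's least-squares estimates
#' and covariance `g x (X'X)^-1`, where the scale `g` is a single
#' hyperparameter per submodel, shared across lakes, with a noninformative
#' inverse-gamma hyperprior. The shared `g` is the pooling channel: the
#' weight of lake-specific information grows with the lake's sample size.
#' Noise scales get noninformative inverse-gamma priors on the variance.
#'
#' @param panel a multi-lake [lake_panel()].
#' @param stocking named logical vector (per lake) of stocking eligibility;
#'   default none eligible.
#' @param hyper list of inverse-gamma hyperparameters `g_shape`, `g_rate`
#'   (on each submodel's `g`) and `sigma_shape`, `sigma_rate` (on each
#'   submodel's noise variance); defaults 0.001 throughout.
#' @return a `bnm_priors` object: per submodel, per lake, the prior `mean`,
#'   `cov_unscaled`, prior precision factor `XtX`, residual variance and
#'   `n_used`; plus the hyperprior spec and eligibility flags.
#' @export
build_priors <- function(panel, stocking = NULL,
                         hyper = list(g_shape = 0.001, g_rate = 0.001,
                                      sigma_shape = 0.001,
                                      sigma_rate = 0.001)) {
  panel <- lake_panel(panel)
  lakes <- unique(panel$lake_id)
  if (is.null(stocking)) stocking <- setNames(rep(FALSE, length(lakes)), lakes)
  stopifnot(all(lakes %in% names(stocking)))
  out <- list()
  for (sm in .bnm_submodels) {
    out[[sm]] <- lapply(setNames(lakes, lakes), function(id) {
      ls <- least_squares_fit(panel, sm, id, stocking = stocking[[id]])
      list(mean = ls$coef, cov_unscaled = ls$cov_unscaled, XtX = ls$XtX,
           sigma2 = ls$sigma2, n_used = ls$n_used, terms = ls$terms)
    })
  }
  structure(list(submodels = out, hyper = hyper,
                 stocking = stocking[lakes], lakes = lakes),
            class = "bnm_priors")
}

#' Realize a prior covariance at a given scale
#'
#' @param priors a `bnm_priors` object.
#' @param submodel submodel name.
#' @param lake lake id.
#' @param g scale hyperparameter value.
#' @return the prior covariance matrix `g x (X'X)^-1`.
#' @export
prior_covariance <- function(priors, submodel, lake, g) {
  if (g <= 0) stop("g must be positive")
  g * priors$submodels[[submodel]][[lake]]$cov_unscaled
}

#' @export
print.bnm_priors <- function(x, ...) {
  cat(sprintf("bnm_priors: %d lakes, submodels %s; %d stocking-eligible\n",
              length(x$lakes), paste(.bnm_submodels, collapse = "/"),
              sum(x$stocking)))
  invisible(x)
}
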