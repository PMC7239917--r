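## Convergence diagnostics: split Gelman-Rubin statistic and lag-1
## autocorrelation per monitored parameter.

#' Split Gelman-Rubin diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (so within-chain drift also inflates the statistic). A parameter
#' with zero within-chain variance is flagged as undefined rather than
#' silently reported as 1.
#'
#' @param draws a `bnm_draws` (>= 2 chains, >= 10 retained iterations).
#' @return data frame joined to the parameter registry with columns `rhat`,
#'   `defined` and `ac_lag1` (mean lag-1 autocorrelation across chains).
#' @export
gelman_rubin <- function(draws) {
  a <- draws$draws
  n_chain <- dim(a)[1]; n_iter <- dim(a)[2]
  if (n_chain < 2) stop("gelman_rubin needs >= 2 chains")
  if (n_iter < 10) stop("gelman_rubin needs >= 10 retained iterations")
  half <- n_iter %/% 2
  out <- data.frame(draws$params, rhat = NA_real_, defined = FALSE,
                    ac_lag1 = NA_real_)
  for (p in seq_len(dim(a)[3])) {
    segs <- list()
    ac <- numeric(0)
    for (ch in seq_len(n_chain)) {
      x <- a[ch, , p]
      segs <- c(segs, list(x[seq_len(half)], x[half + seq_len(half)]))
      if (sd(x) > 0)
        ac <- c(ac, acf(x, lag.max = 1, plot = FALSE)$acf[2])
    }
    wvar <- vapply(segs, var, numeric(1))
    W <- mean(wvar)
    if (!is.finite(W) || W <= 0) next   # undefined: constant chains
    means <- vapply(segs, mean, numeric(1))
    B <- half * var(means)
    vplus <- (half - 1) / half * W + B / half
    out$rhat[p] <- sqrt(vplus / W)
    out$defined[p] <- TRUE
    out$ac_lag1[p] <- if (length(ac)) mean(ac) else NA_real_
  }
  out
}

#' Maximum split R-hat over model coefficients
#'
#' @param draws a `bnm_draws`.
#' @param type parameter types to include (default the beta coefficients,
#'   the quantities the convergence criterion is stated for).
#' @return scalar maximum R-hat (over defined parameters).
#' @export
max_rhat <- function(draws, type = "beta") {
  gr <- gelman_rubin(draws)
  gr <- gr[gr$type %in% type & gr$defined, ]
  max(gr$rhat)
}
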