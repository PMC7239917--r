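## Block-conjugate Gibbs sampler for the four-level conditional model.
##
## Every predicted mean is linear in each coefficient block given the other
## blocks, so each block's full conditional is Gaussian; noise variances and
## the prior scales are conditionally inverse-gamma. All per-iteration
## algebra runs on small Gram matrices precomputed once per lake, so the
## cost per sweep does not grow with panel length.

#' MCMC and pipeline configuration
#'
#' @param chains number of chains (>= 2 for the Gelman-Rubin diagnostic).
#' @param burnin iterations discarded per chain.
#' @param retained iterations kept per chain.
#' @param thin thinning interval (1 = keep all).
#' @param seed integer master seed.
#' @param scale `"demo"` (default, 2,000 + 5,000) or `"paper"` (20,000
#'   burn-in + 50,000 retained, the full-scale run).
#' @param submodels submodels to estimate. Downstream submodels need the
#'   upstream ones: `CHL` requires `WT` and `dWL`; `CATCH` requires all.
#' @param fix_sigma optional named vector of noise SDs to hold fixed.
#' @param fix_g optional named vector of prior scales to hold fixed.
#' @param level classification level for credible-interval effect calls
#'   (default 0.75).
#' @param mc_target accepted Monte-Carlo samples per lake x driver.
#' @param mc_window catch-ratio acceptance window (closed interval).
#' @return a `bnm_config` list.
#' @export
bnm_config <- function(chains = 3, burnin = 2000, retained = 5000, thin = 1,
                       seed = 1, scale = c("demo", "paper"),
                       submodels = .bnm_submodels, fix_sigma = NULL,
                       fix_g = NULL, level = 0.75, mc_target = 10000,
                       mc_window = c(0.74, 0.76)) {
  scale <- match.arg(scale)
  if (scale == "paper") { burnin <- 20000; retained <- 50000 }
  stopifnot(chains >= 1, burnin >= 0, retained >= 1, thin >= 1,
            level > 0.5, level < 1, mc_window[1] < mc_window[2])
  submodels <- match.arg(submodels, .bnm_submodels, several.ok = TRUE)
  if ("CATCH" %in% submodels &&
      !all(c("WT", "dWL", "CHL") %in% submodels))
    stop("CATCH submodel requires WT, dWL and CHL")
  if ("CHL" %in% submodels && !all(c("WT", "dWL") %in% submodels))
    stop("CHL submodel requires WT and dWL")
  structure(list(chains = chains, burnin = burnin, retained = retained,
                 thin = thin, seed = as.integer(seed), scale = scale,
                 submodels = submodels, fix_sigma = fix_sigma,
                 fix_g = fix_g, level = level, mc_target = mc_target,
                 mc_window = mc_window),
            class = "bnm_config")
}

# draw from N(P^-1 b, P^-1) given precision P and linear term b
.rmvn_prec <- function(P, b) {
  P <- (P + t(P)) / 2
  R <- chol(P)
  mu <- backsolve(R, forwardsolve(t(R), b))
  drop(mu + backsolve(R, rnorm(length(b))))
}

# per-lake Gram-matrix precomputation for the likelihood terms
.precompute_lake <- function(sub, stocking) {
  sub <- add_delta_wl(sub)
  pre <- list(stocking = stocking)

  ok <- .rows_likelihood(sub, "WT")
  A1 <- cbind(1, sub$AT[ok]); y1 <- sub$WT[ok]
  pre$WT <- list(XtX = crossprod(A1), Xty = drop(crossprod(A1, y1)),
                 yss = sum(y1^2), n = length(y1))

  ok <- .rows_likelihood(sub, "dWL")
  D1 <- cbind(1, sub$PRE[ok], sub$PE[ok], sub$PE[ok] * sub$LUag[ok])
  y2 <- sub$dWL[ok]
  pre$dWL <- list(XtX = crossprod(D1), Xty = drop(crossprod(D1, y2)),
                  yss = sum(y2^2), n = length(y2))

  ok <- .rows_likelihood(sub, "CHL")
  s <- sub[ok, ]
  M3 <- cbind(1, log(s$PRE), log(s$LUag),            # Z block (CHL terms)
              1, s$PRE, s$PE, s$PE * s$LUag,         # D block (dWL design)
              1, s$AT)                               # A block (WT design)
  y3 <- log(s$CHL)
  pre$CHL <- list(G = crossprod(M3), h = drop(crossprod(M3, y3)),
                  yss = sum(y3^2), n = nrow(s),
                  iZ = 1:3, iD = 4:7, iA = 8:9)

  ok <- .rows_likelihood(sub, "CATCH", stocking)
  s <- sub[ok, ]
  F4 <- cbind(1, log(s$PRE), log(s$LUag),
              1, s$PRE, s$PE, s$PE * s$LUag,
              1, s$AT,
              if (stocking) log(s$ST) else NULL,
              log(s$EFF))
  y4 <- log(s$CATCH)
  pre$CATCH <- list(G = crossprod(F4), h = drop(crossprod(F4, y4)),
                    yss = sum(y4^2), n = nrow(s),
                    iZ = 1:3, iD = 4:7, iA = 8:9,
                    iS = if (stocking) 10L else NULL,
                    iE = if (stocking) 11L else 10L,
                    nc = ncol(F4))
  pre
}

# split coefficient vector of the CATCH block into scalars, stocking-aware
.k_parts <- function(k, stocking) {
  list(k0 = k[["Intercept"]], k1 = k[["muWT"]], k2 = k[["muDWL"]],
       k3 = k[["muCHL"]], k4 = if (stocking) k[["logST"]] else 0,
       k5 = k[["logEFF"]])
}

# one Gibbs sweep over all lakes' blocks plus sigma and g; state is a list
# with $beta[[lake]][[submodel]], $sigma2 (named), $g (named)
.gibbs_sweep <- function(state, pres, priors, act, fix) {
  lakes <- names(pres)
  s2 <- state$sigma2
  g <- state$g
  rss <- c(WT = 0, dWL = 0, CHL = 0, CATCH = 0)
  nobs <- c(WT = 0, dWL = 0, CHL = 0, CATCH = 0)
  gquad <- c(WT = 0, dWL = 0, CHL = 0, CATCH = 0)
  gnp <- c(WT = 0, dWL = 0, CHL = 0, CATCH = 0)

  for (id in lakes) {
    pre <- pres[[id]]
    st <- pre$stocking
    be <- state$beta[[id]]
    w <- be$WT; d <- be$dWL; cc <- be$CHL; k <- be$CATCH
    C3 <- pre$CHL; C4 <- pre$CATCH
    iZ <- C3$iZ; iD <- C3$iD; iA <- C3$iA

    # --- beta_WT block ----------------------------------------------------
    if (act["WT"]) {
      pr <- priors$submodels$WT[[id]]
      P <- pr$XtX / g["WT"] + pre$WT$XtX / s2["WT"]
      b <- drop(pr$XtX %*% pr$mean) / g["WT"] + pre$WT$Xty / s2["WT"]
      if (act["CHL"] && C3$n > 0) {
        c012 <- cc[1:3]; c3 <- cc[[4]]; c4 <- cc[[5]]
        u <- c(c012, c3 * d, 0, 0)
        rv <- C3$h - drop(C3$G %*% u)
        P <- P + (c4^2 / s2["CHL"]) * C3$G[iA, iA]
        b <- b + (c4 / s2["CHL"]) * rv[iA]
      }
      if (act["CATCH"] && C4$n > 0) {
        kp <- .k_parts(k, st)
        c012 <- cc[1:3]; c3 <- cc[[4]]; c4 <- cc[[5]]
        aK <- kp$k1 + kp$k3 * c4
        dK <- kp$k2 + kp$k3 * c3
        q <- numeric(C4$nc)
        q[C4$iZ] <- kp$k3 * c012 + c(kp$k0, 0, 0)
        q[C4$iD] <- dK * d
        if (!is.null(C4$iS)) q[C4$iS] <- kp$k4
        q[C4$iE] <- kp$k5
        rv <- C4$h - drop(C4$G %*% q)
        P <- P + (aK^2 / s2["CATCH"]) * C4$G[C4$iA, C4$iA]
        b <- b + (aK / s2["CATCH"]) * rv[C4$iA]
      }
      w <- .rmvn_prec(P, b)
      names(w) <- pr$terms
      be$WT <- w
      dev <- w - pr$mean
      gquad["WT"] <- gquad["WT"] + drop(t(dev) %*% pr$XtX %*% dev)
      gnp["WT"] <- gnp["WT"] + length(w)
    }

    # --- beta_dWL block ---------------------------------------------------
    if (act["dWL"]) {
      pr <- priors$submodels$dWL[[id]]
      P <- pr$XtX / g["dWL"] + pre$dWL$XtX / s2["dWL"]
      b <- drop(pr$XtX %*% pr$mean) / g["dWL"] + pre$dWL$Xty / s2["dWL"]
      if (act["CHL"] && C3$n > 0) {
        c012 <- cc[1:3]; c3 <- cc[[4]]; c4 <- cc[[5]]
        u <- c(c012, rep(0, 4), c4 * w)
        rv <- C3$h - drop(C3$G %*% u)
        P <- P + (c3^2 / s2["CHL"]) * C3$G[iD, iD]
        b <- b + (c3 / s2["CHL"]) * rv[iD]
      }
      if (act["CATCH"] && C4$n > 0) {
        kp <- .k_parts(k, st)
        c012 <- cc[1:3]; c3 <- cc[[4]]; c4 <- cc[[5]]
        aK <- kp$k1 + kp$k3 * c4
        dK <- kp$k2 + kp$k3 * c3
        q <- numeric(C4$nc)
        q[C4$iZ] <- kp$k3 * c012 + c(kp$k0, 0, 0)
        q[C4$iA] <- aK * w
        if (!is.null(C4$iS)) q[C4$iS] <- kp$k4
        q[C4$iE] <- kp$k5
        rv <- C4$h - drop(C4$G %*% q)
        P <- P + (dK^2 / s2["CATCH"]) * C4$G[C4$iD, C4$iD]
        b <- b + (dK / s2["CATCH"]) * rv[C4$iD]
      }
      d <- .rmvn_prec(P, b)
      names(d) <- pr$terms
      be$dWL <- d
      dev <- d - pr$mean
      gquad["dWL"] <- gquad["dWL"] + drop(t(dev) %*% pr$XtX %*% dev)
      gnp["dWL"] <- gnp["dWL"] + length(d)
    }

    # --- beta_CHL block ---------------------------------------------------
    if (act["CHL"] && C3$n > 0) {
      pr <- priors$submodels$CHL[[id]]
      # design-in-c Gram via the block map (Z | D d | A w)
      TtT <- function(G, iZ, iD, iA) {
        Gzd <- drop(G[iZ, iD] %*% d); Gza <- drop(G[iZ, iA] %*% w)
        dd <- drop(t(d) %*% G[iD, iD] %*% d)
        aa <- drop(t(w) %*% G[iA, iA] %*% w)
        da <- drop(t(d) %*% G[iD, iA] %*% w)
        M <- matrix(0, 5, 5)
        M[1:3, 1:3] <- G[iZ, iZ]
        M[1:3, 4] <- Gzd; M[4, 1:3] <- Gzd
        M[1:3, 5] <- Gza; M[5, 1:3] <- Gza
        M[4, 4] <- dd; M[5, 5] <- aa
        M[4, 5] <- da; M[5, 4] <- da
        M
      }
      P <- pr$XtX / g["CHL"] + TtT(C3$G, iZ, iD, iA) / s2["CHL"]
      b <- drop(pr$XtX %*% pr$mean) / g["CHL"] +
        c(C3$h[iZ], sum(d * C3$h[iD]), sum(w * C3$h[iA])) / s2["CHL"]
      if (act["CATCH"] && C4$n > 0) {
        kp <- .k_parts(k, st)
        q <- numeric(C4$nc)
        q[C4$iZ] <- c(kp$k0, 0, 0)
        q[C4$iD] <- kp$k2 * d
        q[C4$iA] <- kp$k1 * w
        if (!is.null(C4$iS)) q[C4$iS] <- kp$k4
        q[C4$iE] <- kp$k5
        rv <- C4$h - drop(C4$G %*% q)
        P <- P + (kp$k3^2 / s2["CATCH"]) * TtT(C4$G, C4$iZ, C4$iD, C4$iA)
        b <- b + (kp$k3 / s2["CATCH"]) *
          c(rv[C4$iZ], sum(d * rv[C4$iD]), sum(w * rv[C4$iA]))
      }
      cc <- .rmvn_prec(P, b)
      names(cc) <- pr$terms
      be$CHL <- cc
      dev <- cc - pr$mean
      gquad["CHL"] <- gquad["CHL"] + drop(t(dev) %*% pr$XtX %*% dev)
      gnp["CHL"] <- gnp["CHL"] + length(cc)
    }

    # --- beta_CATCH block -------------------------------------------------
    if (act["CATCH"] && C4$n > 0) {
      pr <- priors$submodels$CATCH[[id]]
      c012 <- cc[1:3]; c3 <- cc[[4]]; c4 <- cc[[5]]
      pk <- length(pr$mean)
      Ck <- matrix(0, C4$nc, pk)
      colnames(Ck) <- pr$terms
      Ck[C4$iZ[1], "Intercept"] <- 1
      Ck[C4$iA, "muWT"] <- w
      Ck[C4$iD, "muDWL"] <- d
      Ck[C4$iZ, "muCHL"] <- c012
      Ck[C4$iD, "muCHL"] <- Ck[C4$iD, "muCHL"] + c3 * d
      Ck[C4$iA, "muCHL"] <- Ck[C4$iA, "muCHL"] + c4 * w
      if (!is.null(C4$iS)) Ck[C4$iS, "logST"] <- 1
      Ck[C4$iE, "logEFF"] <- 1
      P <- pr$XtX / g["CATCH"] + crossprod(Ck, C4$G %*% Ck) / s2["CATCH"]
      b <- drop(pr$XtX %*% pr$mean) / g["CATCH"] +
        drop(crossprod(Ck, C4$h)) / s2["CATCH"]
      k <- .rmvn_prec(P, b)
      names(k) <- pr$terms
      be$CATCH <- k
      dev <- k - pr$mean
      gquad["CATCH"] <- gquad["CATCH"] + drop(t(dev) %*% pr$XtX %*% dev)
      gnp["CATCH"] <- gnp["CATCH"] + length(k)
    }

    # --- residual sums of squares (for the sigma draws) -------------------
    if (act["WT"]) {
      rss["WT"] <- rss["WT"] + pre$WT$yss - 2 * sum(w * pre$WT$Xty) +
        drop(t(w) %*% pre$WT$XtX %*% w)
      nobs["WT"] <- nobs["WT"] + pre$WT$n
    }
    if (act["dWL"]) {
      rss["dWL"] <- rss["dWL"] + pre$dWL$yss - 2 * sum(d * pre$dWL$Xty) +
        drop(t(d) %*% pre$dWL$XtX %*% d)
      nobs["dWL"] <- nobs["dWL"] + pre$dWL$n
    }
    if (act["CHL"] && C3$n > 0) {
      u <- c(cc[1:3], cc[[4]] * d, cc[[5]] * w)
      rss["CHL"] <- rss["CHL"] + C3$yss - 2 * sum(u * C3$h) +
        drop(t(u) %*% C3$G %*% u)
      nobs["CHL"] <- nobs["CHL"] + C3$n
    }
    if (act["CATCH"] && C4$n > 0) {
      kp <- .k_parts(k, st)
      c012 <- cc[1:3]; c3 <- cc[[4]]; c4 <- cc[[5]]
      u <- numeric(C4$nc)
      u[C4$iZ] <- kp$k3 * c012 + c(kp$k0, 0, 0)
      u[C4$iD] <- (kp$k2 + kp$k3 * c3) * d
      u[C4$iA] <- (kp$k1 + kp$k3 * c4) * w
      if (!is.null(C4$iS)) u[C4$iS] <- kp$k4
      u[C4$iE] <- kp$k5
      rss["CATCH"] <- rss["CATCH"] + C4$yss - 2 * sum(u * C4$h) +
        drop(t(u) %*% C4$G %*% u)
      nobs["CATCH"] <- nobs["CATCH"] + C4$n
    }
    state$beta[[id]] <- be
  }

  h <- priors$hyper
  for (sm in names(act)[act]) {
    if (is.null(fix$sigma[[sm]])) {
      prec <- rgamma(1, shape = h$sigma_shape + nobs[sm] / 2,
                     rate = h$sigma_rate + max(rss[sm], 0) / 2)
      state$sigma2[sm] <- 1 / prec
    }
    if (is.null(fix$g[[sm]])) {
      prec <- rgamma(1, shape = h$g_shape + gnp[sm] / 2,
                     rate = h$g_rate + max(gquad[sm], 0) / 2)
      state$g[sm] <- 1 / prec
    }
  }
  if (any(!is.finite(unlist(state$sigma2))) ||
      any(!is.finite(unlist(state$g))))
    stop("sampler divergence: non-finite sigma/g")
  state
}

# parameter registry: one row per monitored parameter
.param_registry <- function(priors, submodels) {
  reg <- NULL
  for (id in priors$lakes)
    for (sm in submodels) {
      terms <- priors$submodels[[sm]][[id]]$terms
      reg <- rbind(reg, data.frame(
        param = sprintf("beta_%s[%s:%s]", sm, id, terms),
        type = "beta", submodel = sm, lake_id = id, term = terms,
        stringsAsFactors = FALSE))
    }
  for (sm in submodels)
    reg <- rbind(reg,
      data.frame(param = paste0("sigma_", sm), type = "sigma", submodel = sm,
                 lake_id = NA, term = NA, stringsAsFactors = FALSE),
      data.frame(param = paste0("g_", sm), type = "g", submodel = sm,
                 lake_id = NA, term = NA, stringsAsFactors = FALSE))
  reg
}

#' Run the block-Gibbs sampler
#'
#' Fits the four-level model to a multi-lake panel against
#' least-squares-anchored MVN priors ([build_priors()]). Each coefficient
#' block's full conditional is Gaussian (every predicted mean is linear in
#' each block given the others); noise variances and the per-submodel prior
#' scales are drawn from conjugate inverse-gamma conditionals. Chains start
#' from independent random perturbations of the prior means (`N(0, 0.1 x
#' prior SD)`), and the run is reproducible given `config$seed`.
#'
#' @param panel a [lake_panel()].
#' @param priors a `bnm_priors` from [build_priors()].
#' @param config a [bnm_config()].
#' @return a `bnm_draws` object: `draws` array (chain x iteration x
#'   parameter), parameter registry `params`, and the `config`.
#' @export
run_mcmc <- function(panel, priors, config = bnm_config()) {
  stopifnot(inherits(priors, "bnm_priors"))
  panel <- lake_panel(panel)
  act <- setNames(.bnm_submodels %in% config$submodels, .bnm_submodels)
  pres <- lapply(setNames(priors$lakes, priors$lakes), function(id)
    .precompute_lake(panel[panel$lake_id == id, ], priors$stocking[[id]]))
  reg <- .param_registry(priors, config$submodels)
  npar <- nrow(reg)
  fix <- list(sigma = as.list(config$fix_sigma), g = as.list(config$fix_g))

  n_keep <- config$retained %/% config$thin
  draws <- array(NA_real_, dim = c(config$chains, n_keep, npar),
                 dimnames = list(NULL, NULL, reg$param))

  sigma2_init <- vapply(.bnm_submodels, function(sm)
    mean(vapply(priors$submodels[[sm]], `[[`, numeric(1), "sigma2")),
    numeric(1))

  for (ch in seq_len(config$chains)) {
    set.seed((config$seed * 97L + ch) %% .Machine$integer.max)
    state <- list(
      beta = lapply(setNames(priors$lakes, priors$lakes), function(id)
        lapply(setNames(.bnm_submodels, .bnm_submodels), function(sm) {
          pr <- priors$submodels[[sm]][[id]]
          sdv <- sqrt(pmax(diag(pr$cov_unscaled), 1e-12))
          setNames(pr$mean + rnorm(length(pr$mean), 0, 0.1 * sdv), pr$terms)
        })),
      sigma2 = vapply(.bnm_submodels, function(sm)
        if (!is.null(fix$sigma[[sm]])) fix$sigma[[sm]]^2
        else sigma2_init[[sm]], numeric(1)),
      g = vapply(.bnm_submodels, function(sm)
        if (!is.null(fix$g[[sm]])) fix$g[[sm]] else 1, numeric(1)))

    keep_row <- 0L
    total <- config$burnin + config$retained
    for (it in seq_len(total)) {
      state <- .gibbs_sweep(state, pres, priors, act, fix)
      if (it > config$burnin &&
          (it - config$burnin) %% config$thin == 0L) {
        keep_row <- keep_row + 1L
        row <- numeric(npar)
        j <- 0L
        for (id in priors$lakes)
          for (sm in config$submodels) {
            v <- state$beta[[id]][[sm]]
            row[j + seq_along(v)] <- v
            j <- j + length(v)
          }
        for (sm in config$submodels) {
          row[j + 1L] <- sqrt(state$sigma2[[sm]])
          row[j + 2L] <- state$g[[sm]]
          j <- j + 2L
        }
        draws[ch, keep_row, ] <- row
      }
    }
  }
  structure(list(draws = draws, params = reg, config = config,
                 lakes = priors$lakes, stocking = priors$stocking),
            class = "bnm_draws")
}

#' @export
print.bnm_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("bnm_draws: %d chains x %d iterations x %d parameters\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Flatten draws to a matrix
#'
#' @param draws a `bnm_draws`.
#' @return matrix (chains x iterations) rows by parameter columns.
#' @export
as_draw_matrix <- function(draws) {
  d <- dim(draws$draws)
  m <- matrix(aperm(draws$draws, c(2, 1, 3)), d[1] * d[2], d[3])
  colnames(m) <- draws$params$param
  m
}

#' Posterior summary table
#'
#' @param draws a `bnm_draws`.
#' @param probs quantiles to report.
#' @return data frame with mean, sd, median and quantiles per parameter,
#'   joined to the parameter registry.
#' @export
posterior_summary <- function(draws, probs = c(0.25, 0.5, 0.75)) {
  m <- as_draw_matrix(draws)
  qs <- t(apply(m, 2, quantile, probs = probs))
  colnames(qs) <- paste0("q", probs * 100)
  cbind(draws$params,
        data.frame(mean = colMeans(m), sd = apply(m, 2, sd)), qs,
        row.names = NULL)
}

#' Coefficient draws for one lake
#'
#' @param draws a `bnm_draws`.
#' @param lake lake id.
#' @return list of draw matrices (`WT`, `dWL`, `CHL`, `CATCH`), one column
#'   per coefficient, plus the `stocking` flag.
#' @export
coefficient_draws <- function(draws, lake) {
  m <- as_draw_matrix(draws)
  reg <- draws$params
  out <- lapply(setNames(.bnm_submodels, .bnm_submodels), function(sm) {
    sel <- reg$type == "beta" & reg$submodel == sm &
      !is.na(reg$lake_id) & reg$lake_id == lake
    if (!any(sel)) return(NULL)
    mm <- m[, reg$param[sel], drop = FALSE]
    colnames(mm) <- reg$term[sel]
    mm
  })
  out$stocking <- isTRUE(draws$stocking[[lake]])
  out
}
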