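#' Gelman-Rubin potential scale reduction
#'
#' The classic diagnostic computed from between- and within-chain
#' variances for every stored scalar parameter: with `m` chains of `n`
#' draws, `W` the mean within-chain variance and `B/n` the between-chain
#' variance of the chain means, the statistic is
#' `sqrt(((n-1)/n * W + B/n) / W)`. Values near 1 indicate convergence.
#'
#' @param fit a `shared_car_fit` with at least 2 chains and 10 retained
#'   draws per chain.
#' @param parameters which stored parameters to scan (default: the
#'   identified ones entering the linear predictor plus the weights).
#' @return named numeric vector of statistics, one per scalar component.
#' @export
gelman_rubin <- function(fit, parameters = c("alpha", "beta", "log_delta",
                                             "phi", "deviance")) {
  stopifnot(inherits(fit, "shared_car_fit"))
  nc <- fit$settings$n_chains
  n <- fit$settings$retained_per_chain
  check(nc >= 2, "Gelman-Rubin requires at least 2 chains")
  check(n >= 10, "Gelman-Rubin requires at least 10 retained draws per chain")
  out <- numeric(0)
  for (par in parameters) {
    if (par == "deviance") {
      mats <- list(deviance = fit$deviance)
    } else {
      if (is.null(fit$draws[[par]])) next
      pm <- pooled_draws(fit, par)
      mats <- lapply(seq_len(ncol(pm)), function(j) {
        matrix(pm[, j], n, nc)
      })
      names(mats) <- colnames(pm)
    }
    for (nm in names(mats)) {
      out[nm] <- psrf(mats[[nm]])
    }
  }
  out
}

## potential scale reduction factor for one n x m draw matrix
psrf <- function(x) {
  n <- nrow(x); m <- ncol(x)
  W <- mean(apply(x, 2, stats::var))
  B_over_n <- stats::var(colMeans(x))
  if (W == 0) return(1.0)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` where `Dbar` is the posterior mean of the deviance
#' `-2 log L` over the retained draws and `pD = Dbar - Dhat` is the
#' effective number of parameters, with `Dhat` the deviance at the
#' posterior mean of the parameters entering the likelihood (intercepts,
#' coefficients, unstructured and structured effects, shared field and
#' weights) — the plug-in construction focused at the linear-predictor
#' level. Smaller DIC indicates better fit.
#'
#' @param fit a `shared_car_fit`.
#' @return An object of class `fit_report`: list with `dic`, `dbar`, `pd`,
#'   plus the variant label and a cohort fingerprint used by
#'   [compare_variants()].
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "shared_car_fit"))
  check(length(fit$deviance) >= 1, "fit holds no retained draws")
  dbar <- mean(fit$deviance)
  state <- posterior_mean_state(fit)
  dhat <- -2 * loglik_from_data(state, fit$spec, fit$data)
  pd <- dbar - dhat
  structure(list(dic = dbar + pd, dbar = dbar, pd = pd,
                 variant = fit$spec$variant, cohort_hash = fit$cohort_hash),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit_report (%s): DIC = %.1f (Dbar = %.1f, pD = %.1f)\n",
              x$variant, x$dic, x$dbar, x$pd))
  if (!is.null(x$ppc)) cat(sprintf("  PPC coverage = %.4f\n", x$ppc))
  invisible(x)
}

## posterior means of the likelihood-level parameters, as a parameter_state.
## The weights are averaged on the natural (delta) scale since they scale
## the shared field linearly in the predictor.
posterior_mean_state <- function(fit) {
  p <- length(fit$beta_names)
  A <- fit$graph$n_areas
  st <- parameter_state(fit$spec, A, p, fit$beta_names)
  st$alpha <- colMeans(pooled_draws(fit, "alpha"))
  if (p > 0) st$beta <- matrix(colMeans(pooled_draws(fit, "beta")), p, 3)
  st$u <- matrix(colMeans(pooled_draws(fit, "u")), A, 3)
  st$s <- matrix(colMeans(pooled_draws(fit, "s")), A, 3)
  st$phi <- colMeans(pooled_draws(fit, "phi"))
  delta_bar <- colMeans(exp(pooled_draws(fit, "log_delta")))
  st$log_delta <- log(delta_bar)
  if (!is.null(fit$spec$second_shared_pair)) {
    st$phi2 <- colMeans(pooled_draws(fit, "phi2"))
    st$log_delta2 <- log(colMeans(exp(pooled_draws(fit, "log_delta2"))))
  }
  st
}

#' Posterior predictive coverage of the observed outcomes
#'
#' For every individual-by-treatment cell, replicate outcomes are
#' simulated from the Bernoulli likelihood under a random subsample of
#' retained posterior draws; the observation counts as covered when it
#' lies within the central 95 % (2.5th-97.5th percentile) range of its
#' replicate set. Returns the covered fraction. For binary replicates the
#' central range excludes an outcome only when the replicate frequency is
#' extreme, so a well-specified model yields values very near 1.
#'
#' @param fit a `shared_car_fit` with at least 100 retained draws.
#' @param n_rep number of posterior draws to subsample per cell.
#' @param seed RNG seed for subsampling and replicate simulation.
#' @return scalar proportion in `[0, 1]`.
#' @export
ppc_coverage <- function(fit, n_rep = 200, seed = 1L) {
  stopifnot(inherits(fit, "shared_car_fit"))
  check(fit$settings$retained_total >= 100, "need at least 100 retained draws")
  check(fit$data$n > 0, "empty cohort")
  n <- fit$data$n
  with_seed(seed, {
    pick <- sample.int(fit$settings$retained_total, n_rep,
                       replace = n_rep > fit$settings$retained_total)
    alpha <- pooled_draws(fit, "alpha")[pick, , drop = FALSE]
    beta <- pooled_draws(fit, "beta")[pick, , drop = FALSE]
    phi <- pooled_draws(fit, "phi")[pick, , drop = FALSE]
    sdr <- pooled_draws(fit, "s")[pick, , drop = FALSE]
    udr <- pooled_draws(fit, "u")[pick, , drop = FALSE]
    ld <- pooled_draws(fit, "log_delta")[pick, , drop = FALSE]
    if (!is.null(fit$spec$second_shared_pair)) {
      phi2 <- pooled_draws(fit, "phi2")[pick, , drop = FALSE]
      ld2 <- pooled_draws(fit, "log_delta2")[pick, , drop = FALSE]
    }
    A <- fit$graph$n_areas
    p <- length(fit$beta_names)
    ones <- matrix(0, n, 3)   # replicate frequency of 1 per cell
    for (r in seq_len(n_rep)) {
      eta <- matrix(rep(alpha[r, ], each = n), n, 3)
      if (p > 0) eta <- eta + fit$data$X %*% matrix(beta[r, ], p, 3)
      if (fit$spec$include_u) {
        eta <- eta + matrix(udr[r, ], A, 3)[fit$data$area, ]
      }
      if (fit$spec$include_shared) {
        eta <- eta + outer(phi[r, fit$data$area], exp(ld[r, ]))
      }
      if (fit$spec$include_s) {
        eta <- eta + matrix(sdr[r, ], A, 3)[fit$data$area, ]
      }
      if (!is.null(fit$spec$second_shared_pair)) {
        pr <- fit$spec$second_shared_pair
        d2 <- exp(ld2[r, ])
        eta[, pr[1]] <- eta[, pr[1]] + d2[1] * phi2[r, fit$data$area]
        eta[, pr[2]] <- eta[, pr[2]] + d2[2] * phi2[r, fit$data$area]
      }
      ones <- ones + (matrix(stats::runif(n * 3), n, 3) < inv_logit(eta))
    }
    freq <- ones / n_rep
    ## central 95% of a 0/1 replicate set: lower quantile is 1 only when
    ## the replicate frequency of ones exceeds 0.975; upper is 0 only when
    ## it falls below 0.025.
    lo <- as.numeric(freq > 0.975)
    hi <- as.numeric(freq >= 0.025)
    covered <- (fit$data$y >= lo) & (fit$data$y <= hi)
    mean(covered)
  })
}

#' Posterior odds-ratio summaries for the fixed effects
#'
#' Per design column and treatment: the posterior median odds ratio
#' `exp(beta)`, the central 95 % credible interval, and a substantive
#' flag that is `TRUE` exactly when the interval excludes unity. An
#' interval touching 1 exactly counts as including unity (conservative).
#' No multiplicity correction is applied.
#'
#' @param fit a `shared_car_fit`.
#' @return data frame with columns `treatment`, `term`, `median_or`,
#'   `cri_low`, `cri_high`, `substantive`.
#' @export
summarize_effects <- function(fit) {
  stopifnot(inherits(fit, "shared_car_fit"))
  b <- pooled_draws(fit, "beta")
  tn <- treatment_names()
  p <- length(fit$beta_names)
  out <- data.frame(
    treatment = rep(tn, each = p),
    term = rep(fit$beta_names, 3),
    stringsAsFactors = FALSE)
  or <- exp(b)
  qs <- apply(or, 2, stats::quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)
  out$median_or <- qs[1, ]
  out$cri_low <- qs[2, ]
  out$cri_high <- qs[3, ]
  out$substantive <- out$cri_low > 1 | out$cri_high < 1
  out
}

#' Relative weights of the shared component
#'
#' Draw-wise ratios of the shared-component weights —
#' `delta_chemo/delta_radio`, `delta_hormone/delta_radio` and
#' `delta_hormone/delta_chemo` — summarised by the posterior median and
#' central 95 % credible interval, with the same substantive-difference
#' flag as [summarize_effects()]. The ratios measure the relative
#' influence of the shared spatial component on each pair of treatments.
#'
#' @param fit a `shared_car_fit` whose variant has a shared component.
#' @return data frame with one row per ratio.
#' @export
relative_weights <- function(fit) {
  stopifnot(inherits(fit, "shared_car_fit"))
  check(fit$spec$include_shared, "variant has no shared component")
  ld <- pooled_draws(fit, "log_delta")
  ratios <- cbind(`chemo/radio` = exp(ld[, 2] - ld[, 1]),
                  `hormone/radio` = exp(ld[, 3] - ld[, 1]),
                  `hormone/chemo` = exp(ld[, 3] - ld[, 2]))
  qs <- apply(ratios, 2, stats::quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)
  data.frame(ratio = colnames(ratios),
             median = qs[1, ], cri_low = qs[2, ], cri_high = qs[3, ],
             substantive = qs[2, ] > 1 | qs[3, ] < 1,
             row.names = NULL, stringsAsFactors = FALSE)
}
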