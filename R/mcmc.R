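#' MCMC settings
#'
#' Chain schedule and master seed. The published full-cohort schedule is 2
#' chains of 17,500 iterations with 10,000 discarded as burn-in and a
#' thinning factor of 3: each chain retains floor(7,500 / 3) = 2,500
#' draws, 5,000 pooled over the two chains. Both the per-chain and the
#' pooled counts are recorded explicitly.
#'
#' @param n_chains number of chains (>= 1).
#' @param n_iterations iterations per chain.
#' @param burn_in iterations discarded per chain (< `n_iterations`).
#' @param thin thinning factor (>= 1).
#' @param seed master seed; all chain seeds derive from it.
#' @param adapt_interval proposal-scale adaptation cadence during burn-in.
#' @return An object of class `mcmc_settings` with derived fields
#'   `retained_per_chain` and `retained_total`.
#' @export
mcmc_settings <- function(n_chains = 2, n_iterations = 17500, burn_in = 10000,
                          thin = 3, seed = 1L, adapt_interval = 50L) {
  check(n_chains >= 1, "n_chains must be >= 1")
  check(thin >= 1, "thin must be >= 1")
  check(burn_in >= 0 && burn_in < n_iterations, "burn_in must be < n_iterations")
  ret <- (n_iterations - burn_in) %/% thin
  check(ret >= 1, "no draws retained under these settings")
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 adapt_interval = as.integer(adapt_interval),
                 retained_per_chain = as.integer(ret),
                 retained_total = as.integer(ret * n_chains)),
            class = "mcmc_settings")
}

#' @export
print.mcmc_settings <- function(x, ...) {
  cat(sprintf("mcmc_settings: %d chain(s) x %d iterations, burn-in %d, thin %d\n",
              x$n_chains, x$n_iterations, x$burn_in, x$thin))
  cat(sprintf("  retained: %d per chain, %d pooled; seed %d\n",
              x$retained_per_chain, x$retained_total, x$seed))
  invisible(x)
}

#' Published chain schedules
#'
#' Full-cohort default: 2 chains, 17,500 iterations, 10,000 burn-in,
#' thinning 3 (5,000 pooled retained draws). Sub-cohort default: 2
#' chains, 37,500 iterations, 30,000 burn-in, thinning 3.
#'
#' @param sub_cohort logical; use the longer sub-cohort schedule.
#' @param seed master seed.
#' @return An `mcmc_settings`.
#' @export
default_settings <- function(sub_cohort = FALSE, seed = 1L) {
  if (sub_cohort) mcmc_settings(2, 37500, 30000, 3, seed = seed)
  else mcmc_settings(2, 17500, 10000, 3, seed = seed)
}

## over-dispersed chain initialisation; spread grows with the chain index
initial_state <- function(chain, spec, A, p) {
  sf <- 0.5 + 0.5 * chain
  list(alpha = stats::rnorm(3, 0, 0.3 * sf),
       beta = matrix(stats::rnorm(p * 3, 0, 0.2 * sf), p, 3),
       u = matrix(if (spec$include_u) stats::rnorm(A * 3, 0, 0.1 * sf) else 0, A, 3),
       s = matrix(if (spec$include_s) stats::rnorm(A * 3, 0, 0.1 * sf) else 0, A, 3),
       phi = if (spec$include_shared) stats::rnorm(A, 0, 0.1 * sf) else numeric(A),
       nu = if (spec$include_shared) stats::rnorm(2, 0, 0.2 * sf) else numeric(2),
       phi2 = if (!is.null(spec$second_shared_pair)) stats::rnorm(A, 0, 0.1 * sf) else numeric(A),
       nu2 = if (!is.null(spec$second_shared_pair)) stats::rnorm(1, 0, 0.2 * sf) else 0,
       tau_phi = exp(stats::rnorm(1, log(10), 0.3 * sf)),
       tau_s = exp(stats::rnorm(3, log(10), 0.3 * sf)),
       tau_alpha = exp(stats::rnorm(1, 0, 0.3 * sf)),
       tau_beta = exp(stats::rnorm(3, 0, 0.3 * sf)),
       tau_u = exp(stats::rnorm(3, log(10), 0.3 * sf)),
       tau_phi2 = exp(stats::rnorm(1, log(10), 0.3 * sf)),
       P = diag(3) * exp(stats::rnorm(1, log(10), 0.3 * sf)))
}

#' Fit the shared spatial-component model by MCMC
#'
#' Metropolis-within-Gibbs sampling of the posterior of the variant
#' described by `spec`: adaptive single-site random-walk updates for the
#' intercepts, coefficients, unstructured effects, CAR fields and free
#' log-weights, with conjugate Gibbs draws for every precision. Every
#' retained draw satisfies the identifiability constraints (per-component
#' sum-to-zero CAR fields, product-one weights). Chains are initialised
#' over-dispersed, with spread growing in the chain index, and all
#' randomness derives from `settings$seed`, so a rerun with the same seed
#' is identical.
#'
#' @param spec a `model_spec`.
#' @param cohort cohort data frame or `synthetic_cohort`.
#' @param graph an `area_graph` containing every cohort area.
#' @param settings an `mcmc_settings`.
#' @param schema a `covariate_schema`.
#' @param drop_covariates covariates omitted from the design (sub-cohort
#'   analyses drop the covariate that defines the sub-cohort).
#' @return An object of class `shared_car_fit`: retained draws per chain
#'   for every parameter (`$draws`, arrays indexed draw x chain x ...),
#'   per-draw deviance, the spec, settings, design column names, graph
#'   and the data used.
#' @export
run_mcmc <- function(spec, cohort, graph, settings = default_settings(),
                     schema = default_schema(), drop_covariates = character(0)) {
  stopifnot(inherits(spec, "model_spec"), inherits(graph, "area_graph"),
            inherits(settings, "mcmc_settings"))
  dat <- model_data(cohort, graph, schema, drop_covariates)
  check(all(dat$X %in% c(0, 1)), "design must be 0/1 dummy-coded")
  A <- graph$n_areas
  p <- ncol(dat$X)
  area0 <- dat$area - 1L
  area_rows <- lapply(seq_len(A), function(a) which(dat$area == a) - 1L)
  col_rows <- lapply(seq_len(p), function(m) which(dat$X[, m] != 0) - 1L)
  flags <- list(include_u = spec$include_u,
                u_mvn = spec$u_prior == "multivariate",
                include_s = spec$include_s,
                include_shared = spec$include_shared,
                flat_fixed = spec$fixed_effect_prior == "flat",
                pair = if (is.null(spec$second_shared_pair)) integer(0)
                       else as.integer(spec$second_shared_pair - 1L))
  chain_seeds <- split_seed(settings$seed, settings$n_chains)
  chains <- vector("list", settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    chains[[ch]] <- with_seed(chain_seeds[ch], {
      init <- initial_state(ch, spec, A, p)
      mcmc_chain_cpp(dat$y, dat$X, area0, area_rows, col_rows,
                     lapply(graph$neighbours, function(v) as.integer(v - 1L)),
                     as.integer(graph$component_labels - 1L),
                     graph$n_components,
                     init, flags, spec$hyper,
                     settings$n_iterations, settings$burn_in, settings$thin,
                     settings$adapt_interval)
    })
  }
  n_ret <- settings$retained_per_chain
  nc <- settings$n_chains
  bind <- function(name, dims) {
    arr <- array(NA_real_, c(n_ret, nc, dims))
    for (ch in seq_len(nc)) {
      m <- chains[[ch]][[name]]
      arr[slice.index(arr, 2) == ch] <- as.vector(array(m, c(n_ret, dims)))
    }
    arr
  }
  draws <- list(
    alpha = bind("alpha", 3),
    beta = bind("beta", c(p, 3)),
    log_delta = bind("log_delta", 3),
    phi = bind("phi", A),
    s = bind("s", c(A, 3)),
    u = bind("u", c(A, 3)),
    Sigma_u_prec = bind("Sigma_u_prec", c(3, 3)),
    tau_u = bind("tau_u", 3))
  tau <- bind("tau", 9)
  draws$tau_phi <- tau[, , 1, drop = FALSE]; dim(draws$tau_phi) <- c(n_ret, nc)
  draws$tau_s <- tau[, , 2:4, drop = FALSE]; dim(draws$tau_s) <- c(n_ret, nc, 3)
  draws$tau_alpha <- tau[, , 5, drop = FALSE]; dim(draws$tau_alpha) <- c(n_ret, nc)
  draws$tau_beta <- tau[, , 6:8, drop = FALSE]; dim(draws$tau_beta) <- c(n_ret, nc, 3)
  draws$tau_phi2 <- tau[, , 9, drop = FALSE]; dim(draws$tau_phi2) <- c(n_ret, nc)
  if (!is.null(spec$second_shared_pair)) {
    draws$phi2 <- bind("phi2", A)
    draws$log_delta2 <- bind("log_delta2", 2)
  }
  deviance <- bind("deviance", 1)
  dim(deviance) <- c(n_ret, nc)
  structure(
    list(draws = draws, deviance = deviance, spec = spec, settings = settings,
         beta_names = dat$beta_names, graph = graph,
         schema = schema, drop_covariates = drop_covariates,
         data = dat, chain_seeds = chain_seeds,
         cohort_hash = cohort_hash(dat)),
    class = "shared_car_fit")
}

## stable fingerprint of the fitted data, for cross-report consistency checks
cohort_hash <- function(dat) {
  v <- c(dim(dat$y), sum(dat$y), dim(dat$X), round(sum(dat$X), 6),
         sum(dat$area), length(dat$beta_names))
  paste(v, collapse = "-")
}

#' @export
print.shared_car_fit <- function(x, ...) {
  cat("shared_car_fit:", x$spec$variant, "variant,",
      x$data$n, "individuals,", x$graph$n_areas, "areas\n")
  print(x$settings)
  cat("  design columns:", length(x$beta_names), "\n")
  invisible(x)
}

#' Pooled posterior draws of one parameter
#'
#' Stacks the retained draws of all chains into a matrix with one row per
#' draw. Vector/matrix parameters are flattened column-major; `beta`
#' columns are labelled `<treatment>:<term>`.
#'
#' @param fit a `shared_car_fit`.
#' @param parameter name of a stored parameter (e.g. `"beta"`, `"phi"`,
#'   `"log_delta"`).
#' @return numeric matrix, `retained_total` rows.
#' @export
pooled_draws <- function(fit, parameter) {
  stopifnot(inherits(fit, "shared_car_fit"))
  arr <- fit$draws[[parameter]]
  check(!is.null(arr), "no stored draws for parameter %s", parameter)
  d <- dim(arr)
  n_ret <- d[1]; nc <- d[2]
  flat <- if (length(d) == 2) 1 else prod(d[-(1:2)])
  m <- do.call(rbind, lapply(seq_len(nc), function(ch) {
    matrix(array(arr, c(n_ret, nc, flat))[, ch, ], n_ret, flat)
  }))
  colnames(m) <- parameter_labels(fit, parameter, flat)
  m
}

parameter_labels <- function(fit, parameter, flat) {
  A <- fit$graph$n_areas
  tn <- treatment_names()
  switch(parameter,
         alpha = paste0("alpha:", tn),
         beta = as.vector(outer(fit$beta_names, tn,
                                function(b, t) paste0(t, ":", b))),
         log_delta = paste0("log_delta:", tn),
         phi = paste0("phi:", fit$graph$area_ids),
         phi2 = paste0("phi2:", fit$graph$area_ids),
         s = as.vector(outer(fit$graph$area_ids, tn,
                             function(a, t) paste0("s:", t, ":", a))),
         u = as.vector(outer(fit$graph$area_ids, tn,
                             function(a, t) paste0("u:", t, ":", a))),
         Sigma_u_prec = paste0("Sigma_u_prec:", as.vector(outer(1:3, 1:3, paste, sep = ","))),
         tau_s = paste0("tau_s:", tn),
         tau_beta = paste0("tau_beta:", tn),
         tau_u = paste0("tau_u:", tn),
         log_delta2 = paste0("log_delta2:", 1:2),
         rep(parameter, flat))
}

#' Persist posterior draws as per-parameter CSV files plus a manifest
#'
#' Each parameter is written as `<dir>/<parameter>.csv` with columns
#' `draw`, `chain` and one column per scalar component; `manifest.json`
#' records the variant, settings, seed and design columns.
#'
#' @param fit a `shared_car_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_samples <- function(fit, dir) {
  stopifnot(inherits(fit, "shared_car_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_ret <- fit$settings$retained_per_chain
  nc <- fit$settings$n_chains
  idx <- data.frame(draw = rep(seq_len(n_ret), nc),
                    chain = rep(seq_len(nc), each = n_ret))
  for (nm in names(fit$draws)) {
    m <- pooled_draws(fit, nm)
    utils::write.csv(cbind(idx, as.data.frame(m)),
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  utils::write.csv(cbind(idx, deviance = as.vector(fit$deviance)),
                   file.path(dir, "deviance.csv"), row.names = FALSE)
  manifest <- list(variant = fit$spec$variant,
                   settings = unclass(fit$settings),
                   chain_seeds = fit$chain_seeds,
                   beta_names = fit$beta_names,
                   n_areas = fit$graph$n_areas,
                   drop_covariates = fit$drop_covariates,
                   cohort_hash = fit$cohort_hash)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
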