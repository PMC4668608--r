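#' Model specification for the shared spatial-component model
#'
#' The baseline model (variant `"A0"`) for three binary treatment
#' intentions is, for individual `j` in area `i` and treatment `k`,
#' \deqn{Y_{ijk} \sim Bernoulli(p_{ijk}), \quad
#'   logit(p_{ijk}) = \alpha_k + \beta_k' X_{ij} + u_{ik} +
#'   \delta_k \phi_i + s_{ik},}
#' with an intrinsic CAR prior on the shared field `phi` and on each
#' treatment-specific field `s_k`, a trivariate Gaussian prior with
#' Wishart-distributed precision on the rows of `u`, product-one positive
#' weights `delta`, hierarchical Gaussian priors on `alpha` and `beta`
#' whose precisions carry Gamma(0.005, 0.5) hyperpriors (shape/rate), and
#' Gamma(0.5, 0.005) hyperpriors on the CAR precisions. Log-weights carry
#' Gaussian priors with precision 5.9.
#'
#' Variants alter exactly one ingredient:
#' \describe{
#'   \item{A1}{independent Gaussian priors on each `u` column (no Wishart).}
#'   \item{A2/A3/A4}{a second shared CAR field for the treatment pair
#'     radio+chemo / radio+hormone / chemo+hormone.}
#'   \item{A5}{no unstructured effect `u`.}
#'   \item{A6}{no treatment-specific structured effect `s`.}
#'   \item{A7}{flat fixed-effect priors: Gaussian with fixed precision 1e-4
#'     on `alpha` and `beta`, no hyperprior.}
#' }
#'
#' @param variant one of `"A0"` ... `"A7"`.
#' @param include_shared set `FALSE` to drop the shared component entirely
#'   (outside the published variant set; useful for degenerate checks).
#' @param include_u,include_s optional logical overrides of the variant's
#'   effect-term flags, for degenerate configurations such as a plain
#'   logistic model with every spatial term disabled.
#' @param hyper named list overriding hyperparameters: `a_fixed`,
#'   `b_fixed` (fixed-effect precision Gamma shape/rate), `a_car`, `b_car`
#'   (CAR precision Gamma shape/rate), `wishart_df`, `wishart_scale`,
#'   `prec_log_delta`, `flat_prec`, `a_u`, `b_u` (independent-u precisions
#'   under A1).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(variant = "A0", include_shared = TRUE,
                       include_u = NULL, include_s = NULL, hyper = list()) {
  check(variant %in% paste0("A", 0:7), "variant must be one of A0..A7")
  h <- list(a_fixed = 0.005, b_fixed = 0.5,
            a_car = 0.5, b_car = 0.005,
            wishart_df = 5, wishart_scale = diag(3),
            prec_log_delta = 5.9, flat_prec = 1e-4,
            a_u = 0.5, b_u = 0.005)
  bad <- setdiff(names(hyper), names(h))
  check(length(bad) == 0, "unknown hyperparameters: %s", paste(bad, collapse = ", "))
  h[names(hyper)] <- hyper
  pair <- switch(variant, A2 = c(1L, 2L), A3 = c(1L, 3L), A4 = c(2L, 3L), NULL)
  structure(
    list(variant = variant,
         include_u = if (is.null(include_u)) variant != "A5" else isTRUE(include_u),
         u_prior = if (variant == "A1") "independent" else "multivariate",
         include_s = if (is.null(include_s)) variant != "A6" else isTRUE(include_s),
         include_shared = isTRUE(include_shared),
         second_shared_pair = pair,
         fixed_effect_prior = if (variant == "A7") "flat" else "hierarchical",
         hyper = h),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec", x$variant, "\n")
  cat("  unstructured u:", if (!x$include_u) "absent" else x$u_prior, "\n")
  cat("  specific s:", if (x$include_s) "present" else "absent",
      "| shared phi:", if (x$include_shared) "present" else "absent", "\n")
  if (!is.null(x$second_shared_pair)) {
    cat("  second shared component:",
        paste(treatment_names()[x$second_shared_pair], collapse = "+"), "\n")
  }
  cat("  fixed-effect prior:", x$fixed_effect_prior, "\n")
  invisible(x)
}

#' Serialise / read a model specification as JSON
#' @param spec a `model_spec`.
#' @param path file path.
#' @return `path` invisibly, or the `model_spec` read back.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  obj <- list(variant = spec$variant, include_shared = spec$include_shared,
              hyper = spec$hyper)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hyper <- obj$hyper
  if (!is.null(hyper$wishart_scale)) hyper$wishart_scale <- as.matrix(hyper$wishart_scale)
  model_spec(obj$variant, include_shared = isTRUE(obj$include_shared), hyper = hyper)
}

#' Parameter state of the shared spatial-component model
#'
#' A plain container for one full set of parameter values, used by the
#' likelihood/prior functions and as an MCMC initial state. All fields
#' absent under a variant are held at zero.
#'
#' @param spec a `model_spec`.
#' @param n_areas number of areas.
#' @param p number of design columns.
#' @param beta_names optional design column names.
#' @return An object of class `parameter_state` with fields `alpha` (3),
#'   `beta` (p x 3), `u`, `s` (n_areas x 3), `phi` (n_areas), `log_delta`
#'   (3, summing to 0), `phi2`/`log_delta2` (second shared component, when
#'   present), precisions `tau_phi`, `tau_s` (3), `tau_alpha`, `tau_beta`
#'   (3), `tau_u` (3), `tau_phi2`, and `Sigma_u_prec` (3 x 3).
#' @export
parameter_state <- function(spec, n_areas, p, beta_names = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  beta <- matrix(0, p, 3)
  if (!is.null(beta_names)) rownames(beta) <- beta_names
  colnames(beta) <- treatment_names()
  structure(
    list(alpha = numeric(3),
         beta = beta,
         u = matrix(0, n_areas, 3),
         s = matrix(0, n_areas, 3),
         phi = numeric(n_areas),
         log_delta = numeric(3),
         phi2 = if (!is.null(spec$second_shared_pair)) numeric(n_areas) else NULL,
         log_delta2 = if (!is.null(spec$second_shared_pair)) numeric(2) else NULL,
         tau_phi = 1, tau_s = rep(1, 3),
         tau_alpha = 1, tau_beta = rep(1, 3),
         tau_u = rep(1, 3), tau_phi2 = 1,
         Sigma_u_prec = diag(3)),
    class = "parameter_state")
}

#' Linear predictor for one individual, area and treatment
#'
#' Returns `alpha_k + beta_k' x + u_ik + delta_k phi_i + s_ik` plus the
#' second shared term when the variant has one and `k` belongs to the
#' designated pair; terms absent under the variant contribute zero.
#'
#' @param state a `parameter_state`.
#' @param spec a `model_spec`.
#' @param x dummy-coded covariate vector (length p).
#' @param area area index (1-based).
#' @param k treatment index in 1..3.
#' @return the logit of the outcome probability.
#' @export
linear_predictor <- function(state, spec, x, area, k) {
  stopifnot(inherits(state, "parameter_state"), inherits(spec, "model_spec"))
  check(k %in% 1:3, "treatment index k must be in 1..3")
  check(length(x) == nrow(state$beta), "x has length %d, design has %d columns",
        length(x), nrow(state$beta))
  check(area >= 1 && area <= length(state$phi), "area index out of range")
  eta <- state$alpha[k] + sum(state$beta[, k] * x)
  if (spec$include_u) eta <- eta + state$u[area, k]
  if (spec$include_shared) eta <- eta + exp(state$log_delta[k]) * state$phi[area]
  if (spec$include_s) eta <- eta + state$s[area, k]
  pr <- spec$second_shared_pair
  if (!is.null(pr) && k %in% pr) {
    eta <- eta + exp(state$log_delta2[match(k, pr)]) * state$phi2[area]
  }
  eta
}

## n x 3 matrix of linear predictors for a whole design at once
compute_eta <- function(state, spec, X, area) {
  n <- nrow(X)
  eta <- matrix(rep(state$alpha, each = n), n, 3) + X %*% state$beta
  if (spec$include_u) eta <- eta + state$u[area, , drop = FALSE]
  if (spec$include_shared) {
    eta <- eta + outer(state$phi[area], exp(state$log_delta))
  }
  if (spec$include_s) eta <- eta + state$s[area, , drop = FALSE]
  pr <- spec$second_shared_pair
  if (!is.null(pr)) {
    d2 <- exp(state$log_delta2)
    eta[, pr[1]] <- eta[, pr[1]] + d2[1] * state$phi2[area]
    eta[, pr[2]] <- eta[, pr[2]] + d2[2] * state$phi2[area]
  }
  eta
}

## Assemble the numeric pieces of a fit: outcome matrix, design, area index
model_data <- function(cohort, graph, schema = default_schema(),
                       drop_covariates = character(0)) {
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$cohort
  stopifnot(inherits(graph, "area_graph"))
  y <- as.matrix(cohort[c("y_radio", "y_chemo", "y_hormone")])
  check(all(y %in% c(0, 1)), "outcomes must be exactly 0 or 1")
  area <- match(as.character(cohort$area_id), graph$area_ids)
  check(!anyNA(area), "cohort area ids not all present in the graph")
  X <- build_design(cohort, schema, drop_covariates)
  list(y = y, X = X, area = area, beta_names = colnames(X), n = nrow(X))
}

#' Bernoulli log-likelihood of the full cohort
#'
#' Sum over individuals and treatments of
#' `y * log(p) + (1 - y) * log(1 - p)` with `p` the inverse logit of the
#' linear predictor under the given state and variant.
#'
#' @param state a `parameter_state`.
#' @param spec a `model_spec`.
#' @param cohort cohort data frame or `synthetic_cohort`.
#' @param graph an `area_graph`.
#' @param schema a `covariate_schema`.
#' @param drop_covariates covariates omitted from the design.
#' @return the log-likelihood (0 for an empty cohort).
#' @export
model_log_likelihood <- function(state, spec, cohort, graph,
                                 schema = default_schema(),
                                 drop_covariates = character(0)) {
  dat <- model_data(cohort, graph, schema, drop_covariates)
  loglik_from_data(state, spec, dat)
}

loglik_from_data <- function(state, spec, dat) {
  if (dat$n == 0) return(0)
  eta <- compute_eta(state, spec, dat$X, dat$area)
  sum(dat$y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))
}

## log of the multivariate gamma function
lmvgamma <- function(p, a) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

## Wishart log-density in the shape/rate-style parameterisation used by
## BUGS-family software: dwish(R, k) has density proportional to
## |P|^{(k-p-1)/2} exp(-tr(R P)/2); its mean is k R^{-1}.
dwishart_log <- function(P, R, df) {
  p <- nrow(P)
  ldP <- determinant(P, logarithm = TRUE)$modulus
  ldR <- determinant(R, logarithm = TRUE)$modulus
  as.numeric(((df - p - 1) / 2) * ldP - 0.5 * sum(diag(R %*% P)) +
               (df / 2) * ldR - (df * p / 2) * log(2) - lmvgamma(p, df / 2))
}

#' Joint log-prior of a parameter state
#'
#' Sums every prior term active under the variant: hierarchical Gaussian
#' priors on `alpha` and `beta` with Gamma(0.005, 0.5) precision
#' hyperpriors (or fixed precision 1e-4 under A7); the Wishart(I, 5)
#' precision and trivariate Gaussian rows of `u` (or independent Gaussians
#' with Gamma hyperpriors under A1); Gaussian(0, precision 5.9) priors on
#' the free log-weights; and intrinsic CAR terms via [car_log_density()]
#' with Gamma(0.5, 0.005) hyperpriors on each CAR precision. Constant in
#' the CAR normalising term beyond `(rank/2) log tau`.
#'
#' @inheritParams linear_predictor
#' @param graph an `area_graph`.
#' @return the joint log-prior, up to the additive constant of the
#'   intrinsic CAR terms.
#' @export
model_log_prior <- function(state, spec, graph) {
  stopifnot(inherits(state, "parameter_state"), inherits(spec, "model_spec"),
            inherits(graph, "area_graph"))
  h <- spec$hyper
  lp <- 0
  ## fixed effects
  if (spec$fixed_effect_prior == "flat") {
    sd0 <- 1 / sqrt(h$flat_prec)
    lp <- lp + sum(stats::dnorm(state$alpha, 0, sd0, log = TRUE))
    lp <- lp + sum(stats::dnorm(state$beta, 0, sd0, log = TRUE))
  } else {
    check(state$tau_alpha > 0 && all(state$tau_beta > 0),
          "fixed-effect precisions must be positive")
    lp <- lp + sum(stats::dnorm(state$alpha, 0, 1 / sqrt(state$tau_alpha), log = TRUE)) +
      stats::dgamma(state$tau_alpha, h$a_fixed, rate = h$b_fixed, log = TRUE)
    for (k in 1:3) {
      lp <- lp + sum(stats::dnorm(state$beta[, k], 0, 1 / sqrt(state$tau_beta[k]),
                                  log = TRUE)) +
        stats::dgamma(state$tau_beta[k], h$a_fixed, rate = h$b_fixed, log = TRUE)
    }
  }
  ## unstructured effects
  if (spec$include_u) {
    A <- nrow(state$u)
    if (spec$u_prior == "multivariate") {
      P <- state$Sigma_u_prec
      ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
      check(all(ev > 0), "Sigma_u_prec must be positive definite")
      ldP <- determinant(P, logarithm = TRUE)$modulus
      quad <- sum((state$u %*% P) * state$u)
      lp <- lp + A * (0.5 * as.numeric(ldP) - 1.5 * log(2 * pi)) - 0.5 * quad
      lp <- lp + dwishart_log(P, h$wishart_scale, h$wishart_df)
    } else {
      for (k in 1:3) {
        check(state$tau_u[k] > 0, "tau_u must be positive")
        lp <- lp + sum(stats::dnorm(state$u[, k], 0, 1 / sqrt(state$tau_u[k]),
                                    log = TRUE)) +
          stats::dgamma(state$tau_u[k], h$a_u, rate = h$b_u, log = TRUE)
      }
    }
  }
  ## shared component and weights
  if (spec$include_shared) {
    check(abs(sum(state$log_delta)) < 1e-9, "log_delta must sum to 0")
    lp <- lp + car_log_density(state$phi, state$tau_phi, graph) +
      stats::dgamma(state$tau_phi, h$a_car, rate = h$b_car, log = TRUE)
    lp <- lp + sum(stats::dnorm(state$log_delta[1:2], 0,
                                1 / sqrt(h$prec_log_delta), log = TRUE))
  }
  ## treatment-specific structured effects
  if (spec$include_s) {
    for (k in 1:3) {
      lp <- lp + car_log_density(state$s[, k], state$tau_s[k], graph) +
        stats::dgamma(state$tau_s[k], h$a_car, rate = h$b_car, log = TRUE)
    }
  }
  ## second shared component
  if (!is.null(spec$second_shared_pair)) {
    check(abs(sum(state$log_delta2)) < 1e-9, "log_delta2 must sum to 0")
    lp <- lp + car_log_density(state$phi2, state$tau_phi2, graph) +
      stats::dgamma(state$tau_phi2, h$a_car, rate = h$b_car, log = TRUE)
    lp <- lp + stats::dnorm(state$log_delta2[1], 0,
                            1 / sqrt(h$prec_log_delta), log = TRUE)
  }
  lp
}

#' Enforce the model's identifiability constraints on a state
#'
#' Centres the shared field, each treatment-specific field and any second
#' shared field to sum to zero within every connected component, and
#' projects the log-weights so they sum to zero (equivalently the weights
#' have unit product). Idempotent.
#'
#' @inheritParams model_log_prior
#' @return the constrained `parameter_state`.
#' @export
apply_constraints <- function(state, graph) {
  stopifnot(inherits(state, "parameter_state"), inherits(graph, "area_graph"))
  state$phi <- center_sum_to_zero(state$phi, graph)
  for (k in 1:3) state$s[, k] <- center_sum_to_zero(state$s[, k], graph)
  state$log_delta <- state$log_delta - mean(state$log_delta)
  if (!is.null(state$phi2)) {
    state$phi2 <- center_sum_to_zero(state$phi2, graph)
    state$log_delta2 <- state$log_delta2 - mean(state$log_delta2)
  }
  state
}
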