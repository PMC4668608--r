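test_that("variant flags resolve as specified", {
  a0 <- model_spec("A0")
  expect_true(a0$include_u && a0$include_s && a0$include_shared)
  expect_equal(a0$u_prior, "multivariate")
  expect_null(a0$second_shared_pair)
  expect_equal(a0$fixed_effect_prior, "hierarchical")
  expect_equal(model_spec("A1")$u_prior, "independent")
  expect_equal(model_spec("A2")$second_shared_pair, c(1L, 2L))
  expect_equal(model_spec("A3")$second_shared_pair, c(1L, 3L))
  expect_equal(model_spec("A4")$second_shared_pair, c(2L, 3L))
  expect_false(model_spec("A5")$include_u)
  expect_false(model_spec("A6")$include_s)
  expect_equal(model_spec("A7")$fixed_effect_prior, "flat")
  expect_error(model_spec("A8"), "variant")
  expect_error(model_spec("A0", hyper = list(bogus = 1)), "unknown")
  # JSON round trip
  sp <- model_spec("A3", hyper = list(b_car = 0.05, prec_log_delta = 2.9))
  path <- tempfile(fileext = ".json")
  write_model_spec(sp, path)
  back <- read_model_spec(path)
  expect_equal(back$variant, "A3")
  expect_equal(back$hyper$b_car, 0.05)
  expect_equal(back$hyper$prec_log_delta, 2.9)
})

test_that("linear_predictor sums exactly the active terms", {
  spec <- model_spec("A0")
  st <- parameter_state(spec, n_areas = 4, p = 2)
  expect_equal(linear_predictor(st, spec, c(0, 0), 1, 1), 0)
  # alpha = 1, delta_1 = 2, phi = 0.5 -> logit 2
  st$alpha[1] <- 1
  st$log_delta <- c(log(2), -log(2), 0)
  st$phi[2] <- 0.5
  expect_equal(linear_predictor(st, spec, c(0, 0), 2, 1), 2)
  expect_error(linear_predictor(st, spec, c(0, 0), 2, 4), "1..3")
  expect_error(linear_predictor(st, spec, c(0, 0, 1), 2, 1), "length")
  # independently coded dot-product oracle on random states
  set.seed(99)
  for (rep in 1:20) {
    st <- parameter_state(spec, 4, 2)
    st$alpha <- rnorm(3); st$beta[] <- rnorm(6)
    st$u[] <- rnorm(12); st$s[] <- rnorm(12); st$phi <- rnorm(4)
    ld <- rnorm(2); st$log_delta <- c(ld, -sum(ld))
    x <- rbinom(2, 1, 0.5); a <- sample(4, 1); k <- sample(3, 1)
    oracle <- unname(st$alpha[k] + st$beta[1, k] * x[1] + st$beta[2, k] * x[2] +
      st$u[a, k] + exp(st$log_delta[k]) * st$phi[a] + st$s[a, k])
    expect_equal(linear_predictor(st, spec, x, a, k), oracle, tolerance = 1e-12)
  }
})

test_that("log-likelihood matches a per-row Bernoulli oracle", {
  g <- path3_graph()
  spec <- model_spec("A0")
  # one reference-level individual: every design column empty, p = 0
  st0 <- parameter_state(spec, 3, 0)
  one <- cohort_from_y(matrix(c(1L, 0L, 1L), 1), "a")
  expect_equal(suppressWarnings(model_log_likelihood(st0, spec, one, g)),
               3 * log(0.5))
  st30 <- parameter_state(spec, 3, length(design_columns(default_schema())))
  empty <- model_log_likelihood(st30, spec, cohort_from_y(matrix(0L, 0, 3), "a"), g)
  expect_equal(empty, 0)
  # random states vs dbinom on each cell
  set.seed(17)
  sim <- generate_cohort(truth_config(n_individuals = 20, seed = 4),
                         graph = g)
  X <- suppressWarnings(build_design(sim$cohort))
  p <- ncol(X)
  st <- parameter_state(spec, 3, p, colnames(X))
  st$alpha <- rnorm(3); st$beta[] <- rnorm(p * 3, 0, 0.4)
  st$u[] <- rnorm(9, 0, 0.3); st$s[] <- rnorm(9, 0, 0.3); st$phi <- rnorm(3)
  ld <- rnorm(2, 0, 0.3); st$log_delta <- c(ld, -sum(ld))
  a <- match(sim$cohort$area_id, g$area_ids)
  oracle <- 0
  for (j in 1:20) for (k in 1:3) {
    eta <- linear_predictor(st, spec, X[j, ], a[j], k)
    y <- sim$cohort[j, c("y_radio", "y_chemo", "y_hormone")][[k]]
    oracle <- oracle + dbinom(y, 1, plogis(eta), log = TRUE)
  }
  expect_equal(suppressWarnings(model_log_likelihood(st, spec, sim$cohort, g)),
               unname(oracle), tolerance = 1e-10)
  bad <- sim$cohort; bad$y_radio[1] <- 2L
  expect_error(suppressWarnings(model_log_likelihood(st, spec, bad, g)), "0 or 1")
})

test_that("Wishart prior term matches a textbook density oracle", {
  # oracle written directly from the |R|^{k/2}|P|^{(k-p-1)/2}exp(-tr(RP)/2)
  # normalised form, independent of the package implementation
  oracle <- function(P, R, k) {
    p <- nrow(P)
    lmg <- p * (p - 1) / 4 * log(pi) +
      sum(lgamma(k / 2 + (1 - seq_len(p)) / 2))
    k / 2 * log(det(R)) + (k - p - 1) / 2 * log(det(P)) -
      sum(diag(R %*% P)) / 2 - k * p / 2 * log(2) - lmg
  }
  set.seed(31)
  for (rep in 1:10) {
    Z <- matrix(rnorm(9), 3)
    P <- crossprod(Z) + diag(3)
    expect_equal(sharedCAR:::dwishart_log(P, diag(3), 5),
                 oracle(P, diag(3), 5), tolerance = 1e-9)
  }
})

test_that("log-prior CAR term responds to tau exactly as car_log_density", {
  g <- grid_graph(4, 4)
  spec <- model_spec("A0")
  st <- parameter_state(spec, 16, 2)
  set.seed(3)
  st$phi <- center_sum_to_zero(rnorm(16), g)
  st2 <- st; st2$tau_phi <- 2 * st$tau_phi
  delta_prior <- model_log_prior(st2, spec, g) - model_log_prior(st, spec, g)
  delta_car <- car_log_density(st$phi, st2$tau_phi, g) -
    car_log_density(st$phi, st$tau_phi, g)
  delta_hyper <- dgamma(st2$tau_phi, 0.5, rate = 0.005, log = TRUE) -
    dgamma(st$tau_phi, 0.5, rate = 0.005, log = TRUE)
  expect_equal(delta_prior, delta_car + delta_hyper, tolerance = 1e-9)
})

test_that("log-prior differences in spatial terms are identical across A0 and A7", {
  # the flat-prior variant alters only the alpha/beta terms
  g <- grid_graph(3, 3)
  set.seed(23)
  phi_a <- center_sum_to_zero(rnorm(9), g)
  phi_b <- center_sum_to_zero(rnorm(9), g)
  s_b <- center_sum_to_zero(rnorm(9), g)
  d_by_variant <- vapply(c("A0", "A7"), function(variant) {
    spec <- model_spec(variant)
    st <- parameter_state(spec, 9, 2)
    st$phi <- phi_a
    st2 <- st
    st2$phi <- phi_b
    st2$s[, 2] <- s_b
    model_log_prior(st2, spec, g) - model_log_prior(st, spec, g)
  }, 0)
  expect_equal(d_by_variant[["A0"]], d_by_variant[["A7"]], tolerance = 1e-9)
})

test_that("variant predictors reduce exactly to A0 with terms zeroed", {
  g <- grid_graph(3, 3)
  set.seed(71)
  sim <- generate_cohort(truth_config(n_individuals = 40, seed = 6), graph = g)
  p <- ncol(suppressWarnings(build_design(sim$cohort)))
  rnd_state <- function(spec) {
    st <- parameter_state(spec, 9, p)
    st$alpha <- rnorm(3); st$beta[] <- rnorm(p * 3, 0, 0.3)
    st$u[] <- rnorm(27, 0, 0.3); st$s[] <- rnorm(27, 0, 0.3)
    st$phi <- rnorm(9)
    ld <- rnorm(2, 0, 0.3); st$log_delta <- c(ld, -sum(ld))
    st
  }
  st <- rnd_state(model_spec("A0"))
  ll <- function(state, spec) {
    suppressWarnings(model_log_likelihood(state, spec, sim$cohort, g))
  }
  # A5: no u
  st5 <- st; st5$u[] <- 0
  expect_equal(ll(st, model_spec("A5")), ll(st5, model_spec("A0")))
  # A6: no s -> eta is delta_k phi_i plus non-spatial terms
  st6 <- st; st6$s[] <- 0
  expect_equal(ll(st, model_spec("A6")), ll(st6, model_spec("A0")))
})

test_that("apply_constraints projects and is idempotent", {
  g <- two_component_graph()
  spec <- model_spec("A2")
  st <- parameter_state(spec, 5, 2)
  st$log_delta <- c(0.3, -0.1, -0.2)
  expect_equal(apply_constraints(st, g)$log_delta, c(0.3, -0.1, -0.2))
  st$log_delta <- c(1, 1, 1)
  expect_equal(apply_constraints(st, g)$log_delta, c(0, 0, 0))
  set.seed(12)
  st$phi <- rnorm(5); st$s[] <- rnorm(15); st$phi2 <- rnorm(5)
  st$log_delta <- rnorm(3); st$log_delta2 <- rnorm(2)
  once <- apply_constraints(st, g)
  expect_equal(apply_constraints(once, g), once)
  for (cc in 1:2) {
    idx <- g$component_labels == cc
    expect_lt(abs(sum(once$phi[idx])), 1e-9)
    expect_lt(max(abs(colSums(once$s[idx, , drop = FALSE]))), 1e-9)
    expect_lt(abs(sum(once$phi2[idx])), 1e-9)
  }
  expect_lt(abs(sum(once$log_delta)), 1e-12)
  expect_lt(abs(sum(once$log_delta2)), 1e-12)
})

test_that("posterior kernel is finite for constrained finite states", {
  g <- grid_graph(3, 3)
  sim <- generate_cohort(truth_config(n_individuals = 30, seed = 9), graph = g)
  p <- ncol(suppressWarnings(build_design(sim$cohort)))
  set.seed(44)
  for (variant in c("A0", "A1", "A3", "A5", "A6", "A7")) {
    spec <- model_spec(variant)
    st <- parameter_state(spec, 9, p)
    st$alpha <- rnorm(3); st$beta[] <- rnorm(p * 3)
    st$u[] <- rnorm(27); st$s[] <- rnorm(27); st$phi <- rnorm(9)
    st$log_delta <- rnorm(3)
    if (!is.null(st$phi2)) { st$phi2 <- rnorm(9); st$log_delta2 <- rnorm(2) }
    st <- apply_constraints(st, g)
    val <- suppressWarnings(model_log_likelihood(st, spec, sim$cohort, g)) +
      model_log_prior(st, spec, g)
    expect_true(is.finite(val))
  }
})

test_that("build_design drops absent categories with a warning", {
  g <- grid_graph(2, 2)
  sim <- generate_cohort(truth_config(n_individuals = 60, seed = 10), graph = g)
  co <- sim$cohort
  co$surgery <- "breast_conserving"    # every non-reference level now absent
  expect_warning(X <- build_design(co), "absent")
  expect_false(any(grepl("^surgery=", colnames(X))))
  # sub-cohort convention: dropped covariate leaves no columns
  X2 <- suppressWarnings(build_design(sim$cohort, drop_covariates = "age_group"))
  expect_false(any(grepl("^age_group=", colnames(X2))))
})
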