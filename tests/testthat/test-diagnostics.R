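test_that("potential scale reduction separates mixed from unmixed chains", {
  set.seed(61)
  x <- rnorm(2000)
  # duplicated chains: no between-chain variance
  expect_equal(sharedCAR:::psrf(cbind(x, x)), 1.0, tolerance = 1e-3)
  # chains from the same distribution
  expect_lt(sharedCAR:::psrf(matrix(rnorm(10000), 5000, 2)), 1.05)
  # chains centred 10 apart
  expect_gt(sharedCAR:::psrf(cbind(rnorm(1000), rnorm(1000, 10))), 1.1)
})

test_that("gelman_rubin scans the fitted parameters and needs 2+ chains", {
  fit <- fixture_fit()
  rh <- gelman_rubin(fit)
  expect_true(all(c("alpha:radio", "log_delta:chemo", "deviance") %in% names(rh)))
  expect_true(any(grepl("^radio:tract=", names(rh))))
  expect_true(all(is.finite(rh)))
  one <- fit
  one$settings$n_chains <- 1L
  expect_error(gelman_rubin(one), "2 chains")
})

test_that("DIC decomposes exactly and collapses for a single retained draw", {
  fit <- fixture_fit()
  rep <- dic(fit)
  expect_lt(abs(rep$dic - rep$dbar - rep$pd), 1e-9)
  expect_gt(rep$pd, 0)
  # one retained draw: the posterior mean is the draw, so pD = 0
  g <- fixture_graph()
  sim <- fixture_sim()
  single <- run_mcmc(model_spec("A0"), sim, g,
                     mcmc_settings(1, 40, 39, 1, seed = 4))
  rep1 <- dic(single)
  expect_equal(rep1$pd, 0, tolerance = 1e-6)
  expect_equal(rep1$dic, rep1$dbar, tolerance = 1e-6)
})

test_that("pD matches the analytic quadratic excess in a Gaussian-deviance toy", {
  # two draws symmetric about the mean with deviance quadratic in theta:
  # Dbar - D(mean) = (D(m-h) + D(m+h))/2 - D(m) = c h^2 for D = c theta^2
  D <- function(theta) 3.2 * theta^2
  m <- 0.7; h <- 0.4
  dbar <- mean(c(D(m - h), D(m + h)))
  expect_equal(dbar - D(m), 3.2 * h^2, tolerance = 1e-9)
})

test_that("posterior predictive coverage behaves at the degenerate extremes", {
  fit <- fixture_fit()
  # doctor the draws into a flat posterior: p = 0.5 for every cell
  flat <- fit
  for (nm in c("alpha", "beta", "phi", "s", "u", "log_delta")) {
    flat$draws[[nm]][] <- 0
  }
  expect_equal(ppc_coverage(flat, seed = 2), 1.0)
  # near-certain p with contradicting observations leaves cells uncovered
  conc <- flat
  conc$draws$alpha[] <- 7    # p ~ 0.999 for all treatments
  expected_uncovered <- mean(fit$data$y == 0)
  expect_equal(ppc_coverage(conc, seed = 2), 1 - expected_uncovered,
               tolerance = 0.02)
  # a well-specified fit covers nearly everything
  expect_gte(ppc_coverage(fit, seed = 3), 0.99)
})

test_that("effect summaries follow the percentile oracle and flag rules", {
  g <- path3_graph()
  n_ret <- 501
  set.seed(8)
  ldraws <- rnorm(n_ret * 2, log(0.41), 0.02)
  draws <- list(beta = array(ldraws, c(n_ret, 2, 1, 3)))
  draws$beta[, , 1, 2:3] <- 0
  fit <- fake_fit(draws, g, beta_names = "tract=4-<6h")
  eff <- summarize_effects(fit)
  expect_equal(nrow(eff), 3)
  radio <- eff[eff$treatment == "radio", ]
  expect_equal(radio$median_or, exp(median(draws$beta[, , 1, 1])),
               tolerance = 1e-9)
  expect_equal(radio$median_or, 0.41, tolerance = 0.02)
  expect_true(radio$substantive)
  # quantile equivariance under the monotone exp transform (odd draw count)
  expect_equal(radio$cri_low,
               exp(quantile(draws$beta[, , 1, 1], 0.025, names = FALSE)),
               tolerance = 1e-9)
  # all-zero draws: OR exactly 1, boundary interval counts as including unity
  chemo <- eff[eff$treatment == "chemo", ]
  expect_equal(chemo$median_or, 1)
  expect_equal(c(chemo$cri_low, chemo$cri_high), c(1, 1))
  expect_false(chemo$substantive)
})

test_that("relative weights obey the product-constraint algebra", {
  g <- path3_graph()
  n_ret <- 200
  ld <- const_draws(c(0, 0, 0), n_ret, 2, 3)
  fit <- fake_fit(list(log_delta = ld), g)
  rw <- relative_weights(fit)
  expect_equal(rw$median, c(1, 1, 1))
  # concentrated weights (1.25, 0.8, 1.0): chemo/radio = 0.64
  ld2 <- const_draws(log(c(1.25, 0.8, 1.0)), n_ret, 2, 3)
  rw2 <- relative_weights(fake_fit(list(log_delta = ld2), g))
  expect_equal(rw2$median[rw2$ratio == "chemo/radio"], 0.64, tolerance = 1e-9)
  # draw-wise cyclic product of the three ratios is identically 1
  set.seed(3)
  free <- matrix(rnorm(400), 200, 2)
  anyld <- array(0, c(200, 1, 3))
  anyld[, 1, ] <- cbind(free, -rowSums(free))
  d <- exp(anyld[, 1, ])
  expect_lt(max(abs((d[, 2] / d[, 1]) * (d[, 3] / d[, 2]) * (d[, 1] / d[, 3]) - 1)),
            1e-12)
  # variant without a shared component refuses
  nos <- fake_fit(list(log_delta = ld), g,
                  spec = model_spec("A0", include_shared = FALSE))
  expect_error(relative_weights(nos), "shared")
})

test_that("summaries are equivariant under draw permutation", {
  fit <- fixture_fit()
  eff1 <- summarize_effects(fit)
  perm <- fit
  set.seed(14)
  idx <- sample(dim(fit$draws$beta)[1])
  perm$draws$beta <- fit$draws$beta[idx, , , , drop = FALSE]
  eff2 <- summarize_effects(perm)
  expect_equal(eff1$median_or, eff2$median_or)
  expect_equal(eff1$substantive, eff2$substantive)
})
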