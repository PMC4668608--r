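test_that("shared effect summary applies the fixed bins and threshold rules", {
  g <- path3_graph()
  n_ret <- 400
  phi <- array(0, c(n_ret, 2, 3))
  set.seed(9)
  # area b: 85% of draws above 0; area c: all far below
  phi[, , 2] <- ifelse(runif(n_ret * 2) < 0.85, 0.3, -0.3)
  phi[, , 3] <- -0.5
  fit <- fake_fit(list(phi = phi), g)
  sm <- shared_effect_summary(fit)
  expect_s3_class(sm, "spatial_effect_summary")
  # degenerate draws at 0: OR exactly 1, central bin
  expect_equal(sm$median_or[1], 1)
  expect_equal(sm$map_bin[1], "0.91-1.10")
  expect_equal(sm$exceed_class[2], "high")
  expect_equal(sm$exceed_class[3], "low")
  expect_equal(sm$exceed_prob[3], 0)
  expect_true(all(sm$exceed_prob >= 0 & sm$exceed_prob <= 1))
  expect_equal(sum(table(sm$exceed_class)), g$n_areas)
  nos <- fake_fit(list(phi = phi), g,
                  spec = model_spec("A0", include_shared = FALSE))
  expect_error(shared_effect_summary(nos), "shared")
})

test_that("map bins partition (0, Inf) with left-closed published cutpoints", {
  ors <- c(0.01, 0.7699, 0.77, 0.9099, 0.91, 1.0, 1.0999, 1.10, 1.2999, 1.30, 50)
  bins <- as.character(cut(ors, sharedCAR:::map_bin_breaks(),
                           sharedCAR:::map_bin_labels(), right = FALSE))
  expect_equal(bins, c("<0.77", "<0.77", "0.77-0.91", "0.77-0.91", "0.91-1.10",
                       "0.91-1.10", "0.91-1.10", "1.10-1.30", "1.10-1.30",
                       "1.30+", "1.30+"))
  expect_false(anyNA(bins))
})

test_that("treatment-specific summaries map exp(u + s) and its reductions", {
  g <- path3_graph()
  n_ret <- 50
  u <- const_draws(rep(log(2), 9), n_ret, 2, c(3, 3))
  s <- const_draws(rep(log(3), 9), n_ret, 2, c(3, 3))
  fit <- fake_fit(list(u = u, s = s), g)
  for (k in 1:3) {
    sm <- treatment_specific_summary(fit, k)
    expect_equal(sm$median_or, rep(6, 3))
  }
  expect_error(treatment_specific_summary(fit, 4), "1..3")
  # no-u variant: the summary is exp(s) alone
  fit5 <- fake_fit(list(u = u, s = s), g, spec = model_spec("A5"))
  expect_equal(treatment_specific_summary(fit5, 2)$median_or, rep(3, 3))
  # neither term present
  none <- fake_fit(list(u = u, s = s), g,
                   spec = model_spec("A5", include_s = FALSE))
  expect_error(treatment_specific_summary(none, 1), "neither")
})

test_that("category box-plot tables count exceedance shares and quartiles", {
  g <- grid_graph(2, 2)
  sm <- structure(data.frame(
    area_id = g$area_ids,
    median_or = c(1.2, 0.9, 1.05, 1.4),
    cri_low = 1, cri_high = 1,
    exceed_prob = c(0.1, 0.15, 0.5, 0.9),
    exceed_class = "uncertain", map_bin = "0.91-1.10",
    stringsAsFactors = FALSE),
    class = c("spatial_effect_summary", "data.frame"))
  one <- category_boxplot_summary(sm, rep("band", 4))
  expect_equal(one$pct_low, 50)
  expect_equal(one$pct_high, 25)
  expect_equal(c(one$q25, one$q50, one$q75),
               unname(quantile(log(sm$median_or), c(0.25, 0.5, 0.75))))
  # uniform P = 0.5 and OR = 1: both columns vanish
  sm2 <- sm; sm2$median_or <- 1; sm2$exceed_prob <- 0.5
  two <- category_boxplot_summary(sm2, c("x", "x", "y", "y"))
  expect_equal(two$pct_low, c(0, 0))
  expect_equal(two$pct_high, c(0, 0))
  expect_error(category_boxplot_summary(sm, c("a", NA, "a", "a")), "unlabelled")
  expect_error(category_boxplot_summary(sm, c("a", "a")), "per area")
})

test_that("ranked caterpillar sorts stably with area-order tie-breaks", {
  g <- path3_graph()
  mk <- function(med) structure(data.frame(
    area_id = g$area_ids, median_or = med, cri_low = med / 2,
    cri_high = med * 2, exceed_prob = 0.5, exceed_class = "uncertain",
    map_bin = "0.91-1.10", stringsAsFactors = FALSE),
    class = c("spatial_effect_summary", "data.frame"))
  ties <- ranked_caterpillar(mk(c(1, 1, 1)))
  expect_equal(ties$area_id, c("a", "b", "c"))
  expect_equal(ties$rank, 1:3)
  ord <- ranked_caterpillar(mk(c(1.2, 0.8, 1.0)))
  expect_equal(ord$area_id, c("b", "c", "a"))
  # rank order invariant under a monotone transform of the medians
  logged <- mk(log(c(1.2, 0.8, 1.0)) + 2)
  expect_equal(ranked_caterpillar(logged)$area_id, ord$area_id)
})

test_that("posterior shared effects track a monotone spatial gradient", {
  # truth: phi increases along the grid column axis; the fitted posterior
  # median shared OR must recover that ordering
  g <- grid_graph(10, 10)
  coords <- attr(g, "coords")
  phi_true <- center_sum_to_zero(0.12 * coords[, "col"], g)  # sd ~ 0.35
  sc <- default_schema()
  tr <- truth_config(n_individuals = 4000, tau_s = 1e12,
                     Sigma_u = diag(1e-18, 3), seed = 202,
                     dirichlet_shape = 20)
  sim <- generate_cohort(tr, graph = g)
  # rebuild outcomes under the fixed gradient field instead of the sampled one
  X <- build_design(sim$cohort, sc)
  a <- match(sim$cohort$area_id, g$area_ids)
  eta <- matrix(rep(tr$alpha, each = nrow(X)), ncol = 3) +
    X %*% tr$beta + outer(phi_true[a], tr$delta)
  set.seed(7)
  yy <- matrix(rbinom(length(eta), 1, plogis(eta)), ncol = 3)
  sim$cohort$y_radio <- yy[, 1]; sim$cohort$y_chemo <- yy[, 2]
  sim$cohort$y_hormone <- yy[, 3]
  fit <- run_mcmc(model_spec("A0"), sim$cohort, g,
                  mcmc_settings(1, 1000, 500, 1, seed = 17))
  sm <- shared_effect_summary(fit)
  rho <- cor(sm$median_or, coords[, "col"], method = "spearman")
  expect_gt(rho, 0.5)
  # and the sum-to-zero constraint propagates to the posterior medians
  expect_lt(abs(mean(log(sm$median_or))), 0.05)
})
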