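test_that("default schema carries the published category structure", {
  sc <- default_schema()
  expect_length(sc, 10)
  sizes <- c(tract = 5, ses = 5, age_group = 4, indigenous = 3, marital = 4,
             stage = 3, occupation = 5, tumour_type = 5, first_screen = 2,
             surgery = 4)
  for (nm in names(sizes)) {
    expect_length(sc[[nm]]$levels, sizes[[nm]])
    expect_equal(sum(sc[[nm]]$probs), 1)
  }
  expect_equal(unname(sc$tract$probs),
               c(4514, 502, 750, 317, 274) / sum(c(4514, 502, 750, 317, 274)))
  expect_equal(unname(sc$age_group$probs),
               c(933, 2064, 2074, 1225) / sum(c(933, 2064, 2074, 1225)))
  expect_equal(sc$ses$ref, "Q5")
  expect_equal(sc$surgery$ref, "breast_conserving")
  expect_equal(length(design_columns(sc)), 30)
})

null_truth <- function(n, alpha = c(0, 0, 0), beta = NULL, seed = 1,
                       delta = NULL, phi_sd = NULL, ...) {
  sc <- default_schema()
  if (is.null(beta)) beta <- matrix(0, length(design_columns(sc)), 3,
                                    dimnames = list(design_columns(sc), NULL))
  args <- list(schema = sc, alpha = alpha, beta = beta, delta = delta,
               tau_phi = 1e12, tau_s = 1e12, Sigma_u = diag(1e-18, 3),
               n_individuals = n, seed = seed, ...)
  if (!is.null(phi_sd)) { args$tau_phi <- NULL; args$phi_sd <- phi_sd }
  do.call(truth_config, args)
}

test_that("generator margins follow the inverse-logit of the predictor", {
  g <- grid_graph(5, 5)
  sim <- generate_cohort(null_truth(20000, seed = 8), graph = g)
  freq <- colMeans(sim$cohort[c("y_radio", "y_chemo", "y_hormone")])
  expect_true(all(abs(freq - 0.5) < 0.01))
  sim2 <- generate_cohort(null_truth(20000, alpha = c(log(0.2 / 0.8), 0, 0),
                                     seed = 9), graph = g)
  expect_equal(mean(sim2$cohort$y_radio), 0.2, tolerance = 0.05)
})

test_that("a single log(3) effect reproduces a sample odds ratio of 3", {
  sc <- default_schema()
  beta <- matrix(0, length(design_columns(sc)), 3,
                 dimnames = list(design_columns(sc), NULL))
  beta["first_screen=yes", 1] <- log(3)
  g <- grid_graph(5, 5)
  sim <- generate_cohort(null_truth(50000, beta = beta, seed = 21), graph = g)
  tab <- table(sim$cohort$first_screen, sim$cohort$y_radio)
  or <- (tab["yes", "1"] * tab["no", "0"]) / (tab["yes", "0"] * tab["no", "1"])
  expect_equal(unname(or), 3, tolerance = 0.1)
})

test_that("shared field with equal weights induces positive cross-treatment
           correlation of area-level empirical logits", {
  g <- grid_graph(10, 10)
  tr <- null_truth(30000, delta = c(1, 1, 1), phi_sd = 0.6, seed = 30,
                   dirichlet_shape = 50)   # near-uniform allocation
  sim <- generate_cohort(tr, graph = g)
  co <- sim$cohort
  emp_logit <- function(y, a) {
    agg <- tapply(y, a, function(v) (sum(v) + 0.5) / (length(v) + 1))
    log(agg / (1 - agg))
  }
  l1 <- emp_logit(co$y_radio, co$area_id)
  l2 <- emp_logit(co$y_chemo, co$area_id)
  l3 <- emp_logit(co$y_hormone, co$area_id)
  expect_gt(cor(l1, l2), 0)
  expect_gt(cor(l1, l3), 0)
  expect_gt(cor(l2, l3), 0)
})

test_that("generated latent fields honour the requested strengths", {
  g <- grid_graph(10, 10)
  tr <- truth_config(n_individuals = 10, phi_sd = 0.3, s_sd = 0.15, seed = 2)
  sim <- generate_cohort(tr, graph = g)
  expect_equal(sum(sim$phi), 0, tolerance = 1e-9)
  expect_true(all(abs(colSums(sim$s)) < 1e-9))
  expect_equal(sim$tau_phi, car_precision_for_sd(g, 0.3))
})

test_that("truth_config validates its invariants", {
  expect_error(truth_config(delta = c(2, 1, 1)), "product")
  expect_error(truth_config(delta = c(-1, 1, -1)), "positive")
  expect_error(truth_config(Sigma_u = matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)),
               "positive definite")
  expect_error(truth_config(area_allocation = c(0.5, 0.4)), "sum to 1")
  # defaults: unit-product weights, headline effects in place
  tr <- truth_config()
  expect_equal(prod(tr$delta), 1, tolerance = 1e-12)
  expect_equal(exp(tr$beta["tract=4-<6h", "radio"]), 0.41)
  expect_equal(exp(tr$beta["stage=advanced", "chemo"]), 11.21)
})

test_that("tabulate_combinations counts all eight cells with the treated-base
           percentage convention", {
  co <- table1_cohort()
  tab <- tabulate_combinations(co)
  expect_equal(sum(tab$count), nrow(co))
  expect_equal(attr(tab, "treated_total"), 5251)
  expect_equal(tab$count[tab$combination == "none"], 1106)
  expect_equal(tab$pct[tab$combination == "radio_hormone"],
               100 * 1990 / 5251)
  # all-negative cohort: seven treated cells empty
  zero <- cohort_from_y(matrix(0L, 10, 3))
  tz <- tabulate_combinations(zero)
  expect_true(all(tz$count[tz$combination != "none"] == 0))
  expect_equal(tz$count[tz$combination == "none"], 10)
})

test_that("generation and CSV export are byte-identical under a fixed seed", {
  g <- grid_graph(4, 4)
  tr <- truth_config(n_individuals = 300, seed = 77)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(tr, graph = g), f1)
  write_cohort(generate_cohort(tr, graph = g), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # round trip preserves content
  back <- read_cohort(f1, g)
  expect_equal(nrow(back), 300)
  expect_true(all(back$area_id %in% g$area_ids))
})

test_that("truth JSON persists coefficients and realised fields", {
  g <- grid_graph(3, 3)
  sim <- generate_cohort(truth_config(n_individuals = 50, seed = 3), graph = g)
  path <- tempfile(fileext = ".json")
  write_truth(sim, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$delta, sim$truth$delta, tolerance = 1e-12)
  expect_equal(obj$phi, sim$phi, tolerance = 1e-12)
})

test_that("the area-tilted travel-time option induces spatial confounding", {
  g <- grid_graph(8, 8)
  tr <- truth_config(n_individuals = 8000, phi_sd = 0.5, tract_tilt = 1.5,
                     seed = 55, dirichlet_shape = 50)
  sim <- generate_cohort(tr, graph = g)
  score <- sim$phi + sim$s[, 1]
  area_idx <- match(sim$cohort$area_id, g$area_ids)
  near <- tapply(sim$cohort$tract == "<1h", area_idx, mean)
  expect_gt(cor(score[as.integer(names(near))], near), 0.3)
})
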