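# Shared fixtures: tiny graphs, GAL writers, doctored fits and one
# memoised synthetic fit reused by the diagnostics/summary tests.

path3_graph <- function() area_graph(list(2L, c(1L, 3L), 2L), c("a", "b", "c"))

two_component_graph <- function() {
  # 3-clique {1,2,3} plus 2-clique {4,5}
  area_graph(list(c(2L, 3L), c(1L, 3L), c(1L, 2L), 5L, 4L))
}

random_graph <- function(n, p_edge = 0.4) {
  nb <- replicate(n, integer(0), simplify = FALSE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p_edge) {
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  area_graph(nb)
}

write_gal_text <- function(lines) {
  path <- tempfile(fileext = ".gal")
  writeLines(lines, path)
  path
}

# cohort data frame with given outcome matrix and arbitrary covariates
cohort_from_y <- function(y, area_ids = "1") {
  n <- nrow(y)
  sc <- default_schema()
  cov <- lapply(sc, function(cv) rep(cv$ref, n))
  data.frame(individual_id = seq_len(n),
             area_id = rep_len(area_ids, n),
             as.data.frame(cov, stringsAsFactors = FALSE, col.names = names(sc)),
             y_radio = y[, 1], y_chemo = y[, 2], y_hormone = y[, 3],
             stringsAsFactors = FALSE)
}

# cohort realising the published therapy-combination counts
table1_cohort <- function() {
  cells <- rbind(
    c(1, 0, 0, 800), c(0, 1, 0, 205), c(0, 0, 1, 899),
    c(1, 1, 0, 511), c(1, 0, 1, 1990), c(0, 1, 1, 239),
    c(1, 1, 1, 607), c(0, 0, 0, 1106))
  y <- cells[rep(seq_len(nrow(cells)), cells[, 4]), 1:3, drop = FALSE]
  cohort_from_y(y)
}

# minimal shared_car_fit carrying prescribed draw arrays; enough structure
# for pooled_draws / summaries / effect tables
fake_fit <- function(draws, graph, spec = model_spec("A0"),
                     beta_names = character(0), deviance = NULL) {
  d <- dim(draws[[1]])
  n_ret <- d[1]; nc <- d[2]
  settings <- structure(list(n_chains = nc, n_iterations = n_ret, burn_in = 0L,
                             thin = 1L, seed = 1L, adapt_interval = 50L,
                             retained_per_chain = n_ret,
                             retained_total = n_ret * nc),
                        class = "mcmc_settings")
  structure(list(draws = draws, deviance = deviance, spec = spec,
                 settings = settings, beta_names = beta_names, graph = graph,
                 schema = default_schema(), drop_covariates = character(0),
                 data = list(n = 0), chain_seeds = 1L, cohort_hash = "fake"),
            class = "shared_car_fit")
}

# constant-valued draw array [n_ret, nc, dims...]
const_draws <- function(value, n_ret, nc, dims) {
  array(rep(value, each = n_ret * nc), c(n_ret, nc, dims))
}

# one moderate well-specified synthetic fit, memoised across test files
fixture_env <- new.env(parent = emptyenv())

fixture_fit <- function() {
  if (is.null(fixture_env$fit)) {
    g <- grid_graph(8, 8)
    tr <- truth_config(n_individuals = 2000, seed = 314)
    sim <- generate_cohort(tr, graph = g)
    st <- mcmc_settings(2, 1200, 600, 2, seed = 99)
    fixture_env$sim <- sim
    fixture_env$graph <- g
    fixture_env$fit <- run_mcmc(model_spec("A0"), sim, g, st)
  }
  fixture_env$fit
}

fixture_sim <- function() { fixture_fit(); fixture_env$sim }
fixture_graph <- function() { fixture_fit(); fixture_env$graph }

# batch-means Monte Carlo standard error of the mean of a draw vector
mcse_mean <- function(x, n_batches = 25) {
  nb <- min(n_batches, floor(length(x) / 4))
  bs <- floor(length(x) / nb)
  bm <- vapply(seq_len(nb), function(b) mean(x[((b - 1) * bs + 1):(b * bs)]), 0)
  stats::sd(bm) / sqrt(nb)
}

# MCSE of a quantile via the effective sample size implied by mcse_mean
mcse_quantile <- function(x, q) {
  n_eff <- max(4, stats::var(x) / mcse_mean(x)^2)
  xq <- stats::quantile(x, q, names = FALSE)
  f <- stats::approx(stats::density(x)$x, stats::density(x)$y, xout = xq,
                     rule = 2)$y
  sqrt(q * (1 - q) / n_eff) / max(f, 1e-12)
}
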