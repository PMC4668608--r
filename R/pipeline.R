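#' Run configuration for an end-to-end study
#'
#' Bundles everything one analysis run needs: the inputs (a cohort and an
#' adjacency structure, in memory or as files), the variant and its
#' hyperparameter overrides (the published sensitivity analyses replace
#' the Gamma(0.5, 0.005) CAR hyperprior by Gamma(0.5, 0.5) or
#' Gamma(0.5, 0.05) and the log-weight precision 5.9 by 2.9), the chain
#' schedule, an optional sub-cohort filter, the output directory and the
#' master seed.
#'
#' @param cohort cohort data frame, `synthetic_cohort`, or path to a CSV
#'   written by [write_cohort()].
#' @param adjacency an `area_graph` or path to a GAL file.
#' @param out_dir output directory for all artefacts.
#' @param variant model variant `"A0"` ... `"A7"`.
#' @param settings optional `mcmc_settings`; default is the published
#'   schedule for the cohort type (full or sub-cohort), with `seed`.
#' @param subcohort optional `list(covariate =, value =)`: the analysis is
#'   restricted to individuals with that category and is not adjusted for
#'   the corresponding covariate (it is dropped from the design).
#' @param hyper named list of hyperparameter overrides (see [model_spec()]).
#' @param seed master seed.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort, adjacency, out_dir, variant = "A0",
                       settings = NULL, subcohort = NULL, hyper = list(),
                       seed = 1L, overwrite = FALSE) {
  check(variant %in% paste0("A", 0:7), "invalid variant: %s", variant)
  if (!is.null(subcohort)) {
    check(is.list(subcohort) && all(c("covariate", "value") %in% names(subcohort)),
          "subcohort must be list(covariate =, value =)")
    sc <- default_schema()
    check(subcohort$covariate %in% names(sc),
          "subcohort covariate %s not in schema", subcohort$covariate)
    check(subcohort$value %in% sc[[subcohort$covariate]]$levels,
          "subcohort value %s is not a category of %s",
          subcohort$value, subcohort$covariate)
  }
  structure(list(cohort = cohort, adjacency = adjacency, out_dir = out_dir,
                 variant = variant, settings = settings, subcohort = subcohort,
                 hyper = hyper, seed = as.integer(seed),
                 overwrite = isTRUE(overwrite)),
            class = "run_config")
}

#' Run a full study: fit, diagnose, summarise and persist
#'
#' End-to-end orchestration of one model run: reads or accepts the cohort
#' and adjacency, applies any sub-cohort filter (dropping its covariate
#' from the design), fits the variant by MCMC, computes DIC, Gelman-Rubin
#' statistics and the posterior predictive coverage, writes effect,
#' relative-weight and per-area spatial summaries as CSV, persists the
#' posterior draws, and emits a manifest recording the configuration, the
#' retained-draw arithmetic, the constraint-residual maxima and a checksum
#' of every artefact. Deterministic under a fixed master seed.
#'
#' @param config a `run_config`.
#' @return Invisibly, a list with the `shared_car_fit`, the `fit_report`,
#'   the summary tables and the artefact paths.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  graph <- if (inherits(config$adjacency, "area_graph")) config$adjacency
           else read_gal(config$adjacency)
  cohort <- config$cohort
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$cohort
  if (is.character(cohort)) cohort <- read_cohort(cohort, graph)
  bad <- setdiff(unique(as.character(cohort$area_id)), graph$area_ids)
  check(length(bad) == 0, "cohort area ids not in adjacency: %s",
        paste(utils::head(bad, 5), collapse = ", "))

  out <- config$out_dir
  if (dir.exists(out) && length(list.files(out)) > 0 && !config$overwrite) {
    stop("output directory exists and is non-empty: ", out,
         " (set overwrite = TRUE to allow)", call. = FALSE)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  drop <- character(0)
  if (!is.null(config$subcohort)) {
    keep <- as.character(cohort[[config$subcohort$covariate]]) == config$subcohort$value
    message(sprintf("sub-cohort %s = %s: %d of %d individuals",
                    config$subcohort$covariate, config$subcohort$value,
                    sum(keep), nrow(cohort)))
    cohort <- cohort[keep, , drop = FALSE]
    drop <- config$subcohort$covariate
  }
  spec <- model_spec(config$variant, hyper = config$hyper)
  settings <- config$settings
  if (is.null(settings)) {
    settings <- default_settings(sub_cohort = !is.null(config$subcohort),
                                 seed = config$seed)
  } else {
    settings$seed <- config$seed
  }

  message(sprintf("fitting %s: %d individuals, %d areas, %d x %d iterations",
                  spec$variant, nrow(cohort), graph$n_areas,
                  settings$n_chains, settings$n_iterations))
  fit <- run_mcmc(spec, cohort, graph, settings, drop_covariates = drop)

  message("diagnostics")
  report <- dic(fit)
  rhat <- gelman_rubin(fit)
  report$ppc <- ppc_coverage(fit, seed = config$seed)
  report$max_rhat <- max(rhat)
  resid <- constraint_residuals(fit)

  message("summaries")
  paths <- character(0)
  wr <- function(obj, name) {
    pth <- file.path(out, name)
    utils::write.csv(obj, pth, row.names = FALSE)
    paths <<- c(paths, pth)
    pth
  }
  effects <- summarize_effects(fit)
  wr(effects, "effects.csv")
  wr(data.frame(parameter = names(rhat), rhat = unname(rhat)), "gelman_rubin.csv")
  rel <- NULL
  shared <- NULL
  if (spec$include_shared) {
    rel <- relative_weights(fit)
    wr(rel, "relative_weights.csv")
    shared <- shared_effect_summary(fit)
    wr(shared, "shared_effect.csv")
  }
  if (spec$include_u || spec$include_s) {
    for (k in 1:3) {
      wr(treatment_specific_summary(fit, k),
         sprintf("specific_effect_%s.csv", treatment_names()[k]))
    }
  }
  samples_dir <- file.path(out, "samples")
  write_samples(fit, samples_dir)
  paths <- c(paths, list.files(samples_dir, full.names = TRUE))

  fitrep_path <- file.path(out, "fit_report.json")
  jsonlite::write_json(list(variant = report$variant, dic = report$dic,
                            dbar = report$dbar, pd = report$pd,
                            ppc = report$ppc, max_rhat = report$max_rhat),
                       fitrep_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, fitrep_path)

  manifest <- list(
    variant = config$variant,
    seed = config$seed,
    subcohort = config$subcohort,
    hyper = config$hyper,
    settings = unclass(settings),
    retained = list(per_chain = settings$retained_per_chain,
                    pooled = settings$retained_total),
    constraint_residuals = resid,
    n_individuals = nrow(cohort),
    n_areas = graph$n_areas,
    versions = list(r = as.character(getRversion()),
                    package = as.character(utils::packageVersion("sharedCAR"))),
    checksums = as.list(tools::md5sum(sort(paths))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("done: ", out)
  invisible(list(fit = fit, report = report, effects = effects,
                 relative_weights = rel, shared_effect = shared,
                 rhat = rhat, manifest = manifest, out_dir = out))
}

## maxima of the identifiability-constraint residuals over retained draws
constraint_residuals <- function(fit) {
  comp <- fit$graph$component_labels
  comp_max <- function(mat) {   # draws x areas
    m <- 0
    for (cc in unique(comp)) {
      idx <- which(comp == cc)
      m <- max(m, max(abs(rowSums(mat[, idx, drop = FALSE]))))
    }
    m
  }
  res <- list(log_delta_sum = max(abs(rowSums(pooled_draws(fit, "log_delta")))))
  if (fit$spec$include_shared) res$phi_component_sum <- comp_max(pooled_draws(fit, "phi"))
  if (fit$spec$include_s) {
    A <- fit$graph$n_areas
    s <- pooled_draws(fit, "s")
    res$s_component_sum <- max(vapply(1:3, function(k) {
      comp_max(s[, ((k - 1) * A + 1):(k * A), drop = FALSE])
    }, 0))
  }
  res
}

#' Rank fitted variants by DIC
#'
#' Orders a set of fit reports for the same cohort by ascending DIC
#' (smaller indicates better fit) and reports each model's DIC difference
#' to the best.
#'
#' @param reports list of `fit_report` objects (at least 2), all from fits
#'   of the same cohort.
#' @return data frame with columns `variant`, `dic`, `dbar`, `pd`,
#'   `delta_dic`, ordered by `dic`.
#' @export
compare_variants <- function(reports) {
  check(is.list(reports) && length(reports) >= 2,
        "need at least 2 fit reports to compare")
  check(all(vapply(reports, function(r) inherits(r, "fit_report"), TRUE)),
        "reports must be fit_report objects")
  hashes <- unlist(lapply(reports, function(r) r$cohort_hash))
  check(length(unique(hashes)) <= 1, "reports come from different cohorts")
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(variant = r$variant, dic = r$dic, dbar = r$dbar, pd = r$pd,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$dic), , drop = FALSE]
  df$delta_dic <- df$dic - df$dic[1]
  rownames(df) <- NULL
  df
}
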