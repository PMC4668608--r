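# sharedCAR

Bayesian shared spatial-component models for several correlated binary
outcomes observed on individuals nested in areal units — the disease-mapping
setting in which, say, three adjuvant-therapy decisions (radiotherapy,
chemotherapy, hormonal therapy) made by breast cancer patients vary both
with individual characteristics and with *where the patient lives*, and the
residual geography is partly common to all three decisions.

For individual *j* in area *i* and outcome *k* = 1, 2, 3:

```
Y_ijk ~ Bernoulli(p_ijk)
logit(p_ijk) = alpha_k + beta_k' X_ij + u_ik + delta_k * phi_i + s_ik
```

where `phi` is a single spatially structured latent field shared by all
outcomes (intrinsic CAR prior on the areal adjacency graph), `delta_k > 0`
are outcome-specific weights constrained to unit product (their ratios
measure the relative influence of the common geography), `s_k` are
outcome-specific structured CAR remainders, and the rows of `u` are
trivariate Gaussian unstructured effects with a Wishart-prior precision
matrix. Sum-to-zero constraints per connected component identify the CAR
fields. Seven published variants (independent `u`; a second shared
component for each outcome pair; no `u`; no `s`; flat fixed-effect priors)
are selectable as `model_spec("A0")` … `model_spec("A7")`.

The package provides:

* **Areal machinery** — `read_gal()` / `write_gal()` for GAL
  spatial-weights files, `grid_graph()` synthetic maps, exact
  `car_log_density()` / `sample_car_field()` mathematics with correct
  handling of disconnected maps.
* **A calibrated synthetic-cohort generator** — `generate_cohort()` draws
  cohorts with the exact structure the model assumes, with defaults
  matching the published study conditions (6,357 individuals, 478 areas of
  which ~61 empty, published covariate frequencies and effect sizes).
* **MCMC inference** — `run_mcmc()`: adaptive Metropolis-within-Gibbs with
  conjugate precision updates in compiled code; fully reproducible from one
  master seed; published chain schedules via `default_settings()`.
* **Diagnostics** — `dic()`, `gelman_rubin()`, `ppc_coverage()`,
  `summarize_effects()`, `relative_weights()`.
* **Small-area summaries** — `shared_effect_summary()`,
  `treatment_specific_summary()` (`exp(u+s)`), exceedance classification at
  0.2/0.8, fixed map bins (0.77, 0.91, 1.10, 1.30),
  `category_boxplot_summary()`, `ranked_caterpillar()`.
* **Orchestration** — `run_study()` runs simulate → fit → diagnose →
  summarise end to end and persists every artefact with a checksummed
  manifest; `compare_variants()` ranks fits by DIC.

## Worked example

Simulate a cohort on a 10×10 grid with the published effect sizes as
ground truth, fit the baseline model and summarise:

```r
library(sharedCAR)
graph <- grid_graph(10, 10)
truth <- truth_config(n_individuals = 4000, seed = 1)
sim   <- generate_cohort(truth, graph = graph)
sim
#> synthetic_cohort: 4000 individuals, 100 areas, 3 empty
#>   outcome frequencies: radio 0.590, chemo 0.316, hormone 0.569

fit <- run_mcmc(model_spec("A0"), sim, graph,
                mcmc_settings(2, 2000, 1000, 2, seed = 1))

subset(summarize_effects(fit), treatment == "radio" & grepl("tract", term))
#>   treatment        term median_or cri_low cri_high substantive
#> 1     radio tract=1-<2h     0.654   0.489    0.887        TRUE
#> 2     radio tract=2-<4h     0.653   0.485    0.856        TRUE
#> 3     radio tract=4-<6h     0.580   0.400    0.866        TRUE
#> 4     radio   tract=6+h     0.472   0.313    0.760        TRUE

dic(fit)
#> fit_report (A0): DIC = 12634.8 (Dbar = 12452.0, pD = 182.8)

head(shared_effect_summary(fit), 4)
#>   area_id median_or cri_low cri_high exceed_prob exceed_class   map_bin
#> 1    r1c1      1.01   0.827     1.26       0.525    uncertain 0.91-1.10
#> 2    r1c2      1.01   0.859     1.22       0.554    uncertain 0.91-1.10
#> 3    r1c3      1.03   0.870     1.25       0.668    uncertain 0.91-1.10
#> 4    r1c4      1.03   0.853     1.28       0.672    uncertain 0.91-1.10
```

The effect table reads as posterior median odds ratios against each
covariate's reference category with 95 % credible intervals: at this short
demonstration schedule the fitted travel-time gradient for radiotherapy
(0.65 → 0.47 with increasing distance, all intervals excluding 1) tracks
the generating values (0.88, 0.66, 0.41, 0.41). The shared-effect table
gives each area's common spatial odds ratio, its exceedance probability
`P(OR > 1)`, the 0.2/0.8 classification and the fixed map bin.
`relative_weights(fit)` reports the draw-wise ratios of the
shared-component weights (`delta` ratios) with the same interval-exclusion
flag.

A full persisted run, including sub-cohort filters and the published
sensitivity-analysis hyperparameter overrides:

```r
cfg <- run_config(sim, graph, "out/a0", variant = "A0", seed = 7,
                  subcohort = list(covariate = "age_group", value = "50-59"))
res <- run_study(cfg)
```

See the methods vignette
(`vignettes/shared-spatial-component-model.Rmd`) for the model, priors,
identifiability constraints, sampler composition and every documented
design decision.

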