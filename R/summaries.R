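map_bin_breaks <- function() c(0, 0.77, 0.91, 1.10, 1.30, Inf)
map_bin_labels <- function() c("<0.77", "0.77-0.91", "0.91-1.10", "1.10-1.30", "1.30+")

## per-area summary from a draws x areas matrix of log odds ratios
area_summary <- function(log_or_draws, area_ids) {
  qs <- apply(log_or_draws, 2, stats::quantile,
              probs = c(0.5, 0.025, 0.975), names = FALSE)
  exceed <- colMeans(log_or_draws > 0)
  med <- exp(qs[1, ])
  out <- data.frame(
    area_id = area_ids,
    median_or = med,
    cri_low = exp(qs[2, ]),
    cri_high = exp(qs[3, ]),
    exceed_prob = exceed,
    exceed_class = ifelse(exceed < 0.2, "low",
                          ifelse(exceed > 0.8, "high", "uncertain")),
    map_bin = as.character(cut(med, breaks = map_bin_breaks(),
                               labels = map_bin_labels(), right = FALSE)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("spatial_effect_summary", "data.frame")
  out
}

#' Per-area summary of the shared spatial effect
#'
#' Summarises the draw-wise shared odds ratio `exp(phi_i)` of each area:
#' posterior median, central 95 % credible interval, the exceedance
#' probability `P(exp(phi_i) > 1)` (computed on the log scale as
#' `P(phi_i > 0)`), the exceedance class (`low` below 0.2, `high` above
#' 0.8, otherwise `uncertain`) and the fixed map bin with cutpoints
#' 0.77, 0.91, 1.10, 1.30 (intervals closed on the left).
#'
#' @param fit a `shared_car_fit` whose variant has a shared component.
#' @return data frame of class `spatial_effect_summary`, one row per area:
#'   `area_id`, `median_or`, `cri_low`, `cri_high`, `exceed_prob`,
#'   `exceed_class`, `map_bin`.
#' @export
shared_effect_summary <- function(fit) {
  stopifnot(inherits(fit, "shared_car_fit"))
  check(fit$spec$include_shared, "variant has no shared component")
  area_summary(pooled_draws(fit, "phi"), fit$graph$area_ids)
}

#' Per-area summary of a treatment-specific spatial effect
#'
#' Summarises `exp(u_ik + s_ik)` per area for treatment `k`. Only the sum
#' of the structured and unstructured effects is well identified, so the
#' two are mapped jointly; terms absent under the variant contribute zero
#' (under a model without `u` this is `exp(s)` alone).
#'
#' @param fit a `shared_car_fit` including at least one of `u`, `s`.
#' @param k treatment index in 1..3 (radio, chemo, hormone).
#' @return data frame as in [shared_effect_summary()].
#' @export
treatment_specific_summary <- function(fit, k) {
  stopifnot(inherits(fit, "shared_car_fit"))
  check(k %in% 1:3, "treatment index k must be in 1..3")
  check(fit$spec$include_u || fit$spec$include_s,
        "variant has neither u nor s")
  A <- fit$graph$n_areas
  cols <- ((k - 1) * A + 1):(k * A)
  total <- matrix(0, fit$settings$retained_total, A)
  if (fit$spec$include_u) total <- total + pooled_draws(fit, "u")[, cols, drop = FALSE]
  if (fit$spec$include_s) total <- total + pooled_draws(fit, "s")[, cols, drop = FALSE]
  area_summary(total, fit$graph$area_ids)
}

#' Category box-plot table for a spatial effect summary
#'
#' Groups areas by a per-area category (travel-time band, socio-economic
#' quintile, ...) and reports, per category, the box-plot quartiles of the
#' median odds ratio on the log scale together with the two percentage
#' columns: the share of areas with exceedance probability below 0.2
#' (left column) and above 0.8 (right column).
#'
#' @param summary a `spatial_effect_summary`.
#' @param category per-area labels, aligned to `summary$area_id`; every
#'   area must be labelled.
#' @return data frame with one row per category: `category`, `n_areas`,
#'   `q25`, `q50`, `q75` (log scale), `pct_low`, `pct_high`.
#' @export
category_boxplot_summary <- function(summary, category) {
  stopifnot(inherits(summary, "spatial_effect_summary"))
  check(length(category) == nrow(summary), "one category label per area required")
  check(!anyNA(category), "unlabelled area (NA category)")
  lev <- unique(as.character(category))
  rows <- lapply(lev, function(cv) {
    sub <- summary[as.character(category) == cv, ]
    q <- stats::quantile(log(sub$median_or), probs = c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(category = cv, n_areas = nrow(sub),
               q25 = q[1], q50 = q[2], q75 = q[3],
               pct_low = 100 * mean(sub$exceed_prob < 0.2),
               pct_high = 100 * mean(sub$exceed_prob > 0.8),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Areas ranked by median spatial odds ratio
#'
#' Stable sort of a spatial effect summary by increasing median odds
#' ratio, ties broken by original area order — the tabular form of the
#' ranked caterpillar plot of area effects with credible intervals.
#'
#' @param summary a `spatial_effect_summary`.
#' @return the summary rows in rank order with a `rank` column prepended.
#' @export
ranked_caterpillar <- function(summary) {
  stopifnot(inherits(summary, "spatial_effect_summary"))
  ord <- order(summary$median_or, seq_len(nrow(summary)))
  out <- summary[ord, ]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("spatial_effect_summary", "data.frame")
  out
}
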