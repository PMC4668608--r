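#' Covariate schema of the synthetic cohort
#'
#' Ten categorical covariates describing a screen-detected breast cancer
#' cohort: road travel time to the nearest radiotherapy facility (TRACT),
#' area socio-economic quintile (IRSAD), age group at diagnosis,
#' Indigenous status, marital status, tumour stage, occupation, invasive
#' tumour type, whether the cancer was found at the first screening
#' episode, and intended surgery. Category sampling probabilities are
#' proportional to the cohort's published category frequencies, and the
#' reference level of each covariate matches the published baseline.
#'
#' @return An object of class `covariate_schema`: a named list with one
#'   element per covariate, each holding `name`, `levels`, `ref` and
#'   `probs` (summing to 1, in level order).
#' @examples
#' sc <- default_schema()
#' sc$tract$probs
#' @export
default_schema <- function() {
  def <- function(name, levels, ref, n) {
    check(length(levels) == length(n), "schema %s: levels/counts mismatch", name)
    check(ref %in% levels, "schema %s: reference level missing", name)
    p <- n / sum(n)
    names(p) <- levels
    list(name = name, levels = levels, ref = ref, probs = p)
  }
  sc <- list(
    tract = def("tract",
                c("<1h", "1-<2h", "2-<4h", "4-<6h", "6+h"),
                "<1h", c(4514, 502, 750, 317, 274)),
    ses = def("ses",
              c("Q1", "Q2", "Q3", "Q4", "Q5"),
              "Q5", c(817, 1458, 1762, 1539, 781)),
    age_group = def("age_group",
                    c("40-49", "50-59", "60-69", "70-89"),
                    "50-59", c(933, 2064, 2074, 1225)),
    indigenous = def("indigenous",
                     c("non_indigenous", "indigenous", "unknown"),
                     "non_indigenous", c(5467, 63, 766)),
    marital = def("marital",
                  c("married", "never_married", "widowed_divorced_separated", "unknown"),
                  "married", c(4150, 305, 1665, 176)),
    stage = def("stage",
                c("localised", "advanced", "unknown"),
                "localised", c(4081, 2139, 76)),
    occupation = def("occupation",
                     c("blue_collar", "white_collar", "professional",
                       "not_in_labour_force", "unknown"),
                     "not_in_labour_force", c(245, 907, 1061, 2631, 1452)),
    tumour_type = def("tumour_type",
                      c("invasive_ductal", "tubular", "lobular_classical",
                        "other", "unknown"),
                      "invasive_ductal", c(4074, 167, 506, 434, 1115)),
    first_screen = def("first_screen", c("yes", "no"), "no", c(1508, 4788)),
    surgery = def("surgery",
                  c("breast_conserving", "mastectomy", "no_surgery", "unknown"),
                  "breast_conserving", c(4255, 2009, 15, 17))
  )
  structure(sc, class = "covariate_schema")
}

#' @export
print.covariate_schema <- function(x, ...) {
  cat("covariate_schema:", length(x), "covariates\n")
  for (cv in x) {
    cat(sprintf("  %-13s %d levels (ref %s)\n", cv$name, length(cv$levels), cv$ref))
  }
  invisible(x)
}

#' Names of the design columns implied by a schema
#'
#' One dummy column per non-reference category, named
#' `<covariate>=<level>`, in schema order.
#' @param schema a `covariate_schema`.
#' @param drop_covariates covariates to omit entirely.
#' @return character vector of column names.
#' @export
design_columns <- function(schema, drop_covariates = character(0)) {
  unlist(lapply(schema, function(cv) {
    if (cv$name %in% drop_covariates) return(character(0))
    lv <- setdiff(cv$levels, cv$ref)
    paste0(cv$name, "=", lv)
  }), use.names = FALSE)
}

#' Dummy-coded design matrix for a cohort
#'
#' Builds the 0/1 design with one column per non-reference category of
#' each covariate. Covariates named in `drop_covariates` are omitted (used
#' for sub-cohort analyses, which are not adjusted for the covariate that
#' defines them). Categories absent from the cohort are dropped from the
#' design with a warning rather than carried as inestimable columns.
#'
#' @param cohort a cohort data frame (see [generate_cohort()]).
#' @param schema a `covariate_schema`.
#' @param drop_covariates character vector of covariate names to omit.
#' @param keep_empty keep all-zero columns for categories absent from the
#'   cohort instead of dropping them (used when the design represents a
#'   known generating truth rather than an estimation problem).
#' @return numeric matrix with `nrow(cohort)` rows; column names as in
#'   [design_columns()], minus any empty categories.
#' @export
build_design <- function(cohort, schema = default_schema(),
                         drop_covariates = character(0), keep_empty = FALSE) {
  stopifnot(inherits(schema, "covariate_schema"))
  unknown <- setdiff(drop_covariates, names(schema))
  check(length(unknown) == 0, "drop_covariates not in schema: %s",
        paste(unknown, collapse = ", "))
  cols <- list()
  dropped <- character(0)
  for (cv in schema) {
    if (cv$name %in% drop_covariates) next
    check(cv$name %in% names(cohort), "cohort lacks covariate column %s", cv$name)
    v <- as.character(cohort[[cv$name]])
    bad <- setdiff(unique(v), cv$levels)
    check(length(bad) == 0, "covariate %s has unknown categories: %s",
          cv$name, paste(bad, collapse = ", "))
    for (lv in setdiff(cv$levels, cv$ref)) {
      col <- as.numeric(v == lv)
      nm <- paste0(cv$name, "=", lv)
      if (!keep_empty && nrow(cohort) > 0 && sum(col) == 0) {
        dropped <- c(dropped, nm)
      } else {
        cols[[nm]] <- col
      }
    }
  }
  if (length(dropped)) {
    warning("dropping design columns for categories absent from the cohort: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(cols) == 0) {
    return(matrix(0, nrow(cohort), 0))
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  X
}
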