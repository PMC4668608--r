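logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

#' Stop unless a condition holds
#' @noRd
check <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Derive per-chain seeds from a master seed
#'
#' All randomness in a run flows from one master seed: the master seed
#' initialises R's RNG, from which one sub-seed per chain is drawn.
#' Sub-seeds stay below 2^31 so they are valid R integer seeds.
#' @noRd
split_seed <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Evaluate an expression under a local RNG seed, restoring global state
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

treatment_names <- function() c("radio", "chemo", "hormone")
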