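## Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the caller's RNG
#' state, so generators are pure functions of (parameters, seed) and never
#' disturb global randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Attach generator ground truth to an artifact
#' @keywords internal
#' @noRd
set_ground_truth <- function(x, generator, parameters, seed) {
  attr(x, "ground_truth") <- list(
    generator_name = generator,
    parameters = parameters,
    seed = as.integer(seed)
  )
  x
}

#' Retrieve the ground truth recorded by a synthetic generator
#'
#' Every object produced by the `gen_*()` generators carries the parameters
#' and seed it was built from, so recovery tests can compare analysis output
#' against known truth.
#'
#' @param x an object produced by a `gen_*()` generator.
#' @return a list with elements `generator_name`, `parameters`, and `seed`,
#'   or `NULL` if `x` carries no ground truth.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
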