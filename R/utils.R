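`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the previous
#' global RNG state afterwards, so seeded operations (ternary boundary
#' resolution, synthetic data generation) never perturb the caller's
#' random-number stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# scalar integer check with an informative message
check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != floor(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

trimws2 <- function(x) trimws(as.character(x))

# sample std dev that returns 0 (not NA) for a single observation
sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
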