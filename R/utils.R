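# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so that seeded helpers do not perturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Derive a stream seed from a master seed
#'
#' Deterministically maps (master seed, stream index) to a new seed below
#' 2^31, so that each pipeline stage (and each (module, comorbidity) pair in
#' the subsampling evaluator) gets its own reproducible stream.
#'
#' @param master integer master seed.
#' @param stream nonnegative integer stream index.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(master, stream = 0L) {
  m <- as.numeric(master) %% 2147483647
  s <- (m * 48271 + as.numeric(stream) * 1299721 + 12345) %% 2147483629
  as.integer(s + 1)
}

# stop() with a consistent prefix for input-validation errors
abort_input <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == floor(x) && x >= 1
}
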