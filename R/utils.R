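#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so library functions never perturb user randomness.
#' A `NULL` seed leaves the RNG untouched.
#'
#' @param seed integer seed or NULL.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from a single integer seed; sub-streams
#' (one per simulated table, CV run, permutation batch, ...) are derived with a
#' small multiplicative congruential mix. Exact in double arithmetic because
#' all intermediates stay below 2^53; results stay below 2^31.
#'
#' @param seed master integer seed.
#' @param index stream index (any non-negative integer; vectorized).
#' @return integer vector of derived seeds.
#' @export
child_seed <- function(seed, index) {
  s <- as.double(seed) %% 2147483647
  s <- (s * 69069 + 1) %% 2147483647
  s <- (s + as.double(index)) %% 2147483647
  s <- (s * 69069 + 1) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_finite_params <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop(sprintf("parameter '%s' must be finite numeric", nm), call. = FALSE)
    }
  }
  invisible(TRUE)
}
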