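#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the previous RNG state so
#' generators are bit-reproducible without clobbering the caller's stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive k child seeds < 2^31 from a parent seed, reproducibly
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max, k))
}

stopifnot_scalar_num <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  ok <- if (strict) x > min else x >= min
  if (!ok) {
    stop(sprintf("`%s` must be %s %s", name, if (strict) ">" else ">=", min),
         call. = FALSE)
  }
  invisible(x)
}
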