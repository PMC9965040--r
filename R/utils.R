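## Internal helpers shared across the pipeline.

CLUSTERS <- c("occipital", "parietal", "central", "frontal")
COMPONENTS <- c("P1", "N170", "P2", "P3")

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the generator locally and restores the caller's `.Random.seed`
#' afterwards, so simulation functions are deterministic without clobbering the
#' session RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a master seed and one or more counters, staying
## inside the 32-bit integer range. Deterministic and independent of call order.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + as.double(i) * 7919 + 1) %% 2147483647
  }
  as.integer(s)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower) {
    if (x <= lower) stop(sprintf("`%s` must be > %s", name, lower), call. = FALSE)
  } else if (x < lower) {
    stop(sprintf("`%s` must be >= %s", name, lower), call. = FALSE)
  }
  if (x > upper) stop(sprintf("`%s` must be <= %s", name, upper), call. = FALSE)
  invisible(x)
}

## index of the sample nearest to time t (ms)
nearest_sample <- function(times, t) which.min(abs(times - t))
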