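# Internal helpers shared across modules.

#' Derive a reproducible integer seed from a sequence of keys
#'
#' Mixes integers and strings into a single seed below 2^31 so that every
#' stochastic stage (per-subject streams, per-run classification streams) can
#' be keyed deterministically off one master seed.
#'
#' @param ... integers or strings identifying the stream.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
hash_seed <- function(...) {
  keys <- unlist(list(...), use.names = FALSE)
  h <- 0
  for (k in keys) {
    if (is.character(k)) {
      codes <- utf8ToInt(k)
      k <- sum(codes * seq_along(codes)) %% 100003
    }
    stopifnot(is.finite(k))
    h <- (h * 69069 + (as.numeric(k) + 1) * 40503) %% 2147483629
  }
  as.integer(h)
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
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

# Numerical tolerance used when locating samples in closed time intervals.
.t_eps <- 1e-9

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
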