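#' @keywords internal
"_PACKAGE"

# Population (1/N) variance; the response statistics in this package use the
# population convention throughout so that moments of short windows are
# well defined down to a single sample.
var_pop <- function(x) {
  mean((x - mean(x))^2)
}

sem <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  stats::sd(x) / sqrt(n)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}

# Draw `n` independent child seeds from a single master seed without
# disturbing the caller's RNG stream. Stage k of a pipeline always receives
# the k-th child, so stages can be rerun in isolation.
expand_seeds <- function(seed, n) {
  stopifnot_scalar(seed, "seed")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
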