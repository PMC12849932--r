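## Internal RNG plumbing: every user-facing stochastic operation takes an
## integer seed, scopes it locally (the caller's global RNG state is restored
## on exit), and fans out to named child streams so components can be
## regenerated independently.

#' @noRd
local_rng <- function(seed, envir = parent.frame()) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  expr <- if (has_old) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call("on.exit", list(expr, add = TRUE), envir = envir)
  set.seed(as.integer(seed))
  invisible(NULL)
}

#' Derive a deterministic child seed from a parent seed
#'
#' One global seed fans out to per-component streams ("design", "ratings",
#' "choices", "neural", ...) so components can be regenerated independently
#' while staying reproducible. Always returns a positive integer < 2^31.
#'
#' @param seed Parent integer seed.
#' @param stream Character stream name.
#' @return Integer child seed.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131)
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483563) + 1L
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_complete_table <- function(values, what = "values") {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (anyNA(values)) stop(what, " table must be complete (no missing cells)")
  values
}
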