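#' @keywords internal
#' @useDynLib hypercon, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Internal helpers shared across modules. Nothing here is exported.

stop_hc <- function(..., class = "hypercon_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf,
                                 lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_hc(name, " must be a finite numeric scalar",
            class = "hypercon_param_error")
  ok_lo <- if (lo_open) x > lo else x >= lo
  ok_hi <- if (hi_open) x < hi else x <= hi
  if (!ok_lo || !ok_hi)
    stop_hc(name, " = ", format(x), " outside allowed range ",
            if (lo_open) "(" else "[", lo, ", ", hi,
            if (hi_open) ")" else "]",
            class = "hypercon_param_error")
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      x < min)
    stop_hc(name, " must be an integer >= ", min,
            class = "hypercon_param_error")
  invisible(as.integer(x))
}

# One named RNG stream per operation: every sampling routine runs under
# withr-style local seed so callers' RNG state is never disturbed.
with_seed <- function(seed, code) {
  seed <- assert_count(seed, "seed", min = 0L)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Derive a child seed from a base seed, kept inside 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

upper_pairs <- function(n) {
  # all unordered pairs i < j as a 2-column integer matrix
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)[, c(1L, 2L), drop = FALSE]
}
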