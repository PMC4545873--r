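#' @keywords internal
#' @useDynLib sweepscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Deterministic sub-seed from a top-level seed and a stream label.
# Keeps restarts of one population from perturbing the other's stream.
derive_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(as.character(label))) {
    h <- (h * 31 + k) %% 2147483629
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trapezoidal integral of y against x (x ascending).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite scalar", name), call. = FALSE)
  invisible(x)
}
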