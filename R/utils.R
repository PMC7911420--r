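# Internal helpers: seeded evaluation, seed derivation, circular statistics.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so seeded operations do not perturb the
# global stream. `seed = NULL` evaluates in the ambient state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a child seed from a parent seed plus integer salts.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  salts <- c(seed, ...)
  h <- 0
  for (s in salts) h <- (h * 69069 + as.numeric(s) + 12345) %% 2147483629
  as.integer(h)
}

#' Circular mean of angles
#'
#' Mean direction of a set of angles, computed as the argument of the mean
#' unit phasor. Returns `NA` for an empty input.
#'
#' @param theta numeric vector of angles in radians.
#' @return a single angle in `(-pi, pi]`, or `NA_real_` if `theta` is empty.
#' @export
circular_mean <- function(theta) {
  theta <- theta[is.finite(theta)]
  if (length(theta) == 0L) return(NA_real_)
  wrap_angle(atan2(mean(sin(theta)), mean(cos(theta))))
}

#' Signed circular distance between two angles
#'
#' @param a,b angles in radians.
#' @return the signed difference `a - b`, wrapped into `(-pi, pi]`.
#' @export
circular_diff <- function(a, b) wrap_angle(a - b)

#' Wrap angles into the interval (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into `(-pi, pi]`.
#' @export
wrap_angle <- function(x) {
  w <- x - 2 * pi * floor((x + pi) / (2 * pi))
  w[w <= -pi] <- pi   # map the -pi representative to +pi
  w
}

# Short content hash (FNV-1a over the serialized object) used for provenance.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mod <- function(stage, fmt, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(fmt, ...)), call. = FALSE)
}
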