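#' @keywords internal
"_PACKAGE"

# Evaluate `expr` with a temporarily fixed RNG state; restores (or removes)
# the global .Random.seed afterwards so callers stay reproducible.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a 32-bit hash of an R object's deparsed form. Used to stamp outputs
# with a configuration fingerprint; not cryptographic.
#' Fingerprint a configuration object
#'
#' Computes a 32-bit FNV-1a hash over the deparsed object, so any change to
#' a threshold or option changes the reported hash.
#'
#' @param x Any R object (typically a config list).
#' @return A character scalar, 8 hex digits.
#' @export
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    # xor only touches the low byte since b < 256
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    # multiply mod 2^32 without losing double precision
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * m) %% 65536) * 65536 + h0 * m) %% 2^32
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

vec_norm <- function(v) sqrt(sum(v^2))

# Unit vector orthogonal to `v`, drawn uniformly at random (RNG state of the
# caller is used).
random_perpendicular <- function(v) {
  v <- v / vec_norm(v)
  repeat {
    w <- stats::rnorm(3)
    w <- w - sum(w * v) * v
    n <- vec_norm(w)
    if (n > 1e-8) return(w / n)
  }
}

# Rotate vector x about unit axis k by angle theta (radians), Rodrigues.
rotate_about_axis <- function(x, k, theta) {
  k <- k / vec_norm(k)
  x * cos(theta) + pracma_cross(k, x) * sin(theta) +
    k * sum(k * x) * (1 - cos(theta))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
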