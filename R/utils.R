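# Shared small helpers: angle arithmetic and circular distributions.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles into [0, 2*pi)
#' @param x numeric vector of angles (radians).
#' @return angles wrapped to [0, 2*pi).
#' @export
wrap_angle <- function(x) {
  x %% (2 * pi)
}

#' Signed angular difference a - b wrapped to (-pi, pi]
#' @param a,b numeric vectors of angles (radians).
#' @return signed differences in (-pi, pi].
#' @export
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' von Mises density
#' @param x angles (radians).
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @param log return log-density?
#' @return density values.
#' @export
dvonmises <- function(x, mu = 0, kappa = 1, log = FALSE) {
  stopifnot(kappa >= 0)
  # besselI with expon.scaled for numerical stability at large kappa
  ld <- kappa * cos(x - mu) - kappa -
    log(2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
  if (log) ld else exp(ld)
}

#' Sample from a von Mises distribution
#'
#' Best & Fisher rejection sampler; uses the session RNG stream.
#' @param n sample size.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0); 0 gives the circular uniform.
#' @return angles in [0, 2*pi).
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) {
    return(stats::runif(n, 0, 2 * pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    m <- ceiling(m * 1.3)
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- stats::runif(m)
    acc <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    if (any(acc)) {
      u3 <- stats::runif(sum(acc))
      out <- c(out, mu + sign(u3 - 0.5) * acos(f[acc]))
    }
  }
  wrap_angle(out[seq_len(n)])
}

# Mean resultant length -> kappa (A1 inverse, Fisher 1993 approximation).
a1inv <- function(r) {
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

# Deterministic child seeds below 2^31 from one parent seed.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
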