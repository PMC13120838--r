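#' @keywords internal
"_PACKAGE"

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# route through this so that (config, seed) -> bit-identical output holds
# without clobbering the user's RNG stream.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible child seed from a parent seed and a stream index,
# kept within 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 101 * stream) %% 2147483647L)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' Analytic signal via the Hilbert transform
#'
#' Computes the complex analytic extension of a real series using the
#' frequency-domain construction (positive frequencies doubled, negative
#' zeroed). The argument of the result is the instantaneous phase and its
#' modulus the instantaneous amplitude envelope.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) stop_config("analytic_signal: empty input")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Hann taper of length n (periodic symmetric form used for spectral windows).
hann_taper <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Draw n angles from a von Mises distribution with mean mu and
# concentration kappa, by Best & Fisher (1979) rejection sampling.
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop_config("von Mises concentration must be >= 0")
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (kappa > 5e5) return(rep(wrap_angle(mu), n)) # degenerate limit
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- wrap_angle(mu + sign(u[3] - 0.5) * acos(f))
      i <- i + 1L
    }
  }
  out
}

# Wrap angles to (-pi, pi].
wrap_angle <- function(x) {
  w <- x - 2 * pi * floor((x + pi) / (2 * pi))
  w[w <= -pi] <- pi # map -pi to pi so the interval is (-pi, pi]
  w
}

# FFT-friendly length at or above n (products of 2, 3 and 5).
next_fast_len <- function(n) stats::nextn(n, c(2L, 3L, 5L))
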