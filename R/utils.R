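#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators are pure
#' functions of their arguments and do not disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# smallest power of two >= n (FFT-friendly length)
next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

# smallest 5-smooth number >= n: R's mixed-radix FFT handles 2^a 3^b 5^c
# lengths efficiently, and these sit much closer to n than the next power of 2
next_smooth <- function(n) {
  n <- max(as.integer(n), 2L)
  best <- next_pow2(n)
  p5 <- 1
  while (p5 < best) {
    p35 <- p5
    while (p35 < best) {
      # smallest 2^a * p35 >= n
      cand <- p35 * 2^max(1, ceiling(log2(n / p35)))  # keep lengths even
      if (cand >= n && cand < best) best <- cand
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  best
}

# centred moving average over an odd window; edges use shrinking windows
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  k <- rep(1 / width, width)
  n <- length(x)
  y <- stats::filter(x, k, sides = 2)
  # repair NA edges with cumulative means
  half <- (width - 1L) %/% 2L
  for (i in seq_len(half)) {
    y[i] <- mean(x[1:min(n, i + half)])
    y[n - i + 1L] <- mean(x[max(1L, n - i + 1L - half):n])
  }
  as.numeric(y)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Draw from a von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler. `kappa = 0` reduces to the uniform
#' distribution on the circle; large `kappa` concentrates tightly around `mu`.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration parameter, `>= 0`.
#' @return numeric vector of angles in (-pi, pi] shifted by `mu`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stopf("kappa must be >= 0 (got %g)", kappa)
  if (kappa == 0) {
    return(stats::runif(n, -pi, pi) + mu)
  }
  if (kappa > 1e6) {
    # numerically degenerate: effectively a point mass with tiny wrapped-normal spread
    return(mu + stats::rnorm(n, 0, sqrt(1 / kappa)))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      u3 <- stats::runif(1)
      out[i] <- sign(u3 - 0.5) * acos(f) + mu
      i <- i + 1L
    }
  }
  out
}

# expected resultant length of the von Mises distribution, I1(k)/I0(k)
vm_mean_resultant <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}
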