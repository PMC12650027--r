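#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm sd quantile shapiro.test t.test wilcox.test
#'   p.adjust qnorm approx
#' @importFrom rlang .data abort
#' @useDynLib learnwalk, .registration = TRUE
NULL

# Wrap an angle (radians) into (-pi, pi].
wrap_angle <- function(a) {
  w <- ((a + pi) %% (2 * pi)) - pi
  w[w <= -pi + 1e-15] <- pi
  w
}

# Absolute circular difference in [0, pi].
ang_diff <- function(a, b) abs(wrap_angle(a - b))

#' Draw from a von Mises distribution
#'
#' Circular analogue of the Gaussian, used for the agent's stochastic steps.
#' Uses the Best-Fisher (1979) rejection sampler.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration parameter (>= 0); `kappa = 0` is uniform on the
#'   circle.
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (kappa < 1e-8) return(wrap_angle(runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
        break
      }
    }
  }
  wrap_angle(out + mu)
}

# Derive reproducible sub-seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
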