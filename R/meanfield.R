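#' Stationary Poisson abundance profile
#'
#' In the transfer/loss regime (`p_d = 0`) the mean-field steady state of the
#' collisional model is a Poisson distribution whose single parameter is the
#' (conserved) mean abundance `lambda`. The pmf is evaluated in log space and
#' truncated at `v_max`.
#'
#' @param lambda mean abundance (> 0).
#' @param v_max truncation of the support (default 450, matching the
#'   truncation used by the empirical L1 statistic).
#' @return An `analytic_profile`: list with `lambda`, `v_max`, `pmf` (over
#'   `v = 0..v_max`), and `family = "poisson"`.
#' @examples
#' pr <- poisson_profile(30)
#' sum(pr$pmf)  # ~1
#' @export
poisson_profile <- function(lambda, v_max = 450L) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L)
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  v_max <- as.integer(v_max)
  if (v_max < 0L) stop("v_max must be >= 0")
  v <- 0:v_max
  pmf <- exp(v * log(lambda) - lambda - lgamma(v + 1))
  structure(list(lambda = lambda, v_max = v_max, pmf = pmf, family = "poisson"),
            class = "analytic_profile")
}

#' Mean-field stationary variance of the abundance
#'
#' At steady state the model predicts
#' `Var(V) = lambda * (1 + p_d / (p_h * (1 - p_h)))`: duplication inflates the
#' variance above the Poisson value `lambda`, and the formula is singular at
#' `p_h = 0` or `p_h = 1`.
#'
#' @param lambda mean abundance (> 0).
#' @param p_h horizontal gain probability, strictly inside (0, 1).
#' @param p_d duplication probability (>= 0).
#' @return The stationary variance.
#' @examples
#' stationary_variance(30, 0.01, 0)        # 30: Poisson
#' stationary_variance(30, 0.001, 0.009)   # ~300.27
#' @export
stationary_variance <- function(lambda, p_h, p_d) {
  stopifnot(lambda > 0, p_d >= 0)
  if (p_h <= 0 || p_h >= 1)
    stop("the variance formula is singular at p_h = 0 or 1")
  lambda * (1 + p_d / (p_h * (1 - p_h)))
}

#' Negative-binomial profile in the grazing-collision limit
#'
#' When `p_d` and `p_h` both tend to 0 at fixed ratio, the stationary profile
#' is a negative binomial with mean `lambda` and variance
#' `lambda * (p_d + p_h) / p_h`. Moment matching fixes the parameterization:
#' success probability `q = p_h / (p_d + p_h)` and size
#' `r = lambda * p_h / p_d`. For `p_d = 0` the Poisson profile is returned.
#'
#' @inheritParams poisson_profile
#' @param p_h horizontal gain probability (> 0).
#' @param p_d duplication probability (>= 0).
#' @return An `analytic_profile` with `family = "negative_binomial"` (or
#'   `"poisson"` when `p_d = 0`); negative-binomial profiles also carry
#'   `size` and `prob`.
#' @examples
#' pr <- grazing_limit_profile(30, p_h = 0.001, p_d = 0.009)
#' sum(pr$pmf * 0:pr$v_max)  # mean ~30
#' @export
grazing_limit_profile <- function(lambda, p_h, p_d, v_max = 450L) {
  stopifnot(lambda > 0, p_h > 0, p_d >= 0)
  if (p_d == 0) return(poisson_profile(lambda, v_max))
  v_max <- as.integer(v_max)
  v <- 0:v_max
  size <- lambda * p_h / p_d
  prob <- p_h / (p_d + p_h)
  pmf <- dnbinom(v, size = size, prob = prob)
  structure(list(lambda = lambda, v_max = v_max, pmf = pmf,
                 family = "negative_binomial", size = size, prob = prob),
            class = "analytic_profile")
}

#' @export
print.analytic_profile <- function(x, ...) {
  v <- 0:x$v_max
  cat(sprintf("Analytic %s profile: lambda = %g (mean by summation %.4f, var %.4f), v_max = %d\n",
              x$family, x$lambda, sum(v * x$pmf),
              sum(v^2 * x$pmf) - sum(v * x$pmf)^2, x$v_max))
  invisible(x)
}

#' Relaxation time of the abundance moments
#'
#' All moments approach their stationary values exponentially with time
#' constant `1 / (p_h * (1 - p_h))`, measured in sweeps of `N` collisions.
#' The relaxation depends only on `p_h`, even when `p_d > 0`.
#'
#' @param p_h horizontal gain probability, strictly inside (0, 1).
#' @return The relaxation time in sweeps.
#' @examples
#' relaxation_time_sweeps(0.5)   # 4
#' relaxation_time_sweeps(0.01)  # ~101
#' @export
relaxation_time_sweeps <- function(p_h) {
  if (p_h <= 0 || p_h >= 1) stop("p_h must lie strictly inside (0, 1)")
  1 / (p_h * (1 - p_h))
}

#' Expected exponential approach of the variance to stationarity
#'
#' @param t time in sweeps (>= 0, vectorized).
#' @param var0 initial ensemble variance.
#' @param var_inf stationary variance.
#' @param p_h horizontal gain probability.
#' @return `var_inf + (var0 - var_inf) * exp(-t * p_h * (1 - p_h))`.
#' @export
expected_variance_trajectory <- function(t, var0, var_inf, p_h) {
  stopifnot(all(t >= 0))
  var_inf + (var0 - var_inf) * exp(-t * p_h * (1 - p_h))
}
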