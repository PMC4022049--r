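#' Fit a beta distribution to a mean and 95% confidence limits
#'
#' Annual transition probabilities are modelled as beta distributed. Printed
#' summaries report a mean and a 95% confidence interval, so the shape pair
#' is recovered numerically: the mean is matched exactly (which leaves one
#' free shape parameter once `alpha/(alpha+beta) = mean_p` is imposed) and
#' the remaining degree of freedom is chosen to reproduce the central 95%
#' interval as closely as possible. When no shape pair brings both limits
#' within `tol_ci` of the targets, the fit falls back to method of moments
#' on the implied standard deviation `(ucl - lcl)/3.92` and flags itself.
#'
#' @param mean_p Mean annual probability, strictly inside (0, 1).
#' @param lcl,ucl 95% confidence limits, with `lcl < mean_p < ucl`.
#' @param tol_ci Acceptance tolerance on each reproduced quantile.
#' @return A list with elements `alpha`, `beta`, `method` (`"ci_match"` or
#'   `"moments"`), and `ci_error` (largest absolute deviation of the fitted
#'   2.5%/97.5% quantiles from the requested limits).
#' @examples
#' fit_beta_from_ci(0.10, 0.05, 0.17)
#' @export
fit_beta_from_ci <- function(mean_p, lcl, ucl, tol_ci = 5e-3) {
  if (!is.finite(mean_p) || mean_p <= 0 || mean_p >= 1) {
    stop("mean_p must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!(lcl < mean_p && mean_p < ucl)) {
    stop("confidence limits must bracket the mean: lcl < mean_p < ucl",
         call. = FALSE)
  }
  lcl <- max(lcl, 0)
  ucl <- min(ucl, 1)

  shapes <- function(log_alpha) {
    a <- exp(log_alpha)
    c(alpha = a, beta = a * (1 - mean_p) / mean_p)
  }
  objective <- function(log_alpha) {
    s <- shapes(log_alpha)
    (stats::qbeta(0.025, s[1], s[2]) - lcl)^2 +
      (stats::qbeta(0.975, s[1], s[2]) - ucl)^2
  }
  opt <- stats::optimize(objective, interval = c(-12, 18))
  s <- shapes(opt$minimum)
  err <- max(abs(stats::qbeta(0.025, s[1], s[2]) - lcl),
             abs(stats::qbeta(0.975, s[1], s[2]) - ucl))
  if (err <= tol_ci) {
    return(list(alpha = unname(s[1]), beta = unname(s[2]),
                method = "ci_match", ci_error = err))
  }

  # Method-of-moments fallback: normal-approximation SD from the interval
  # width. Also preserves the mean exactly.
  sd <- (ucl - lcl) / 3.92
  k <- mean_p * (1 - mean_p) / sd^2 - 1
  if (k <= 0) {
    # Interval wider than a Bernoulli spread allows; use a vague fit.
    k <- 2
  }
  alpha <- mean_p * k
  beta <- (1 - mean_p) * k
  err_mm <- max(abs(stats::qbeta(0.025, alpha, beta) - lcl),
                abs(stats::qbeta(0.975, alpha, beta) - ucl))
  list(alpha = alpha, beta = beta, method = "moments", ci_error = err_mm)
}

#' Triangular distribution
#'
#' Utility and cost parameters enter the probabilistic sensitivity analysis
#' as triangular distributions: the point estimate is the mode and the 95%
#' confidence limits are the minimum and maximum. `sample_triangular` draws
#' by inverse-CDF; `ptriangular` evaluates the distribution function.
#' A degenerate specification (`min == mode == max`) returns the mode.
#'
#' @param n Number of draws.
#' @param mode Most likely value, with `min <= mode <= max`.
#' @param min,max Support limits.
#' @param q Quantile(s) at which to evaluate the CDF.
#' @return `sample_triangular` returns a numeric vector of `n` draws in
#'   `[min, max]`; `ptriangular` returns CDF values.
#' @examples
#' set.seed(1)
#' mean(sample_triangular(1e4, mode = 0.5, min = 0, max = 1)) # ~ 0.5
#' @export
sample_triangular <- function(n, mode, min, max) {
  if (any(min > max)) stop("min must not exceed max", call. = FALSE)
  if (any(mode < min | mode > max)) {
    stop("mode must lie within [min, max]", call. = FALSE)
  }
  if (max == min) return(rep(mode, n))
  u <- stats::runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' @rdname sample_triangular
#' @export
ptriangular <- function(q, mode, min, max) {
  if (min > max) stop("min must not exceed max", call. = FALSE)
  if (max == min) return(as.numeric(q >= mode))
  p <- numeric(length(q))
  left <- q > min & q <= mode
  right <- q > mode & q < max
  p[left] <- (q[left] - min)^2 / ((max - min) * (mode - min))
  p[right] <- 1 - (max - q[right])^2 / ((max - min) * (max - mode))
  p[q >= max] <- 1
  p
}
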