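#' Goodness-of-fit statistics for a fitted distribution
#'
#' EDF statistics comparing a sample with a fitted continuous CDF, in the
#' forms standard for model-adequacy tables of lifetime analyses:
#'
#' * `ks_test_fitted`: the Kolmogorov-Smirnov statistic
#'   \eqn{D = \max_i \max\{i/n - z_i,\; z_i - (i-1)/n\}} over the order
#'   statistics \eqn{z_i = F(x_{(i)})}, with p-value from the asymptotic
#'   Kolmogorov distribution at \eqn{\sqrt{n}D} (no small-sample
#'   correction).
#' * `ad_statistic`: the modified Anderson-Darling statistic
#'   \eqn{A^* = A^2 (1 + 0.75/n + 2.25/n^2)} with
#'   \eqn{A^2 = -n - n^{-1}\sum (2i-1)\{\ln z_i + \ln(1 - z_{n+1-i})\}}.
#' * `cvm_statistic`: the modified Cramer-von Mises statistic
#'   \eqn{W^* = W^2 (1 + 0.5/n)} with
#'   \eqn{W^2 = 1/(12n) + \sum \{z_i - (2i-1)/(2n)\}^2}.
#'
#' `z` values numerically at 0 or 1 are clipped to
#' \eqn{[10^{-12}, 1-10^{-12}]} with a warning (the log terms would
#' otherwise be infinite).
#'
#' @param x sample (will be sorted).
#' @param cdf a vectorized CDF function of one argument.
#' @return `ks_test_fitted` returns `list(statistic, p.value)`; the other
#'   two return a single numeric value.
#' @examples
#' x <- ollged_data("kiama64")
#' lam <- 1 / mean(x)
#' ks_test_fitted(x, function(q) pexp(q, lam))
#' @export
ks_test_fitted <- function(x, cdf) {
  x <- check_sample(x)
  n <- length(x)
  z <- cdf(x)
  i <- seq_len(n)
  D <- max(pmax(i / n - z, z - (i - 1) / n))
  list(statistic = D, p.value = ks_pvalue(sqrt(n) * D))
}

# Asymptotic Kolmogorov distribution Q(t) = P(sup|B| > t); two convergent
# series, switched at t = 0.755 where both are fast.
ks_pvalue <- function(t) {
  if (!is.finite(t) || t <= 0) return(1)
  if (t < 0.2) return(1)
  if (t < 0.755) {
    k <- 1:20
    return(max(0, min(1, 1 - sqrt(2 * pi) / t *
                        sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * t^2))))))
  }
  k <- 1:101
  max(0, min(1, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

.clip_z <- function(z) {
  if (any(z <= 0) || any(z >= 1)) {
    warning("fitted CDF values at 0 or 1 clipped for EDF statistics")
    z <- pmin(pmax(z, 1e-12), 1 - 1e-12)
  }
  z
}

#' @rdname ks_test_fitted
#' @export
ad_statistic <- function(x, cdf) {
  x <- check_sample(x)
  n <- length(x)
  z <- .clip_z(cdf(x))
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (log(z) + log(1 - rev(z))))
  A2 * (1 + 0.75 / n + 2.25 / n^2)
}

#' @rdname ks_test_fitted
#' @export
cvm_statistic <- function(x, cdf) {
  x <- check_sample(x)
  n <- length(x)
  z <- .clip_z(cdf(x))
  i <- seq_len(n)
  W2 <- 1 / (12 * n) + sum((z - (2 * i - 1) / (2 * n))^2)
  W2 * (1 + 0.5 / n)
}

#' Information criteria from a maximized log-likelihood
#'
#' `aic = -2l + 2k` and `bic = -2l + k log(n)`.
#'
#' @param minus2loglik minus twice the maximized log-likelihood.
#' @param k number of free parameters.
#' @param n sample size.
#' @return Named vector `c(aic, bic)`.
#' @examples
#' information_criteria(579.4480, 3, 64)
#' @export
information_criteria <- function(minus2loglik, k, n) {
  c(aic = minus2loglik + 2 * k, bic = minus2loglik + k * log(n))
}

#' Goodness-of-fit report for one fitted model
#'
#' Bundles \eqn{-2\hat\ell}, AIC, BIC and the EDF statistics
#' (\eqn{W^*}, \eqn{A^*}, KS with asymptotic p-value) for a fit returned by
#' [fit_mle()].  AIC and BIC are always recomputed from \eqn{-2\hat\ell},
#' `k` and `n`, never stored independently.
#'
#' @param fit an `"ollged_fit"` object.
#' @return An object of class `"gof_report"` (a named list).
#' @examples
#' gof_report(fit_mle(ollged_data("chemo45"), ed_model()))
#' @export
gof_report <- function(fit) {
  stopifnot(inherits(fit, "ollged_fit"))
  x <- fit$x
  cdf <- function(q) fit$model$cdf(q, fit$estimate)
  ic <- information_criteria(fit$minus2loglik, fit$model$k, fit$n)
  ks <- ks_test_fitted(x, cdf)
  structure(list(model = fit$model$name,
                 minus2loglik = fit$minus2loglik,
                 aic = unname(ic["aic"]), bic = unname(ic["bic"]),
                 w_star = cvm_statistic(x, cdf),
                 a_star = ad_statistic(x, cdf),
                 ks_stat = ks$statistic, ks_pvalue = ks$p.value,
                 k_params = fit$model$k, n = fit$n),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, digits = 4, ...) {
  cat("Goodness of fit:", x$model, sprintf("(k = %d, n = %d)\n",
                                           x$k_params, x$n))
  v <- c("-2l" = x$minus2loglik, AIC = x$aic, BIC = x$bic,
         "W*" = x$w_star, "A*" = x$a_star, KS = x$ks_stat,
         "p" = x$ks_pvalue)
  print(round(v, digits))
  invisible(x)
}
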