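#' Log-likelihood of a fitted family
#'
#' Sum of log-densities of `x` under `model` at parameter vector `theta`
#' (natural scale, in the model's parameter order).  Returns `-Inf` when
#' any observation has zero density.
#'
#' @param x positive sample.
#' @param theta parameter vector on the natural scale.
#' @param model a `"surv_model"`, default the OLLGED.
#' @return The log-likelihood (a single number).
#' @examples
#' ollged_loglik(c(1), c(1, 1, 1))   # log dexp(1) = -1
#' @export
ollged_loglik <- function(x, theta, model = ollged_model()) {
  x <- check_sample(x)
  sum(model$logpdf(x, theta))
}

# guarded negative log-likelihood in log-parameter space
.make_nll <- function(model, x) {
  function(psi) {
    if (any(!is.finite(psi)) || any(abs(psi) > 40)) return(1e10)
    v <- -sum(model$logpdf(x, exp(psi)))
    if (!is.finite(v)) 1e10 else v
  }
}

#' Maximum-likelihood fit by multi-start quasi-Newton optimization
#'
#' Maximizes the log-likelihood of `model` over log-parameterized space
#' (so positivity constraints are free), running BFGS from every point of a
#' deterministic start grid (plus seeded log-normal jitter when `n_starts`
#' exceeds the grid) and keeping the best local optimum, which is then
#' polished by a Nelder-Mead/BFGS round.  Ties in likelihood between starts
#' are broken towards the smaller shape estimate.  Standard errors come from
#' the numerically observed information ([observed_information()]); when
#' that matrix is not positive definite the fit is still returned with `se`
#' set to `NA`.
#'
#' The one-parameter exponential model bypasses optimization entirely:
#' \eqn{\hat\lambda = 1/\bar x} in closed form.
#'
#' @param x positive sample (coerced to sorted).
#' @param model a `"surv_model"`; default [ollged_model()].
#' @param n_starts number of starting points; `NULL` uses the model's full
#'   deterministic grid.
#' @param seed integer seed controlling the jittered starts (the
#'   deterministic grid does not depend on it).
#' @param control passed on to [stats::optim()] (merged over the defaults
#'   `maxit = 500`, `reltol = 1e-12`).
#' @return An object of class `"ollged_fit"`: a list with `estimate`
#'   (named), `se`, `loglik`, `minus2loglik`, `converged`, `n_starts`,
#'   `best_start`, `info` (observed information), `vcov`, `model` and the
#'   sorted sample `x`.
#' @examples
#' x <- ollged_data("chemo45")
#' fit <- fit_mle(x, ged_model())
#' coef(fit); logLik(fit)
#' @export
fit_mle <- function(x, model = ollged_model(), n_starts = NULL, seed = 1L,
                    control = list()) {
  x <- check_sample(x)
  stopifnot(inherits(model, "surv_model"))
  if (length(x) < model$k + 1)
    stop("need at least ", model$k + 1, " observations to fit ",
         model$name, call. = FALSE)

  if (!is.null(model$closed_fit)) {
    th <- model$closed_fit(x)
    ll <- sum(model$logpdf(x, th))
    info <- observed_information(x, th, model)
    return(.finish_fit(model, x, th, ll, TRUE, 1L, th, info))
  }

  nll <- .make_nll(model, x)
  ctl <- utils::modifyList(list(maxit = 500, reltol = 1e-12), control)
  starts <- model$starts(x, n_starts, seed)
  best <- NULL; best_start <- NULL; any_conv <- FALSE
  for (s in starts) {
    f <- tryCatch(stats::optim(log(s), nll, method = "BFGS", control = ctl),
                  error = function(e) NULL)
    if (is.null(f) || !is.finite(f$value) || f$value >= 1e9) next
    any_conv <- any_conv || f$convergence == 0
    take <- is.null(best) || f$value < best$value - 1e-10 ||
      (abs(f$value - best$value) <= 1e-10 && !is.na(model$tie_par) &&
         f$par[model$tie_par] < best$par[model$tie_par])
    if (take) { best <- f; best_start <- s }
  }
  if (is.null(best))
    stop("all optimization starts failed for model ", model$name,
         call. = FALSE)
  # polish: a Nelder-Mead sweep can slide further along flat ridges, then
  # BFGS re-tightens
  p <- best$par
  f <- tryCatch(stats::optim(p, nll, method = "Nelder-Mead",
                             control = list(maxit = 2000, reltol = 1e-14)),
                error = function(e) NULL)
  if (!is.null(f) && f$value <= best$value) { best <- f; p <- f$par }
  f <- tryCatch(stats::optim(p, nll, method = "BFGS", control = ctl),
                error = function(e) NULL)
  if (!is.null(f) && f$value <= best$value) best <- f

  th <- exp(best$par)
  info <- observed_information(x, th, model)
  .finish_fit(model, x, th, -best$value, any_conv, length(starts),
              best_start, info)
}

.finish_fit <- function(model, x, theta, loglik, converged, n_starts,
                        best_start, info) {
  names(theta) <- model$par_names
  vc <- tryCatch(solve(info), error = function(e) NULL)
  se <- rep(NA_real_, model$k)
  if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0))
    se <- sqrt(diag(vc))
  names(se) <- model$par_names
  structure(list(model = model, x = x, n = length(x),
                 estimate = theta, se = se,
                 loglik = loglik, minus2loglik = -2 * loglik,
                 converged = converged, n_starts = n_starts,
                 best_start = best_start, info = info, vcov = vc),
            class = "ollged_fit")
}

#' Numerically observed information matrix
#'
#' Negative Hessian of the log-likelihood at `theta`, computed by central
#' finite differences of the log-likelihood in log-parameter space (step
#' \eqn{h = 10^{-4}} per log-parameter) and mapped back to the natural scale
#' by the chain rule \eqn{H_\theta = D^{-1}(H_\psi - \mathrm{diag}\,g_\psi)
#' D^{-1}} with \eqn{\psi = \log\theta}, \eqn{D = \mathrm{diag}\,\theta}.
#' Working on the log scale keeps the differencing well conditioned when the
#' parameters differ by orders of magnitude.
#'
#' @param x positive sample.
#' @param theta parameter vector (natural scale), normally the MLE.
#' @param model a `"surv_model"`.
#' @return A symmetric k-by-k matrix.
#' @examples
#' x <- ollged_data("kiama64")
#' observed_information(x, 1 / mean(x), ed_model())  # ~ n * mean(x)^2
#' @export
observed_information <- function(x, theta, model = ollged_model()) {
  x <- check_sample(x)
  k <- length(theta)
  ll <- function(psi) {
    v <- sum(model$logpdf(x, exp(psi)))
    if (!is.finite(v)) NA_real_ else v
  }
  psi <- log(theta)
  h <- rep(1e-4, k)
  H <- matrix(NA_real_, k, k)
  g <- numeric(k)
  f0 <- ll(psi)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    g[i] <- (ll(psi + ei) - ll(psi - ei)) / (2 * h[i])
    H[i, i] <- (ll(psi + ei) - 2 * f0 + ll(psi - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (ll(psi + ei + ej) - ll(psi + ei - ej) -
           ll(psi - ei + ej) + ll(psi - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  D <- diag(1 / theta, k)
  Htheta <- D %*% (H - diag(g, k)) %*% D
  -(Htheta + t(Htheta)) / 2
}

#' @export
print.ollged_fit <- function(x, digits = 4, ...) {
  cat("Maximum-likelihood fit:", x$model$label, "\n")
  cat("  n =", x$n, " (", x$n_starts, "start(s),",
      if (x$converged) "converged" else "NOT converged", ")\n")
  est <- format(round(x$estimate, digits), nsmall = digits)
  se <- ifelse(is.na(x$se), "NA", format(round(x$se, digits), nsmall = digits))
  for (i in seq_along(est))
    cat(sprintf("  %-8s %s (%s)\n", names(x$estimate)[i], est[i], se[i]))
  cat(sprintf("  log-likelihood %.4f  (-2l = %.4f)\n", x$loglik,
              x$minus2loglik))
  invisible(x)
}

#' @export
coef.ollged_fit <- function(object, ...) object$estimate

#' @export
logLik.ollged_fit <- function(object, ...) {
  structure(object$loglik, df = object$model$k, nobs = object$n,
            class = "logLik")
}

#' @export
vcov.ollged_fit <- function(object, ...) object$vcov
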