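#' Fit and compare several lifetime models on one sample
#'
#' Fits each model by [fit_mle()], computes the full goodness-of-fit panel
#' ([gof_report()]) and flags the winning model under each criterion
#' (smallest \eqn{-2\hat\ell}, AIC, BIC, \eqn{W^*}, \eqn{A^*} and KS;
#' largest KS p-value).  AIC/BIC are recomputed from \eqn{-2\hat\ell},
#' `k` and `n` inside [gof_report()] rather than carried along, so a report
#' can never be internally inconsistent.  A model whose fit fails is kept
#' as a row of `NA`s rather than aborting the report.
#'
#' @param x positive sample.
#' @param models list of `"surv_model"` objects (or character names among
#'   `"ollged"`, `"ged"`, `"ed"`, `"lld"`).
#' @param seed seed forwarded to each fit's jittered starts.
#' @param n_starts forwarded to [fit_mle()].
#' @return A `data.frame` of class `"model_comparison"` with one row per
#'   model and columns `model`, `minus2loglik`, `aic`, `bic`, `w_star`,
#'   `a_star`, `ks_stat`, `ks_pvalue`.  The fitted objects are attached as
#'   `attr(, "fits")` and the per-criterion winners as `attr(, "best")`.
#' @examples
#' cmp <- compare_models(ollged_data("kiama64"),
#'                       models = c("ollged", "ged", "ed", "lld"))
#' cmp
#' @export
compare_models <- function(x, models = list(ollged_model(), ged_model(),
                                            ed_model(), lld_model()),
                           seed = 1L, n_starts = NULL) {
  x <- check_sample(x)
  if (length(models) < 1) stop("need at least one model", call. = FALSE)
  models <- lapply(models, function(m)
    if (inherits(m, "surv_model")) m else model_by_name(m))

  rows <- list(); fits <- list()
  for (m in models) {
    fit <- tryCatch(fit_mle(x, m, n_starts = n_starts, seed = seed),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[m$name]] <- data.frame(model = m$name, minus2loglik = NA_real_,
                                   aic = NA_real_, bic = NA_real_,
                                   w_star = NA_real_, a_star = NA_real_,
                                   ks_stat = NA_real_, ks_pvalue = NA_real_)
      fits[[m$name]] <- NULL
      next
    }
    g <- gof_report(fit)
    rows[[m$name]] <- data.frame(model = m$name,
                                 minus2loglik = g$minus2loglik,
                                 aic = g$aic, bic = g$bic,
                                 w_star = g$w_star, a_star = g$a_star,
                                 ks_stat = g$ks_stat,
                                 ks_pvalue = g$ks_pvalue)
    fits[[m$name]] <- fit
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  lower_better <- c("minus2loglik", "aic", "bic", "w_star", "a_star",
                    "ks_stat")
  best <- lapply(out[lower_better], function(v)
    if (all(is.na(v))) NA_character_ else out$model[which.min(v)])
  best$ks_pvalue <- if (all(is.na(out$ks_pvalue))) NA_character_ else
    out$model[which.max(out$ks_pvalue)]
  structure(out, fits = fits, best = best, n = length(x),
            class = c("model_comparison", "data.frame"))
}

#' @export
print.model_comparison <- function(x, digits = 4, ...) {
  cat("Model comparison (n =", attr(x, "n"), "); * marks the best model",
      "per criterion\n")
  df <- as.data.frame(x)
  best <- attr(x, "best")
  disp <- df
  for (cn in names(df)[-1]) {
    val <- formatC(df[[cn]], format = "f", digits = digits)
    if (cn %in% names(best) && !is.na(best[[cn]]))
      val[df$model == best[[cn]]] <- paste0(val[df$model == best[[cn]]], "*")
    disp[[cn]] <- val
  }
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Estimates and standard errors of a comparison's fits
#'
#' @param cmp a `"model_comparison"`.
#' @return A data.frame with one row per parameter of each fitted model.
#' @export
comparison_estimates <- function(cmp) {
  fits <- attr(cmp, "fits")
  out <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm, parameter = names(f$estimate),
               estimate = unname(f$estimate), se = unname(f$se))
  })
  do.call(rbind, out)
}
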