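test_that("baseline distribution functions round-trip and reduce correctly", {
  p <- c(0.01, 0.2, 0.5, 0.8, 0.99)
  for (th in list(c(0.5, 2), c(2, 0.7), c(1, 1))) {
    expect_equal(pged(qged(p, th[1], th[2]), th[1], th[2]), p,
                 tolerance = 1e-10)
    expect_equal(plld(qlld(p, th[1], th[2]), th[1], th[2]), p,
                 tolerance = 1e-10)
  }
  x <- c(0.1, 1, 4)
  expect_equal(dged(x, 1.3, 1), dexp(x, 1.3), tolerance = 1e-13)
  expect_equal(qlld(0.5, 28.3, 1.96), 28.3, tolerance = 1e-12)  # median = scale
  I <- integrate(dlld, 0, Inf, scale = 2, shape = 1.5, rel.tol = 1e-10)$value
  expect_equal(I, 1, tolerance = 1e-8)
})

test_that("log-logistic density matches the flexsurv implementation", {
  library(flexsurv)
  x <- c(0.05, 0.4, 1, 3, 10)
  expect_equal(dlld(x, scale = 2.5, shape = 1.7),
               dllogis(x, shape = 1.7, scale = 2.5), tolerance = 1e-12)
  expect_equal(plld(x, scale = 2.5, shape = 1.7),
               pllogis(x, shape = 1.7, scale = 2.5), tolerance = 1e-12)
})

test_that("generalized exponential fit on the waiting times reproduces the published optimum", {
  x <- ollged_data("kiama64")
  fit <- fit_mle(x, ged_model(), seed = 1)
  expect_equal(fit$minus2loglik, 591.3320, tolerance = 0.01 / 591)
  expect_equal(unname(fit$estimate["lambda"]), 0.0349, tolerance = 0.01)
  expect_equal(unname(fit$estimate["alpha"]), 1.7309, tolerance = 0.01)
})

test_that("log-logistic fit on the waiting times reproduces the published optimum", {
  x <- ollged_data("kiama64")
  fit <- fit_mle(x, lld_model(), seed = 1)
  expect_equal(fit$minus2loglik, 593.1488, tolerance = 0.01 / 593)
  expect_equal(unname(fit$estimate["scale"]), 28.3417, tolerance = 0.01)
  expect_equal(unname(fit$estimate["shape"]), 1.9650, tolerance = 0.01)
})

test_that("exponential fits on both datasets hit the closed-form optima", {
  fitk <- fit_mle(ollged_data("kiama64"), ed_model())
  expect_equal(fitk$minus2loglik, 599.6254, tolerance = 1e-4 / 600)
  fitc <- fit_mle(ollged_data("chemo45"), ed_model())
  expect_equal(fitc$minus2loglik, 116.4372, tolerance = 1e-4 / 116)
  expect_equal(unname(fitc$estimate), 0.7455, tolerance = 1e-4)
})

test_that("model comparison flags the OLLGED as best on likelihood criteria", {
  cmp <- compare_models(ollged_data("kiama64"), seed = 1)
  best <- attr(cmp, "best")
  expect_identical(best$minus2loglik, "ollged")
  expect_identical(best$aic, "ollged")
  expect_identical(best$bic, "ollged")
  # AIC/BIC rows internally consistent with -2l, k, n
  k <- unname(c(ollged = 3, ged = 2, ed = 1, lld = 2)[cmp$model])
  expect_equal(cmp$aic, cmp$minus2loglik + 2 * k, tolerance = 1e-10)
  expect_equal(cmp$bic, cmp$minus2loglik + k * log(attr(cmp, "n")),
               tolerance = 1e-10)
  est <- comparison_estimates(cmp)
  expect_true(all(c("model", "parameter", "estimate", "se") %in% names(est)))
})

test_that("a single-model comparison yields a one-row report", {
  cmp <- compare_models(ollged_data("chemo45"), models = list(ed_model()))
  expect_equal(nrow(cmp), 1L)
  expect_identical(cmp$model, "ed")
})
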