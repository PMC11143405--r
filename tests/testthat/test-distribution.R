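test_that("odd log-logistic transform has its fixed points and closed-form values", {
  for (g in c(0.3, 1, 2.7, 10))
    expect_equal(oll_transform(0.5, g), 0.5)
  p <- seq(0.01, 0.99, by = 0.07)
  expect_equal(oll_transform(p, 1), p, tolerance = 1e-14)
  expect_equal(oll_transform(0.9, 2), 0.81 / (0.81 + 0.01))
  expect_equal(oll_transform(c(0, 1), 3), c(0, 1))
  expect_error(oll_transform(1.2, 2))
  expect_error(oll_transform(-0.1, 2))
  expect_error(oll_transform(0.5, -1))
})

test_that("gamma = 1 collapses to the generalized exponential, gamma = alpha = 1 to the exponential", {
  x <- c(0.05, 0.3, 1, 2.5, 7)
  for (la in c(0.5, 1, 2)) for (al in c(0.5, 1, 3)) {
    expect_equal(pollged(x, la, al, 1), pged(x, la, al), tolerance = 1e-12)
    expect_equal(pollged(x, la, al, 1), (-expm1(-la * x))^al, tolerance = 1e-12)
    expect_equal(dollged(x, la, al, 1), dged(x, la, al), tolerance = 1e-12)
  }
  for (la in c(0.5, 1, 2)) {
    expect_equal(dollged(x, la, 1, 1), dexp(x, la), tolerance = 1e-12)
    expect_equal(pollged(x, la, 1, 1), pexp(x, la), tolerance = 1e-12)
    expect_equal(qollged(c(0.1, 0.5, 0.9), la, 1, 1),
                 qexp(c(0.1, 0.5, 0.9), la), tolerance = 1e-12)
  }
})

test_that("density integrates to one over the full parameter grid", {
  vals <- c(0.2, 0.5, 1, 1.5, 2, 5)
  # piecewise quadrature anchored at quantiles; the lower piece substitutes
  # x = t^(1/(alpha*gamma)) to flatten the x^(alpha*gamma - 1) origin
  # singularity when alpha*gamma < 1
  total_mass <- function(la, al, ga) {
    cuts <- qollged(c(0.5, 0.999), la, al, ga)
    k <- max(1, 1 / (al * ga))
    low <- integrate(function(t)
      dollged(t^k, la, al, ga) * k * t^(k - 1),
      0, cuts[1]^(1 / k), rel.tol = 1e-10, subdivisions = 400L)$value
    low +
      integrate(dollged, cuts[1], cuts[2], lambda = la, alpha = al,
                gamma = ga, rel.tol = 1e-10, subdivisions = 400L)$value +
      integrate(dollged, cuts[2], Inf, lambda = la, alpha = al, gamma = ga,
                rel.tol = 1e-10, subdivisions = 400L)$value
  }
  for (la in vals) for (al in vals) for (ga in vals)
    expect_equal(total_mass(la, al, ga), 1, tolerance = 1e-8)
})

test_that("pdf is the derivative of the cdf", {
  set.seed(7)
  for (p in param_grid()) {
    x <- qollged(runif(5, 0.1, 0.95), p[1], p[2], p[3])
    dnum <- vapply(x, function(xx)
      num_deriv(function(t) pollged(t, p[1], p[2], p[3]), xx, h = 1e-5), 0)
    expect_equal(dollged(x, p[1], p[2], p[3]), dnum, tolerance = 1e-3)
  }
})

test_that("log density is consistent, stable far in the tail, and zero off-support", {
  set.seed(8)
  for (p in param_grid()) {
    x <- qollged(runif(20, 0.01, 0.99), p[1], p[2], p[3])
    lp <- dollged(x, p[1], p[2], p[3], log = TRUE)
    expect_equal(exp(lp), dollged(x, p[1], p[2], p[3]), tolerance = 1e-12)
  }
  expect_equal(dollged(500, 1, 1, 1, log = TRUE), -500)
  x <- c(0.4, 3)
  expect_equal(dollged(x, 2, 1, 1, log = TRUE), log(2) - 2 * x)
  expect_equal(dollged(c(-1, 0), 1, 2, 3), c(0, 0))
  expect_identical(dollged(-1, 1, 2, 3, log = TRUE), -Inf)
})

test_that("survival function complements the cdf without cancellation", {
  x <- c(0.01, 0.5, 2, 10, 50)
  for (p in param_grid()) {
    expect_equal(sollged(x, p[1], p[2], p[3]) + pollged(x, p[1], p[2], p[3]),
                 rep(1, length(x)), tolerance = 1e-14)
  }
  expect_equal(sollged(0, 1, 2, 3), 1)
  expect_equal(sollged(x, 2, 1, 1), exp(-2 * x), tolerance = 1e-13)
  # deep tail: log S(x) ~ gamma*(log alpha - lambda x); no underflow to 0
  ls <- log(sollged(200, 1, 1, 0.5))
  expect_equal(ls, -100, tolerance = 1e-6)
})

test_that("hazard equals pdf/sf, is constant for the exponential and increasing for GED alpha > 1", {
  x <- seq(0.1, 8, length.out = 40)
  for (p in param_grid()) {
    expect_equal(hollged(x, p[1], p[2], p[3]),
                 dollged(x, p[1], p[2], p[3]) / sollged(x, p[1], p[2], p[3]),
                 tolerance = 1e-10)
  }
  expect_equal(hollged(x, 1.7, 1, 1), rep(1.7, length(x)), tolerance = 1e-12)
  h <- hollged(seq(0.05, 10, length.out = 100), 1, 2, 1)
  expect_true(all(diff(h) > 0))
  expect_error(hollged(0, 1, 1, 1))
  expect_error(hollged(-2, 1, 1, 1))
})

test_that("quantile function inverts the cdf and has a gamma-free median", {
  qs <- c(0.001, 0.01, 0.1, 0.25, 0.5, 0.75, 0.9, 0.99, 0.999)
  for (p in param_grid()) {
    x <- qollged(qs, p[1], p[2], p[3])
    expect_true(all(diff(x) > 0))
    expect_equal(pollged(x, p[1], p[2], p[3]), qs, tolerance = 1e-10)
  }
  for (ga in c(0.2, 1, 3, 8))
    expect_equal(qollged(0.5, 2, 1.5, ga),
                 -log(1 - 2^(-1 / 1.5)) / 2, tolerance = 1e-12)
  expect_equal(qollged(0.3, 1, 1, 1), -log(0.7), tolerance = 1e-13)
  expect_error(qollged(1.5, 1, 1, 1))
  expect_error(qollged(-0.2, 1, 1, 1))
})

test_that("random generation is seed-reproducible and matches the cdf", {
  set.seed(10); a <- rollged(100, 1, 2, 0.5)
  set.seed(10); b <- rollged(100, 1, 2, 0.5)
  expect_identical(a, b)
  set.seed(20)
  triples <- replicate(5, exp(runif(3, log(0.3), log(3))), simplify = FALSE)
  for (p in triples) {
    x <- rollged(1e5, p[1], p[2], p[3])
    D <- max(abs(ecdf(x)(sort(x)) - pollged(sort(x), p[1], p[2], p[3])))
    expect_lt(D, 0.01)
  }
  set.seed(30)
  expect_equal(mean(rollged(1e6, 1, 1, 1)), 1, tolerance = 0.01)
  expect_error(rollged(0, 1, 1, 1))
})

test_that("invalid parameters are rejected everywhere", {
  expect_error(dollged(1, -1, 1, 1))
  expect_error(pollged(1, 1, 0, 1))
  expect_error(qollged(0.5, 1, 1, Inf))
  expect_error(rollged(5, 1, NA, 1))
})
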