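# Shared parameter grids and small oracles used across the suite.

# moderate parameter triples (lambda, alpha, gamma) covering both shapes
param_grid <- function() {
  list(c(1, 1, 1), c(0.5, 2, 1), c(2, 0.5, 0.5), c(1, 1.5, 0.8),
       c(0.2, 1, 2), c(1.5, 3, 1.5))
}

# central finite difference of a scalar function
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
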