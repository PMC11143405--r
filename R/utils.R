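# Internal numeric primitives and argument checking.

# log(1 - exp(-a)) for a > 0, without cancellation on either side of a = log 2.
log1mexp <- function(a) {
  out <- a
  small <- a <= log(2)
  out[small] <- log(-expm1(-a[small]))
  out[!small] <- log1p(-exp(-a[!small]))
  out
}

# log(1 + exp(x)), safe against overflow for large x.
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  mid <- x > 18 & x <= 33
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

check_params <- function(lambda, alpha, gamma) {
  for (nm in c("lambda", "alpha", "gamma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) < 1L || any(!is.finite(v)) || any(v <= 0))
      stop("'", nm, "' must be a finite, strictly positive numeric value",
           call. = FALSE)
  }
  invisible(TRUE)
}

check_sample <- function(x, arg = "x") {
  if (!is.numeric(x) || length(x) < 1L)
    stop("'", arg, "' must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("'", arg, "' must contain finite, strictly positive values",
         call. = FALSE)
  sort(as.numeric(x))
}

# Deterministic stream seed for replicate i of a study seeded with `base`.
# Kept below 2^31 so it is always a valid seed for set.seed().
derive_seed <- function(base, i) {
  as.integer((as.numeric(base) * 48271 + as.numeric(i) * 1000003) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
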