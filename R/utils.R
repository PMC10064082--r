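# Internal helpers shared across modules.

# Two-sided p-value from a z statistic, floored at the smallest positive
# double rather than printed as 0.
.p_from_z <- function(z) pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)

# Two-sided p from a t statistic with df degrees of freedom.
.p_from_t <- function(t, df) pmax(2 * stats::pt(-abs(t), df = df), .Machine$double.xmin)

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Gini mean difference: mean |x_i - x_j| over all unordered pairs,
# computed from the order statistics in O(n log n).
.gini_mean_difference <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  xs <- sort(x)
  i <- seq_len(n)
  2 * sum((2 * i - n - 1) * xs) / (n * (n - 1))
}

# Wald-Wolfowitz runs test on the signs of a numeric sequence (normal
# approximation). Used by diagnostics to flag residual curvature.
.runs_test <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(list(runs = 1, p = 1))
  runs <- 1 + sum(diff(s) != 0)
  n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  sigma2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(sigma2)
  list(runs = runs, p = .p_from_z(z))
}

# Evaluate an expression with a temporary RNG state when `seed` is given;
# leaves the caller's RNG untouched in that case.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.assert_numeric <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  if (positive && any(x <= 0))
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
  invisible(x)
}
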