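## Shared statistical kernels: Pearson correlation with t-based p-values,
## Benjamini-Hochberg q-values, and a Mann-Whitney U test that is exact at
## small n and tie-corrected normal at screen scale.

#' Pearson correlation with a two-sided p-value
#'
#' Plain Pearson product-moment correlation; the p-value comes from the
#' classical t transform `t = r * sqrt((n-2)/(1-r^2))` with `n - 2` degrees
#' of freedom.
#'
#' @param x,y numeric vectors of equal length (>= 3), finite, with nonzero
#'   variance.
#' @return list with elements `r`, `p` and `n`.
#' @examples
#' pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_invalid("pearson needs >= 3 complete observations (got %d)", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_invalid("undefined correlation: zero variance input")
  r <- stats::cor(x, y)
  list(r = r, p = pearson_p(r, n), n = n)
}

## vectorized p from r and n
pearson_p <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

## All-pairs correlation between the columns of X (n x p) and Y (n x q).
## Returns list(r = p x q, p = p x q).
pearson_matrix <- function(X, Y) {
  n <- nrow(X)
  stopifnot(nrow(Y) == n, n >= 3L)
  r <- suppressWarnings(stats::cor(X, Y))
  list(r = r, p = pearson_p(r, n), n = n)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: `q_(i) = min_{j >= i}
#' (p_(j) * m / j)`, capped at 1, returned in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop_invalid("p-values must be numeric in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Mann-Whitney U test (exact at small n, tie-corrected normal otherwise)
#'
#' `U` counts pairs `(a, b)` with `a > b` for `a` in `x`, `b` in `y`
#' (ties count 1/2), i.e. the convention in which `x = c(4,5,6)` versus
#' `y = c(1,2,3)` gives `U = 9`. The exact two-sided p-value enumerates all
#' `choose(n1+n2, n1)` group assignments of the pooled values and measures
#' `P(|U* - n1 n2 / 2| >= |U - n1 n2 / 2|)`; enumeration is used when
#' `min(n1, n2) <= 8` and `n1 + n2 <= 25`, otherwise the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param x,y numeric vectors (each nonempty).
#' @param exact logical or NULL; NULL picks the rule above.
#' @return list with `U`, `p`, `n1`, `n2`, `method`.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop_invalid("both groups must be nonempty")
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (is.null(exact)) exact <- (min(n1, n2) <= 8L && n1 + n2 <= 25L)
  mid <- n1 * n2 / 2
  if (all(duplicated(pooled)[-1L]) && n1 + n2 > 1L) {
    # all values identical: no evidence either way
    return(list(U = U, p = 1, n1 = n1, n2 = n2, method = "degenerate"))
  }
  if (exact) {
    combs <- utils::combn(n1 + n2, n1)
    Uperm <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Uperm - mid) >= abs(U - mid) - 1e-9)
    method <- "exact"
  } else {
    nties <- table(pooled)
    sigma2 <- (n1 * n2 / 12) *
      ((n1 + n2 + 1) - sum(nties^3 - nties) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1, n1 = n1, n2 = n2, method = "degenerate"))
    z <- (abs(U - mid) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal"
  }
  list(U = U, p = p, n1 = n1, n2 = n2, method = method)
}
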