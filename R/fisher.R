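#' Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, the count in the top-left cell follows a
#' hypergeometric distribution. The two-sided p-value is the sum of the
#' probabilities of all tables (with the same margins) whose probability
#' does not exceed that of the observed table. The reported odds ratio is
#' the sample odds ratio \eqn{(a d)/(b c)}, infinite when \eqn{b c = 0}
#' with \eqn{a d > 0}.
#'
#' @param table 2x2 matrix (or something coercible) of non-negative integer
#'   counts with a positive grand total.
#' @return An object of class `rw_fisher`: list with `odds_ratio`,
#'   `p_value`, `table`.
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2))
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if (any(tab != round(tab))) stop("cell counts must be integers", call. = FALSE)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  N <- a + b + c + d
  if (N <= 0) stop("grand total must be positive", call. = FALSE)
  m <- a + b    # first-row margin
  k <- a + c    # first-column margin
  support <- max(0, m + k - N):min(m, k)
  probs <- stats::dhyper(support, k, N - k, m)
  p_obs <- stats::dhyper(a, k, N - k, m)
  # relative tolerance guards against ties broken by floating-point noise
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else {
    (a * d) / (b * c)
  }
  out <- list(odds_ratio = or, p_value = p, table = tab)
  class(out) <- "rw_fisher"
  out
}

#' @export
print.rw_fisher <- function(x, ...) {
  cat("Fisher's exact test (two-sided)\n")
  print(x$table)
  cat(sprintf("Odds ratio = %s, p = %.6g\n", format(x$odds_ratio), x$p_value))
  invisible(x)
}
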