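#' Log-rank test
#'
#' Compares the survival experience of two or more groups by summing
#' observed-minus-expected event counts over the pooled distinct event
#' times, with the variance of the observed counts taken from the
#' multivariate hypergeometric distribution at each event time. The
#' statistic is \eqn{(O - E)^T V^{-1} (O - E)} over the first \eqn{g - 1}
#' groups and is referred to a chi-square distribution with \eqn{g - 1}
#' degrees of freedom.
#'
#' @param records An `rw_survival` data frame (needs `time`, `event` and a
#'   group column).
#' @param by_group Name of the grouping column (default `"group"`).
#' @return An object of class `rw_logrank`: list with `statistic`, `df`,
#'   `p_value`, `observed`, `expected` (named per group) and `n` per group.
#' @examples
#' rec <- data.frame(time = c(1, 2, 10, 11), event = 1,
#'                   group = c("A", "A", "B", "B"))
#' logrank_test(rec)
#' @export
logrank_test <- function(records, by_group = "group") {
  time <- records$time
  event <- records$event
  grp <- as.character(records[[by_group]])
  groups <- sort(unique(grp))
  g <- length(groups)
  if (g < 2L) stop("log-rank test needs at least two non-empty groups",
                   call. = FALSE)
  if (any(table(factor(grp, levels = groups)) == 0L)) {
    stop("every group must contain at least one record", call. = FALSE)
  }
  if (sum(event) == 0L) stop("no events observed in any group", call. = FALSE)

  etimes <- sort(unique(time[event == 1]))
  O <- stats::setNames(numeric(g), groups)
  E <- stats::setNames(numeric(g), groups)
  V <- matrix(0, g, g, dimnames = list(groups, groups))
  for (t in etimes) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(time == t & event == 1)
    n_gt <- vapply(groups, function(gg) sum(at_risk & grp == gg), numeric(1))
    d_gt <- vapply(groups, function(gg) sum(time == t & event == 1 & grp == gg),
                   numeric(1))
    O <- O + d_gt
    E <- E + n_gt * d_t / n_t
    if (n_t > 1) {
      p <- n_gt / n_t
      # multivariate hypergeometric covariance of the group event counts
      Vt <- (diag(p, g) - tcrossprod(p)) * d_t * (n_t - d_t) / (n_t - 1)
      V <- V + Vt
    }
  }
  u <- (O - E)[-g]
  Vred <- V[-g, -g, drop = FALSE]
  stat <- tryCatch(drop(t(u) %*% solve(Vred, u)),
                   error = function(e) {
                     # singular variance (e.g. a group with no time at risk
                     # overlap); fall back to the pseudo-inverse
                     s <- svd(Vred)
                     pos <- s$d > max(s$d) * 1e-12
                     drop(t(u) %*% s$v[, pos, drop = FALSE] %*%
                            ((t(s$u[, pos, drop = FALSE]) %*% u) / s$d[pos]))
                   })
  df <- g - 1L
  out <- list(statistic = stat, df = df,
              p_value = stats::pchisq(stat, df, lower.tail = FALSE),
              observed = O, expected = E,
              n = stats::setNames(as.integer(table(factor(grp, levels = groups))),
                                  groups))
  class(out) <- "rw_logrank"
  out
}

#' @export
print.rw_logrank <- function(x, ...) {
  cat("Log-rank test\n")
  tab <- data.frame(n = x$n, observed = x$observed, expected = x$expected)
  print(tab)
  cat(sprintf("Chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
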