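#' Cox proportional hazards regression
#'
#' Fits the semiparametric hazard model
#' \eqn{h(t \mid x) = h_0(t) \exp(\beta^T x)} by maximizing the partial
#' likelihood with damped Newton-Raphson iteration started at \eqn{\beta = 0}.
#' Ties are handled by the Breslow (default) or Efron approximation —
#' day-granularity real-world data produces tied event times routinely.
#' Convergence is declared when the maximum absolute score component falls
#' below `tol` (default 1e-8) within `max_iter` iterations; runaway
#' coefficients (\eqn{|\beta| > 50}, the signature of complete separation)
#' stop the iteration with `converged = FALSE` rather than an error.
#'
#' @param records An `rw_survival`-like data frame with `time` and `event`
#'   columns plus the covariate columns.
#' @param covariates Character vector of covariate column names. Numeric
#'   columns enter as-is; a character/factor column with exactly two levels
#'   is converted to a 0/1 indicator of its second (sorted) level.
#' @param ties `"breslow"` or `"efron"`.
#' @param tol Convergence tolerance on the score.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `rw_cox`: list with `coefficients`,
#'   `standard_errors`, `hazard_ratios`, `ci95` (2-column matrix),
#'   `log_partial_likelihood`, `null_log_partial_likelihood`, `score_test`
#'   (the score chi-square at \eqn{\beta = 0}), `ties_method`, `converged`,
#'   `n_iterations`, `n`, `n_events`.
#' @examples
#' set.seed(1)
#' x <- rep(0:1, each = 40)
#' rec <- data.frame(time = rexp(80, rate = 0.01 * exp(0.7 * x)),
#'                   event = 1, arm = x)
#' cox_ph(rec, "arm")
#' @export
cox_ph <- function(records, covariates, ties = c("breslow", "efron"),
                   tol = 1e-8, max_iter = 50L) {
  ties <- match.arg(ties)
  time <- records$time
  event <- records$event
  if (sum(event) < 1L) stop("no events: partial likelihood is flat", call. = FALSE)
  X <- build_design(records, covariates)
  for (j in seq_len(ncol(X))) {
    if (stats::var(X[, j]) == 0) {
      stop("covariate '", colnames(X)[j],
           "' is constant: information matrix is degenerate", call. = FALSE)
    }
  }
  p <- ncol(X)
  prep <- cox_prepare(time, event, X)

  beta <- rep(0, p)
  d0 <- cox_derivs(beta, prep, ties)
  null_ll <- d0$loglik
  score_test <- drop(t(d0$grad) %*% solve(d0$info, d0$grad))
  ll <- null_ll
  grad <- d0$grad
  info <- d0$info
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    step <- solve(info, grad)
    # damped update: halve the step until the partial likelihood does not
    # decrease. The tolerance scales with |loglik| because near the optimum
    # the change is dominated by summation rounding noise and a fixed
    # absolute threshold would strangle the Newton step.
    lambda <- 1
    ll_tol <- (abs(ll) + 1) * 1e-9
    repeat {
      cand <- beta + lambda * step
      dc <- cox_derivs(cand, prep, ties)
      if (dc$loglik >= ll - ll_tol || lambda < 1e-10) break
      lambda <- lambda / 2
    }
    beta <- cand
    ll <- dc$loglik
    grad <- dc$grad
    info <- dc$info
    if (any(abs(beta) > 50)) break # complete separation
  }
  if (!converged && max(abs(grad)) < tol) converged <- TRUE
  # Under complete separation the score vanishes as beta diverges, so a
  # gradient criterion alone can "converge" on a flat likelihood; a
  # collapsing information diagonal (relative to beta = 0) marks the
  # runaway direction and the fit is flagged as non-converged.
  if (converged && any(diag(as.matrix(info)) <
                       1e-6 * diag(as.matrix(d0$info)))) {
    converged <- FALSE
  }
  se <- sqrt(diag(solve(info)))
  names(beta) <- colnames(X)
  names(se) <- colnames(X)
  ci <- cbind(lower = beta - 1.96 * se, upper = beta + 1.96 * se)
  out <- list(coefficients = beta, standard_errors = se,
              hazard_ratios = exp(beta), ci95 = ci,
              log_partial_likelihood = ll,
              null_log_partial_likelihood = null_ll,
              score_test = score_test,
              ties_method = ties, converged = converged, n_iterations = iter,
              n = length(time), n_events = sum(event))
  class(out) <- "rw_cox"
  out
}

build_design <- function(records, covariates) {
  cols <- lapply(covariates, function(v) {
    if (!v %in% names(records)) stop("covariate '", v, "' not found", call. = FALSE)
    x <- records[[v]]
    if (is.numeric(x)) {
      m <- matrix(x, ncol = 1, dimnames = list(NULL, v))
    } else {
      lev <- sort(unique(as.character(x)))
      if (length(lev) != 2L) {
        stop("covariate '", v, "' must be numeric or two-level; found ",
             length(lev), " level(s)", call. = FALSE)
      }
      m <- matrix(as.numeric(as.character(x) == lev[2L]), ncol = 1,
                  dimnames = list(NULL, paste0(v, "=", lev[2L])))
    }
    m
  })
  do.call(cbind, cols)
}

# Pre-sort once: descending time, with the tie structure flattened so each
# Newton iteration is a single pass.
cox_prepare <- function(time, event, X) {
  ord <- order(time, decreasing = TRUE)
  t_s <- time[ord]
  list(t_s = t_s, e_s = event[ord], X_s = X[ord, , drop = FALSE],
       # boundaries of tie groups in the descending sort
       grp_end = cumsum(rle(t_s)$lengths), n = length(time), p = ncol(X))
}

# Partial log-likelihood, score and information in one pass over the
# descending-time sort, accumulating risk-set sums S0, S1, S2.
cox_derivs <- function(beta, prep, ties) {
  p <- prep$p
  eta <- drop(prep$X_s %*% beta)
  w <- exp(eta)
  S0 <- 0; S1 <- rep(0, p); S2 <- matrix(0, p, p)
  ll <- 0; grad <- rep(0, p); info <- matrix(0, p, p)
  start <- 1L
  for (end in prep$grp_end) {
    ix <- start:end
    start <- end + 1L
    Xg <- prep$X_s[ix, , drop = FALSE]
    wg <- w[ix]
    S0 <- S0 + sum(wg)
    S1 <- S1 + drop(crossprod(Xg, wg))
    S2 <- S2 + crossprod(Xg, Xg * wg)
    ev <- prep$e_s[ix] == 1
    d <- sum(ev)
    if (d == 0L) next
    Xd <- Xg[ev, , drop = FALSE]
    ll <- ll + sum(eta[ix][ev])
    grad <- grad + colSums(Xd)
    if (ties == "breslow" || d == 1L) {
      m1 <- S1 / S0
      ll <- ll - d * log(S0)
      grad <- grad - d * m1
      info <- info + d * (S2 / S0 - tcrossprod(m1))
    } else { # efron
      wd <- wg[ev]
      s0d <- sum(wd)
      s1d <- drop(crossprod(Xd, wd))
      s2d <- crossprod(Xd, Xd * wd)
      for (l in 0:(d - 1L)) {
        f <- l / d
        den <- S0 - f * s0d
        z <- (S1 - f * s1d) / den
        ll <- ll - log(den)
        grad <- grad - z
        info <- info + (S2 - f * s2d) / den - tcrossprod(z)
      }
    }
  }
  list(loglik = ll, grad = grad, info = info)
}

#' @export
print.rw_cox <- function(x, ...) {
  cat("Cox proportional hazards fit (", x$ties_method, " ties)\n", sep = "")
  cat("n =", x$n, ", events =", x$n_events, "\n")
  z <- x$coefficients / x$standard_errors
  tab <- data.frame(coef = x$coefficients, se = x$standard_errors,
                    HR = x$hazard_ratios,
                    `HR lower .95` = exp(x$ci95[, "lower"]),
                    `HR upper .95` = exp(x$ci95[, "upper"]),
                    z = z, p = 2 * stats::pnorm(-abs(z)),
                    check.names = FALSE)
  print(tab)
  cat(sprintf("Log partial likelihood: %.4f (null %.4f); score test %.4g\n",
              x$log_partial_likelihood, x$null_log_partial_likelihood,
              x$score_test))
  if (!x$converged) cat("WARNING: did not converge\n")
  invisible(x)
}

#' @export
summary.rw_cox <- function(object, ...) {
  print(object)
  invisible(object)
}
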