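#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit estimator
#' \eqn{S(t) = \prod_{t_j \le t} (1 - d_j / n_j)} over the distinct event
#' times, with Greenwood standard errors. Censored observations tied with an
#' event time are treated as still at risk for that event time and removed
#' afterwards (censoring after events at equal times). The median is the
#' smallest listed event time at which the survival estimate drops to 0.5 or
#' below, without interpolation; it is `NA` when the curve never reaches 0.5.
#'
#' @param records An `rw_survival` data frame, or anything with numeric
#'   `time` (> 0) and 0/1 `event` columns. Alternatively pass `time` and
#'   `event` vectors directly.
#' @param time,event Optional vectors used when `records` is missing.
#' @return An object of class `rw_km`: list with `time` (ascending distinct
#'   event times), `n_risk`, `n_event`, `n_censor` (censorings in
#'   `[t_j, t_{j+1})`), `survival`, `se` (Greenwood), `median`, `n`.
#' @examples
#' km_estimate(time = c(1, 2, 3), event = c(1, 1, 1))
#' @export
km_estimate <- function(records = NULL, time = NULL, event = NULL) {
  if (!is.null(records)) { time <- records$time; event <- records$event }
  if (!length(time)) stop("no survival records supplied", call. = FALSE)
  if (any(time <= 0)) stop("all survival times must be positive", call. = FALSE)
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  n <- length(time)
  etimes <- sort(unique(time[event == 1]))
  if (!length(etimes)) {
    out <- list(time = numeric(0), n_risk = integer(0), n_event = integer(0),
                n_censor = integer(0), survival = numeric(0), se = numeric(0),
                median = NA_real_, n = n,
                censor_times = sort(time[event == 0]))
    class(out) <- "rw_km"
    return(out)
  }
  n_risk <- vapply(etimes, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(etimes, function(t) sum(time == t & event == 1), numeric(1))
  upper <- c(etimes[-1L], Inf)
  n_censor <- vapply(seq_along(etimes), function(j) {
    sum(event == 0 & time >= etimes[j] & time < upper[j])
  }, numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood: Var(S) = S^2 * sum d / (n (n - d)); terms with n == d give a
  # degenerate (zero-survival) tail where the SE is reported as 0.
  gterm <- ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), 0)
  se <- surv * sqrt(cumsum(gterm))
  med <- if (any(surv <= 0.5)) etimes[which(surv <= 0.5)[1L]] else NA_real_
  out <- list(time = etimes, n_risk = as.integer(n_risk),
              n_event = as.integer(n_event), n_censor = as.integer(n_censor),
              survival = surv, se = se, median = med, n = n,
              censor_times = sort(time[event == 0]))
  class(out) <- "rw_km"
  out
}

#' @export
print.rw_km <- function(x, ...) {
  cat("Kaplan-Meier estimate: n =", x$n, ", events =", sum(x$n_event), "\n")
  cat("Median survival:", if (is.na(x$median)) "not reached" else
      paste(format(x$median), "days"), "\n")
  if (length(x$time)) {
    print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                     n_censor = x$n_censor, survival = x$survival, se = x$se),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.rw_km <- function(object, ...) {
  cat("Kaplan-Meier product-limit estimate\n")
  print(object)
  invisible(object)
}

#' Kaplan-Meier estimates per group
#'
#' @param records An `rw_survival` data frame with a `group` column.
#' @return Named list of `rw_km` curves, one per group, of class
#'   `rw_km_list`.
#' @export
km_by_group <- function(records) {
  groups <- split(seq_len(nrow(records)), records$group)
  out <- lapply(groups, function(ix) km_estimate(records[ix, , drop = FALSE]))
  class(out) <- "rw_km_list"
  out
}

#' @export
print.rw_km_list <- function(x, ...) {
  for (g in names(x)) { cat("Group:", g, "\n"); print(x[[g]]); cat("\n") }
  invisible(x)
}

#' Plot-ready step-function table for KM curves
#'
#' Expands one or more KM curves into step coordinates (right-continuous
#' steps starting at survival 1 at time 0) plus censoring tick marks, in a
#' single long table any plotting front end can consume. The curve values
#' are reconstructed exactly at every listed time.
#'
#' @param curves An `rw_km`, an `rw_km_list`, or a named list of `rw_km`.
#' @return Data frame with columns `group`, `time`, `survival`, `se`,
#'   `type` (`"step"` or `"censor"`).
#' @export
km_plot_data <- function(curves) {
  if (inherits(curves, "rw_km")) curves <- list(all = curves)
  parts <- lapply(names(curves), function(g) {
    cv <- curves[[g]]
    step <- data.frame(group = g, time = c(0, cv$time),
                       survival = c(1, cv$survival),
                       se = c(0, cv$se), type = "step",
                       stringsAsFactors = FALSE)
    cens <- if (length(cv$censor_times)) {
      s_at <- vapply(cv$censor_times, function(t) {
        j <- which(cv$time <= t)
        if (length(j)) cv$survival[max(j)] else 1
      }, numeric(1))
      data.frame(group = g, time = cv$censor_times, survival = s_at,
                 se = NA_real_, type = "censor", stringsAsFactors = FALSE)
    } else NULL
    rbind(step, cens)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' @param x An `rw_km` or `rw_km_list`.
#' @param ... Passed to [graphics::plot()].
#' @rdname km_estimate
#' @export
plot.rw_km <- function(x, ...) {
  plot_km_curves(list(all = x), ...)
}

#' @export
plot.rw_km_list <- function(x, ...) {
  plot_km_curves(x, ...)
}

plot_km_curves <- function(curves, xlab = "Days", ylab = "Survival probability",
                           main = "Kaplan-Meier estimate", col = NULL, ...) {
  if (is.null(col)) col <- seq_along(curves)
  xmax <- max(1, unlist(lapply(curves, function(cv) c(cv$time, cv$censor_times))))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1), xlab = xlab,
                 ylab = ylab, main = main, ...)
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    tt <- c(0, cv$time, xmax)
    ss <- c(1, cv$survival, if (length(cv$survival)) cv$survival[length(cv$survival)] else 1)
    graphics::lines(stats::stepfun(tt[-1L], ss), do.points = FALSE, col = col[i])
    if (length(cv$censor_times)) {
      s_at <- vapply(cv$censor_times, function(t) {
        j <- which(cv$time <= t); if (length(j)) cv$survival[max(j)] else 1
      }, numeric(1))
      graphics::points(cv$censor_times, s_at, pch = 3, col = col[i])
    }
  }
  if (length(curves) > 1L) {
    graphics::legend("topright", legend = names(curves), col = col, lty = 1,
                     bty = "n")
  }
  invisible(curves)
}
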