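# Shared fixture builders. Everything is constructed in code; no files on
# disk beyond tempfiles written inside individual tests.

# Minimal event data frame -> rw_events (internal constructor keeps the
# fixture honest about the public column contract).
make_events <- function(patient_id, event_name, category, start_age,
                        end_age = start_age, details = "") {
  df <- data.frame(patient_id = patient_id, event_name = event_name,
                   category = category, start_age = start_age,
                   end_age = end_age,
                   source_table = "fixture",
                   event_id = sprintf("fixture:%d", seq_along(patient_id)),
                   details = details, stringsAsFactors = FALSE)
  rwevents:::as_rw_events(df)
}

timeline_of <- function(events, pid) build_timelines(events)[[pid]]

# One-patient timeline with treatments at the given start ages.
treatment_timeline <- function(starts, names = NULL, pid = "P1",
                               ends = starts) {
  if (is.null(names)) names <- sprintf("Drug%02d", seq_along(starts))
  ev <- make_events(rep(pid, length(starts)), names, "Treatment",
                    starts, ends)
  timeline_of(ev, pid)
}

# Brute-force evaluator of the textual line-clustering rules; the oracle
# the implementation is checked against. Operates on a vector of start
# times, returns the cluster index per (sorted) start.
oracle_cluster <- function(starts, window, mode) {
  starts <- sort(starts)
  n <- length(starts)
  assigned <- rep(NA_integer_, n)
  if (mode == "anchor") {
    cl <- 0L
    while (anyNA(assigned)) {
      cl <- cl + 1L
      s0 <- min(starts[is.na(assigned)])
      take <- is.na(assigned) & starts <= s0 + window
      assigned[take] <- cl
    }
  } else { # gap: join if within window of the latest member start
    cl <- 1L
    assigned[1] <- 1L
    if (n > 1) for (i in 2:n) {
      latest <- max(starts[which(assigned == cl)])
      if (starts[i] <= latest + window) assigned[i] <- cl
      else { cl <- cl + 1L; assigned[i] <- cl }
    }
  }
  assigned
}

# Random survival records for property tests.
random_records <- function(n, p_event = 0.7, groups = NULL) {
  rec <- data.frame(time = round(rexp(n, 0.1), 3) + 0.001,
                    event = rbinom(n, 1, p_event))
  if (!is.null(groups)) rec$group <- sample(groups, n, replace = TRUE)
  rec
}

# Random cohort of treatment timelines (list) for clustering properties.
random_treatment_cohort <- function(n_patients, max_events = 8,
                                    horizon = 1000) {
  evs <- do.call(rbind, lapply(seq_len(n_patients), function(i) {
    k <- sample(1:max_events, 1)
    data.frame(patient_id = sprintf("P%03d", i),
               event_name = sample(LETTERS[1:5], k, replace = TRUE),
               category = "Treatment",
               start_age = sort(round(runif(k, 0, horizon), 1)),
               stringsAsFactors = FALSE)
  }))
  evs$end_age <- evs$start_age + round(runif(nrow(evs), 0, 50), 1)
  evs$source_table <- "sim"
  evs$event_id <- sprintf("sim:%d", seq_len(nrow(evs)))
  evs$details <- ""
  build_timelines(rwevents:::as_rw_events(evs))
}

# Direct product-limit arithmetic, independent of km_estimate.
oracle_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(et))
  for (j in seq_along(et)) {
    n <- sum(time >= et[j])
    d <- sum(time == et[j] & event == 1)
    s <- s * (1 - d / n)
    surv[j] <- s
  }
  list(time = et, survival = surv)
}

# Direct partial log-likelihood (Breslow) for the grid-search oracle.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(beta * x[d]) - length(d) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# Hypergeometric pmf from binomial coefficients (independent of dhyper).
oracle_fisher_p <- function(a, b, c, d) {
  N <- a + b + c + d; m <- a + b; k <- a + c
  support <- max(0, m + k - N):min(m, k)
  probs <- choose(k, support) * choose(N - k, m - support) / choose(N, m)
  p_obs <- choose(k, a) * choose(N - k, m - a) / choose(N, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
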