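test_that("product-limit arithmetic matches the worked examples", {
  # all events at distinct times
  km <- km_estimate(time = c(1, 2, 3), event = c(1, 1, 1))
  expect_equal(km$survival, c(2/3, 1/3, 0))
  expect_equal(km$median, 2)
  expect_equal(km$n_risk, c(3L, 2L, 1L))

  # censoring between events: at-risk drops from 3 to 1
  km2 <- km_estimate(time = c(1, 2, 3), event = c(1, 0, 1))
  expect_equal(km2$time, c(1, 3))
  expect_equal(km2$survival, c(2/3, 0))
  expect_equal(km2$n_risk, c(3L, 1L))
  expect_equal(km2$n_censor, c(1L, 0L))

  # all censored: flat curve, median absent
  km3 <- km_estimate(time = c(5, 6), event = c(0, 0))
  expect_length(km3$time, 0L)
  expect_true(is.na(km3$median))

  expect_error(km_estimate(time = numeric(0), event = numeric(0)), "no")
  expect_error(km_estimate(time = c(0, 1), event = c(1, 1)), "positive")
})

test_that("censored observations tied with an event time stay at risk for it", {
  km <- km_estimate(time = c(2, 2, 4), event = c(1, 0, 1))
  expect_equal(km$n_risk, c(3L, 1L))
  expect_equal(km$survival, c(2/3, 0))
})

test_that("KM equals the empirical survival function with no censoring", {
  set.seed(601)
  for (rep in 1:30) {
    t <- round(rexp(sample(5:60, 1), 0.2), 2) + 0.01
    km <- km_estimate(time = t, event = rep(1, length(t)))
    emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
    expect_equal(km$survival, emp)
  }
})

test_that("KM matches the product-limit oracle on random censored data", {
  set.seed(602)
  for (rep in 1:30) {
    rec <- random_records(sample(5:80, 1), p_event = 0.6)
    km <- km_estimate(rec)
    orc <- oracle_km(rec$time, rec$event)
    expect_equal(km$time, orc$time)
    expect_equal(km$survival, orc$survival)
  }
})

test_that("KM agrees with the reference implementation to 1e-12", {
  skip_if_not_installed("survival")
  set.seed(603)
  for (rep in 1:25) {
    rec <- random_records(sample(5:100, 1), p_event = 0.5)
    if (sum(rec$event) == 0) rec$event[1] <- 1
    km <- km_estimate(rec)
    sf <- survival::survfit(survival::Surv(rec$time, rec$event) ~ 1)
    sm <- summary(sf, times = km$time)
    expect_equal(km$survival, sm$surv, tolerance = 1e-12)
    # the reference leaves the SE undefined (NaN) once survival hits zero
    ok <- is.finite(sm$std.err)
    expect_equal(km$se[ok], sm$std.err[ok], tolerance = 1e-12)
    expect_equal(km$n_risk, sm$n.risk)
  }
})

test_that("km_plot_data reconstructs the curve exactly at every time", {
  set.seed(604)
  rec <- random_records(40, p_event = 0.6, groups = c("A", "B"))
  curves <- km_by_group(rec)
  pd <- km_plot_data(curves)
  for (g in names(curves)) {
    cv <- curves[[g]]
    steps <- pd[pd$group == g & pd$type == "step", ]
    expect_equal(steps$time, c(0, cv$time))
    expect_equal(steps$survival, c(1, cv$survival))
    cens <- pd[pd$group == g & pd$type == "censor", ]
    expect_equal(nrow(cens), sum(rec$event == 0 & rec$group == g))
  }
})

test_that("log-rank is zero on duplicated groups and matches the O/E/V oracle", {
  # identical survival experience -> statistic 0, p 1
  rec <- data.frame(time = c(1, 3, 5, 1, 3, 5), event = c(1, 1, 0, 1, 1, 0),
                    group = rep(c("A", "B"), each = 3))
  lr <- logrank_test(rec)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)
  expect_equal(sum(lr$observed), sum(lr$expected))

  # hand oracle over the four pooled event times {1,2,10,11}
  rec2 <- data.frame(time = c(1, 2, 10, 11), event = 1,
                     group = c("A", "A", "B", "B"))
  O <- 0; E <- 0; V <- 0
  tt <- c(1, 2, 10, 11)
  for (t in tt) {
    at <- rec2$time >= t
    n <- sum(at); n1 <- sum(at & rec2$group == "A"); d <- 1
    O <- O + (rec2$group[rec2$time == t] == "A")
    E <- E + n1 / n
    if (n > 1) V <- V + (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  lr2 <- logrank_test(rec2)
  expect_equal(lr2$statistic, (sum(O) - E)^2 / V)
  expect_equal(lr2$df, 1L)

  expect_error(logrank_test(data.frame(time = 1:3, event = 1, group = "A")),
               "two")
  expect_error(logrank_test(data.frame(time = 1:4, event = 0,
                                       group = rep(c("A", "B"), 2))),
               "events")
})

test_that("log-rank is invariant under group-label swap and matches survdiff", {
  skip_if_not_installed("survival")
  set.seed(605)
  for (rep in 1:20) {
    rec <- random_records(sample(20:80, 1), p_event = 0.7,
                          groups = c("A", "B"))
    if (length(unique(rec$group)) < 2 || sum(rec$event) == 0) next
    lr <- logrank_test(rec)
    swapped <- rec
    swapped$group <- ifelse(rec$group == "A", "B", "A")
    expect_equal(logrank_test(swapped)$statistic, lr$statistic)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = rec)
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-10)
  }
})

test_that("log-rank equals the squared Cox score test without ties", {
  set.seed(606)
  for (rep in 1:10) {
    n <- 60
    rec <- data.frame(time = rexp(n, 0.1), event = rbinom(n, 1, 0.8),
                      group = sample(c("A", "B"), n, replace = TRUE))
    if (sum(rec$event) == 0 || length(unique(rec$group)) < 2) next
    lr <- logrank_test(rec)
    cx <- cox_ph(rec, "group")
    expect_equal(lr$statistic, cx$score_test, tolerance = 1e-8)
  }
})

test_that("Cox estimate is zero by symmetry on mirrored groups", {
  rec <- data.frame(time = rep(c(2, 5, 9, 14), 2),
                    event = rep(c(1, 1, 0, 1), 2),
                    arm = rep(0:1, each = 4))
  fit <- cox_ph(rec, "arm")
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-10)
  expect_equal(unname(fit$hazard_ratios), 1, tolerance = 1e-10)
})

test_that("Cox recovers a known log hazard ratio and matches the grid oracle", {
  set.seed(607)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.01 * exp(0.7 * x))
  t_c <- rexp(n, 0.004)
  rec <- data.frame(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c),
                    arm = x)
  fit <- cox_ph(rec, "arm")
  expect_true(fit$converged)
  beta <- unname(fit$coefficients)
  expect_lt(abs(beta - 0.7), 3 * unname(fit$standard_errors))

  # grid-search maximizer of the same partial likelihood, step 1e-4
  coarse <- seq(-3, 3, by = 0.01)
  ll_c <- vapply(coarse, oracle_cox_loglik, numeric(1),
                 time = rec$time, event = rec$event, x = rec$arm)
  b0 <- coarse[which.max(ll_c)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-4)
  ll_f <- vapply(fine, oracle_cox_loglik, numeric(1),
                 time = rec$time, event = rec$event, x = rec$arm)
  expect_lt(abs(beta - fine[which.max(ll_f)]), 1e-4 + 1e-8)
})

test_that("Cox matches the reference implementation with Breslow and Efron ties", {
  skip_if_not_installed("survival")
  set.seed(608)
  for (rep in 1:10) {
    n <- 120
    rec <- data.frame(time = sample(1:25, n, replace = TRUE), # heavy ties
                      event = rbinom(n, 1, 0.7),
                      age = round(rnorm(n, 60, 8), 1),
                      arm = rbinom(n, 1, 0.5))
    if (sum(rec$event) < 5 || var(rec$arm) == 0) next
    for (ties in c("breslow", "efron")) {
      fit <- cox_ph(rec, c("arm", "age"), ties = ties)
      ref <- survival::coxph(survival::Surv(time, event) ~ arm + age,
                             data = rec, ties = ties)
      expect_equal(unname(fit$coefficients), unname(coef(ref)),
                   tolerance = 1e-6)
      expect_equal(unname(fit$standard_errors),
                   unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
    }
  }
})

test_that("partial likelihood at the estimate dominates the null", {
  set.seed(609)
  for (rep in 1:10) {
    n <- 80
    rec <- data.frame(time = rexp(n, 0.05), event = rbinom(n, 1, 0.7),
                      x = rnorm(n))
    if (sum(rec$event) == 0) next
    fit <- cox_ph(rec, "x")
    expect_gte(fit$log_partial_likelihood, fit$null_log_partial_likelihood)
  }
})

test_that("degenerate and separated designs are handled as specified", {
  rec <- data.frame(time = c(1, 2, 3, 4), event = 1, x = 1)
  expect_error(cox_ph(rec, "x"), "degenerate")

  # complete separation: all early events in one arm, diverging beta
  rec2 <- data.frame(time = c(1, 2, 3, 4, 100, 110, 120, 130),
                     event = c(1, 1, 1, 1, 0, 0, 0, 0),
                     arm = c(1, 1, 1, 1, 0, 0, 0, 0))
  fit2 <- cox_ph(rec2, "arm")
  expect_false(fit2$converged)
})

test_that("CI coverage of the true log hazard ratio is nominal", {
  set.seed(610)
  hits <- 0L
  n_rep <- 60
  for (rep in seq_len(n_rep)) {
    n <- 120
    x <- rbinom(n, 1, 0.5)
    t_ev <- rexp(n, 0.01 * exp(0.7 * x))
    t_c <- rexp(n, 0.004)
    rec <- data.frame(time = pmin(t_ev, t_c),
                      event = as.integer(t_ev <= t_c), arm = x)
    fit <- cox_ph(rec, "arm")
    hits <- hits + (fit$ci95[1, "lower"] <= 0.7 && 0.7 <= fit$ci95[1, "upper"])
  }
  expect_gte(hits / n_rep, 0.85)
  expect_lte(hits / n_rep, 1.0)
})

test_that("Fisher's exact test matches enumeration on the worked tables", {
  sym <- fisher_exact(matrix(c(1, 1, 1, 1), 2))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)

  t2 <- fisher_exact(matrix(c(3, 1, 1, 3), 2))
  expect_equal(t2$odds_ratio, 9)
  expect_equal(t2$p_value, 34 / 70)

  t3 <- fisher_exact(matrix(c(2, 0, 0, 2), 2))
  expect_equal(t3$odds_ratio, Inf)
  expect_equal(t3$p_value, 1 / 3) # 2 / choose(4, 2)

  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_error(fisher_exact(matrix(0, 2, 2)), "positive")
})

test_that("Fisher p equals the binomial-coefficient oracle on random tables", {
  set.seed(611)
  for (rep in 1:200) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) == 0) next
    fr <- fisher_exact(tab)
    expect_equal(fr$p_value,
                 min(1, oracle_fisher_p(tab[1, 1], tab[1, 2],
                                        tab[2, 1], tab[2, 2])),
                 tolerance = 1e-12)
  }
})
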