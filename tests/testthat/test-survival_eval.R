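test_that("log-rank statistic matches the observed-vs-expected hand computation", {
  # 6-subject worked dataset
  surv <- data.frame(sample = paste0("p", 1:6),
                     time = c(3, 5, 7, 8, 10, 14),
                     event = c(1, 1, 0, 1, 1, 0))
  g <- c("A", "B", "A", "B", "A", "B")
  got <- km_logrank(g, surv)
  expect_equal(got$chi2, oracle_logrank(g, surv$time, surv$event),
               tolerance = 1e-10)
  expect_equal(got$p, pchisq(got$chi2, 1, lower.tail = FALSE))

  # identical survival experience in both groups: statistic exactly 0
  base <- random_surv(30)
  twin <- rbind(base, base)
  twin$sample <- paste0("q", seq_len(nrow(twin)))
  null <- km_logrank(rep(c("A", "B"), each = 30), twin)
  expect_equal(null$chi2, 0, tolerance = 1e-10)
  expect_equal(null$p, 1, tolerance = 1e-6)

  expect_error(km_logrank(rep("A", 6), surv), "non-empty")
})

test_that("multivariate Cox coefficients maximize the enumerated partial likelihood", {
  # 8-subject, 2-covariate dataset against a dense grid search
  surv <- data.frame(sample = paste0("p", 1:8),
                     time = c(2, 3, 5, 6, 8, 9, 11, 13),
                     event = c(1, 1, 1, 0, 1, 1, 0, 1))
  z1 <- c(0, 1, 0, 1, 1, 0, 1, 0)
  z2 <- c(0.2, -0.5, 1.1, 0.4, -0.2, 0.9, -1.3, 0.6)
  got <- suppressWarnings(cox_multivariate(surv, data.frame(z1 = z1, z2 = z2)))

  pll <- function(b1, b2) {                      # Efron, by enumeration
    eta <- b1 * z1 + b2 * z2
    ll <- 0
    for (tt in surv$time[surv$event == 1]) {
      R <- which(surv$time >= tt)
      i <- which(surv$time == tt & surv$event == 1)
      ll <- ll + eta[i] - log(sum(exp(eta[R])))
    }
    ll
  }
  grid <- seq(-3, 3, by = 0.05)
  best <- c(NA, NA); bestll <- -Inf
  for (b1 in grid) for (b2 in grid) {
    v <- pll(b1, b2)
    if (v > bestll) { bestll <- v; best <- c(b1, b2) }
  }
  expect_lt(abs(got$coef[1] - best[1]), 0.05)
  expect_lt(abs(got$coef[2] - best[2]), 0.05)
  expect_equal(got$hr, exp(got$coef))

  # null covariate at large n has HR near 1
  set.seed(31)
  big <- random_surv(800)
  noise <- rnorm(800)
  hr <- suppressWarnings(cox_multivariate(big, data.frame(noise = noise)))$hr
  expect_lt(abs(hr - 1), 0.1)

  expect_error(cox_multivariate(big, data.frame(k = rep(1, 800))), "constant")
})

test_that("concordance equals pairwise enumeration and respects symmetry", {
  set.seed(23)
  surv <- random_surv(20)
  scores <- rnorm(20)
  expect_equal(harrell_c(scores, surv),
               oracle_harrell(scores, surv$time, surv$event),
               tolerance = 1e-12)
  # perfect and inverted scores without censoring
  full <- random_surv(15, cens_frac = 0)
  expect_equal(harrell_c(-full$time, full), 1)
  expect_equal(harrell_c(full$time, full), 0)
  # complement identity when scores are tie-free
  expect_equal(harrell_c(scores, surv) + harrell_c(-scores, surv), 1,
               tolerance = 1e-12)
})

test_that("resampling protocol is deterministic and degenerates correctly", {
  set.seed(25)
  surv <- random_surv(60)
  scores <- -surv$time + rnorm(60, sd = 2)
  r1 <- suppressWarnings(resample_c(scores, surv, reps = 50L, seed = 11L))
  r2 <- suppressWarnings(resample_c(scores, surv, reps = 50L, seed = 11L))
  expect_identical(r1, r2)

  # fraction 1: every draw is the whole cohort, so the SD collapses to 0
  rf <- resample_c(scores, surv, fraction = 1, reps = 100L, seed = 1L)
  expect_identical(rf$c_sd, 0)
  expect_identical(rf$c_mean, harrell_c(scores, surv))

  expect_error(resample_c(scores, surv, fraction = 1.2, reps = 100L), "fraction")
})

test_that("time-dependent AUC matches the explicit IPCW summation", {
  # 15-subject censored toy, horizons inside follow-up
  set.seed(27)
  surv <- random_surv(15)
  surv$time <- surv$time + 1
  scores <- rnorm(15)
  for (t0 in quantile(surv$time, c(0.35, 0.6))) {
    if (!any(surv$time <= t0 & surv$event == 1)) next
    got <- time_dependent_auc(scores, surv, times = t0, times_unit = "months")
    expect_equal(unname(got), oracle_ipcw_auc(scores, surv$time, surv$event, t0),
                 tolerance = 1e-12)
  }

  # monotone score without censoring discriminates perfectly
  full <- random_surv(40, cens_frac = 0)
  t0 <- median(full$time)
  expect_equal(unname(time_dependent_auc(-full$time, full, t0, "months")), 1)

  expect_error(time_dependent_auc(scores, surv, max(surv$time) + 1, "months"),
               "follow-up")
  early <- surv; early$event[early$time <= 2] <- 0L
  expect_error(time_dependent_auc(scores, early, 2, "months"), "no events")
})

test_that("null scores give chance-level AUC at every horizon", {
  set.seed(29)
  surv <- random_surv(2000)
  noise <- rnorm(2000)
  auc <- time_dependent_auc(noise, surv,
                            times = quantile(surv$time, c(0.3, 0.5, 0.7)),
                            times_unit = "months")
  expect_true(all(abs(auc - 0.5) < 0.05))
})

test_that("RMS ratio integrates the KM step functions", {
  # identical survival in both groups
  base <- random_surv(25)
  twin <- rbind(base, base); twin$sample <- paste0("q", seq_len(50))
  g <- rep(c("LRisk", "HRisk"), each = 25)
  expect_equal(rms_ratio(factor(g, levels = c("LRisk", "HRisk")), twin), 1)

  # step-area arithmetic: all high-risk events at t=1, no low-risk event
  surv <- data.frame(sample = paste0("p", 1:8),
                     time = c(rep(1, 4), rep(10, 4)),
                     event = c(rep(1L, 4), rep(0L, 4)))
  g2 <- factor(rep(c("HRisk", "LRisk"), each = 4), levels = c("LRisk", "HRisk"))
  expect_equal(rms_ratio(g2, surv, tau = 10), 0.1)

  # toy curves vs independent step integration
  set.seed(33)
  s3 <- random_surv(30)
  g3 <- factor(rep(c("LRisk", "HRisk"), 15), levels = c("LRisk", "HRisk"))
  tau <- min(tapply(s3$time, g3, max))
  want <- oracle_rmst(s3$time[g3 == "HRisk"], s3$event[g3 == "HRisk"], tau) /
          oracle_rmst(s3$time[g3 == "LRisk"], s3$event[g3 == "LRisk"], tau)
  expect_equal(rms_ratio(g3, s3, tau), want, tolerance = 1e-12)

  # a censored tail forbids extrapolation beyond follow-up
  tail_cens <- data.frame(sample = paste0("p", 1:6),
                          time = c(1, 2, 3, 1.5, 2.5, 3.5),
                          event = c(1L, 1L, 0L, 1L, 1L, 0L))
  g4 <- factor(rep(c("LRisk", "HRisk"), each = 3), levels = c("LRisk", "HRisk"))
  expect_error(rms_ratio(g4, tail_cens, tau = 5), "tau")
})

test_that("ratio drops below 1 when the high-risk curve is dominated", {
  set.seed(35)
  n <- 120
  g <- factor(rep(c("LRisk", "HRisk"), each = n / 2), levels = c("LRisk", "HRisk"))
  t_ev <- rexp(n, ifelse(g == "HRisk", 0.08, 0.02))
  surv <- data.frame(sample = paste0("p", 1:n), time = t_ev, event = 1L)
  expect_lt(rms_ratio(g, surv), 1)
})

test_that("evaluation report bundles consistent statistics", {
  set.seed(37)
  surv <- random_surv(150)
  scores <- -log(surv$time) + rnorm(150, sd = 0.8)
  rep <- suppressWarnings(
    evaluate_cohort(scores, surv, times = quantile(surv$time, c(0.3, 0.5)) / 12,
                    reps = 100L, seed = 5L))
  expect_s3_class(rep, "irgpi_eval")
  expect_identical(rep$c_index, harrell_c(scores, surv))
  expect_true(rep$c_index > 0.5)
  expect_equal(rep$frac_significant + rep$frac_p_above_threshold, 1)
  expect_true(all(unlist(rep$auc_at_times) >= 0 & unlist(rep$auc_at_times) <= 1))
  expect_gt(rep$rms_ratio, 0)
})
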