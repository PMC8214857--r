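# helper: wrap a raw 0/1 matrix as a pair_indicators object
as_pairind <- function(X) {
  P <- nrow(X)
  structure(list(pairs = data.frame(gene_a = sprintf("a%02d", seq_len(P)),
                                    gene_b = sprintf("b%02d", seq_len(P)),
                                    stringsAsFactors = FALSE),
                 indicators = matrix(as.integer(X), nrow = P)),
            class = "pair_indicators")
}

test_that("screen p-values match the hand-enumerated Efron score test", {
  # 6-subject worked dataset with a tied event time to exercise the
  # tie correction
  time <- c(2, 4, 4, 6, 9, 12)
  event <- c(1, 1, 1, 0, 1, 0)
  x <- c(1, 0, 1, 0, 1, 0)
  surv <- data.frame(sample = paste0("p", 1:6), time = time, event = event)
  got <- univariate_cox_screen(as_pairind(rbind(x)), surv, screen_p = 1)
  want <- oracle_score_test(x, time, event)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  # and against the survival package on the same data
  cf <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  expect_equal(got$p, unname(summary(cf)$sctest["pvalue"]), tolerance = 1e-8)
})

test_that("vectorized score test agrees with coxph across random tied data", {
  set.seed(77)
  n <- 40
  for (rep in 1:5) {
    time <- sample(1:12, n, replace = TRUE)      # month-resolution ties
    event <- rbinom(n, 1, 0.6)
    if (sum(event) < 2) event[1:2] <- 1L
    X <- matrix(rbinom(3 * n, 1, 0.5), nrow = 3)
    X[1, 1:2] <- c(0L, 1L)                       # keep rows non-constant
    st <- irgpi:::cox_score_test_matrix(X, time, event)
    for (i in 1:3) {
      if (length(unique(X[i, ])) < 2) next
      cf <- survival::coxph(survival::Surv(time, event) ~ x,
                            data = data.frame(time = time, event = event,
                                              x = X[i, ]), ties = "efron")
      expect_equal(unname(st$chi2[i]), unname(summary(cf)$sctest["test"]),
                   tolerance = 1e-6)
    }
  }
})

test_that("screen retains extreme signal, skips constants, needs events", {
  set.seed(42)
  n <- 100
  t_ev <- rexp(n, 0.05)
  surv <- data.frame(sample = paste0("p", 1:n), time = t_ev,
                     event = rep(1L, n))
  strong <- as.integer(t_ev < median(t_ev))      # indicator = early death
  X <- rbind(strong, rbinom(n, 1, 0.5), rep(1L, n))
  expect_warning(kept <- univariate_cox_screen(as_pairind(X), surv, 0.05),
                 "constant")
  expect_true("a01" %in% kept$gene_a)            # the extreme-signal pair
  expect_false("a03" %in% kept$gene_a)           # the constant pair

  surv0 <- surv; surv0$event <- c(1L, rep(0L, n - 1))
  expect_error(univariate_cox_screen(as_pairind(X[1:2, ]), surv0, 0.05),
               "2 events")
})

test_that("infinite penalty empties the selection", {
  set.seed(4)
  surv <- random_surv(60)
  X <- matrix(rbinom(5 * 60, 1, 0.5), nrow = 5)
  sel <- suppressWarnings(
    fit_lasso_cox(as_pairind(X), surv, train_config(), lambda = Inf))
  expect_equal(nrow(sel), 0L)
})

test_that("one-pair unpenalized fit matches a grid argmax of the partial likelihood", {
  set.seed(55)
  n <- 80
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.05 * exp(1.2 * x))
  surv <- data.frame(sample = paste0("p", 1:n), time = t_ev, event = rep(1L, n))
  sel <- suppressWarnings(
    fit_lasso_cox(as_pairind(rbind(x)), surv, train_config(), lambda = 0))
  expect_equal(nrow(sel), 1L)
  expect_gt(sel$beta, 0)

  grid <- seq(-3, 3, by = 0.001)
  pll <- vapply(grid, function(b) oracle_efron_pll(b, x, surv$time, surv$event),
                numeric(1))
  expect_lt(abs(sel$beta - grid[which.max(pll)]), 0.002)

  cf <- survival::coxph(survival::Surv(time, event) ~ x,
                        data = data.frame(time = surv$time, event = surv$event,
                                          x = x), ties = "efron")
  expect_equal(sel$beta, unname(coef(cf)), tolerance = 1e-4)
})

test_that("training is deterministic given the seed and errors without events", {
  cfg <- sim_config(n_samples = 250L, n_genes = 40L, n_true_pairs = 4L,
                    censoring_rate_target = 0.2, seed = 3L)
  co <- simulate_cohort(cfg)
  tc <- train_config(seed = 3L)
  s1 <- suppressMessages(train_signature(co$base, rownames(co$base), co$surv, tc))
  s2 <- suppressMessages(train_signature(co$base, rownames(co$base), co$surv, tc))
  expect_identical(s1, s2)
  expect_true(length(s1) >= 1L)
  expect_equal(s1$metadata$cutoff_rule, "training_median")
  # cutoff is the median training score
  sc <- score_cohort(co$base, s1)
  expect_identical(s1$cutoff, median(sc$irgpi))

  surv0 <- co$surv; surv0$event <- 0L
  expect_error(suppressMessages(
    train_signature(co$base, rownames(co$base), surv0, tc)),
    "signature_trainer")
})

test_that("metadata hash tracks config and input changes", {
  cfg <- sim_config(n_samples = 250L, n_genes = 40L, n_true_pairs = 4L, seed = 3L)
  co <- simulate_cohort(cfg)
  s1 <- suppressMessages(train_signature(co$base, rownames(co$base), co$surv,
                                         train_config(seed = 3L)))
  s2 <- suppressMessages(train_signature(co$base, rownames(co$base), co$surv,
                                         train_config(seed = 3L, screen_p = 0.04)))
  expect_false(identical(s1$metadata$hash, s2$metadata$hash))
  surv_j <- co$surv; surv_j$time[1] <- surv_j$time[1] + 0.01
  s3 <- suppressMessages(train_signature(co$base, rownames(co$base), surv_j,
                                         train_config(seed = 3L)))
  expect_false(identical(s1$metadata$hash, s3$metadata$hash))
})

test_that("training is invariant to per-sample monotone distortion", {
  cfg <- sim_config(n_samples = 250L, n_genes = 40L, n_true_pairs = 4L, seed = 9L)
  co <- simulate_cohort(cfg)
  tc <- train_config(seed = 9L)
  s_base <- suppressMessages(train_signature(co$base, rownames(co$base), co$surv, tc))
  s_dist <- suppressMessages(train_signature(co$expr[[1]], rownames(co$base),
                                             co$surv, tc))
  expect_equal(s_base$pairs, s_dist$pairs)
  expect_identical(s_base$cutoff, s_dist$cutoff)
})
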