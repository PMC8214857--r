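# Independent brute-force oracles used to pin expected values. These are
# written as plain enumerations/loops over definitions, deliberately sharing
# no code path with the package.

# element-wise double-loop order indicator
oracle_indicators <- function(expr, pairs) {
  out <- matrix(NA_integer_, nrow(pairs), ncol(expr))
  for (i in seq_len(nrow(pairs))) {
    for (s in seq_len(ncol(expr))) {
      a <- expr[pairs$gene_a[i], s]; b <- expr[pairs$gene_b[i], s]
      out[i, s] <- if (is.na(a) || is.na(b)) NA_integer_
                   else if (a < b) 1L else 0L
    }
  }
  out
}

# median absolute deviation with the 1.4826 consistency constant
oracle_mad <- function(x) {
  m <- sort(x)[ceiling(length(x) / 2)]
  if (length(x) %% 2 == 0) m <- mean(sort(x)[length(x) / 2 + c(0, 1)])
  d <- sort(abs(x - m))
  md <- if (length(d) %% 2 == 0) mean(d[length(d) / 2 + c(0, 1)])
        else d[ceiling(length(d) / 2)]
  1.4826 * md
}

# Harrell's C by pairwise enumeration (continuous times assumed)
oracle_harrell <- function(scores, time, event) {
  num <- den <- 0
  n <- length(scores)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    first <- if (time[i] < time[j]) i else j
    second <- if (time[i] < time[j]) j else i
    if (event[first] == 0) next       # earlier subject censored: unusable
    den <- den + 1
    if (scores[first] > scores[second]) num <- num + 1
    else if (scores[first] == scores[second]) num <- num + 0.5
  }
  num / den
}

# two-sample log-rank chi-square by observed-vs-expected at each event time
oracle_logrank <- function(g, time, event) {
  g <- as.integer(factor(g)) - 1L
  dtimes <- sort(unique(time[event == 1]))
  OE <- V <- 0
  for (tt in dtimes) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(event == 1 & time == tt)
    d1 <- sum(event == 1 & time == tt & g == 1)
    OE <- OE + (d1 - d * n1 / n)
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OE^2 / V
}

# Kaplan-Meier survival curve by explicit product-limit recursion
oracle_km <- function(time, event) {
  dtimes <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(dtimes))
  for (k in seq_along(dtimes)) {
    tt <- dtimes[k]
    n <- sum(time >= tt)
    d <- sum(event == 1 & time == tt)
    s <- s * (1 - d / n)
    surv[k] <- s
  }
  list(time = dtimes, surv = surv)
}

# area under the KM step function on [0, tau]
oracle_rmst <- function(time, event, tau) {
  km <- oracle_km(time, event)
  knots <- c(0, km$time[km$time < tau], tau)
  heights <- c(1, km$surv[km$time < tau])
  area <- 0
  for (k in seq_len(length(knots) - 1))
    area <- area + heights[k] * (knots[k + 1] - knots[k])
  area
}

# IPCW cumulative/dynamic AUC at horizon t0 by direct summation:
# cases (event by t0) weighted by 1 / G(T_i-), G = censoring KM
oracle_ipcw_auc <- function(scores, time, event, t0) {
  gkm <- oracle_km(time, 1 - event)
  G_left <- function(t) {
    s <- 1
    for (k in seq_along(gkm$time)) if (gkm$time[k] < t) s <- gkm$surv[k]
    s
  }
  cases <- which(time <= t0 & event == 1)
  ctrls <- which(time > t0)
  num <- den <- 0
  for (i in cases) {
    w <- 1 / G_left(time[i])
    for (j in ctrls) {
      cmp <- if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
      num <- num + w * cmp
      den <- den + w
    }
  }
  num / den
}

# Efron partial log-likelihood for a single binary covariate, by explicit
# risk-set enumeration
oracle_efron_pll <- function(beta, x, time, event) {
  ll <- 0
  for (tt in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == tt)
    R <- which(time >= tt)
    d <- length(D)
    sR <- sum(exp(beta * x[R])); sD <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) ll <- ll - log(sR - (l / d) * sD)
  }
  ll
}

# score test at beta = 0 from the Efron partial likelihood, by enumeration
oracle_score_test <- function(x, time, event) {
  U <- V <- 0
  for (tt in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == tt)
    R <- which(time >= tt)
    d <- length(D)
    U <- U + sum(x[D])
    for (l in seq_len(d) - 1) {
      mu <- (sum(x[R]) - (l / d) * sum(x[D])) / (length(R) - l)
      m2 <- (sum(x[R]^2) - (l / d) * sum(x[D]^2)) / (length(R) - l)
      U <- U - mu
      V <- V + (m2 - mu^2)
    }
  }
  chi2 <- U^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# small random survival dataset with continuous (tie-free) times
random_surv <- function(n, cens_frac = 0.3) {
  t_ev <- rexp(n, 0.05)
  t_cn <- if (cens_frac > 0) rexp(n, 0.05 * cens_frac / (1 - cens_frac)) else Inf
  data.frame(sample = sprintf("P%03d", seq_len(n)),
             time = pmin(t_ev, t_cn),
             event = as.integer(t_ev <= t_cn),
             stringsAsFactors = FALSE)
}

# small random expression matrix
random_expr <- function(genes = 6, samples = 10) {
  m <- matrix(round(runif(genes * samples, 1, 100), 3), genes, samples)
  dimnames(m) <- list(paste0("g", seq_len(genes)), paste0("s", seq_len(samples)))
  m
}

# strictly increasing per-sample transforms used in invariance checks
monotone_transforms <- list(
  log2p1 = function(x) log2(x + 1),
  rank = function(x) rank(x),
  affine = function(x) 2.5 * x + 7,
  cube = function(x) x^3,
  expdec = function(x) 1 - exp(-x / 50)
)

apply_per_sample <- function(expr, fun_list) {
  out <- expr
  for (s in seq_len(ncol(expr))) {
    f <- fun_list[[((s - 1) %% length(fun_list)) + 1]]
    out[, s] <- f(expr[, s])
  }
  out
}
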