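# Evaluation statistics for a risk score on right-censored survival data:
# Kaplan-Meier / log-rank group comparison, multivariate Cox adjustment,
# Harrell's concordance with an 80%-resampling robustness protocol,
# IPCW cumulative/dynamic time-dependent AUC, and the restricted mean
# survival time ratio.

#' Kaplan-Meier curves and two-sample log-rank test
#'
#' @param groups factor/vector of two group labels, one per survival row.
#' @param surv survival data frame (`sample`, `time`, `event`).
#' @return list with `chi2`, `p` (1 df), and `km` (a
#'   [survival::survfit] object with per-group product-limit curves).
#' @export
km_logrank <- function(groups, surv) {
  validate_survival(surv, "survival_eval")
  groups <- factor(groups)
  if (length(groups) != nrow(surv))
    stop_stage("survival_eval", "groups length must match survival rows")
  tab <- table(droplevels(groups))
  if (length(tab) < 2L)
    stop_stage("survival_eval", "both groups must be non-empty; got levels: ",
               paste(names(tab), collapse = ", "))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = data.frame(time = surv$time, event = surv$event,
                                             g = groups))
  km <- survival::survfit(survival::Surv(time, event) ~ g,
                          data = data.frame(time = surv$time, event = surv$event,
                                            g = groups))
  list(chi2 = as.numeric(sd$chisq),
       p = pchisq(as.numeric(sd$chisq), df = 1L, lower.tail = FALSE),
       km = km)
}

#' Multivariate Cox proportional hazards adjustment
#'
#' Fits `Surv(time, event) ~ .` over the supplied covariates (typically the
#' risk score or group plus clinicopathological features) by partial
#' likelihood with Efron tie handling; returns Wald hazard ratios, CIs and
#' p-values per covariate.
#'
#' @param surv survival data frame.
#' @param covariates data frame of covariates, rows aligned to `surv`.
#' @param conf_level Wald CI level (default 0.95).
#' @return data frame: `covariate`, `coef`, `hr`, `hr_lo`, `hr_hi`, `p`.
#' @export
cox_multivariate <- function(surv, covariates, conf_level = 0.95) {
  validate_survival(surv, "survival_eval")
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(surv))
    stop_stage("survival_eval", "covariate rows must match survival rows")
  const <- vapply(covariates, function(x) length(unique(x[!is.na(x)])) < 2L,
                  logical(1L))
  if (any(const))
    stop_stage("survival_eval", "constant covariate(s): ",
               paste(names(covariates)[const], collapse = ", "))
  n_ev <- sum(surv$event)
  if (n_ev < ncol(covariates))
    stop_stage("survival_eval", "fewer events (", n_ev, ") than covariates")
  if (n_ev < 10L * ncol(covariates))
    warn_stage("survival_eval", "fewer than 10 events per covariate (",
               n_ev, " events, ", ncol(covariates), " covariates)")
  dat <- cbind(data.frame(.time = surv$time, .event = surv$event), covariates)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w)))
        stop_stage("survival_eval",
                   "monotone likelihood / separation while fitting covariates (",
                   paste(colnames(covariates), collapse = ", "), "): ",
                   conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit, conf.int = conf_level)
  data.frame(covariate = rownames(sm$coefficients),
             coef = sm$coefficients[, "coef"],
             hr = sm$conf.int[, 1L],
             hr_lo = sm$conf.int[, 3L],
             hr_hi = sm$conf.int[, 4L],
             p = sm$coefficients[, "Pr(>|z|)"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Harrell's concordance index
#'
#' Fraction of usable (comparable under censoring) subject pairs whose risk
#' ordering agrees with their survival ordering; tied scores count 0.5.
#' Higher scores are treated as higher risk (shorter survival).
#'
#' @param scores numeric risk scores.
#' @param surv survival data frame aligned to `scores`.
#' @return concordance index in \[0, 1\].
#' @export
harrell_c <- function(scores, surv) {
  validate_survival(surv, "survival_eval")
  if (length(scores) != nrow(surv))
    stop_stage("survival_eval", "scores length must match survival rows")
  cf <- survival::concordance(
    survival::Surv(time, event) ~ s,
    data = data.frame(time = surv$time, event = surv$event, s = scores),
    reverse = TRUE)
  cnt <- cf$count
  comparable <- cnt[["concordant"]] + cnt[["discordant"]] + cnt[["tied.x"]]
  if (comparable == 0)
    stop_stage("survival_eval", "no comparable pairs under censoring")
  as.numeric(cf$concordance)
}

#' Resampling robustness of concordance and group separation
#'
#' Mirrors the 80%-subsample protocol: for each repetition, draw
#' `floor(fraction * n)` subjects without replacement, compute Harrell's C of
#' the scores, split the resample at its own median score, and record the
#' log-rank p-value of that split. Reports the mean and SD of C and the
#' fraction of repetitions whose p-value beats `p_threshold`.
#'
#' @param scores numeric risk scores.
#' @param surv aligned survival data frame.
#' @param fraction subsample fraction in (0, 1\] (default 0.8).
#' @param reps number of repetitions (>= 100 recommended for a stable SD).
#' @param p_threshold log-rank significance threshold (default 0.05).
#' @param seed integer seed; the run is bit-reproducible given it.
#' @return list: `c_mean`, `c_sd`, `frac_significant`, `c_values`, `p_values`.
#' @export
resample_c <- function(scores, surv, fraction = 0.8, reps = 1000L,
                       p_threshold = 0.05, seed = 1L) {
  validate_survival(surv, "survival_eval")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop_stage("survival_eval", "fraction must lie in (0, 1], got ", fraction)
  if (reps < 100L)
    warn_stage("survival_eval", "reps < 100 gives an unstable SD estimate")
  n <- nrow(surv)
  m <- floor(fraction * n)
  if (m < 2L) stop_stage("survival_eval", "subsample too small")
  set.seed(derive_seed(seed, "resample"))
  cs <- numeric(reps); ps <- numeric(reps)
  for (r in seq_len(reps)) {
    idx <- if (m == n) seq_len(n) else sample.int(n, m)
    sub <- surv[idx, , drop = FALSE]
    s <- scores[idx]
    cs[r] <- harrell_c(s, sub)
    g <- stratify(s, mode = "median")
    ps[r] <- if (nlevels(droplevels(g)) < 2L) NA_real_
             else km_logrank(g, sub)$p
  }
  list(c_mean = mean(cs), c_sd = stats::sd(cs),
       frac_significant = mean(!is.na(ps) & ps < p_threshold),
       c_values = cs, p_values = ps)
}

# Evaluate a KM step function fitted on (times S at knots) at points t;
# left = TRUE gives the left-continuous value S(t-).
km_step_eval <- function(knots, surv_at_knots, t, left = FALSE) {
  if (length(knots) == 0L) return(rep(1, length(t)))
  idx <- if (left) findInterval(t, knots, left.open = TRUE)
         else findInterval(t, knots)
  c(1, surv_at_knots)[idx + 1L]
}

#' Time-dependent cumulative/dynamic AUC with IPCW
#'
#' Discrimination of a risk score for event-by-time-t status. Cases at
#' horizon t are subjects with an observed event at or before t, weighted by
#' the inverse of the Kaplan-Meier censoring survival function evaluated
#' just before their event time; controls are subjects still at risk beyond
#' t. Tied scores count 0.5. No smoothing is involved.
#'
#' @param scores numeric risk scores.
#' @param surv aligned survival data frame (times in months).
#' @param times evaluation horizons, by default in years (converted to
#'   months); each must be smaller than the maximum follow-up.
#' @param times_unit `"years"` (default) or `"months"`.
#' @return named numeric vector of AUC values, one per horizon.
#' @export
time_dependent_auc <- function(scores, surv, times = c(3, 5, 10),
                               times_unit = c("years", "months")) {
  times_unit <- match.arg(times_unit)
  validate_survival(surv, "survival_eval")
  if (length(scores) != nrow(surv))
    stop_stage("survival_eval", "scores length must match survival rows")
  horizons <- if (times_unit == "years") times * 12 else times
  if (any(horizons >= max(surv$time)))
    stop_stage("survival_eval", "evaluation time(s) at or beyond maximum follow-up (",
               format(max(surv$time), digits = 4), " months)")
  # censoring distribution: KM on flipped event indicator
  cfit <- survival::survfit(survival::Surv(time, cens) ~ 1,
                            data = data.frame(time = surv$time,
                                              cens = 1 - surv$event))
  out <- vapply(seq_along(horizons), function(k) {
    t0 <- horizons[k]
    case <- which(surv$time <= t0 & surv$event == 1)
    ctrl <- which(surv$time > t0)
    if (length(case) == 0L)
      stop_stage("survival_eval", "no events before horizon ", times[k],
                 " ", times_unit)
    if (length(ctrl) == 0L)
      stop_stage("survival_eval", "no subjects at risk beyond horizon ",
                 times[k], " ", times_unit)
    Gi <- km_step_eval(cfit$time, cfit$surv, surv$time[case], left = TRUE)
    if (any(Gi <= 0))
      stop_stage("survival_eval", "censoring survival reaches 0 before horizon ",
                 times[k], "; cannot weight all cases")
    w <- 1 / Gi
    cmp <- outer(scores[case], scores[ctrl], ">") +
           0.5 * outer(scores[case], scores[ctrl], "==")
    sum(w * rowSums(cmp)) / (sum(w) * length(ctrl))
  }, numeric(1L))
  names(out) <- as.character(times)
  out
}

# Area under a KM curve from 0 to tau (restricted mean survival time).
km_area <- function(time, event, tau) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = data.frame(time = time, event = event))
  knots <- c(0, fit$time[fit$time < tau], tau)
  sv <- c(1, km_step_eval(fit$time, fit$surv, knots[-length(knots)][-1L]))
  sum(sv * diff(knots))
}

#' Restricted mean survival time ratio between risk groups
#'
#' Area under each group's Kaplan-Meier curve from 0 to `tau`; returns the
#' high-risk area divided by the low-risk area. Values below 1 indicate
#' shorter average survival (up to `tau`) in the high-risk group.
#'
#' @param groups factor with levels `LRisk`, `HRisk` (or any two labels; the
#'   second level is the numerator).
#' @param surv aligned survival data frame.
#' @param tau horizon; defaults to the smaller of the two groups' largest
#'   observed times. It may exceed a group's follow-up only when that
#'   group's KM curve has already reached zero (otherwise the restricted
#'   mean would require extrapolation and an error is raised).
#' @return ratio of restricted mean survival times (numerator / denominator).
#' @export
rms_ratio <- function(groups, surv, tau = NULL) {
  validate_survival(surv, "survival_eval")
  groups <- factor(groups)
  if (length(groups) != nrow(surv))
    stop_stage("survival_eval", "groups length must match survival rows")
  lv <- levels(droplevels(groups))
  if (length(lv) != 2L)
    stop_stage("survival_eval", "need exactly two non-empty groups, got: ",
               paste(lv, collapse = ", "))
  t_hi <- surv$time[groups == lv[2L]]; e_hi <- surv$event[groups == lv[2L]]
  t_lo <- surv$time[groups == lv[1L]]; e_lo <- surv$event[groups == lv[1L]]
  if (is.null(tau)) tau <- min(max(t_lo), max(t_hi))
  # tau beyond a group's follow-up is only meaningful when that group's KM
  # curve has already dropped to zero (the step extension is then exact)
  for (g in list(list(t = t_lo, e = e_lo, lab = lv[1L]),
                 list(t = t_hi, e = e_hi, lab = lv[2L]))) {
    if (tau > max(g$t)) {
      fit <- survival::survfit(survival::Surv(g$t, g$e) ~ 1)
      if (min(fit$surv) > 0)
        stop_stage("survival_eval", "tau = ", tau, " exceeds follow-up of group ",
                   g$lab, " (max ", format(max(g$t)),
                   ") with survival still above 0")
    }
  }
  hi <- km_area(t_hi, e_hi, tau)
  lo <- km_area(t_lo, e_lo, tau)
  hi / lo
}

#' Full evaluation report for a scored cohort
#'
#' Bundles the evaluation statistics: median or fixed-cutoff stratification,
#' KM/log-rank, Cox hazard ratio of the (standardized) score and of the risk
#' group, Harrell's C with the resampling protocol, time-dependent AUC at
#' the requested horizons, and the RMS ratio.
#'
#' @param scores numeric risk scores.
#' @param surv aligned survival data frame.
#' @param times AUC horizons in years (default 3, 5, 10).
#' @param reps resampling repetitions (default 1000).
#' @param fraction resampling fraction (default 0.8).
#' @param seed integer seed for the resampling protocol.
#' @param mode,cutoff stratification rule, see [stratify()].
#' @param covariates optional extra covariate data frame for the Cox model.
#' @return list of class `irgpi_eval`.
#' @export
evaluate_cohort <- function(scores, surv, times = c(3, 5, 10), reps = 1000L,
                            fraction = 0.8, seed = 1L,
                            mode = c("median", "fixed"), cutoff = NULL,
                            covariates = NULL) {
  mode <- match.arg(mode)
  groups <- stratify(scores, mode = mode, cutoff = cutoff)
  lr <- km_logrank(groups, surv)
  covs <- data.frame(irgpi = scores)
  if (!is.null(covariates)) covs <- cbind(covs, covariates)
  cox <- cox_multivariate(surv, covs)
  grp_cox <- cox_multivariate(surv, data.frame(group = as.integer(groups == "HRisk")))
  rc <- resample_c(scores, surv, fraction = fraction, reps = reps, seed = seed)
  auc <- tryCatch(time_dependent_auc(scores, surv, times = times),
                  error = function(e) {
                    warn_stage("survival_eval", conditionMessage(e))
                    stats::setNames(rep(NA_real_, length(times)), times)
                  })
  tau <- min(tapply(surv$time, groups, max))
  structure(list(
    n = nrow(surv), n_events = sum(surv$event),
    cutoff = attr(groups, "cutoff"), mode = mode,
    group_sizes = as.list(table(groups)),
    logrank_chi2 = lr$chi2, logrank_p = lr$p,
    hr_with_ci = cox,
    hr_group = grp_cox$hr[1L], hr_group_p = grp_cox$p[1L],
    c_index = harrell_c(scores, surv),
    c_resample_mean = rc$c_mean, c_resample_sd = rc$c_sd,
    frac_p_above_threshold = 1 - rc$frac_significant,
    frac_significant = rc$frac_significant,
    auc_at_times = as.list(auc),
    rms_ratio = rms_ratio(groups, surv, tau = tau),
    tau = tau
  ), class = "irgpi_eval")
}

#' @export
print.irgpi_eval <- function(x, ...) {
  cat("Cohort evaluation (n =", x$n, ",", x$n_events, "events)\n")
  cat("  cutoff:", format(x$cutoff, digits = 4), "(", x$mode, ")\n")
  cat("  log-rank chi2 =", format(x$logrank_chi2, digits = 4),
      ", p =", format(x$logrank_p, digits = 3), "\n")
  cat("  group HR =", format(x$hr_group, digits = 3), "\n")
  cat("  C-index =", format(x$c_index, digits = 3),
      "(resampled", format(x$c_resample_mean, digits = 3), "+/-",
      format(x$c_resample_sd, digits = 2), ")\n")
  cat("  AUC:", paste(names(x$auc_at_times), "y =",
                      vapply(x$auc_at_times, function(a) format(a, digits = 3), ""),
                      collapse = ", "), "\n")
  cat("  RMS ratio =", format(x$rms_ratio, digits = 3),
      "at tau =", format(x$tau, digits = 4), "months\n")
  invisible(x)
}
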