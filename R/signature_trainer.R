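# Training: univariate score-test screening of candidate pairs, then
# L1-penalized Cox selection with cross-validated penalty, producing a
# portable signature (pairs + coefficients + cutoff).

#' Training configuration
#'
#' @param screen_p univariate score-test retention threshold, in (0, 1].
#' @param cv_folds folds for cross-validated penalty selection (>= 3); folds
#'   are stratified by event status to stabilize partial-likelihood CV.
#' @param lambda_rule `"min"` (CV-optimal penalty, default) or `"1se"`
#'   (sparser: largest penalty within one SE of the optimum).
#' @param seed integer seed driving fold assignment; stored in signature
#'   metadata so a training run can be reproduced exactly.
#' @param f_min informative-pair frequency band edge, see
#'   [filter_informative_pairs()].
#' @param mad_threshold gene variability prefilter, see [prefilter_genes()].
#' @param max_pairs cap on the number of active pairs along the penalized
#'   path (default 40); an events-per-variable guardrail that also keeps the
#'   coordinate descent away from its unstable dense tail.
#' @return list of class `train_config`.
#' @export
train_config <- function(screen_p = 0.05, cv_folds = 5L,
                         lambda_rule = c("min", "1se"), seed = 1L,
                         f_min = 0.2, mad_threshold = 0.5, max_pairs = 40L) {
  lambda_rule <- match.arg(lambda_rule)
  if (!is.numeric(screen_p) || screen_p <= 0 || screen_p > 1)
    stop_stage("signature_trainer", "screen_p must lie in (0, 1]")
  if (cv_folds < 3L) stop_stage("signature_trainer", "cv_folds must be >= 3")
  if (max_pairs < 1L) stop_stage("signature_trainer", "max_pairs must be >= 1")
  structure(list(screen_p = screen_p, cv_folds = as.integer(cv_folds),
                 lambda_rule = lambda_rule, seed = as.integer(seed),
                 f_min = f_min, mad_threshold = mad_threshold,
                 max_pairs = as.integer(max_pairs)),
            class = "train_config")
}

# Vectorized Cox score test at beta = 0 for binary covariates, with Efron
# correction for tied event times. X is pairs x samples; returns per-row
# score chi-square and p. Closed form: for each death time with d tied
# deaths, the l-th Efron term (l = 0..d-1) has mean
# mu_l = (S_R - (l/d) S_D) / (n_R - l) with S_R, S_D the covariate sums over
# the risk and death sets; for a binary covariate the variance term is
# mu_l (1 - mu_l). U = sum(S_D) - sum(mu_l); V = sum(mu_l (1 - mu_l)).
cox_score_test_matrix <- function(X, time, event) {
  stopifnot(ncol(X) == length(time), length(time) == length(event))
  ord <- order(time, decreasing = TRUE)
  td <- time[ord]
  CS <- X[, ord, drop = FALSE]
  for (j in seq_len(ncol(CS))[-1L]) CS[, j] <- CS[, j] + CS[, j - 1L]
  dtimes <- sort(unique(time[event == 1]))
  K <- length(dtimes)
  n_k <- vapply(dtimes, function(tt) sum(time >= tt), integer(1L))
  ev <- which(event == 1)
  grp <- match(time[ev], dtimes)
  SD <- t(rowsum(t(X[, ev, drop = FALSE]), group = grp, reorder = TRUE))
  d_k <- as.integer(table(factor(grp, levels = seq_len(K))))
  SR <- CS[, n_k, drop = FALSE]
  U <- rowSums(SD)
  V <- numeric(nrow(X))
  for (l in seq_len(max(d_k)) - 1L) {
    k <- which(d_k > l)
    mu <- (SR[, k, drop = FALSE] - (l / d_k[k])[col(SR[, k, drop = FALSE])] *
             SD[, k, drop = FALSE]) /
          (n_k[k] - l)[col(SR[, k, drop = FALSE])]
    U <- U - rowSums(mu)
    V <- V + rowSums(mu * (1 - mu))
  }
  chi2 <- ifelse(V > 0, U^2 / V, NA_real_)
  list(u = U, v = V, chi2 = chi2,
       p = pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Univariate Cox score-test screen of candidate pairs
#'
#' Each pair's 0/1 indicator is tested as a single Cox covariate with the
#' partial-likelihood score test (Efron tie handling); pairs with
#' `p < screen_p` are retained. Pairs whose indicator is constant across
#' samples are inestimable and skipped with a warning.
#'
#' @param ind a `pair_indicators` object (samples must match `surv`).
#' @param surv survival data frame (`sample`, `time`, `event`) aligned to the
#'   indicator columns.
#' @param screen_p retention threshold (default 0.05).
#' @return data frame of retained pairs with columns `gene_a`, `gene_b`, `p`.
#' @export
univariate_cox_screen <- function(ind, surv, screen_p = 0.05) {
  stopifnot(inherits(ind, "pair_indicators"))
  validate_survival(surv, "signature_trainer")
  if (ncol(ind$indicators) != nrow(surv))
    stop_stage("signature_trainer", "indicator samples (", ncol(ind$indicators),
               ") do not match survival rows (", nrow(surv), ")")
  if (sum(surv$event) < 2L)
    stop_stage("signature_trainer", "need at least 2 events to screen pairs, got ",
               sum(surv$event))
  X <- ind$indicators
  freq <- rowMeans(X)
  const <- freq == 0 | freq == 1
  if (any(const))
    warn_stage("signature_trainer", sum(const),
               " pair(s) with constant indicator skipped (inestimable)")
  st <- cox_score_test_matrix(X, surv$time, surv$event)
  p <- st$p
  p[const] <- NA_real_
  keep <- which(!is.na(p) & p < screen_p)
  out <- ind$pairs[keep, , drop = FALSE]
  out$p <- p[keep]
  rownames(out) <- NULL
  out
}

# Efron partial log-likelihood for a single covariate (used for the
# one-candidate penalized fit, where coordinate descent has nothing to
# iterate over).
cox_pll_efron <- function(beta, x, time, event) {
  eta <- beta * x
  w <- exp(eta)
  dtimes <- sort(unique(time[event == 1]))
  ll <- 0
  for (tt in dtimes) {
    D <- which(event == 1 & time == tt)
    R <- which(time >= tt)
    d <- length(D)
    sR <- sum(w[R]); sD <- sum(w[D])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1L) ll <- ll - log(sR - (l / d) * sD)
  }
  ll
}

#' Fit an L1-penalized Cox model over candidate pairs
#'
#' Coordinate-descent lasso on the Cox partial likelihood (via
#' \pkg{glmnet}) in its fully relaxed form: the L1 path proposes nested
#' candidate supports, each support is refit by unpenalized partial
#' likelihood, and the penalty (hence the support) is chosen by
#' `cv_folds`-fold cross-validated partial likelihood of the refits under
#' `lambda_rule`. The reported coefficients are the unpenalized refit, so
#' the score scale carries no shrinkage bias. Folds are stratified by event
#' status and derived deterministically from `config$seed`. Pairs with zero
#' coefficient at the chosen penalty are dropped; an empty selection is
#' reported as a zero-row result (callers decide whether that is an error).
#'
#' Indicators are left unstandardized: they already share the 0/1 scale, and
#' coefficients then apply directly to indicator values when scoring.
#'
#' @param ind a `pair_indicators` object of candidate pairs.
#' @param surv aligned survival data frame.
#' @param config a [train_config()].
#' @param lambda optional fixed penalty overriding cross-validation
#'   (`0` gives the unpenalized fit, `Inf` selects nothing).
#' @return data frame with columns `gene_a`, `gene_b`, `beta` (possibly
#'   zero rows), with attribute `lambda` = penalty used.
#' @export
fit_lasso_cox <- function(ind, surv, config = train_config(), lambda = NULL) {
  stopifnot(inherits(ind, "pair_indicators"))
  validate_survival(surv, "signature_trainer")
  n_ev <- sum(surv$event)
  if (n_ev < 10L)
    warn_stage("signature_trainer", "only ", n_ev,
               " events; penalized selection may be unstable (>= 10 recommended)")
  P <- nrow(ind$pairs)
  if (P == 0L) {
    out <- data.frame(gene_a = character(), gene_b = character(), beta = numeric())
    attr(out, "lambda") <- NA_real_
    return(out)
  }
  y <- survival::Surv(surv$time, surv$event)

  if (P == 1L) {
    # 1-D penalized Efron partial likelihood, solved by direct optimization.
    lam <- if (is.null(lambda)) 0 else lambda
    x <- as.numeric(ind$indicators[1L, ])
    if (is.infinite(lam)) b <- 0
    else {
      obj <- function(b) -cox_pll_efron(b, x, surv$time, surv$event) / nrow(surv) +
        lam * abs(b)
      b <- optimize(obj, interval = c(-20, 20), tol = 1e-9)$minimum
      if (abs(b) < 1e-6) b <- 0
    }
    out <- ind$pairs[if (b != 0) 1L else integer(0), , drop = FALSE]
    out$beta <- if (b != 0) b else numeric(0)
    rownames(out) <- NULL
    attr(out, "lambda") <- lam
    if (nrow(out) == 0L) message("[signature_trainer] empty selection at lambda = ", lam)
    return(out)
  }

  x <- t(ind$indicators)
  if (is.null(lambda)) {
    set.seed(derive_seed(config$seed, "cvfolds"))
    foldid <- integer(nrow(surv))
    for (e in c(0L, 1L)) {
      idx <- sample(which(surv$event == e))
      foldid[idx] <- rep_len(seq_len(config$cv_folds), length(idx))
    }
    # Fully relaxed lasso: the L1 path proposes nested supports, each support
    # is refit without penalty, and CV picks the support whose refit partial
    # likelihood validates best. Plain CV-min lasso systematically overselects
    # among correlated rank indicators (pairs sharing a gene), and shrunk
    # coefficients would bias the score scale a fixed cutoff presumes.
    # The path is truncated at max_pairs active pairs and a moderate
    # lambda.min.ratio; the near-unpenalized tail over collinear binary
    # columns is numerically unstable and never CV-optimal. glmnet warns
    # when it truncates the path there; that is expected.
    cv <- suppressWarnings(glmnet::cv.glmnet(
      x, y, family = "cox", foldid = foldid, standardize = FALSE,
      nlambda = 60L, lambda.min.ratio = 0.05,
      pmax = min(ncol(x), config$max_pairs), relax = TRUE, gamma = 0))
    lam <- if (config$lambda_rule == "min") cv$relaxed$lambda.min
           else cv$relaxed$lambda.1se
    b <- as.numeric(glmnet::coef.glmnet(cv, s = lam, gamma = 0))
  } else {
    lam <- lambda
    if (is.infinite(lam)) {
      out <- data.frame(gene_a = character(), gene_b = character(), beta = numeric())
      attr(out, "lambda") <- lam
      message("[signature_trainer] empty selection at lambda = Inf")
      return(out)
    }
    fit <- glmnet::glmnet(x, y, family = "cox", standardize = FALSE,
                          nlambda = 60L, lambda.min.ratio = 0.05)
    b <- as.numeric(glmnet::coef.glmnet(fit, s = lam, exact = FALSE))
  }
  if (!all(is.finite(b)))
    stop_stage("signature_trainer", "penalized Cox fit did not converge")
  keep <- which(b != 0)
  out <- ind$pairs[keep, , drop = FALSE]
  out$beta <- b[keep]
  rownames(out) <- NULL
  attr(out, "lambda") <- lam
  if (nrow(out) == 0L)
    message("[signature_trainer] empty selection at lambda = ", format(lam))
  out
}

#' Train a gene-pair prognostic signature
#'
#' Full pipeline: gene variability prefilter within the immune gene set,
#' candidate pair enumeration (both members immune-related), informative-pair
#' frequency filter, univariate score-test screen, and lasso-Cox selection.
#' The risk cutoff defaults to the median training score (the
#' dataset-specific convention); pass `cutoff` to fix it externally (e.g. a
#' cross-platform constant).
#'
#' @param expr expression matrix (genes x samples).
#' @param gene_set immune gene identifiers (vector or [read_gene_set()]
#'   data frame).
#' @param surv survival data frame (`sample`, `time`, `event`); samples are
#'   intersected with the expression columns.
#' @param config a [train_config()].
#' @param cutoff optional fixed risk cutoff overriding the training median.
#' @return an `irgp_signature` with provenance (`n`, `n_events`, `seed`,
#'   `config`, `hash`) in `$metadata`.
#' @export
train_signature <- function(expr, gene_set, surv, config = train_config(),
                            cutoff = NULL) {
  validate_expression(expr)
  validate_survival(surv, "signature_trainer")
  al <- align_samples(expr, surv, "signature_trainer")
  expr <- al$expr; surv <- al$surv

  genes <- prefilter_genes(expr, gene_set, config$mad_threshold)
  if (length(genes) < 2L)
    stop_stage("signature_trainer", "fewer than 2 genes pass the prefilter")
  ind <- build_indicator_matrix(expr, make_pairs(genes))
  informative <- filter_informative_pairs(ind, config$f_min)
  if (nrow(informative) == 0L)
    stop_stage("signature_trainer", "no informative pairs in the frequency band")
  ind <- subset_pairs(ind, match(paste(informative$gene_a, informative$gene_b),
                                 paste(ind$pairs$gene_a, ind$pairs$gene_b)))

  screened <- univariate_cox_screen(ind, surv, config$screen_p)
  if (nrow(screened) == 0L)
    stop_stage("signature_trainer", "no pairs pass the univariate screen at p < ",
               config$screen_p)
  ind <- subset_pairs(ind, match(paste(screened$gene_a, screened$gene_b),
                                 paste(ind$pairs$gene_a, ind$pairs$gene_b)))

  sel <- fit_lasso_cox(ind, surv, config)
  if (nrow(sel) == 0L)
    stop_stage("signature_trainer",
               "penalized selection retained no pairs (empty signature)")

  sig <- irgp_signature(sel$gene_a, sel$gene_b, sel$beta, cutoff = 0,
                        drop_zero = TRUE)
  scores <- score_cohort(expr, sig, missing_policy = "strict")$irgpi
  sig$cutoff <- if (is.null(cutoff)) median(scores) else as.numeric(cutoff)
  sig$metadata <- list(
    n = nrow(surv), n_events = sum(surv$event), seed = config$seed,
    config = unclass(config), lambda = attr(sel, "lambda"),
    n_candidates = nrow(informative), n_screened = nrow(screened),
    cutoff_rule = if (is.null(cutoff)) "training_median" else "fixed",
    hash = rlang::hash(list(unclass(config), expr, surv))
  )
  sig
}
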