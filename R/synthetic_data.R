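# Multi-platform survival-cohort simulator with known pair-driven hazard.
#
# The generator emulates the structure of a multi-cohort, multi-platform
# compendium: a base lognormal expression matrix, a small set of disjoint
# "true" gene pairs whose order indicators drive an exponential
# proportional-hazards event process with independent exponential censoring,
# and per-sample strictly monotone platform distortions that change every
# measured value while leaving all within-sample orderings intact.

#' Simulation configuration
#'
#' Defaults define the standard recovery scenario used throughout the test
#' suite: 600 samples, a 150-gene immune panel, 8 true pairs with
#' |beta| in \[0.5, 1\], ~30% censoring, 2 platforms.
#'
#' @param n_samples,n_genes,n_true_pairs cohort dimensions; the true pairs
#'   use `2 * n_true_pairs` disjoint genes, so that many genes are required.
#' @param beta_range positive interval for |beta|; signs are drawn at random.
#' @param baseline_hazard events per month at the average linear predictor
#'   (default 0.012, median survival near five years).
#' @param censoring_rate_target expected fraction censored, in \[0, 0.99).
#' @param n_platforms number of distorted copies of the base matrix.
#' @param distortion character vector of per-platform distortion families
#'   (`"log"`, `"power"`, `"rank"`, `"affine"`), recycled across platforms;
#'   every family applies a different strictly increasing transform to each
#'   sample.
#' @param weibull_shape event-time shape; 1 (default) gives exponential
#'   times, other positive values Weibull with the same scale structure.
#' @param seed integer; the whole cohort is a deterministic function of it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 600L, n_genes = 150L, n_true_pairs = 8L,
                       beta_range = c(0.5, 1.0), baseline_hazard = 0.012,
                       censoring_rate_target = 0.3, n_platforms = 2L,
                       distortion = c("log", "rank"), weibull_shape = 1,
                       seed = 1L) {
  if (any(c(n_samples, n_genes, n_true_pairs, n_platforms) < 1L))
    stop_stage("synthetic_data", "all counts must be positive")
  if (2L * n_true_pairs > n_genes)
    stop_stage("synthetic_data", "need n_genes >= 2 * n_true_pairs for disjoint pairs")
  if (censoring_rate_target < 0 || censoring_rate_target > 0.99)
    stop_stage("synthetic_data", "censoring_rate_target must lie in [0, 0.99]")
  if (length(beta_range) != 2L || any(beta_range < 0) || beta_range[1] > beta_range[2])
    stop_stage("synthetic_data", "beta_range must be an increasing non-negative interval")
  if (baseline_hazard <= 0 || weibull_shape <= 0)
    stop_stage("synthetic_data", "baseline_hazard and weibull_shape must be > 0")
  distortion <- match.arg(distortion, c("log", "power", "rank", "affine"),
                          several.ok = TRUE)
  structure(list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
                 n_true_pairs = as.integer(n_true_pairs), beta_range = beta_range,
                 baseline_hazard = baseline_hazard,
                 censoring_rate_target = censoring_rate_target,
                 n_platforms = as.integer(n_platforms), distortion = distortion,
                 weibull_shape = weibull_shape, seed = as.integer(seed)),
            class = "sim_config")
}

# Strictly increasing per-sample distortions. Each call draws fresh
# per-sample parameters from the current RNG stream.
distort_matrix <- function(expr, type) {
  n <- ncol(expr)
  out <- switch(type,
    log = {
      a <- runif(n, 0.5, 2)
      sweep(log2(expr + 1), 2L, a, `*`)
    },
    power = {
      g <- runif(n, 0.3, 3)
      sweep(expr, 2L, g, `^`)
    },
    rank = apply(expr, 2L, rank),
    affine = {
      a <- runif(n, 0.5, 2); b <- runif(n, -2, 2)
      sweep(sweep(expr, 2L, a, `*`), 2L, b, `+`)
    })
  dimnames(out) <- dimnames(expr)
  out
}

#' Simulate a multi-platform cohort with pair-driven hazard
#'
#' Base expression is lognormal with gene-specific location and scale; the
#' two members of each true pair share a similar location so their ordering
#' varies across samples (an informative pair). The per-sample linear
#' predictor is `eta = sum_i beta_i I_i` over the true pair indicators;
#' event times follow a Weibull (default exponential) hazard proportional to
#' `exp(eta - mean(eta))`, and independent exponential censoring is tuned by
#' root-finding so the expected censored fraction matches the target.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort`: `expr` (list of platform matrices),
#'   `base` (undistorted matrix), `surv` (survival data frame), `truth`
#'   (an `irgp_signature` of the true pairs/betas with the median-eta
#'   cutoff), `eta` (true linear predictor per sample), `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "cohort"))
  n <- config$n_samples; G <- config$n_genes; npair <- config$n_true_pairs

  genes <- sprintf("G%04d", seq_len(G))
  samples <- sprintf("S%04d", seq_len(n))
  mu <- runif(G, 2, 8)
  sdlog <- runif(G, 0.6, 1.4)

  pair_genes <- matrix(sample.int(G, 2L * npair), nrow = 2L)
  # true-pair members share a similar location so ordering is informative
  mu[pair_genes[2L, ]] <- mu[pair_genes[1L, ]] + rnorm(npair, 0, 0.3)
  sdlog[pair_genes[2L, ]] <- sdlog[pair_genes[1L, ]] * runif(npair, 0.8, 1.25)

  base <- exp(matrix(rnorm(G * n), nrow = G) * sdlog + mu)
  dimnames(base) <- list(genes, samples)

  ga <- genes[pair_genes[1L, ]]
  gb <- genes[pair_genes[2L, ]]
  beta <- runif(npair, config$beta_range[1L], config$beta_range[2L]) *
    sample(c(-1, 1), npair, replace = TRUE)
  # canonical orientation (gene_a before gene_b); flipping the indicator
  # negates the coefficient up to an additive constant absorbed by the
  # baseline hazard
  flip <- ga > gb
  tmp <- ga[flip]; ga[flip] <- gb[flip]; gb[flip] <- tmp
  beta[flip] <- -beta[flip]

  I <- (base[ga, , drop = FALSE] < base[gb, , drop = FALSE]) * 1
  eta <- as.numeric(crossprod(I, beta))
  rate <- config$baseline_hazard * exp(eta - mean(eta))

  # Weibull via inverse transform; shape 1 is exponential
  u <- runif(n)
  t_event <- (-log(u) / rate)^(1 / config$weibull_shape)

  if (config$censoring_rate_target == 0) {
    time <- t_event; event <- rep(1L, n)
  } else {
    target <- config$censoring_rate_target
    # expected censored fraction as a function of the censoring rate:
    # exponential T gives the closed form c/(c + r); Weibull T uses
    # quadrature over T's quantile grid
    obj <- function(log_c) {
      cr <- exp(log_c)
      if (config$weibull_shape == 1) return(mean(cr / (cr + rate)) - target)
      p <- seq(0.005, 0.995, by = 0.01)
      mean(vapply(seq_len(n), function(i) {
        q <- stats::qweibull(p, shape = config$weibull_shape,
                             scale = rate[i]^(-1 / config$weibull_shape))
        mean(1 - exp(-cr * q))
      }, numeric(1L))) - target
    }
    c_rate <- exp(uniroot(obj, c(-15, 15))$root)
    t_cens <- rexp(n, c_rate)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  }

  surv <- data.frame(sample = samples, time = time, event = event,
                     stringsAsFactors = FALSE)
  # null scenarios (beta_range collapsed at 0) keep their zero coefficients:
  # the truth is then "no pair matters", not an invalid signature
  truth <- suppressWarnings(
    irgp_signature(ga, gb, beta, cutoff = median(eta),
                   metadata = list(seed = config$seed, simulated = TRUE),
                   drop_zero = FALSE))
  dist_types <- rep_len(config$distortion, config$n_platforms)
  expr <- lapply(seq_len(config$n_platforms), function(k)
    distort_matrix(base, dist_types[k]))
  names(expr) <- paste0("platform", seq_len(config$n_platforms), "_", dist_types)

  structure(list(expr = expr, base = base, surv = surv, truth = truth,
                 eta = stats::setNames(eta, samples), config = config),
            class = "sim_cohort")
}

#' Check indicator agreement across simulated platforms
#'
#' Builds the full all-pairs indicator matrix on every platform and returns
#' `TRUE` iff all platforms agree bit-for-bit — the portability property the
#' simulator is designed to preserve (and to break, when a non-monotone
#' distortion is injected as a negative control).
#'
#' @param cohort a `sim_cohort` with at least 2 platforms.
#' @return logical scalar.
#' @export
verify_platform_consistency <- function(cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (length(cohort$expr) < 2L)
    stop_stage("synthetic_data", "need at least 2 platforms to compare")
  pairs <- make_pairs(rownames(cohort$expr[[1L]]))
  ref <- build_indicator_matrix(cohort$expr[[1L]], pairs)$indicators
  for (k in seq_along(cohort$expr)[-1L]) {
    ik <- build_indicator_matrix(cohort$expr[[k]], pairs)$indicators
    if (!identical(ref, ik)) return(FALSE)
  }
  TRUE
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort:", x$config$n_samples, "samples,",
      x$config$n_genes, "genes,", length(x$expr), "platform(s),",
      nrow(x$truth$pairs), "true pairs,",
      round(100 * mean(x$surv$event == 0)), "% censored\n")
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' One expression TSV per platform (`expr_<platform>.tsv`), `survival.tsv`,
#' and the ground-truth signature as `truth_signature.json`.
#'
#' @param cohort a `sim_cohort`.
#' @param outdir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(cohort$expr)) {
    p <- file.path(outdir, paste0("expr_", nm, ".tsv"))
    df <- data.frame(gene = rownames(cohort$expr[[nm]]),
                     cohort$expr[[nm]], check.names = FALSE)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(outdir, "survival.tsv")
  write.table(cohort$surv, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(outdir, "truth_signature.json")
  write_signature(cohort$truth, p)
  paths <- c(paths, p)
  gs <- file.path(outdir, "gene_set.tsv")
  write.table(data.frame(gene = rownames(cohort$base), category = "immune"),
              gs, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, gs)
  invisible(paths)
}
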