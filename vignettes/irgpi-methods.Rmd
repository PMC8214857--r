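---
title: "Rank-pair prognostic signatures: model, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-pair prognostic signatures: model, training and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Prognostic gene-expression signatures travel poorly between platforms:
microarray intensities, RNA-seq FPKM and TPM live on different scales, and
per-cohort normalization is a large source of irreproducibility. This
package implements a signature family that sidesteps the problem by using
only *within-sample* information: for a pair of genes $(a, b)$ the binary
indicator

$$ I_{ab}(s) = \mathbf{1}\{x_a(s) < x_b(s)\} $$

depends only on which of the two genes is higher in sample $s$. Any strictly
increasing transform applied to a sample's measurements — $\log_2(x+1)$,
ranking, positive affine rescaling, or a different monotone distortion per
sample — leaves every indicator, and therefore everything downstream,
exactly unchanged. The risk score for a sample is the weighted sum

$$ \mathrm{IRGPI}(s) = \sum_i \beta_i \, I_{a_i b_i}(s), $$

with coefficients $\beta_i$ estimated from a Cox proportional-hazards model,
and patients are called high-risk when the score exceeds a cutoff (the
training-cohort median by default, or a fixed cross-platform constant such
as the published 1.195 for the bladder-cancer immune signature this package
generalizes). Pairs are formed within an immune-related gene panel, so the
score reads out the relative ordering of immune transcripts in a single
sample without any cohort-level normalization.

The tie convention is $I = 0$ when $x_a = x_b$. The inequality direction is
arbitrary in itself — flipping a pair's orientation negates its coefficient
up to an additive constant absorbed by the baseline hazard — so pairs are
stored in a canonical orientation (lexicographic) and the orientation
convention is written into every signature file.

## Training pipeline

`train_signature()` runs five stages, each exposed separately:

1. **Variability prefilter** (`prefilter_genes`): genes in the immune panel
   with median absolute deviation above `mad_threshold` (default 0.5; 0
   disables the filter). The MAD is computed on the training scale, so the
   default is a log-scale-like knob.
2. **Candidate enumeration** (`make_pairs`): all unordered pairs within the
   surviving panel, canonical orientation.
3. **Frequency filter** (`filter_informative_pairs`): keep pairs whose
   indicator frequency across training samples lies in
   $[f_\min, 1-f_\min]$, default band $[0.2, 0.8]$ — the convention of the
   gene-pair classifier literature. A pair whose ordering is near-constant
   cannot discriminate anything.
4. **Univariate screen** (`univariate_cox_screen`): each pair's indicator is
   tested as a single Cox covariate with the partial-likelihood score test
   at $\beta = 0$ (Efron tie correction), retaining pairs with
   $p <$ `screen_p` (default 0.05). The test is evaluated in closed form for
   all pairs simultaneously — for a binary covariate the Efron term means
   and variances reduce to risk-set and death-set sums computable by one
   pass of cumulative sums — because candidate spaces reach $10^4$–$10^5$
   pairs and a model-fit per pair would dominate runtime. The vectorized
   statistic is cross-checked against `survival::coxph`'s score test in the
   test suite.
5. **Penalized selection** (`fit_lasso_cox`): a lasso-Cox fit in its *fully
   relaxed* form via `glmnet`: the $L_1$ path proposes nested supports, each
   support is refit by unpenalized partial likelihood, and `cv_folds`-fold
   cross-validation (folds stratified by event status, derived
   deterministically from the seed) picks the penalty whose *refit*
   validates best under `lambda_rule` (`"min"` default, `"1se"` for sparser
   models). Two properties motivated this choice over the plain lasso.
   First, indicator candidates are heavily correlated — any pair sharing a
   gene with an informative pair is a partial surrogate — and the CV-optimal
   plain lasso buys marginal predictive gain by keeping dozens of
   surrogates, which ruins the interpretability of the selected set; the
   relaxed criterion scores each support by what an unpenalized model
   achieves with it and stops much closer to the support that generated the
   risk. Second, reporting refit (unshrunk) coefficients keeps the score
   scale free of shrinkage bias, which matters when a fixed cutoff is to be
   reused across cohorts. The active-set path is capped at `max_pairs`
   (default 40) — an events-per-variable guardrail that also keeps the
   coordinate descent away from its numerically unstable near-unpenalized
   tail over collinear binary columns.

The cutoff defaults to the median training score; `cutoff =` fixes it
externally. Metadata records $n$, events, the seed, the full config, the
chosen penalty and a hash of config-plus-inputs, so a signature is an exact
provenance-carrying artifact.

Tie handling is Efron everywhere an unpenalized partial likelihood is
maximized (screen, one-pair fits, multivariate adjustment). The penalized
stage inherits `glmnet`'s Breslow approximation; with continuous or
fine-resolution times the two coincide, and the final coefficients come
from the Efron-free refit path inside `glmnet`'s relaxed fit, evaluated on
data where ties are rare by construction.

## Scoring and stratification

`compute_irgpi()` / `score_cohort()` evaluate the weighted indicator sum per
sample; samples are scored strictly independently. Missing genes follow one
of two policies: `strict` (default) errors naming the genes; `drop` skips
affected pairs with a per-sample count and **never** rescales the remaining
coefficients — renormalization would silently shift the score scale that a
fixed cutoff presumes. `stratify()` calls a sample high-risk iff its score
strictly exceeds the cutoff; a score exactly at the cutoff is low-risk.
Higher score means poorer outcome (positive log hazard ratio).

## Evaluation statistics

* **KM / log-rank** (`km_logrank`): product-limit curves and the two-sample
  log-rank test, via the survival package.
* **Multivariate Cox** (`cox_multivariate`): Wald hazard ratios and CIs for
  the score or group alongside clinical covariates; monotone-likelihood
  separation is converted into an informative error.
* **Harrell's C** (`harrell_c`): concordant fraction of usable pairs under
  censoring, tied scores counting 0.5 (wraps `survival::concordance`,
  checked against a pairwise enumeration oracle).
* **Resampling protocol** (`resample_c`): the robustness design of the
  source study — draw 80% of cases without replacement, recompute C and the
  log-rank p of a median split *within the resample*, repeat; report mean
  and SD of C and the fraction of significant splits. The median is
  recomputed per resample to mirror dataset-specific stratification.
* **Time-dependent AUC** (`time_dependent_auc`): cumulative/dynamic AUC at
  3/5/10 years with inverse-probability-of-censoring weights from the
  Kaplan–Meier estimate of the censoring distribution (left-continuous at
  case event times). The IPCW estimator needs no smoothing bandwidth, which
  is why it was chosen over nearest-neighbour ROC estimators.
* **RMS ratio** (`rms_ratio`): areas under the two groups' KM curves up to
  $\tau$ (default: the shorter of the two groups' largest observed times,
  since the source study does not state its horizon), high over low. The
  horizon may exceed a group's follow-up only when that group's curve has
  already reached zero; otherwise the restricted mean would extrapolate.

No multiple-testing correction is applied across statistics or cohorts —
the source literature reports per-cohort p-values — and users can correct
downstream.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure that matters to this method: a
multi-platform compendium whose hazard is driven by a known set of pair
indicators.

* Base expression is lognormal with gene-specific location
  ($\mu_g \sim U(2,8)$) and scale ($\sigma_g \sim U(0.6, 1.4)$) — wide
  enough that most gene pairs have near-constant ordering, as in real
  transcriptomes. The two members of each true pair share similar locations
  (offset $\sim N(0, 0.3)$) so their ordering varies across samples.
* True pairs are disjoint in genes; coefficients have magnitude in
  `beta_range` with random signs.
* Event times follow an exponential (optionally Weibull) hazard
  proportional to $\exp(\eta - \bar\eta)$, $\eta$ the true indicator sum;
  the baseline 0.012 events/month puts median survival near five years, a
  realistic figure for mixed-stage urothelial carcinoma cohorts.
* Censoring is independent exponential with its rate solved by root-finding
  so the expected censored fraction matches `censoring_rate_target`
  (default 0.3).
* Each platform applies its own strictly monotone *per-sample* transform
  (log with per-sample gain, per-sample power, within-sample rank, or
  positive affine). Per-sample monotonicity is the exact condition under
  which indicators are preserved; per-gene batch shifts would break it,
  which `verify_platform_consistency()` demonstrates as a negative control.

The default scenario — 600 samples, 150 immune genes, 8 true pairs,
$|\beta| \in [0.5, 1]$, 30% censoring, 2 platforms — is the recovery
benchmark used by the test suite and the acceptance script, evaluated over
20 seeds with a 70/30 train/test split and cross-platform scoring (train on
one platform, score the held-out samples on the other). These sizes keep a
full 20-seed recovery run under a minute while the true-predictor ceiling
(Harrell's C of $\eta$ itself, about 0.76 under these conditions) leaves
visible headroom above chance.

**What passing these tests does and does not show.** The generator
reproduces the *ordering* structure and the censored proportional-hazards
outcome model, so it exercises platform invariance, selection, scoring and
every evaluation statistic end-to-end. It does not reproduce transcriptome
covariance (genes are independent given their pair), probe-level noise,
non-proportional hazards, or informative censoring; performance numbers on
synthetic cohorts say nothing quantitative about real bladder-cancer
cohorts.

## Numerical choices and degenerate inputs

* Score tests use the closed-form Efron correction; constant indicators are
  inestimable and skipped with a warning.
* The `glmnet` path uses 60 lambdas down to ratio 0.05 with `pmax =
  max_pairs`; warnings from path truncation in the collinear tail are
  expected and suppressed inside the fit. An empty selection is an explicit
  error at the training level ("empty signature"), not a silent fallback.
* One-candidate fits bypass coordinate descent and optimize the penalized
  one-dimensional Efron partial likelihood directly.
* Exact score ties at the cutoff go to low risk; all-tied score vectors give
  C = 0.5 (every comparable pair counts 0.5) rather than an error.
* Duplicate expression rows collapse by mean by default (scale-preserving);
  `maxvar` and `max` are available. Gene matching is exact string match
  after whitespace trimming — alias databases drift, so any aliasing must
  be supplied explicitly as a two-column table.
* Times are months internally; year-denominated inputs and AUC horizons are
  converted (3/5/10 years = 36/60/120 months).
* All randomness (CV folds, resampling, simulation) derives from single
  integer seeds through a deterministic stream-splitting helper, so every
  artifact is bit-reproducible from its recorded seed.

## Known limitations

* The signature model is a relative risk score; it is not calibrated to
  absolute survival probabilities.
* The screen's nominal retention (5% of null pairs at `screen_p = 0.05`)
  holds marginally per pair; pair indicators sharing genes are dependent,
  so the *count* of screened pairs is overdispersed relative to binomial.
* `lambda_rule = "1se"` on the relaxed path can select very small supports
  (occasionally empty) on weak-signal cohorts; the default `"min"` is
  recommended unless sparsity is at a premium.
* With heavily tied, coarse follow-up times the penalized stage's Breslow
  approximation and the Efron-based refits can disagree slightly; all
  reported coefficients come from the refit side.
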