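# irgpi — immune-related gene-pair prognostic index toolkit

`irgpi` builds, applies and evaluates **rank-pair prognostic signatures**
for right-censored survival outcomes. It is aimed at translational
researchers who want a single-sample risk score that transfers across
expression platforms (microarray log-intensity, RNA-seq FPKM/TPM, ranks)
without any cohort-level normalization — the setting of immune gene-pair
indices for bladder cancer, where a fixed signature plus a fixed cutoff must
work on a new patient's profile in isolation.

## The model

For genes $a, b$ measured in sample $s$, the pair indicator is

$$ I_{ab}(s) = \mathbf{1}\{x_a(s) < x_b(s)\} \qquad (\text{ties} \to 0), $$

and the risk score of a sample is the Cox-weighted sum over the signature's
pairs:

$$ \mathrm{IRGPI}(s) = \sum_i \beta_i\, I_{a_i b_i}(s). $$

Because each indicator compares two genes *within* the same sample, the
score is exactly invariant to any strictly increasing per-sample transform
of the data — the property that makes the signature portable across
platforms. Samples with scores above a cutoff (training-cohort median, or a
fixed cross-platform constant such as the published 1.195) form the
high-risk (`HRisk`) group; higher score means poorer survival.

Training selects pairs from an immune gene panel by a variability
prefilter, an informative-frequency band on the indicators, a univariate
Cox score-test screen, and a relaxed lasso-Cox stage (L1 path for candidate
supports, unpenalized refits, cross-validated choice). Evaluation covers
Kaplan–Meier/log-rank, multivariate Cox hazard ratios, Harrell's C with an
80%-resampling robustness protocol, IPCW time-dependent AUC at 3/5/10
years, and restricted-mean-survival-time ratios. A seed-deterministic
simulator generates multi-platform cohorts with known pair-driven hazard so
the whole pipeline is testable end to end without downloading any cohort.

## Worked example

Simulate a two-platform cohort, train on 70% of platform 1, then score the
held-out 30% **on platform 2** — every sample distorted by a different
monotone transform — and evaluate:

```r
library(irgpi)

co <- simulate_cohort(sim_config(seed = 7))
co
#> Simulated cohort: 600 samples, 150 genes, 2 platform(s), 8 true pairs, 32 % censored

set.seed(7)
n <- nrow(co$surv)
train_idx <- sample(n, floor(0.7 * n))
test_idx  <- setdiff(seq_len(n), train_idx)

sig <- train_signature(co$expr[[1]][, train_idx], rownames(co$base),
                       co$surv[train_idx, ], train_config(seed = 7))
sig
#> IRGP signature: 5 pairs, cutoff -1.32621
#>   gene_a gene_b       beta
#> 1  G0005  G0144 -0.8962884
#> 2  G0021  G0057 -0.7107801
#> 3  G0055  G0098  0.8686269
#> 4  G0070  G0086 -0.8117114
#> 5  G0103  G0147 -0.6154295

scores <- score_cohort(co$expr[[2]][, test_idx], sig)
report <- evaluate_cohort(scores$irgpi, co$surv[test_idx, ],
                          times = c(3, 5, 10), reps = 500, seed = 7)
report
#> Cohort evaluation (n = 180 , 119 events)
#>   cutoff: -1.354 ( median )
#>   log-rank chi2 = 68.61 , p = 1.2e-16
#>   group HR = 4.79
#>   C-index = 0.744 (resampled 0.744 +/- 0.01 )
#>   AUC: 3 y = 0.816, 5 y = 0.81, 10 y = 0.812
#>   RMS ratio = 0.295 at tau = 230.9 months
```

Reading the output: 5 of the 8 planted pairs were recovered (the signature
is trained on indicator data only, on a different platform than it is
applied to); the held-out concordance 0.744 sits below the true-predictor
ceiling (~0.76 under these conditions) and far above chance; the high-risk
group has 4.8-fold hazard and about 30% of the low-risk group's restricted
mean survival over the first 19 years of follow-up.

The same pipeline is available from the shell via the bundled wrapper:

```sh
Rscript inst/cli/irgpi.R simulate --outdir sim/ --seed 7
Rscript inst/cli/irgpi.R train --expr sim/expr_platform1_log.tsv \
    --genes sim/gene_set.tsv --surv sim/survival.tsv --out sig.json --seed 7
Rscript inst/cli/irgpi.R score --expr sim/expr_platform2_rank.tsv \
    --signature sig.json --out scores.tsv
Rscript inst/cli/irgpi.R evaluate --scores scores.tsv --surv sim/survival.tsv \
    --times 3,5,10 --reps 1000 --seed 7 --out report.json
```

Every run writes a manifest (input digests, config snapshot, seed, version)
beside its outputs.

## Further reading

See the methods vignette (`vignettes/irgpi-methods.Rmd`) for the model's
assumptions, every tunable parameter with its default and rationale, what
the simulator does and does not emulate, and known limitations.
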