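# Single-sample risk scoring. The index is a weighted sum of within-sample
# expression-order indicators, so it depends only on gene orderings inside
# each sample: samples are scored independently and the score is exactly
# invariant to any strictly increasing per-sample transform.

#' Compute the gene-pair index for one sample
#'
#' `IRGPI = sum_i beta_i * I(expr[gene_a_i] < expr[gene_b_i])` over the
#' signature pairs (ties give indicator 0).
#'
#' Missing-gene policy: `"strict"` (default) errors naming the absent genes;
#' `"drop"` skips affected pairs with a warning and never rescales the
#' remaining coefficients (rescaling would silently shift the score scale
#' that a fixed cutoff presumes).
#'
#' @param expr_sample named numeric vector, gene -> expression value.
#' @param signature an `irgp_signature`.
#' @param missing_policy `"strict"` or `"drop"`.
#' @return list with `irgpi` (numeric), `n_pairs_used`, `dropped_pairs`.
#' @export
compute_irgpi <- function(expr_sample, signature,
                          missing_policy = c("strict", "drop")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(signature, "irgp_signature"))
  pr <- signature$pairs
  xa <- expr_sample[pr$gene_a]
  xb <- expr_sample[pr$gene_b]
  bad <- is.na(xa) | is.na(xb)
  if (any(bad)) {
    absent <- setdiff(unique(c(pr$gene_a[bad], pr$gene_b[bad])),
                      names(expr_sample)[!is.na(expr_sample)])
    if (missing_policy == "strict")
      stop_stage("scorer", "missing gene(s): ", paste(absent, collapse = ", "),
                 "; use missing_policy = \"drop\" to skip affected pairs")
    warn_stage("scorer", sum(bad), " pair(s) dropped for missing genes (",
               paste(absent, collapse = ", "), "); coefficients not rescaled")
  }
  use <- !bad
  list(irgpi = sum(pr$beta[use] * pair_indicator(xa[use], xb[use])),
       n_pairs_used = sum(use), dropped_pairs = sum(bad))
}

#' Score every sample of a cohort
#'
#' Applies [compute_irgpi()] column-wise; samples are scored independently,
#' so adding or removing samples never changes another sample's score.
#'
#' @param expr expression matrix (genes x samples).
#' @param signature an `irgp_signature`.
#' @param missing_policy `"strict"` or `"drop"`, see [compute_irgpi()].
#' @return data frame with columns `sample`, `irgpi`, `n_pairs_used`.
#' @export
score_cohort <- function(expr, signature, missing_policy = c("strict", "drop")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(signature, "irgp_signature"))
  validate_expression(expr)
  pr <- signature$pairs
  absent <- setdiff(unique(c(pr$gene_a, pr$gene_b)), rownames(expr))
  if (length(absent) > 0L && missing_policy == "strict")
    stop_stage("scorer", "missing gene(s): ", paste(absent, collapse = ", "))
  present <- !(pr$gene_a %in% absent | pr$gene_b %in% absent)
  if (any(!present))
    warn_stage("scorer", sum(!present), " pair(s) dropped cohort-wide for missing genes (",
               paste(absent, collapse = ", "), "); coefficients not rescaled")
  A <- expr[pr$gene_a[present], , drop = FALSE]
  B <- expr[pr$gene_b[present], , drop = FALSE]
  I <- (A < B) * 1
  miss <- is.na(I)
  if (any(miss)) {
    if (missing_policy == "strict")
      stop_stage("scorer", "missing expression values for ",
                 sum(colSums(miss) > 0), " sample(s); use missing_policy = \"drop\"")
    warn_stage("scorer", "missing expression values: affected pairs dropped per sample")
    I[miss] <- 0
  }
  scores <- as.numeric(crossprod(I, pr$beta[present]))
  used <- sum(present) - colSums(miss)
  data.frame(sample = colnames(expr), irgpi = scores,
             n_pairs_used = as.integer(used),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stratify scores into risk groups
#'
#' `"HRisk"` iff score > cutoff; a score exactly at the cutoff goes to
#' `"LRisk"` (higher index means poorer outcome). In `"median"` mode the
#' cutoff is the sample median of the scores (the dataset-specific
#' convention); `"fixed"` mode applies a supplied cutoff such as a
#' cross-platform constant.
#'
#' @param scores numeric vector of index values.
#' @param mode `"median"` or `"fixed"`.
#' @param cutoff required when `mode = "fixed"`.
#' @return factor with levels `LRisk`, `HRisk`, plus attribute `cutoff`.
#' @export
stratify <- function(scores, mode = c("median", "fixed"), cutoff = NULL) {
  mode <- match.arg(mode)
  if (length(scores) == 0L) stop_stage("scorer", "empty score list")
  if (mode == "fixed") {
    if (is.null(cutoff) || !is.finite(cutoff))
      stop_stage("scorer", "fixed mode requires a finite cutoff")
  } else cutoff <- median(scores)
  g <- factor(ifelse(scores > cutoff, "HRisk", "LRisk"),
              levels = c("LRisk", "HRisk"))
  attr(g, "cutoff") <- cutoff
  g
}
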