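#' @keywords internal
"_PACKAGE"

#' @importFrom stats median mad pchisq qnorm rnorm runif rexp rbinom var
#'   quantile uniroot optimize
#' @importFrom utils read.delim write.table head
NULL

stop_stage <- function(stage, ..., class = "irgpi_error") {
  msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  stop(structure(
    class = c(paste0("irgpi_", stage, "_error"), class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

warn_stage <- function(stage, ...) {
  warning(paste0("[", stage, "] ", paste0(..., collapse = "")), call. = FALSE)
}

#' Validate a gene-by-sample expression matrix
#'
#' Checks the container contract used throughout the package: a numeric
#' matrix with unique gene row names and unique sample column names,
#' at least 2 genes and 1 sample. Missing values are allowed.
#'
#' @param expr numeric matrix, genes in rows, samples in columns.
#' @return `expr`, invisibly, after validation.
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop_stage("expr_io", "expression must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop_stage("expr_io", "expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr)))
    stop_stage("expr_io", "duplicate gene identifiers present; collapse_duplicates() first")
  if (anyDuplicated(colnames(expr)))
    stop_stage("expr_io", "duplicate sample identifiers")
  if (nrow(expr) < 2L || ncol(expr) < 1L)
    stop_stage("expr_io", "need at least 2 genes and 1 sample, got ",
               nrow(expr), " x ", ncol(expr))
  invisible(expr)
}

validate_survival <- function(surv, stage = "expr_io") {
  if (!is.data.frame(surv) || !all(c("sample", "time", "event") %in% names(surv)))
    stop_stage(stage, "survival table needs columns sample, time, event")
  if (anyDuplicated(surv$sample))
    stop_stage(stage, "duplicate sample ids in survival table")
  if (any(!is.finite(surv$time)) || any(surv$time <= 0))
    stop_stage(stage, "survival times must be finite and > 0")
  if (!all(surv$event %in% c(0, 1)))
    stop_stage(stage, "event must be 0 (censored) or 1 (event)")
  invisible(surv)
}

# Intersect expression samples with survival rows; reports dropped counts.
align_samples <- function(expr, surv, stage = "expr_io") {
  common <- intersect(colnames(expr), surv$sample)
  if (length(common) == 0L)
    stop_stage(stage, "no samples shared between expression and survival tables")
  n_drop_expr <- ncol(expr) - length(common)
  n_drop_surv <- nrow(surv) - length(common)
  if (n_drop_expr > 0L || n_drop_surv > 0L)
    message("[", stage, "] dropped ", n_drop_expr, " expression-only and ",
            n_drop_surv, " survival-only samples; ", length(common), " retained")
  list(expr = expr[, common, drop = FALSE],
       surv = surv[match(common, surv$sample), , drop = FALSE])
}

# Derive a substream seed (< 2^31) from a base seed and a stage label.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
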