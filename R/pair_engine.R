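# Within-sample expression-order indicators for gene pairs.
#
# The indicator I(a,b) = 1 iff expr_a < expr_b within a sample (ties 0)
# depends only on the relative ordering of two genes in one sample, so it is
# exactly invariant to any strictly increasing per-sample transform of the
# data — the property that makes gene-pair signatures portable across
# platforms without normalization.

#' Pair order indicator
#'
#' Vectorized: returns 1 where `x_a < x_b`, 0 otherwise (ties give 0),
#' `NA` where either value is missing.
#'
#' @param x_a,x_b numeric expression values of the two genes (same sample).
#' @return integer vector of 0/1/NA.
#' @export
pair_indicator <- function(x_a, x_b) {
  as.integer(x_a < x_b)
}

#' Prefilter genes by variability within a gene set
#'
#' Keeps genes present in both the matrix and the gene set whose median
#' absolute deviation (MAD, with the usual 1.4826 normal-consistency
#' constant) across samples exceeds `mad_threshold`. The threshold is a
#' training-scale-dependent knob: 0.5 is a reasonable default on log-like
#' scales, and 0 keeps every intersecting gene.
#'
#' @param expr expression matrix (genes x samples).
#' @param gene_set character vector of gene identifiers, or a data frame with
#'   a `gene` column as returned by [read_gene_set()].
#' @param mad_threshold non-negative MAD cutoff (default 0.5).
#' @return character vector of surviving gene identifiers.
#' @export
prefilter_genes <- function(expr, gene_set, mad_threshold = 0.5) {
  validate_expression(expr)
  if (is.data.frame(gene_set)) gene_set <- gene_set$gene
  if (mad_threshold < 0) stop_stage("pair_engine", "mad_threshold must be >= 0")
  cand <- intersect(rownames(expr), trimws(gene_set))
  if (length(cand) == 0L)
    stop_stage("pair_engine",
               "no gene-set members found in the expression matrix; ",
               "check identifier systems (exact string match is used)")
  mads <- apply(expr[cand, , drop = FALSE], 1L, mad, na.rm = TRUE)
  # threshold 0 disables the filter (all intersecting genes kept)
  keep <- if (mad_threshold == 0) cand else cand[mads > mad_threshold]
  if (length(keep) == 0L)
    stop_stage("pair_engine",
               "no genes pass mad_threshold = ", mad_threshold,
               " (max observed MAD ", format(max(mads), digits = 3),
               "); lower the threshold or check the expression scale")
  keep
}

#' Enumerate candidate gene pairs
#'
#' All unordered combinations of `genes`, one canonical orientation each:
#' `gene_a` precedes `gene_b` in lexicographic order. Direction is meaningful
#' (the indicator is `I(expr_a < expr_b)`); a canonical orientation makes
#' pair identity unambiguous while the coefficient sign carries direction.
#'
#' @param genes character vector (>= 2 unique entries).
#' @return data frame with columns `gene_a`, `gene_b`.
#' @export
make_pairs <- function(genes) {
  genes <- sort(unique(trimws(genes)))
  if (length(genes) < 2L) stop_stage("pair_engine", "need at least 2 genes to form pairs")
  idx <- utils::combn(length(genes), 2L)
  data.frame(gene_a = genes[idx[1L, ]], gene_b = genes[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Build the pair indicator matrix
#'
#' `indicators[i, s] = 1` iff `expr[gene_a_i, s] < expr[gene_b_i, s]`
#' (ties 0, missing members give NA). Output is bit-identical under any
#' strictly increasing per-sample transform of `expr`.
#'
#' @param expr expression matrix (genes x samples).
#' @param pairs data frame with columns `gene_a`, `gene_b` (duplicates not
#'   allowed).
#' @return object of class `pair_indicators`: list with `pairs` (data frame)
#'   and `indicators` (integer pairs x samples matrix, rownames
#'   `"gene_a<gene_b"`).
#' @export
build_indicator_matrix <- function(expr, pairs) {
  validate_expression(expr)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(expr))
  if (length(missing) > 0L)
    stop_stage("pair_engine", "gene(s) absent from expression matrix: ",
               paste(missing, collapse = ", "))
  key <- paste(pairs$gene_a, pairs$gene_b, sep = "\t")
  if (anyDuplicated(key)) stop_stage("pair_engine", "duplicate pairs requested")
  ind <- (expr[pairs$gene_a, , drop = FALSE] <
          expr[pairs$gene_b, , drop = FALSE]) * 1L
  storage.mode(ind) <- "integer"
  rownames(ind) <- paste0(pairs$gene_a, "<", pairs$gene_b)
  structure(list(pairs = pairs[, c("gene_a", "gene_b")], indicators = ind),
            class = "pair_indicators")
}

#' Filter pairs to the informative frequency band
#'
#' Keeps pairs whose indicator mean across samples lies in
#' `[f_min, 1 - f_min]`. Pairs with near-constant order (mean near 0 or 1)
#' carry no discriminative information; 0.2 is the band conventional in the
#' gene-pair signature literature.
#'
#' @param ind a `pair_indicators` object with no missing entries.
#' @param f_min lower band edge, in (0, 0.5).
#' @return data frame of surviving pairs (`gene_a`, `gene_b`).
#' @export
filter_informative_pairs <- function(ind, f_min = 0.2) {
  stopifnot(inherits(ind, "pair_indicators"))
  if (!is.numeric(f_min) || f_min <= 0 || f_min >= 0.5)
    stop_stage("pair_engine", "f_min must lie in (0, 0.5), got ", f_min)
  if (anyNA(ind$indicators))
    stop_stage("pair_engine", "missing indicators present; resolve missing expression first")
  freq <- rowMeans(ind$indicators)
  keep <- freq >= f_min & freq <= 1 - f_min
  ind$pairs[keep, , drop = FALSE]
}

# Subset a pair_indicators object by pair index.
subset_pairs <- function(ind, i) {
  structure(list(pairs = ind$pairs[i, , drop = FALSE],
                 indicators = ind$indicators[i, , drop = FALSE]),
            class = "pair_indicators")
}

#' @export
print.pair_indicators <- function(x, ...) {
  cat("Pair indicator matrix:", nrow(x$indicators), "pairs x",
      ncol(x$indicators), "samples\n")
  invisible(x)
}
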