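# Reading/writing expression matrices, gene sets, survival tables and
# signature files. Gene identifiers are matched by exact string after
# whitespace trimming; no alias mapping is built in (an optional
# user-supplied two-column alias table can be applied at read time).

#' Read a gene-by-sample expression matrix
#'
#' Supported formats: TSV/CSV with gene identifiers in the first column and
#' sample identifiers in the header, and GCT v1.2 (two header lines are
#' skipped and the `Description` column dropped). Duplicate gene rows are
#' collapsed with [collapse_duplicates()] (a warning reports how many).
#'
#' Values are used downstream only through within-sample orderings, so any
#' within-sample monotone-comparable scale (FPKM, TPM, log-intensity, rank)
#' is acceptable; units must not be mixed within a column.
#'
#' @param path path to the file.
#' @param format one of `"tsv"`, `"csv"`, `"gct"`. Default guesses from the
#'   file extension, falling back to TSV.
#' @param collapse method passed to [collapse_duplicates()].
#' @param alias optional data frame with columns `from`, `to` applied to gene
#'   identifiers before duplicate collapsing.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv", "gct"),
                            collapse = "mean", alias = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_stage("expr_io", "file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "gct")) ext else "tsv"
  }
  df <- tryCatch(switch(format,
    tsv = read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE),
    csv = read.delim(path, header = TRUE, sep = ",", check.names = FALSE,
                     stringsAsFactors = FALSE),
    gct = {
      d <- read.delim(path, header = TRUE, sep = "\t", skip = 2,
                      check.names = FALSE, stringsAsFactors = FALSE)
      desc <- which(tolower(names(d)) == "description")
      if (length(desc)) d <- d[, -desc, drop = FALSE]
      d
    }),
    error = function(e) stop_stage("expr_io", "unparseable ", format,
                                   " file ", path, ": ", conditionMessage(e)))
  if (ncol(df) < 2L)
    stop_stage("expr_io", "no sample columns in ", path)
  genes <- trimws(as.character(df[[1L]]))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    suppressWarnings(storage.mode(vals) <- "double")
    if (all(is.na(vals))) stop_stage("expr_io", "non-numeric expression values in ", path)
  }
  rownames(vals) <- genes
  colnames(vals) <- trimws(colnames(df)[-1L])
  if (!is.null(alias)) {
    hit <- match(rownames(vals), trimws(alias$from))
    rownames(vals)[!is.na(hit)] <- trimws(alias$to)[hit[!is.na(hit)]]
  }
  ndup <- sum(duplicated(rownames(vals)))
  if (ndup > 0L) {
    warn_stage("expr_io", ndup, " duplicate gene row(s) collapsed by ", collapse)
    vals <- collapse_duplicates(vals, method = collapse)
  }
  validate_expression(vals)
  message("[expr_io] read ", nrow(vals), " genes x ", ncol(vals),
          " samples from ", basename(path))
  vals
}

#' Collapse duplicate gene rows
#'
#' @param expr numeric matrix with gene rownames (duplicates allowed).
#' @param method `"mean"` (default: element-wise mean, scale-preserving),
#'   `"max"` (element-wise maximum), or `"maxvar"` (keep the single duplicate
#'   row with the largest variance across samples).
#' @return matrix with one row per gene identifier, in first-appearance order.
#' @export
collapse_duplicates <- function(expr, method = c("mean", "max", "maxvar")) {
  method <- match.arg(method)
  ids <- rownames(expr)
  if (!anyDuplicated(ids)) return(expr)
  keep_order <- unique(ids)
  rows <- lapply(keep_order, function(g) {
    block <- expr[ids == g, , drop = FALSE]
    if (nrow(block) == 1L) return(block[1L, ])
    switch(method,
      mean = colMeans(block),
      max = apply(block, 2L, max),
      maxvar = block[which.max(apply(block, 1L, var)), ])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- keep_order
  colnames(out) <- colnames(expr)
  out
}

#' Read an immune-related gene set
#'
#' Two-column TSV: gene identifier and category label. Entries are trimmed
#' and de-duplicated.
#'
#' @param path TSV path.
#' @return data frame with columns `gene`, `category`.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop_stage("expr_io", "file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 1L || nrow(df) == 0L)
    stop_stage("expr_io", "empty gene set file: ", path)
  genes <- trimws(as.character(df[[1L]]))
  cat <- if (ncol(df) >= 2L) trimws(as.character(df[[2L]])) else rep("immune", length(genes))
  keep <- !duplicated(genes)
  data.frame(gene = genes[keep], category = cat[keep], stringsAsFactors = FALSE)
}

#' Read a survival table
#'
#' TSV with columns `sample`, `time`, `event`, then optional clinical
#' covariates. Times must be positive; the package convention is months.
#'
#' @param path TSV path.
#' @param time_unit `"months"` (default) or `"years"`; years are converted to
#'   months so that the 3/5/10-year evaluation horizons are consistent.
#' @return data frame with columns `sample`, `time`, `event`, covariates.
#' @export
read_survival <- function(path, time_unit = c("months", "years")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop_stage("expr_io", "file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("sample", "time", "event")
  df$sample <- trimws(as.character(df$sample))
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  if (time_unit == "years") df$time <- df$time * 12
  validate_survival(df)
  df
}

#' Write a gene-pair signature to JSON
#'
#' The portable artifact of training: ordered pairs with Cox coefficients,
#' the risk cutoff, and training provenance. The indicator convention
#' (`I = 1` iff `expr[gene_a] < expr[gene_b]`, ties 0) is recorded in the
#' file so scoring is unambiguous.
#'
#' @param signature an `irgp_signature` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "irgp_signature"))
  doc <- list(
    version = "1.0",
    indicator = "1 iff expr[gene_a] < expr[gene_b]; ties 0",
    pairs = data.frame(gene_a = signature$pairs$gene_a,
                       gene_b = signature$pairs$gene_b,
                       beta = signature$pairs$beta,
                       stringsAsFactors = FALSE),
    cutoff = signature$cutoff,
    trained_on = signature$metadata
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a gene-pair signature from JSON
#'
#' @param path JSON path written by [write_signature()] (or hand-authored with
#'   keys `pairs` (list of `gene_a`, `gene_b`, `beta`), `cutoff`).
#' @return an `irgp_signature` object.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop_stage("expr_io", "file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop_stage("expr_io", "unparseable signature JSON ",
                                                 path, ": ", conditionMessage(e)))
  for (k in c("pairs", "cutoff"))
    if (is.null(doc[[k]])) stop_stage("expr_io", "signature file missing field '", k, "'")
  pairs <- as.data.frame(doc$pairs, stringsAsFactors = FALSE)
  for (k in c("gene_a", "gene_b", "beta"))
    if (is.null(pairs[[k]])) stop_stage("expr_io", "signature pairs missing field '", k, "'")
  md <- doc$trained_on
  if (is.null(md)) md <- list()
  irgp_signature(pairs$gene_a, pairs$gene_b, as.numeric(pairs$beta),
                 cutoff = as.numeric(doc$cutoff), metadata = md,
                 drop_zero = FALSE)
}

#' Construct a gene-pair signature object
#'
#' @param gene_a,gene_b character vectors naming each pair's members; the
#'   indicator is 1 iff `expr[gene_a] < expr[gene_b]` within a sample.
#' @param beta numeric Cox coefficients, one per pair.
#' @param cutoff finite risk cutoff (scores above it are high risk).
#' @param metadata list of training provenance (n, seed, config hash).
#' @param drop_zero drop pairs with zero coefficient (default TRUE for trained
#'   signatures; reading a file keeps them with a warning).
#' @return object of class `irgp_signature`.
#' @export
irgp_signature <- function(gene_a, gene_b, beta, cutoff,
                           metadata = list(), drop_zero = TRUE) {
  gene_a <- trimws(as.character(gene_a)); gene_b <- trimws(as.character(gene_b))
  if (length(gene_a) != length(gene_b) || length(gene_a) != length(beta))
    stop_stage("expr_io", "pairs and betas must have equal length")
  if (length(gene_a) < 1L) stop_stage("expr_io", "signature must contain at least one pair")
  if (any(gene_a == gene_b)) stop_stage("expr_io", "a pair cannot compare a gene with itself")
  key <- paste(gene_a, gene_b, sep = "\t")
  if (anyDuplicated(key)) stop_stage("expr_io", "duplicate pair in signature")
  if (!is.finite(cutoff)) stop_stage("expr_io", "cutoff must be finite")
  if (any(beta == 0)) {
    if (drop_zero) {
      keep <- beta != 0
      if (!any(keep)) stop_stage("expr_io", "all coefficients zero; empty signature")
      gene_a <- gene_a[keep]; gene_b <- gene_b[keep]; beta <- beta[keep]
    } else {
      warn_stage("expr_io", sum(beta == 0), " pair(s) with zero coefficient (degenerate)")
    }
  }
  structure(list(
    pairs = data.frame(gene_a = gene_a, gene_b = gene_b, beta = as.numeric(beta),
                       stringsAsFactors = FALSE),
    cutoff = as.numeric(cutoff),
    metadata = metadata
  ), class = "irgp_signature")
}

#' @export
print.irgp_signature <- function(x, ...) {
  cat("IRGP signature:", nrow(x$pairs), "pairs, cutoff", format(x$cutoff), "\n")
  print(head(x$pairs, 10L))
  if (nrow(x$pairs) > 10L) cat("... and", nrow(x$pairs) - 10L, "more\n")
  invisible(x)
}

#' @export
length.irgp_signature <- function(x) nrow(x$pairs)
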