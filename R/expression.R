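# Expression matrices, normalization, TPM, and per-gene activity (CNR/BTIF)
# against a control panel.

#' Construct an expression matrix
#'
#' A thin container around a numeric genes x samples matrix carrying a
#' processing-stage tag. The stage gates downstream operations so that, for
#' example, already-normalized data cannot be normalized a second time.
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   are gene identifiers and colnames are sample identifiers. Values must be
#'   non-negative and finite.
#' @param stage processing stage, one of `"raw"`, `"normalized"`, `"tpm"`.
#' @return an object of class `expr_matrix` (a matrix with a `stage`
#'   attribute).
#' @export
expr_matrix <- function(values, stage = c("raw", "normalized", "tpm")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative")
  structure(values, stage = stage, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, stage = %s\n",
              nrow(x), ncol(x), expr_stage(x)))
  invisible(x)
}

#' Stage tag of an expression matrix
#' @param x an `expr_matrix`.
#' @return the stage string.
#' @export
expr_stage <- function(x) attr(x, "stage")

as_plain_matrix <- function(x) {
  attr(x, "stage") <- NULL
  class(x) <- c("matrix", "array")
  x
}

#' Median-of-ratios normalization with a pseudo-count
#'
#' Size factors are computed by the median-of-ratios estimator: for each gene
#' with a positive count in every sample, form the ratio of each sample's
#' count to the gene's geometric mean across samples; the size factor of a
#' sample is the median of its ratios. Counts are divided by the size factor
#' and a pseudo-count is then added, in that order.
#'
#' @param counts an `expr_matrix` at stage `"raw"`.
#' @param pseudocount value added after size-factor division (default 1).
#' @return list with `matrix` (stage `"normalized"`) and `size_factors`
#'   (named numeric, one per sample).
#' @export
normalize_median_of_ratios <- function(counts, pseudocount = 1) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (expr_stage(counts) != "raw")
    stop("normalization requires stage 'raw' (already-processed input refused)")
  m <- as_plain_matrix(counts)
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos))
    stop("no gene has positive counts in every sample; cannot estimate size factors")
  logm <- log(m[all_pos, , drop = FALSE])
  log_geomean <- rowMeans(logm)
  log_ratios <- logm - log_geomean
  sf <- apply(log_ratios, 2, stats::median)
  sf <- exp(sf)
  names(sf) <- colnames(m)
  norm <- sweep(m, 2, sf, "/") + pseudocount
  list(matrix = expr_matrix(norm, stage = "normalized"), size_factors = sf)
}

#' Transcripts per million
#'
#' @param counts an `expr_matrix` at stage `"raw"`.
#' @param gene_lengths named numeric vector of gene lengths in base pairs;
#'   every gene of `counts` must be present and positive.
#' @return an `expr_matrix` at stage `"tpm"`; each non-degenerate column sums
#'   to 1e6. An all-zero column is returned as zeros with a warning.
#' @export
compute_tpm <- function(counts, gene_lengths) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (expr_stage(counts) != "raw")
    stop("TPM requires stage 'raw'")
  m <- as_plain_matrix(counts)
  missing <- setdiff(rownames(m), names(gene_lengths))
  if (length(missing))
    stop("missing gene length for: ", paste(utils::head(missing, 5), collapse = ", "))
  len <- gene_lengths[rownames(m)]
  if (any(!is.finite(len)) || any(len <= 0))
    stop("gene lengths must be positive")
  rate <- m / len
  denom <- colSums(rate)
  zero_col <- denom == 0
  if (any(zero_col)) {
    warning("all-zero column(s): ", paste(colnames(m)[zero_col], collapse = ", "),
            "; TPM set to 0")
    denom[zero_col] <- 1
  }
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  expr_matrix(tpm, stage = "tpm")
}

#' Case-to-normal ratio (CNR)
#'
#' Ratio of a tumor sample's expression to the geometric mean of a control
#' panel, per gene. Inputs are expected to carry the pseudo-count already
#' (all values strictly positive).
#'
#' @param sample named numeric vector of one sample's normalized expression.
#' @param controls `expr_matrix` (stage `"normalized"`) of the control panel,
#'   at least 2 samples, same genes as `sample`.
#' @return named numeric vector of CNR values (positive).
#' @export
compute_cnr <- function(sample, controls) {
  check_activity_inputs(sample, controls)
  ctr <- as_plain_matrix(controls)[names(sample), , drop = FALSE]
  geo <- exp(rowMeans(log(ctr)))
  sample / geo
}

#' Beyond-tolerance-interval flag (BTIF)
#'
#' Flags genes whose log-expression in the sample falls outside the two-sided
#' (1 - alpha) tolerance band of the control panel's log-expression. The
#' default strategy is a per-gene z-score of the sample's log value against
#' the control mean and standard deviation; a rank-based strategy can be
#' substituted via `method`.
#'
#' @param sample,controls as in [compute_cnr()].
#' @param alpha two-sided significance level (default 0.05).
#' @param method `"z"` (default) or `"rank"`. The rank variant flags samples
#'   falling outside the empirical (alpha/2, 1-alpha/2) quantile band of the
#'   controls.
#' @return integer vector of 0/1 flags, one per gene.
#' @export
compute_btif <- function(sample, controls, alpha = 0.05, method = c("z", "rank")) {
  method <- match.arg(method)
  check_activity_inputs(sample, controls)
  ctr <- log(as_plain_matrix(controls)[names(sample), , drop = FALSE])
  s <- log(sample)
  if (method == "z") {
    mu <- rowMeans(ctr)
    sdev <- apply(ctr, 1, stats::sd)
    z <- (s - mu) / sdev
    z[sdev == 0] <- ifelse(s[sdev == 0] == mu[sdev == 0], 0, Inf)
    flag <- abs(z) > stats::qnorm(1 - alpha / 2)
  } else {
    lo <- apply(ctr, 1, stats::quantile, probs = alpha / 2)
    hi <- apply(ctr, 1, stats::quantile, probs = 1 - alpha / 2)
    flag <- s < lo | s > hi
  }
  stats::setNames(as.integer(flag), names(sample))
}

#' Per-gene activity of one sample versus the control panel
#'
#' Convenience wrapper combining [compute_cnr()] and [compute_btif()].
#'
#' @inheritParams compute_btif
#' @return data.frame with columns `gene`, `cnr`, `btif`.
#' @export
gene_activity <- function(sample, controls, alpha = 0.05, method = c("z", "rank")) {
  data.frame(gene = names(sample),
             cnr = unname(compute_cnr(sample, controls)),
             btif = unname(compute_btif(sample, controls, alpha, method)),
             stringsAsFactors = FALSE)
}

check_activity_inputs <- function(sample, controls) {
  stopifnot(inherits(controls, "expr_matrix"))
  if (is.null(names(sample))) stop("`sample` must be a named vector")
  if (ncol(controls) < 2) stop("control panel must have at least 2 samples")
  if (!all(names(sample) %in% rownames(controls)))
    stop("sample and controls must share gene identifiers")
  if (any(sample <= 0) || any(as_plain_matrix(controls) <= 0))
    stop("values must be strictly positive (apply the pseudo-count first)")
  invisible(TRUE)
}

#' Read / write an expression matrix as TSV
#'
#' Format: first column `gene_id`, remaining columns one per sample with the
#' sample identifier as header.
#'
#' @param path file path.
#' @param stage stage tag to attach on read.
#' @return `read_expr_tsv` returns an `expr_matrix`; `write_expr_tsv` returns
#'   `path` invisibly.
#' @export
read_expr_tsv <- function(path, stage = "raw") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  expr_matrix(m, stage = stage)
}

#' @rdname read_expr_tsv
#' @param x an `expr_matrix`.
#' @export
write_expr_tsv <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  dt <- data.table::data.table(gene_id = rownames(x), as_plain_matrix(x))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
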