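# RMA-style preprocessing -----------------------------------------------------
#
# The classic robust multi-array average, minus the convolution background
# model: intensity floor -> quantile normalization (linear scale) -> log2 ->
# per-gene median-polish summarization. A configurable floor stands in for
# background correction; the parameters of the full RMA background
# deconvolution are not part of this pipeline's contract.

#' Quantile-normalize a matrix of intensities
#'
#' Forces every column onto the common distribution given by the
#' across-column mean of order statistics, preserving within-column ranks.
#' Ties within a column receive the mean of the reference values their
#' positions span (average-rank dialect).
#'
#' @param x Numeric matrix with no missing values and at least one column.
#' @return Matrix of the same shape; all columns share the same sorted
#'   values.
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (nrow(x) == 0 || ncol(x) == 0)
    stop("matrix must have positive dimensions")
  if (any(!is.finite(x))) stop("matrix must not contain missing values")
  if (ncol(x) == 1) return(x)
  n <- nrow(x)
  ord_stats <- apply(x, 2, sort)
  ref <- rowMeans(ord_stats)
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    # integer ranks index ref directly; fractional (tied) ranks average the
    # two straddling reference values
    lo <- floor(r); hi <- ceiling(r)
    out[, j] <- (ref[lo] + ref[hi]) / 2
  }
  out
}

#' Summarize probes into gene-level expression by median polish
#'
#' Fits the additive model `log2 intensity ~ overall + sample + probe` per
#' gene by Tukey median polish (alternating row/column median sweeps) and
#' returns the gene-by-sample estimate `overall + sample effect` — the RMA
#' summarization step.
#'
#' @param log2mat Numeric matrix of **log2-scale** probe values, probes x
#'   samples (use [rma_lite()] for the full pipeline from linear
#'   intensities).
#' @param gene_id Character vector, one gene id per probe row.
#' @param tol Convergence tolerance on the relative change in total
#'   absolute residual.
#' @param max_iter Maximum number of polish iterations.
#' @return Numeric matrix, genes x samples, log2 scale.
#' @export
median_polish_summarize <- function(log2mat, gene_id, tol = 1e-6,
                                    max_iter = 10L) {
  stopifnot(is.matrix(log2mat), length(gene_id) == nrow(log2mat))
  gene_id <- as.character(gene_id)
  genes <- unique(gene_id)
  idx <- split(seq_along(gene_id), gene_id)
  if (any(lengths(idx) == 0)) stop("gene with zero probes")
  out <- matrix(NA_real_, length(genes), ncol(log2mat),
                dimnames = list(genes, colnames(log2mat)))
  for (g in genes) {
    block <- log2mat[idx[[g]], , drop = FALSE]
    if (nrow(block) == 1L) {
      out[g, ] <- block[1, ]
    } else {
      # hitting max_iter is a stopping rule, not a failure; silence the
      # non-convergence warning medpolish emits in that case
      fit <- suppressWarnings(
        stats::medpolish(block, eps = tol, maxiter = max_iter,
                         trace.iter = FALSE, na.rm = FALSE))
      out[g, ] <- fit$overall + fit$col
    }
  }
  out
}

#' RMA-style preprocessing from linear probe intensities
#'
#' Pipeline: floor intensities at `floor` -> quantile-normalize across
#' samples on the linear scale -> log2 -> median-polish probe-set
#' summarization. Each step is recorded in the returned run log.
#'
#' @param probes A [probe_matrix()] with linear-scale intensities.
#' @param floor Intensity floor applied before normalization (stands in for
#'   background correction).
#' @param tol,max_iter Passed to [median_polish_summarize()].
#' @return List with `expr` (gene x sample log2 matrix) and `log`
#'   (character vector describing the steps applied).
#' @examples
#' pm <- probe_matrix(matrix(1024, 1, 1, dimnames = list("g1_p1", "S1")),
#'                    gene_id = "g1")
#' rma_lite(pm)$expr   # log2(1024) = 10
#' @export
rma_lite <- function(probes, floor = 1.0, tol = 1e-6, max_iter = 10L) {
  stopifnot(inherits(probes, "probe_matrix"))
  x <- pmax(probes$intensity, floor)
  x <- quantile_normalize(x)
  expr <- median_polish_summarize(log2(x), probes$gene_id,
                                  tol = tol, max_iter = max_iter)
  list(expr = expr,
       log = c(sprintf("floor intensities at %g", floor),
               "quantile normalization (linear scale, average ties)",
               "log2 transform",
               sprintf("median polish summarization (tol %g, max %d iter)",
                       tol, max_iter)))
}
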