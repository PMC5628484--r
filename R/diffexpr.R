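# Differential expression screening ------------------------------------------

#' Per-gene two-sample t-test on log2 expression
#'
#' Two-sided two-sample t-test of KD versus NC for every gene row,
#' vectorized. The pooled-variance (Student) test is the default: with two
#' or three arrays per group its null p-values are exactly uniform under
#' the additive normal model, whereas Welch's approximate degrees of
#' freedom are visibly miscalibrated at such sample sizes. Welch remains
#' available via `var_equal = FALSE`.
#'
#' Degenerate rows (zero variance in both groups) get p = 1 when the group
#' means are equal and p = 0 otherwise.
#'
#' @param expr Numeric matrix, genes x samples, log2 scale.
#' @param groups Factor with levels `NC`, `KD`, one per sample column; each
#'   group needs at least two samples.
#' @param var_equal Pooled-variance Student test (`TRUE`, default) or
#'   Welch (`FALSE`).
#' @return Named numeric vector of two-sided p-values.
#' @export
gene_test <- function(expr, groups, var_equal = TRUE) {
  stopifnot(is.matrix(expr))
  groups <- .check_groups(groups, ncol(expr))
  x <- expr[, groups == "NC", drop = FALSE]
  y <- expr[, groups == "KD", drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- .row_vars(x); v2 <- .row_vars(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(expr))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- 2 * stats::pt(-abs((m2 - m1) / se), df)
  degen <- se == 0 | !is.finite(df)
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  stats::setNames(p, rownames(expr))
}

.row_vars <- function(x) {
  rowSums((x - rowMeans(x))^2) / (ncol(x) - 1)
}

.check_groups <- function(groups, n) {
  groups <- factor(as.character(groups), levels = c("NC", "KD"))
  if (any(is.na(groups))) stop("group labels must be NC or KD")
  if (length(groups) != n) stop("one group label per sample column required")
  groups
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `adj_p(i) = min over j >= i of p(j) * n / j`,
#' capped at 1 and returned in the input order. Inputs outside \[0, 1\] are
#' an error.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Screen differentially expressed genes
#'
#' Runs the full DEG screen on a gene-level log2 expression matrix: group
#' means, log2 fold change (KD minus NC), linear fold change, per-gene
#' t-test, BH adjustment and the fold-change/FDR call.
#'
#' @param expr Numeric matrix, genes x samples, log2 scale, gene row names.
#' @param groups Factor with levels `NC`, `KD`.
#' @param fc_threshold Linear fold-change cut; a gene must exceed it
#'   (`FC > fc_threshold` or `FC < 1/fc_threshold`, both strict).
#' @param alpha FDR cut on the adjusted p (strict).
#' @param var_equal Passed to [gene_test()].
#' @return A `deg_table`: data frame with columns `gene_id`, `mean_nc`,
#'   `mean_kd`, `log2fc`, `fc`, `p`, `adj_p`, `direction`
#'   (`up`/`down`/`none`).
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 300, seed = 3))
#' expr <- rma_lite(sim$probes)$expr
#' deg <- deg_screen(expr, sim$groups)
#' summary(deg)
#' @export
deg_screen <- function(expr, groups, fc_threshold = 2, alpha = 0.05,
                       var_equal = TRUE) {
  groups <- .check_groups(groups, ncol(expr))
  m_nc <- rowMeans(expr[, groups == "NC", drop = FALSE])
  m_kd <- rowMeans(expr[, groups == "KD", drop = FALSE])
  l2fc <- m_kd - m_nc
  p <- gene_test(expr, groups, var_equal = var_equal)
  tab <- data.frame(
    gene_id = rownames(expr),
    mean_nc = m_nc, mean_kd = m_kd,
    log2fc = l2fc, fc = 2^l2fc,
    p = p, adj_p = bh_adjust(p),
    stringsAsFactors = FALSE, row.names = NULL
  )
  call_degs(tab, fc_threshold = fc_threshold, alpha = alpha)
}

#' Apply the fold-change / FDR screening rule
#'
#' A gene is called differentially expressed iff its linear fold change
#' exceeds the threshold in either direction (`fc > fc_threshold` or
#' `fc < 1/fc_threshold`, strict) **and** its adjusted p is below `alpha`
#' (strict). Direction follows the sign of the log2 fold change.
#'
#' @param records Data frame with at least `fc` and `adj_p` columns
#'   (`log2fc` is derived from `fc` when absent).
#' @param fc_threshold,alpha Screening cuts (strict inequalities).
#' @return The input as a `deg_table` with a `direction` column added.
#' @export
call_degs <- function(records, fc_threshold = 2, alpha = 0.05) {
  stopifnot(is.data.frame(records))
  if (is.null(records$adj_p)) stop("records must carry an adj_p column")
  if (is.null(records$fc)) stop("records must carry an fc column")
  if (any(records$fc <= 0)) stop("fold changes must be > 0")
  l2fc <- if (!is.null(records$log2fc)) records$log2fc else log2(records$fc)
  called <- (records$fc > fc_threshold | records$fc < 1 / fc_threshold) &
    records$adj_p < alpha
  records$direction <- ifelse(!called, "none",
                              ifelse(l2fc > 0, "up", "down"))
  attr(records, "fc_threshold") <- fc_threshold
  attr(records, "alpha") <- alpha
  class(records) <- c("deg_table", "data.frame")
  records
}

#' Summarize a DEG table
#'
#' @param table A `deg_table` from [deg_screen()] / [call_degs()].
#' @return List with counts `n_total`, `n_up`, `n_down` (class
#'   `deg_summary`); `n_total = n_up + n_down` by construction.
#' @export
deg_summary <- function(table) {
  stopifnot(is.data.frame(table), !is.null(table$direction))
  n_up <- sum(table$direction == "up")
  n_down <- sum(table$direction == "down")
  structure(list(n_total = n_up + n_down, n_up = n_up, n_down = n_down),
            class = "deg_summary")
}

#' @export
print.deg_summary <- function(x, ...) {
  cat(sprintf("%d differentially expressed genes (%d up, %d down)\n",
              x$n_total, x$n_up, x$n_down))
  invisible(x)
}

#' @export
summary.deg_table <- function(object, ...) deg_summary(object)

#' @export
print.deg_table <- function(x, n = 6L, ...) {
  s <- deg_summary(x)
  cat(sprintf("DEG table: %d genes screened; %d called (%d up / %d down)",
              nrow(x), s$n_total, s$n_up, s$n_down))
  ft <- attr(x, "fc_threshold"); al <- attr(x, "alpha")
  if (!is.null(ft)) cat(sprintf(" at |FC| > %g, FDR < %g", ft, al))
  cat("\n")
  print.data.frame(utils::head(x[order(x$adj_p), ], n), digits = 4,
                   row.names = FALSE)
  invisible(x)
}

#' Write / read a DEG table TSV
#'
#' @param table A `deg_table`.
#' @param path File path.
#' @return `write_deg_table()` returns `path` invisibly; `read_deg_table()`
#'   returns a `deg_table`.
#' @export
write_deg_table <- function(table, path) {
  df <- as.data.frame(table)
  for (col in c("p", "adj_p"))
    df[[col]] <- format(df[[col]], digits = 4, scientific = TRUE)
  for (col in c("mean_nc", "mean_kd", "log2fc", "fc"))
    if (!is.null(df[[col]])) df[[col]] <- format(df[[col]], digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("deg_table", "data.frame")
  df
}
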