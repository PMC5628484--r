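# Directional gene-set enrichment --------------------------------------------
#
# Over-representation analysis of DEG lists against GO-style terms or
# pathway gene sets: two-sided Fisher's exact test (chi-square companion
# statistic), BH FDR across the term family, -log10(p) for histogram
# figures, and up / down / up_down style assignment from separate
# direction-specific runs.

#' Two-sided Fisher's exact test for a 2x2 enrichment table
#'
#' Contingency layout: `k` DEGs inside a term of background size `K`, from a
#' DEG list of size `n` against a background universe of size `N`. The
#' two-sided p sums the hypergeometric probabilities of every table sharing
#' the margins whose point probability does not exceed that of the observed
#' table, with a relative tolerance of 1e-7 for ties — the standard
#' point-probability ("minimum-likelihood") dialect.
#'
#' @param k DEGs in the term.
#' @param K Term size in the background.
#' @param n DEG list size.
#' @param N Background size.
#' @return Two-sided p-value.
#' @examples
#' fisher_two_sided(5, 10, 50, 1000)
#' @export
fisher_two_sided <- function(k, K, n, N) {
  .check_table(k, K, n, N)
  support <- max(0L, K + n - N):min(K, n)
  probs <- stats::dhyper(support, K, N - K, n)
  p_obs <- stats::dhyper(k, K, N - K, n)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

.check_table <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(vals < 0) || any(vals != round(vals)))
    stop("contingency counts must be non-negative integers")
  if (k > K || k > n || K > N || n > N || K + n - k > N)
    stop("inconsistent contingency margins")
  invisible(TRUE)
}

#' Pearson chi-square test for a 2x2 enrichment table
#'
#' Companion statistic to [fisher_two_sided()]: Pearson chi-square on the
#' same 2x2 table, 1 degree of freedom, no continuity correction. Reported
#' alongside the Fisher p; the Fisher p drives significance calls.
#'
#' @inheritParams fisher_two_sided
#' @return List with `statistic` and `p`.
#' @export
chi2_test <- function(k, K, n, N) {
  .check_table(k, K, n, N)
  tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2, 2)
  expected <- outer(rowSums(tab), colSums(tab)) / N
  if (any(expected == 0)) stop("degenerate table: an expected cell is zero")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' Enrichment of a DEG list against a gene-set collection
#'
#' For every term, counts `k` (DEGs in the term), `K` (term members in the
#' background), `n` (DEG list size) and `N` (background size), computes the
#' two-sided Fisher p (and the chi-square companion where the table is not
#' degenerate), adjusts across the term family by BH, and flags
#' significance at `adj_p < fdr`. `-LgP` is `-log10` of the **raw** p, the
#' histogram-axis metric. Terms with no members in the background are
#' dropped with a warning.
#'
#' @param deg_set Character vector of DEG gene ids (must be a subset of
#'   `background`).
#' @param db List of term records (`id`, `name`, `category`, `genes`), e.g.
#'   from [read_gmt()] or [simulate_annotation()].
#' @param background Character vector: the gene universe (typically all
#'   genes on the array after summarization).
#' @param fdr Significance cut on the adjusted p (strict).
#' @return An `enrich_table` data frame: `term_id`, `name`, `category`,
#'   `k`, `K`, `n`, `N`, `p`, `chi2_p`, `adj_p`, `neg_lg_p`, `significant`.
#' @export
enrich_direction <- function(deg_set, db, background, fdr = 0.05) {
  background <- unique(as.character(background))
  if (length(background) == 0) stop("empty background universe")
  deg_set <- unique(as.character(deg_set))
  if (!all(deg_set %in% background))
    stop("deg_set must be a subset of the background")
  N <- length(background)
  n <- length(deg_set)

  rows <- lapply(db, function(term) {
    members <- intersect(term$genes, background)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, deg_set))
    chi <- tryCatch(chi2_test(k, K, n, N)$p, error = function(e) NA_real_)
    data.frame(term_id = term$id, name = term$name,
               category = term$category, k = k, K = K, n = n, N = N,
               p = fisher_two_sided(k, K, n, N), chi2_p = chi,
               stringsAsFactors = FALSE)
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (any(dropped))
    warning(sum(dropped), " term(s) with no background members dropped")
  rows <- rows[!dropped]
  if (length(rows) == 0)
    return(structure(data.frame(term_id = character(), name = character(),
                                category = character(), k = integer(),
                                K = integer(), n = integer(), N = integer(),
                                p = numeric(), chi2_p = numeric(),
                                adj_p = numeric(), neg_lg_p = numeric(),
                                significant = logical(),
                                stringsAsFactors = FALSE),
                     class = c("enrich_table", "data.frame")))
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out$neg_lg_p <- -log10(out$p)
  out$significant <- out$adj_p < fdr
  out <- out[order(out$p, out$term_id), ]
  rownames(out) <- NULL
  class(out) <- c("enrich_table", "data.frame")
  out
}

#' @export
print.enrich_table <- function(x, n = 6L, ...) {
  cat(sprintf("Enrichment table: %d terms, %d significant (FDR < 0.05)\n",
              nrow(x), sum(x$significant)))
  cols <- c("term_id", "category", "k", "K", "p", "adj_p", "neg_lg_p",
            "significant")
  print.data.frame(utils::head(x[, cols], n), digits = 4,
                   row.names = FALSE)
  invisible(x)
}

#' Assign up / down / up_down styles to significant terms
#'
#' Merges the significant-term sets of two direction-specific enrichment
#' runs (up-regulated DEGs vs down-regulated DEGs): a term significant in
#' both runs is styled `up_down`, one significant only for up-DEGs `up`,
#' only for down-DEGs `down`. Terms significant in neither run are absent.
#'
#' @param sig_up,sig_down Character vectors of significant term ids from
#'   the two runs (or `enrich_table`s, whose significant ids are taken).
#' @return Data frame `term_id`, `style`, sorted by term id.
#' @export
assign_style <- function(sig_up, sig_down) {
  pick <- function(x) {
    if (inherits(x, "enrich_table")) x$term_id[x$significant]
    else unique(as.character(x))
  }
  up <- pick(sig_up); down <- pick(sig_down)
  ids <- sort(union(up, down))
  style <- ifelse(ids %in% up & ids %in% down, "up_down",
                  ifelse(ids %in% up, "up", "down"))
  data.frame(term_id = ids, style = style, stringsAsFactors = FALSE)
}

#' Write an enrichment table (and its histogram companion) as TSV
#'
#' @param table An `enrich_table`.
#' @param path Output TSV; p-values are formatted in scientific notation
#'   with 4 significant digits.
#' @param histogram_path Optional second TSV with just `term_id`, `name`,
#'   `neg_lg_p` for significant terms — ready for a -LgP bar chart.
#' @return `path`, invisibly.
#' @export
write_enrich_table <- function(table, path, histogram_path = NULL) {
  df <- as.data.frame(table)
  for (col in c("p", "chi2_p", "adj_p"))
    df[[col]] <- format(df[[col]], digits = 4, scientific = TRUE)
  df$neg_lg_p <- format(df$neg_lg_p, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(histogram_path)) {
    h <- as.data.frame(table)[table$significant,
                              c("term_id", "name", "neg_lg_p")]
    h$neg_lg_p <- format(h$neg_lg_p, digits = 6)
    utils::write.table(h, histogram_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
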