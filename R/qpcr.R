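# qPCR and RNA quality validation ---------------------------------------------

#' Relative expression by the 2^-ddCt method
#'
#' Classic comparative-Ct quantification: per condition, the target Ct is
#' referenced against an internal-control gene (the GAPDH role), Delta-Ct =
#' Ct_target - Ct_reference; the treated condition is then referenced
#' against the control, DeltaDelta-Ct = dCt_treated - dCt_control; relative
#' expression is 2^-DeltaDelta-Ct. Replicate Ct values are averaged
#' (arithmetic mean) before differencing.
#'
#' @param treated,control Data frames of replicate Ct rows with columns
#'   `ct_target` and `ct_reference` (a single-row data frame or a named
#'   list also works).
#' @return Relative expression of the treated condition (control = 1).
#' @examples
#' ddct(data.frame(ct_target = 25, ct_reference = 20),
#'      data.frame(ct_target = 24, ct_reference = 20))  # 0.5
#' @export
ddct <- function(treated, control) {
  dct <- function(x) {
    x <- as.data.frame(x)
    if (is.null(x$ct_target) || is.null(x$ct_reference) ||
        any(is.na(x$ct_reference)))
      stop("Ct records need ct_target and ct_reference values")
    mean(x$ct_target) - mean(x$ct_reference)
  }
  2^-(dct(treated) - dct(control))
}

#' Per-gene relative expression from a Ct table
#'
#' Applies [ddct()] gene by gene to a long Ct table, treating `KD` as the
#' treated condition and `NC` as the control.
#'
#' @param ct Data frame as read by [read_ct()]: columns `sample`,
#'   `condition` (NC/KD), `gene`, `ct_target`, `ct_reference`.
#' @return Data frame `gene`, `rel_expr` (2^-ddCt, NC = 1).
#' @export
qpcr_relative <- function(ct) {
  stopifnot(all(c("condition", "gene", "ct_target", "ct_reference") %in%
                  names(ct)))
  genes <- unique(ct$gene)
  rel <- vapply(genes, function(g) {
    sub <- ct[ct$gene == g, ]
    ddct(sub[sub$condition == "KD", ], sub[sub$condition == "NC", ])
  }, numeric(1))
  data.frame(gene = genes, rel_expr = unname(rel), stringsAsFactors = FALSE)
}

#' RNA quality-control gate
#'
#' Pass iff A260/A280 > 1.9, concentration > 300 ng/uL and 28S/18S > 1.4
#' (all strict); failures list the offending metrics.
#'
#' @param a260_a280 Absorbance ratio.
#' @param concentration RNA concentration, ng/uL.
#' @param ratio_28s_18s Ribosomal band ratio.
#' @return List with `pass` (logical) and `reasons` (character vector,
#'   empty on pass).
#' @export
rna_qc <- function(a260_a280, concentration, ratio_28s_18s) {
  vals <- c(a260_a280 = a260_a280, concentration = concentration,
            ratio_28s_18s = ratio_28s_18s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("QC metrics must be positive numbers")
  reasons <- character(0)
  if (!(a260_a280 > 1.9))
    reasons <- c(reasons, sprintf("A260/A280 %.3g not > 1.9", a260_a280))
  if (!(concentration > 300))
    reasons <- c(reasons,
                 sprintf("concentration %.3g ng/uL not > 300", concentration))
  if (!(ratio_28s_18s > 1.4))
    reasons <- c(reasons, sprintf("28S/18S %.3g not > 1.4", ratio_28s_18s))
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Knockdown efficiency from relative expression
#'
#' Percent decrease of the target transcript in the knockdown condition,
#' `100 * (1 - rel_expr)`, where `rel_expr` is the 2^-ddCt relative
#' expression normalized so the control equals 1.
#'
#' @param rel_expr_kd Relative expression in the knockdown (must be > 0).
#' @return Percent decrease (negative when expression rose).
#' @examples
#' knockdown_efficiency(0.28)  # 72
#' @export
knockdown_efficiency <- function(rel_expr_kd) {
  if (any(!is.finite(rel_expr_kd)) || any(rel_expr_kd <= 0))
    stop("relative expression must be > 0")
  100 * (1 - rel_expr_kd)
}

#' Microarray versus qPCR fold-change concordance
#'
#' Pairs the array fold change of each shared gene with its qPCR 2^-ddCt
#' relative expression and flags direction agreement (both above 1 or both
#' below 1).
#'
#' @param deg A `deg_table` (needs `gene_id` and `fc`).
#' @param qpcr Data frame `gene`, `rel_expr` from [qpcr_relative()].
#' @return List with `table` (gene, array_fc, qpcr_fc, concordant) and
#'   `fraction_concordant`.
#' @export
concordance <- function(deg, qpcr) {
  stopifnot(!is.null(deg$gene_id), !is.null(deg$fc),
            all(c("gene", "rel_expr") %in% names(qpcr)))
  shared <- intersect(deg$gene_id, qpcr$gene)
  if (length(shared) == 0) stop("no shared genes between array and qPCR")
  afc <- deg$fc[match(shared, deg$gene_id)]
  qfc <- qpcr$rel_expr[match(shared, qpcr$gene)]
  conc <- (afc > 1 & qfc > 1) | (afc < 1 & qfc < 1)
  list(table = data.frame(gene = shared, array_fc = afc, qpcr_fc = qfc,
                          concordant = conc, stringsAsFactors = FALSE),
       fraction_concordant = mean(conc))
}
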