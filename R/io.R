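# Containers and plain-text I/O ----------------------------------------------

#' Probe-level intensity container
#'
#' A minimal container for linear-scale probe intensities with a
#' probe-to-gene map: every probe maps to exactly one gene, every gene has
#' at least one probe, intensities are strictly positive.
#'
#' @param intensity Numeric matrix, probes x samples, linear scale, with
#'   probe ids as row names and sample ids as column names.
#' @param gene_id Character vector, one gene id per probe row.
#' @return An object of class `probe_matrix` with components `intensity`,
#'   `probe_id`, `gene_id`, `samples`.
#' @export
probe_matrix <- function(intensity, gene_id) {
  stopifnot(is.matrix(intensity), is.numeric(intensity))
  if (nrow(intensity) == 0 || ncol(intensity) == 0)
    stop("intensity matrix must have positive dimensions")
  if (length(gene_id) != nrow(intensity))
    stop("gene_id must have one entry per probe row")
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("intensities must be finite and > 0")
  if (is.null(rownames(intensity)))
    rownames(intensity) <- sprintf("probe_%d", seq_len(nrow(intensity)))
  if (is.null(colnames(intensity)))
    colnames(intensity) <- sprintf("S%d", seq_len(ncol(intensity)))
  structure(list(intensity = intensity,
                 probe_id = rownames(intensity),
                 gene_id = as.character(gene_id),
                 samples = colnames(intensity)),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes / %d genes x %d samples\n",
              nrow(x$intensity), length(unique(x$gene_id)),
              ncol(x$intensity)))
  invisible(x)
}

#' Write / read a probe matrix TSV
#'
#' Layout: columns `probe_id`, `gene_id`, then one numeric column per
#' sample (linear-scale intensities).
#'
#' @param probes A [probe_matrix()].
#' @param path File path.
#' @return `write_probe_matrix()` returns `path` invisibly;
#'   `read_probe_matrix()` returns a [probe_matrix()].
#' @export
write_probe_matrix <- function(probes, path) {
  stopifnot(inherits(probes, "probe_matrix"))
  df <- data.frame(probe_id = probes$probe_id, gene_id = probes$gene_id,
                   probes$intensity, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_matrix
#' @export
read_probe_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("probe_id", "gene_id")
  if (!all(need %in% names(df)))
    stop("probe TSV must have probe_id and gene_id columns")
  m <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  rownames(m) <- df$probe_id
  probe_matrix(m, df$gene_id)
}

#' Read sample group labels
#'
#' Expects a TSV with columns `sample` and `group`; group labels are
#' normalized to a factor with levels `NC`, `KD` (NC first, so log2FC is
#' always KD minus NC).
#'
#' @param path File path.
#' @param samples Optional sample-id vector to align/validate against.
#' @return Factor of group labels, named by sample.
#' @export
read_groups <- function(path, samples = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df)))
    stop("group TSV must have sample and group columns")
  g <- factor(df$group, levels = c("NC", "KD"))
  if (any(is.na(g))) stop("group labels must be NC or KD")
  names(g) <- df$sample
  if (!is.null(samples)) {
    if (!all(samples %in% names(g)))
      stop("group TSV does not cover all samples")
    g <- g[samples]
  }
  g
}

#' Write / read a gene-level log2 expression matrix TSV
#'
#' Layout: `gene_id` column followed by one numeric column per sample.
#'
#' @param expr Numeric matrix, genes x samples, log2 scale, with gene row
#'   names.
#' @param path File path.
#' @return `write_expression()` returns `path` invisibly;
#'   `read_expression()` returns the matrix.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("expression TSV must start with gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' Read / write GMT gene-set files
#'
#' Standard tab-separated GMT: term id, description, then member gene ids.
#' The description field carries `category|name` when written by this
#' package; on read, a `pathway` category is inferred from a `path:` id
#' prefix otherwise.
#'
#' @param sets List of term records (`id`, `name`, `category`, `genes`).
#' @param path File path.
#' @return `read_gmt()` returns a list of term records; `write_gmt()`
#'   returns `path` invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$id, paste0(s$category, "|", s$name), s$genes),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with fewer than 3 fields")
    desc <- f[2]
    if (grepl("|", desc, fixed = TRUE)) {
      parts <- strsplit(desc, "|", fixed = TRUE)[[1]]
      category <- parts[1]
      name <- paste(parts[-1], collapse = "|")
    } else {
      category <- if (startsWith(f[1], "path:")) "pathway" else "GO"
      name <- desc
    }
    list(id = f[1], name = name, category = category,
         genes = unique(f[-(1:2)]))
  })
}

#' Read a qPCR Ct table
#'
#' TSV with columns `sample`, `condition` (NC/KD), `gene`, `ct_target`,
#' `ct_reference`.
#'
#' @param path File path.
#' @return Data frame of Ct records.
#' @export
read_ct <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "condition", "gene", "ct_target", "ct_reference")
  if (!all(need %in% names(df)))
    stop("Ct TSV must have columns: ", paste(need, collapse = ", "))
  bad <- df$ct_target <= 0 | df$ct_target >= 50 |
    df$ct_reference <= 0 | df$ct_reference >= 50
  if (any(bad)) stop("Ct values must lie in (0, 50)")
  df
}
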