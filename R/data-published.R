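# Published worked-example tables ---------------------------------------------

#' Published PHF20-knockdown hub and partition tables
#'
#' Tabular content reported by the PHF20 shRNA-knockdown microarray study
#' in U87 glioblastoma cells (GEO accession GSE93680), shipped as plain TSV
#' under `inst/extdata` and used as worked-example inputs: the top-12
#' pathway-net hub table, the top-10 signal-net hub table (Entrez gene
#' ids), and the up/down partition counts for DEGs (175/365), styled GO
#' terms (111/125) and significant pathways (41/106). Degree columns are
#' recomputed from outdegree + indegree by the consistency checks, never
#' trusted as printed.
#'
#' @return A list of three data frames: `pathway_hubs`, `signal_hubs`,
#'   `summary_counts`.
#' @examples
#' tabs <- phf20_tables()
#' all(tabs$pathway_hubs$degree ==
#'     tabs$pathway_hubs$outdegree + tabs$pathway_hubs$indegree)
#' @export
phf20_tables <- function() {
  rd <- function(f) utils::read.delim(
    system.file("extdata", f, package = "knocknet", mustWork = TRUE),
    stringsAsFactors = FALSE)
  list(pathway_hubs = rd("phf20_pathway_hubs.tsv"),
       signal_hubs = rd("phf20_signalnet_hubs.tsv"),
       summary_counts = rd("phf20_summary_counts.tsv"))
}
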