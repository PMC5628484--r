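# Simulation configuration ---------------------------------------------------

#' Configuration for the synthetic knockdown study generator
#'
#' Bundles every knob of the synthetic two-group (NC vs KD) expression study:
#' matrix dimensions, planted effect sizes, annotation and relation-document
#' sizes, and the master seed. Defaults emulate a small shRNA-knockdown
#' microarray design: two groups of three arrays, probe sets of four probes,
#' 2% of genes shifted by |log2FC| = 2 against log2-scale noise of sd 0.25.
#'
#' @param n_genes Number of genes on the synthetic array.
#' @param n_probes_per_gene Probes per probe set (all genes equal).
#' @param n_per_group Arrays per group; both NC and KD get this many.
#' @param frac_deg Fraction of genes planted as true DEGs. `0` gives a null
#'   experiment; a positive value that rounds to zero planted genes is an
#'   error.
#' @param effect_log2fc Planted |log2 fold change| applied to the KD group.
#' @param noise_sd Standard deviation of i.i.d. normal noise per
#'   probe-by-sample cell, log2 scale. Must be positive.
#' @param up_fraction Fraction of planted DEGs shifted upward; the rest go
#'   down. `0.5` is the neutral default; set e.g. `175/540` to emulate an
#'   asymmetric knockdown response.
#' @param n_terms Number of GO-style annotation terms to generate.
#' @param term_size_range Length-2 integer vector, inclusive bounds on term
#'   (and pathway gene-set) sizes.
#' @param frac_enriched_terms Fraction of terms (and pathway sets) planted as
#'   truly enriched in one DEG direction.
#' @param n_pathways Number of synthetic pathways (relation documents).
#' @param n_pathway_links Number of pathway-to-pathway maplink relations.
#' @param n_gene_relations Number of gene-to-gene relations across documents.
#' @param seed Master seed. Each artifact type (expression, annotation,
#'   relations, qPCR) draws from its own stream derived from this seed by a
#'   fixed offset, so adding terms never perturbs the expression draws.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_genes = 200, n_terms = 20, seed = 7)
#' cfg$frac_deg
#' @export
sim_config <- function(n_genes = 5000,
                       n_probes_per_gene = 4,
                       n_per_group = 3,
                       frac_deg = 0.02,
                       effect_log2fc = 2,
                       noise_sd = 0.25,
                       up_fraction = 0.5,
                       n_terms = 200,
                       term_size_range = c(10L, 50L),
                       frac_enriched_terms = 0.1,
                       n_pathways = 30,
                       n_pathway_links = 60,
                       n_gene_relations = 150,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_probes_per_gene = as.integer(n_probes_per_gene),
    n_per_group = as.integer(n_per_group),
    frac_deg = as.numeric(frac_deg),
    effect_log2fc = as.numeric(effect_log2fc),
    noise_sd = as.numeric(noise_sd),
    up_fraction = as.numeric(up_fraction),
    n_terms = as.integer(n_terms),
    term_size_range = as.integer(term_size_range),
    frac_enriched_terms = as.numeric(frac_enriched_terms),
    n_pathways = as.integer(n_pathways),
    n_pathway_links = as.integer(n_pathway_links),
    n_gene_relations = as.integer(n_gene_relations),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_genes >= 1, cfg$n_probes_per_gene >= 1, cfg$n_per_group >= 1,
    cfg$n_terms >= 1, cfg$n_pathways >= 1
  )
  if (cfg$frac_deg < 0 || cfg$frac_deg > 1)
    stop("frac_deg must be in [0, 1]")
  if (cfg$frac_enriched_terms < 0 || cfg$frac_enriched_terms > 1)
    stop("frac_enriched_terms must be in [0, 1]")
  if (cfg$up_fraction < 0 || cfg$up_fraction > 1)
    stop("up_fraction must be in [0, 1]")
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop("noise_sd must be > 0")
  if (cfg$effect_log2fc <= 0)
    stop("effect_log2fc must be > 0")
  if (length(cfg$term_size_range) != 2L ||
      any(cfg$term_size_range < 1L) ||
      cfg$term_size_range[1] > cfg$term_size_range[2])
    stop("term_size_range must be an increasing pair of counts >= 1")
  if (cfg$n_pathway_links < 0) stop("n_pathway_links must be >= 0")
  if (cfg$n_gene_relations < 0) stop("n_gene_relations must be >= 0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic knockdown study configuration\n")
  cat(sprintf("  genes: %d (%d probes each), %d vs %d arrays\n",
              x$n_genes, x$n_probes_per_gene, x$n_per_group, x$n_per_group))
  cat(sprintf("  planted DEGs: %.1f%% at |log2FC| = %g (%.0f%% up), noise sd %g\n",
              100 * x$frac_deg, x$effect_log2fc, 100 * x$up_fraction,
              x$noise_sd))
  cat(sprintf("  annotation: %d terms (sizes %d-%d, %.0f%% enriched)\n",
              x$n_terms, x$term_size_range[1], x$term_size_range[2],
              100 * x$frac_enriched_terms))
  cat(sprintf("  relations: %d pathways, %d maplinks, %d gene relations\n",
              x$n_pathways, x$n_pathway_links, x$n_gene_relations))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Fixed per-artifact stream offsets off the master seed. Kept small so any
# user seed below ~2^31 - 500 stays a valid integer.
.stream_seed <- function(cfg, stream = c("expression", "annotation",
                                         "relations", "qpcr")) {
  stream <- match.arg(stream)
  off <- c(expression = 101L, annotation = 202L, relations = 303L,
           qpcr = 404L)[[stream]]
  cfg$seed + off
}
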