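# Synthetic study generator --------------------------------------------------
#
# Emulates a two-group knockdown microarray experiment with known ground
# truth: probe-level intensities with planted fold changes, term->gene
# annotations with planted enrichment, KGML-subset relation documents with
# known edges, and a qPCR Ct table consistent with the planted effects.

#' Simulate probe-level expression for a two-group knockdown design
#'
#' Draws per-gene baseline log2 intensities uniformly on \[4, 14\], shifts a
#' planted subset of genes by `+/- effect_log2fc` in the KD group, adds fixed
#' per-probe offsets (N(0, 0.5^2), so probe-set summarization has real work
#' to do) and i.i.d. N(0, `noise_sd`^2) noise per probe-by-sample cell, then
#' exponentiates to the linear scale.
#'
#' @param config A [sim_config()].
#' @return A list with components `probes` (a [probe_matrix()], linear
#'   scale), `groups` (factor with levels `NC`, `KD`, one per sample column)
#'   and `truth` (a `truth_bundle`: planted DEG table with signed
#'   directions; term and edge slots filled later by
#'   [simulate_annotation()] / [simulate_relations()]).
#' @seealso [simulate_study()] for the one-call bundle.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 50, seed = 1))
#' dim(sim$probes$intensity)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stream_seed(config, "expression"))

  n_deg <- round(config$frac_deg * config$n_genes)
  if (config$frac_deg > 0 && n_deg < 1)
    stop("no DEGs plantable: frac_deg * n_genes rounds to zero")

  genes <- sprintf("G%05d", seq_len(config$n_genes))
  mu <- stats::runif(config$n_genes, 4, 14)

  deg_idx <- sort(sample.int(config$n_genes, n_deg))
  n_up <- round(config$up_fraction * n_deg)
  sgn <- rep(-1, n_deg)
  if (n_up > 0) sgn[sample.int(n_deg, n_up)] <- 1
  delta <- numeric(config$n_genes)
  delta[deg_idx] <- sgn * config$effect_log2fc

  n_probe <- config$n_genes * config$n_probes_per_gene
  gene_of_probe <- rep(genes, each = config$n_probes_per_gene)
  probe_ids <- paste0(gene_of_probe, "_p",
                      rep(seq_len(config$n_probes_per_gene),
                          times = config$n_genes))
  probe_offset <- stats::rnorm(n_probe, 0, 0.5)

  n_samp <- 2L * config$n_per_group
  samples <- c(sprintf("NC_%d", seq_len(config$n_per_group)),
               sprintf("KD_%d", seq_len(config$n_per_group)))
  groups <- factor(rep(c("NC", "KD"), each = config$n_per_group),
                   levels = c("NC", "KD"))

  base <- rep(mu, each = config$n_probes_per_gene) + probe_offset
  shift <- rep(delta, each = config$n_probes_per_gene)
  log2mat <- matrix(base, n_probe, n_samp)
  log2mat[, groups == "KD"] <- log2mat[, groups == "KD"] + shift
  log2mat <- log2mat + matrix(stats::rnorm(n_probe * n_samp, 0,
                                           config$noise_sd),
                              n_probe, n_samp)
  dimnames(log2mat) <- list(probe_ids, samples)

  truth <- structure(list(
    deg = data.frame(
      gene_id = genes[deg_idx],
      direction = ifelse(sgn > 0, "up", "down"),
      log2fc = sgn * config$effect_log2fc,
      stringsAsFactors = FALSE
    ),
    enriched_terms = NULL,
    edges = NULL
  ), class = "truth_bundle")

  list(
    probes = probe_matrix(2^log2mat, gene_id = gene_of_probe),
    groups = groups,
    truth = truth
  )
}

#' Simulate term-to-gene annotations with planted enrichment
#'
#' Generates two gene-set collections over the simulated gene universe: GO
#' style terms (`n_terms`) and pathway gene sets (`n_pathways`), with sizes
#' drawn uniformly from `term_size_range`. A `frac_enriched_terms` fraction
#' of each collection is planted as enriched: at least half of an enriched
#' set's members are drawn from the true DEGs of a single direction, the
#' rest uniformly from the remaining universe. Non-enriched sets are uniform
#' draws.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_expression()] (supplies the gene universe
#'   and the planted-DEG truth).
#' @return `sim` with two new components: `terms` (a list of term records:
#'   `id`, `name`, `category` in `GO`/`pathway`, `genes`) and
#'   `truth$enriched_terms` (data frame of planted term ids with direction
#'   and category).
#' @export
simulate_annotation <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stream_seed(config, "annotation"))
  universe <- sim$probes$gene_id[!duplicated(sim$probes$gene_id)]
  if (config$term_size_range[2] > length(universe))
    stop("term_size_range exceeds the gene universe")

  deg_by_dir <- split(sim$truth$deg$gene_id, sim$truth$deg$direction)

  make_collection <- function(n_sets, prefix, category) {
    n_enr <- round(config$frac_enriched_terms * n_sets)
    if (n_enr > 0 && nrow(sim$truth$deg) == 0)
      stop("cannot plant enriched terms without planted DEGs")
    dirs_avail <- names(deg_by_dir)[vapply(deg_by_dir, length, 1L) > 0]
    if (n_enr > 0 && length(dirs_avail) == 0)
      stop("cannot plant enriched terms without planted DEGs")
    enr_flag <- rep(FALSE, n_sets)
    if (n_enr > 0) enr_flag[sample.int(n_sets, n_enr)] <- TRUE
    sizes <- sample(seq(config$term_size_range[1], config$term_size_range[2]),
                    n_sets, replace = TRUE)
    truth_rows <- list()
    sets <- vector("list", n_sets)
    for (i in seq_len(n_sets)) {
      id <- sprintf("%s%03d", prefix, i)
      if (enr_flag[i]) {
        dir <- sample(dirs_avail, 1)
        pool <- deg_by_dir[[dir]]
        n_core <- min(ceiling(sizes[i] / 2), length(pool))
        core <- sample(pool, n_core)
        rest <- sample(setdiff(universe, core), sizes[i] - n_core)
        members <- sort(c(core, rest))
        truth_rows[[length(truth_rows) + 1L]] <-
          data.frame(term_id = id, direction = dir, category = category,
                     stringsAsFactors = FALSE)
      } else {
        members <- sort(sample(universe, sizes[i]))
      }
      sets[[i]] <- list(id = id,
                        name = sprintf("synthetic %s set %d", category, i),
                        category = category, genes = members)
    }
    list(sets = sets, truth = truth_rows)
  }

  go <- make_collection(config$n_terms, "TERM", "GO")
  pw <- make_collection(config$n_pathways, "path:syn", "pathway")

  sim$terms <- c(go$sets, pw$sets)
  tr <- c(go$truth, pw$truth)
  sim$truth$enriched_terms <- if (length(tr)) do.call(rbind, tr) else
    data.frame(term_id = character(), direction = character(),
               category = character(), stringsAsFactors = FALSE)
  sim
}

#' Simulate KGML-subset relation documents with known edges
#'
#' Emits one XML document per synthetic pathway, in the KGML dialect subset
#' understood by [parse_kgml()]: `entry` elements (gene or map) and
#' `relation` elements with `subtype` children. Gene-gene relations get
#' types sampled from activation / inhibition / phosphorylation / binding;
#' half of them (when possible) connect two true DEGs so a downstream
#' signal-net is non-trivial. Pathway-pathway crosstalk is emitted as
#' maplink relations between map entries. Every emitted edge is recorded in
#' the truth bundle, so a parse round trip can be checked exactly.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_expression()] (optionally annotated).
#' @return `sim` with `kgml` (named character vector, document id ->
#'   serialized XML) and `truth$edges` (data frame `level`, `source`,
#'   `target`, `type`, `document`).
#' @export
simulate_relations <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_gene_relations < 0) stop("n_gene_relations must be >= 0")
  set.seed(.stream_seed(config, "relations"))

  universe <- sim$probes$gene_id[!duplicated(sim$probes$gene_id)]
  degs <- sim$truth$deg$gene_id
  pathways <- sprintf("path:syn%03d", seq_len(config$n_pathways))
  rel_types <- c("activation", "inhibition", "phosphorylation", "binding")

  # Gene-gene relations: distinct ordered pairs, no self-loops, half drawn
  # inside the DEG set when it is large enough.
  draw_pair <- function(pool) {
    p <- sample(pool, 2)
    c(p[1], p[2])
  }
  seen <- character()
  g_edges <- list()
  n_deg_pref <- if (length(degs) >= 2)
    floor(config$n_gene_relations / 2) else 0L
  i <- 0L
  guard <- 0L
  while (i < config$n_gene_relations && guard < 50L * (config$n_gene_relations + 1L)) {
    guard <- guard + 1L
    pool <- if (i < n_deg_pref) degs else universe
    pr <- draw_pair(pool)
    key <- paste(pr, collapse = ">")
    if (key %in% seen) next
    seen <- c(seen, key)
    i <- i + 1L
    g_edges[[i]] <- data.frame(
      level = "gene", source = pr[1], target = pr[2],
      type = sample(rel_types, 1),
      document = sample(pathways, 1), stringsAsFactors = FALSE)
  }
  gene_rel <- if (length(g_edges)) do.call(rbind, g_edges) else
    data.frame(level = character(), source = character(),
               target = character(), type = character(),
               document = character(), stringsAsFactors = FALSE)

  # Pathway-pathway maplinks: distinct ordered pairs, emitted in the source
  # pathway's document.
  max_links <- config$n_pathways * (config$n_pathways - 1L)
  if (config$n_pathway_links > max_links)
    stop("n_pathway_links exceeds the number of distinct ordered pathway pairs")
  all_pairs <- expand.grid(source = pathways, target = pathways,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$source != all_pairs$target, ]
  pick <- all_pairs[sample.int(nrow(all_pairs), config$n_pathway_links), ,
                    drop = FALSE]
  map_rel <- if (nrow(pick)) data.frame(
    level = "pathway", source = pick$source, target = pick$target,
    type = "maplink", document = pick$source, stringsAsFactors = FALSE
  ) else data.frame(level = character(), source = character(),
                    target = character(), type = character(),
                    document = character(), stringsAsFactors = FALSE)

  edges <- rbind(gene_rel, map_rel)
  sim$kgml <- .emit_kgml_documents(pathways, universe, edges)
  rownames(edges) <- NULL
  sim$truth$edges <- edges
  sim
}

# Serialize one KGML-subset document per pathway. Each document declares a
# gene entry per gene it mentions, a map entry for itself and for every
# maplink target, then the relation elements.
.emit_kgml_documents <- function(pathways, universe, edges) {
  out <- stats::setNames(character(length(pathways)), pathways)
  for (pw in pathways) {
    e <- edges[edges$document == pw, , drop = FALSE]
    ge <- e[e$level == "gene", , drop = FALSE]
    me <- e[e$level == "pathway", , drop = FALSE]
    genes_here <- unique(c(ge$source, ge$target))
    maps_here <- unique(c(pw, me$target))
    entry_ids <- stats::setNames(seq_along(c(genes_here, maps_here)),
                                 c(genes_here, maps_here))
    doc <- xml2::xml_new_root("pathway", name = pw,
                              title = paste("synthetic pathway", pw))
    for (g in genes_here)
      xml2::xml_add_child(doc, "entry", id = as.character(entry_ids[[g]]),
                          name = g, type = "gene")
    for (m in maps_here)
      xml2::xml_add_child(doc, "entry", id = as.character(entry_ids[[m]]),
                          name = m, type = "map")
    add_rel <- function(src, tgt, subtype) {
      rel <- xml2::xml_add_child(doc, "relation",
                                 entry1 = as.character(entry_ids[[src]]),
                                 entry2 = as.character(entry_ids[[tgt]]),
                                 type = "PPrel")
      xml2::xml_add_child(rel, "subtype", name = subtype, value = "-")
    }
    if (nrow(ge)) for (k in seq_len(nrow(ge)))
      add_rel(ge$source[k], ge$target[k], ge$type[k])
    if (nrow(me)) for (k in seq_len(nrow(me)))
      add_rel(me$source[k], me$target[k], "maplink")
    out[[pw]] <- as.character(doc)
  }
  out
}

#' Simulate a qPCR Ct table consistent with planted fold changes
#'
#' Picks validation genes (true DEGs when available, padded with null genes)
#' and writes replicate Ct rows per condition where the target Ct drops by
#' one cycle per planted log2 fold change in the KD group, so
#' 2^-ddCt recovers the planted linear fold change up to Ct noise.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_expression()].
#' @param n_genes_validate Number of genes to carry to qPCR.
#' @param n_replicates Technical replicates per condition.
#' @param ct_sd Ct measurement noise (cycles).
#' @return `sim` with a `qpcr` data frame: `sample`, `condition`, `gene`,
#'   `ct_target`, `ct_reference`.
#' @export
simulate_qpcr <- function(config, sim, n_genes_validate = 8L,
                          n_replicates = 3L, ct_sd = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stream_seed(config, "qpcr"))
  universe <- sim$probes$gene_id[!duplicated(sim$probes$gene_id)]
  degs <- sim$truth$deg
  picked <- head(degs$gene_id, n_genes_validate)
  if (length(picked) < n_genes_validate)
    picked <- c(picked, sample(setdiff(universe, picked),
                               n_genes_validate - length(picked)))
  l2fc <- stats::setNames(rep(0, length(picked)), picked)
  hit <- intersect(picked, degs$gene_id)
  l2fc[hit] <- degs$log2fc[match(hit, degs$gene_id)]

  rows <- list()
  for (g in picked) {
    base_ct <- stats::runif(1, 22, 28)
    for (cond in c("NC", "KD")) {
      for (r in seq_len(n_replicates)) {
        # one planted log2FC unit = one fewer amplification cycle in KD
        tgt <- base_ct - (cond == "KD") * l2fc[[g]] +
          stats::rnorm(1, 0, ct_sd)
        ref <- 18 + stats::rnorm(1, 0, ct_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sprintf("%s_%d", cond, r), condition = cond, gene = g,
          ct_target = round(tgt, 3), ct_reference = round(ref, 3),
          stringsAsFactors = FALSE)
      }
    }
  }
  sim$qpcr <- do.call(rbind, rows)
  sim
}

#' Generate the full synthetic study bundle
#'
#' Runs [simulate_expression()], [simulate_annotation()],
#' [simulate_relations()] and [simulate_qpcr()] in order and returns the
#' combined bundle. With a fixed config (including its seed) the bundle is
#' fully deterministic.
#'
#' @param config A [sim_config()].
#' @return An object of class `knocknet_sim`: components `probes`,
#'   `groups`, `terms`, `kgml`, `qpcr`, `truth`.
#' @examples
#' sim <- simulate_study(sim_config(n_genes = 100, n_terms = 10,
#'                                  n_pathways = 5, n_pathway_links = 6,
#'                                  n_gene_relations = 20, seed = 42))
#' print(sim)
#' @export
simulate_study <- function(config = sim_config()) {
  sim <- simulate_expression(config)
  sim <- simulate_annotation(config, sim)
  sim <- simulate_relations(config, sim)
  sim <- simulate_qpcr(config, sim)
  sim$config <- config
  class(sim) <- "knocknet_sim"
  sim
}

#' @export
print.knocknet_sim <- function(x, ...) {
  cat("Synthetic knockdown study bundle\n")
  cat(sprintf("  probes: %d x %d (genes: %d)\n",
              nrow(x$probes$intensity), ncol(x$probes$intensity),
              length(unique(x$probes$gene_id))))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", levels(x$groups), table(x$groups)),
                    collapse = ", ")))
  cat(sprintf("  truth: %d planted DEGs, %d enriched sets, %d relations\n",
              nrow(x$truth$deg),
              if (is.null(x$truth$enriched_terms)) 0L else
                nrow(x$truth$enriched_terms),
              if (is.null(x$truth$edges)) 0L else nrow(x$truth$edges)))
  invisible(x)
}

#' Write a simulated study bundle to disk
#'
#' Serializes every artifact as plain text: probe matrix TSV (probe_id,
#' gene_id, one column per sample), group labels TSV, GMT annotation file,
#' one KGML-subset XML per pathway under `kgml/`, qPCR Ct TSV, and the
#' ground truth as JSON. Output is byte-stable for a fixed bundle.
#'
#' @param sim A `knocknet_sim` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of written paths.
#' @export
write_study <- function(sim, dir) {
  stopifnot(inherits(sim, "knocknet_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "kgml"), showWarnings = FALSE)

  paths <- c(probes = file.path(dir, "probes.tsv"),
             groups = file.path(dir, "groups.tsv"),
             gmt = file.path(dir, "annotation.gmt"),
             qpcr = file.path(dir, "qpcr_ct.tsv"),
             truth = file.path(dir, "truth.json"))
  write_probe_matrix(sim$probes, paths[["probes"]])
  utils::write.table(
    data.frame(sample = colnames(sim$probes$intensity),
               group = as.character(sim$groups)),
    paths[["groups"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(sim$terms, paths[["gmt"]])
  utils::write.table(sim$qpcr, paths[["qpcr"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (pw in names(sim$kgml)) {
    f <- file.path(dir, "kgml", paste0(gsub("[^A-Za-z0-9]+", "_", pw), ".xml"))
    writeLines(sim$kgml[[pw]], f)
    paths[[pw]] <- f
  }
  truth <- sim$truth
  class(truth) <- NULL
  jsonlite::write_json(truth, paths[["truth"]], dataframe = "columns",
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
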