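# Pipeline orchestration ------------------------------------------------------
#
# One-call driver over the module functions, in dependency order:
# simulate -> prep -> deg -> enrich -> net -> qpcr -> report. Each executed
# step is logged once with its parameters and the counts it emitted;
# re-running an unchanged config reproduces byte-identical tables.

#' Assemble a pipeline configuration
#'
#' @param seed Master seed for the synthetic study.
#' @param out_dir Output directory for tables and graphs; `NULL` keeps
#'   everything in memory.
#' @param sim Named list of [sim_config()] overrides (the seed is taken
#'   from `seed`).
#' @param fc_threshold,alpha DEG screening cuts (linear fold change, FDR).
#' @param fdr Enrichment significance cut.
#' @param top Rows kept in hub tables.
#' @param steps Steps to run, a subset of
#'   `c("simulate", "prep", "deg", "enrich", "net", "qpcr", "report")`.
#' @param inputs Named list of input paths (`probes`, `groups`, `gmt`,
#'   `kgml`, `ct`) for runs that start from files instead of the simulate
#'   step.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL, sim = list(),
                            fc_threshold = 2, alpha = 0.05, fdr = 0.05,
                            top = 12L, steps = c("simulate", "prep", "deg",
                                                 "enrich", "net", "qpcr",
                                                 "report"),
                            inputs = list()) {
  all_steps <- c("simulate", "prep", "deg", "enrich", "net", "qpcr",
                 "report")
  steps <- match.arg(steps, all_steps, several.ok = TRUE)
  if (fc_threshold <= 0 || alpha <= 0 || fdr <= 0)
    stop("thresholds must be positive")
  if (top < 1) stop("top must be >= 1")
  structure(list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
                 fc_threshold = fc_threshold, alpha = alpha, fdr = fdr,
                 top = as.integer(top), steps = steps, inputs = inputs),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path Config file (`.json`, `.yml` or `.yaml`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  keep <- intersect(names(raw), names(formals(pipeline_config)))
  do.call(pipeline_config, raw[keep])
}

.require_artifact <- function(state, what, step, producer) {
  if (is.null(state[[what]]))
    stop(sprintf("step '%s' requires '%s' from step '%s', which did not run",
                 step, what, producer))
  state[[what]]
}

#' Run the knockdown-analysis pipeline
#'
#' Executes the enabled steps in dependency order on a synthetic study (or
#' on user-supplied input files), producing the DEG table and summary,
#' direction-specific enrichment tables with styles, the pathway-net and
#' signal-net with degree/hub tables, the per-pathway DEG overlay, the
#' qPCR concordance table, and a run log. A failing step aborts with the
#' step named.
#'
#' @param config A [pipeline_config()] (or a path accepted by
#'   [read_pipeline_config()]).
#' @return An object of class `knocknet_run` holding every computed
#'   artifact plus `log` (one entry per executed step).
#' @examples
#' run <- run_pipeline(pipeline_config(
#'   seed = 11, sim = list(n_genes = 300, n_terms = 30, n_pathways = 8,
#'                         n_pathway_links = 12, n_gene_relations = 40)))
#' print(run)
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  run_log <- list()
  log_step <- function(name, params, counts) {
    run_log[[name]] <<- list(step = name, params = params, counts = counts,
                             time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  }
  emit <- function(writer, ..., file) {
    if (!is.null(out_dir)) writer(..., file.path(out_dir, file))
  }

  if ("simulate" %in% config$steps) {
    sim <- simulate_study(do.call(sim_config,
                                  c(config$sim, list(seed = config$seed))))
    state$probes <- sim$probes; state$groups <- sim$groups
    state$terms <- sim$terms; state$kgml <- sim$kgml
    state$ct <- sim$qpcr; state$truth <- sim$truth
    if (!is.null(out_dir)) write_study(sim, file.path(out_dir, "sim"))
    log_step("simulate", config$sim,
             c(genes = length(unique(sim$probes$gene_id)),
               probes = nrow(sim$probes$intensity),
               samples = ncol(sim$probes$intensity),
               planted_degs = nrow(sim$truth$deg),
               planted_enriched = nrow(sim$truth$enriched_terms),
               relations = nrow(sim$truth$edges)))
  } else {
    inp <- config$inputs
    if (!is.null(inp$probes)) {
      state$probes <- read_probe_matrix(inp$probes)
      state$groups <- read_groups(inp$groups, state$probes$samples)
    }
    if (!is.null(inp$gmt)) state$terms <- read_gmt(inp$gmt)
    if (!is.null(inp$kgml)) state$kgml <- inp$kgml
    if (!is.null(inp$ct)) state$ct <- read_ct(inp$ct)
  }

  if ("prep" %in% config$steps) {
    probes <- .require_artifact(state, "probes", "prep", "simulate")
    rma <- rma_lite(probes)
    state$expr <- rma$expr
    emit(write_expression, state$expr, file = "expression.tsv")
    log_step("prep", list(steps = rma$log),
             c(genes = nrow(state$expr), samples = ncol(state$expr)))
  }

  if ("deg" %in% config$steps) {
    expr <- .require_artifact(state, "expr", "deg", "prep")
    deg <- deg_screen(expr, state$groups, fc_threshold = config$fc_threshold,
                      alpha = config$alpha)
    state$deg <- deg
    s <- deg_summary(deg)
    emit(write_deg_table, deg, file = "deg_table.tsv")
    if (!is.null(out_dir))
      jsonlite::write_json(unclass(s), file.path(out_dir, "deg_summary.json"),
                           auto_unbox = TRUE)
    log_step("deg", list(fc_threshold = config$fc_threshold,
                         alpha = config$alpha),
             c(total = s$n_total, up = s$n_up, down = s$n_down))
  }

  if ("enrich" %in% config$steps) {
    deg <- .require_artifact(state, "deg", "enrich", "deg")
    terms <- .require_artifact(state, "terms", "enrich", "simulate")
    background <- unique(.require_artifact(state, "probes", "enrich",
                                           "simulate")$gene_id)
    state$enrich <- list()
    counts <- c()
    for (cat_ in unique(vapply(terms, `[[`, "", "category"))) {
      db <- Filter(function(t) t$category == cat_, terms)
      runs <- list(
        up = enrich_direction(deg$gene_id[deg$direction == "up"], db,
                              background, fdr = config$fdr),
        down = enrich_direction(deg$gene_id[deg$direction == "down"], db,
                                background, fdr = config$fdr),
        combined = enrich_direction(deg$gene_id[deg$direction != "none"],
                                    db, background, fdr = config$fdr))
      style <- assign_style(runs$up, runs$down)
      nm <- vapply(db, `[[`, "", "name")
      style$name <- nm[match(style$term_id, vapply(db, `[[`, "", "id"))]
      state$enrich[[cat_]] <- c(runs, list(style = style))
      for (d in names(runs))
        emit(write_enrich_table, runs[[d]],
             file = sprintf("enrichment_%s_%s.tsv", cat_, d))
      counts[paste0(cat_, "_styled")] <- nrow(style)
    }
    log_step("enrich", list(fdr = config$fdr), counts)
  }

  if ("net" %in% config$steps) {
    deg <- .require_artifact(state, "deg", "net", "deg")
    kgml <- .require_artifact(state, "kgml", "net", "simulate")
    relations <- parse_kgml_set(kgml)
    state$relations <- relations
    enr <- .require_artifact(state, "enrich", "net", "enrich")
    if (is.null(enr$pathway))
      stop("step 'net' requires a pathway enrichment run")
    pathway_net <- build_pathway_net(enr$pathway$style, relations)
    signal_net <- build_signal_net(deg, relations)
    state$pathway_net <- pathway_net
    state$signal_net <- signal_net
    state$pathway_hubs <- rank_hubs(node_degrees(pathway_net), config$top)
    state$signal_hubs <- rank_hubs(node_degrees(signal_net), config$top)
    pw_sets <- Filter(function(t) t$category == "pathway",
                      .require_artifact(state, "terms", "net", "simulate"))
    state$overlay <- pathway_deg_overlay(pw_sets, deg)
    if (!is.null(out_dir)) {
      write_hub_table(state$pathway_hubs,
                      file.path(out_dir, "pathway_hubs.tsv"))
      write_hub_table(state$signal_hubs,
                      file.path(out_dir, "signal_hubs.tsv"))
      write_sif(pathway_net, file.path(out_dir, "pathway_net.sif"))
      write_sif(signal_net, file.path(out_dir, "signal_net.sif"))
      write_graphml(pathway_net, file.path(out_dir, "pathway_net.graphml"))
      write_graphml(signal_net, file.path(out_dir, "signal_net.graphml"))
      utils::write.table(state$overlay, file.path(out_dir, "overlay.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    log_step("net", list(top = config$top),
             c(pathway_nodes = nrow(pathway_net$nodes),
               pathway_edges = nrow(pathway_net$edges),
               signal_nodes = nrow(signal_net$nodes),
               signal_edges = nrow(signal_net$edges)))
  }

  if ("qpcr" %in% config$steps) {
    ct <- .require_artifact(state, "ct", "qpcr", "simulate")
    deg <- .require_artifact(state, "deg", "qpcr", "deg")
    rel <- qpcr_relative(ct)
    state$qpcr <- rel
    state$concordance <- concordance(deg, rel)
    if (!is.null(out_dir))
      utils::write.table(state$concordance$table,
                         file.path(out_dir, "qpcr_concordance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    log_step("qpcr", list(),
             c(genes = nrow(rel),
               concordant = sum(state$concordance$table$concordant)))
  }

  run <- structure(c(as.list(state), list(log = run_log, config = config)),
                   class = "knocknet_run")

  if ("report" %in% config$steps) {
    txt <- render_report(run)
    if (!is.null(out_dir)) writeLines(txt, file.path(out_dir, "report.txt"))
    run$report <- txt
  }
  run
}

#' Recovery of planted truth by a pipeline run
#'
#' Compares DEG calls and significant enriched terms against the
#' simulation's ground truth.
#'
#' @param run A `knocknet_run` whose bundle carries a truth component.
#' @return List with `deg` (sensitivity, fdr, counts) and `enrichment`
#'   (sensitivity per planted terms), or `NULL` when no truth is present.
#' @export
truth_recovery <- function(run) {
  if (is.null(run$truth)) return(NULL)
  out <- list()
  if (!is.null(run$deg)) {
    called <- run$deg$gene_id[run$deg$direction != "none"]
    truth <- run$truth$deg$gene_id
    tp <- length(intersect(called, truth))
    out$deg <- list(
      sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
      fdr = if (length(called)) 1 - tp / length(called) else 0,
      n_called = length(called), n_true = length(truth))
  }
  if (!is.null(run$enrich)) {
    planted <- run$truth$enriched_terms
    sig <- unlist(lapply(run$enrich, function(e)
      e$combined$term_id[e$combined$significant]))
    tp <- sum(planted$term_id %in% sig)
    out$enrichment <- list(
      sensitivity = if (nrow(planted)) tp / nrow(planted) else NA_real_,
      n_planted = nrow(planted), n_significant = length(sig))
  }
  out
}

#' Render a plain-text pipeline report
#'
#' Counts per executed step, the hub tables, and — when simulated ground
#' truth is available — planted-truth recovery (DEG sensitivity/FDR and
#' enriched-term recovery).
#'
#' @param run A `knocknet_run`.
#' @return Character vector of report lines.
#' @export
render_report <- function(run) {
  stopifnot(inherits(run, "knocknet_run"))
  lines <- c("knocknet pipeline report",
             "========================", "")
  for (entry in run$log) {
    lines <- c(lines, sprintf("step %-9s %s", entry$step,
                              paste(sprintf("%s=%s", names(entry$counts),
                                            entry$counts),
                                    collapse = "  ")))
  }
  fmt_hubs <- function(h, title) {
    c("", title,
      sprintf("  %-14s %-8s %3s %3s %3s", "node", "style", "out", "in",
              "deg"),
      sprintf("  %-14s %-8s %3d %3d %3d", h$id, h$style, h$outdegree,
              h$indegree, h$degree))
  }
  if (!is.null(run$pathway_hubs) && nrow(run$pathway_hubs))
    lines <- c(lines, fmt_hubs(run$pathway_hubs, "Top pathway-net hubs"))
  if (!is.null(run$signal_hubs) && nrow(run$signal_hubs))
    lines <- c(lines, fmt_hubs(run$signal_hubs, "Top signal-net hubs"))
  rec <- truth_recovery(run)
  if (!is.null(rec)) {
    lines <- c(lines, "", "Planted-truth recovery")
    if (!is.null(rec$deg))
      lines <- c(lines, sprintf(
        "  DEG sensitivity %.3f, empirical FDR %.3f (%d called / %d true)",
        rec$deg$sensitivity, rec$deg$fdr, rec$deg$n_called,
        rec$deg$n_true))
    if (!is.null(rec$enrichment))
      lines <- c(lines, sprintf(
        "  enriched-term recovery %.3f (%d planted)",
        rec$enrichment$sensitivity, rec$enrichment$n_planted))
  }
  if (!is.null(run$concordance))
    lines <- c(lines, "", sprintf(
      "qPCR concordance: %.0f%% of %d genes agree in direction",
      100 * run$concordance$fraction_concordant,
      nrow(run$concordance$table)))
  lines
}

#' @export
print.knocknet_run <- function(x, ...) {
  cat("knocknet pipeline run —", length(x$log), "steps\n")
  for (entry in x$log)
    cat(sprintf("  %-9s %s\n", entry$step,
                paste(sprintf("%s=%s", names(entry$counts), entry$counts),
                      collapse = "  ")))
  invisible(x)
}
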