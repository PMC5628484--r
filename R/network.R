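# Pathway-net and signal-net construction ------------------------------------
#
# Parses KGML-subset relation documents into typed directed relations, then
# builds two graphs: the pathway-net (nodes = significantly enriched
# pathways, edges = pathway-pathway maplinks) and the signal-net (nodes =
# called DEGs, edges = gene-gene interactions). Hubs are ranked by degree =
# outdegree + indegree, counted over distinct neighbors.

.KNOWN_SUBTYPES <- c("activation", "inhibition", "phosphorylation",
                     "binding", "binding/association", "maplink")

#' Parse a KGML-subset document into a relation list
#'
#' Understands the KGML dialect subset: `entry` elements with `id`, `name`
#' (one or more whitespace-separated ids) and `type` (`gene` or `map`), and
#' `relation` elements with `entry1`, `entry2` and `subtype` children.
#' A relation between gene entries yields one gene-level relation per
#' (entry1 id) x (entry2 id) pair, directed entry1 -> entry2, typed by the
#' subtype name (unknown subtypes map to `other` with a warning). A
#' relation touching a `map` entry yields a single pathway-level `maplink`
#' relation; a gene entry on one side is replaced by the document's own
#' pathway id.
#'
#' @param x Path to a KGML XML file, or a single XML string.
#' @return Data frame `level` (`gene`/`pathway`), `source`, `target`,
#'   `type`, `document` — one row per relation; empty when the document has
#'   no relation elements.
#' @export
parse_kgml <- function(x) {
  doc <- tryCatch(xml2::read_xml(x), error = function(e)
    stop("malformed KGML document '", substr(paste(x, collapse = " "), 1, 60),
         "': ", conditionMessage(e)))
  doc_id <- xml2::xml_attr(xml2::xml_root(doc), "name")
  if (is.na(doc_id)) doc_id <- "unnamed"

  entries <- xml2::xml_find_all(doc, ".//entry")
  ids <- xml2::xml_attr(entries, "id")
  types <- xml2::xml_attr(entries, "type")
  names_split <- strsplit(trimws(xml2::xml_attr(entries, "name")), "\\s+")
  entry_tab <- stats::setNames(
    Map(function(t, nm) list(type = t, ids = nm), types, names_split), ids)

  rels <- xml2::xml_find_all(doc, ".//relation")
  empty <- data.frame(level = character(), source = character(),
                      target = character(), type = character(),
                      document = character(), stringsAsFactors = FALSE)
  if (length(rels) == 0) return(empty)

  out <- vector("list", length(rels))
  for (i in seq_along(rels)) {
    r <- rels[[i]]
    e1 <- entry_tab[[xml2::xml_attr(r, "entry1")]]
    e2 <- entry_tab[[xml2::xml_attr(r, "entry2")]]
    if (is.null(e1) || is.null(e2)) {
      warning("relation in '", doc_id, "' references an unknown entry; skipped")
      next
    }
    subtypes <- xml2::xml_attr(xml2::xml_find_all(r, "./subtype"), "name")
    if (length(subtypes) == 0) subtypes <- NA_character_

    if (identical(e1$type, "map") || identical(e2$type, "map")) {
      src <- if (identical(e1$type, "map")) e1$ids[1] else doc_id
      tgt <- if (identical(e2$type, "map")) e2$ids[1] else doc_id
      out[[i]] <- data.frame(level = "pathway", source = src, target = tgt,
                             type = "maplink", document = doc_id,
                             stringsAsFactors = FALSE)
    } else {
      unknown <- !is.na(subtypes) & !(subtypes %in% .KNOWN_SUBTYPES)
      if (any(unknown))
        warning("unknown relation subtype(s) in '", doc_id, "': ",
                paste(unique(subtypes[unknown]), collapse = ", "),
                " mapped to 'other'")
      subtypes[is.na(subtypes) | unknown] <- "other"
      grid <- expand.grid(source = e1$ids, target = e2$ids,
                          type = subtypes, stringsAsFactors = FALSE)
      out[[i]] <- data.frame(level = "gene", source = grid$source,
                             target = grid$target, type = grid$type,
                             document = doc_id, stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Parse every KGML document in a directory (or a set of strings)
#'
#' @param x Directory containing `.xml` files, a character vector of file
#'   paths, or a named character vector of XML strings (as produced by
#'   [simulate_relations()]).
#' @return Combined relation data frame, row-order independent of the
#'   listing order in the sense that downstream graphs are identical.
#' @export
parse_kgml_set <- function(x) {
  if (length(x) == 1 && dir.exists(x))
    x <- sort(list.files(x, pattern = "\\.xml$", full.names = TRUE))
  parts <- lapply(x, parse_kgml)
  res <- do.call(rbind, parts)
  if (is.null(res))
    res <- data.frame(level = character(), source = character(),
                      target = character(), type = character(),
                      document = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# Internal constructor: deduplicate ordered pairs, merge types, drop
# self-loops, restrict to the supplied node set.
.relation_graph <- function(nodes, relations, level) {
  stopifnot(is.data.frame(nodes), all(c("id", "style") %in% names(nodes)))
  if (is.null(nodes$name)) nodes$name <- nodes$id
  rel <- relations[relations$level == level &
                     relations$source %in% nodes$id &
                     relations$target %in% nodes$id &
                     relations$source != relations$target, , drop = FALSE]
  if (nrow(rel)) {
    key <- paste(rel$source, rel$target, sep = "\r")
    split_idx <- split(seq_len(nrow(rel)), key)
    edges <- do.call(rbind, lapply(split_idx, function(ix) {
      data.frame(from = rel$source[ix[1]], to = rel$target[ix[1]],
                 types = paste(sort(rel$type[ix]), collapse = ","),
                 n_relations = length(ix), stringsAsFactors = FALSE)
    }))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  } else {
    edges <- data.frame(from = character(), to = character(),
                        types = character(), n_relations = integer(),
                        stringsAsFactors = FALSE)
  }
  nodes <- nodes[order(nodes$id), c("id", "name", "style"), drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, level = level),
            class = "relation_graph")
}

#' @export
print.relation_graph <- function(x, ...) {
  cat(sprintf("relation_graph (%s level): %d nodes, %d directed edges\n",
              x$level, nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) {
    st <- table(x$nodes$style)
    cat("  styles:", paste(sprintf("%s=%d", names(st), st), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Build the pathway-net
#'
#' Directed pathway-pathway crosstalk graph: nodes are the significantly
#' enriched pathways (styled up / down / up_down by [assign_style()]);
#' edges are pathway-level maplink relations with **both** endpoints
#' significant, deduplicated by ordered pair, self-loops dropped. The edge
#' tail is the regulating pathway.
#'
#' @param significant Data frame `term_id`, `style` (output of
#'   [assign_style()]), optionally a `name` column.
#' @param relations Relation data frame from [parse_kgml_set()].
#' @return A `relation_graph`.
#' @export
build_pathway_net <- function(significant, relations) {
  stopifnot(is.data.frame(significant),
            all(c("term_id", "style") %in% names(significant)))
  nodes <- data.frame(id = significant$term_id,
                      name = if (!is.null(significant$name))
                        significant$name else significant$term_id,
                      style = significant$style, stringsAsFactors = FALSE)
  .relation_graph(nodes, relations, level = "pathway")
}

#' Build the signal-net
#'
#' Directed gene-gene interaction graph over the called DEGs: edges are
#' gene-level relations whose endpoints are both called DEGs
#' (deduplicated by ordered pair, types merged, self-loops dropped); nodes
#' are the called DEGs with at least one qualifying edge, styled by their
#' DEG direction.
#'
#' @param degs A `deg_table` from [deg_screen()].
#' @param relations Relation data frame from [parse_kgml_set()].
#' @return A `relation_graph`.
#' @export
build_signal_net <- function(degs, relations) {
  stopifnot(is.data.frame(degs), !is.null(degs$direction))
  called <- degs[degs$direction %in% c("up", "down"), , drop = FALSE]
  nodes <- data.frame(id = called$gene_id, name = called$gene_id,
                      style = called$direction, stringsAsFactors = FALSE)
  g <- .relation_graph(nodes, relations, level = "gene")
  keep <- g$nodes$id %in% c(g$edges$from, g$edges$to)
  g$nodes <- g$nodes[keep, , drop = FALSE]
  rownames(g$nodes) <- NULL
  g
}

#' Per-node degree records
#'
#' Outdegree = number of distinct downstream neighbors, indegree = number
#' of distinct upstream neighbors, degree = their sum (the hub-ranking
#' statistic). Edges are already deduplicated ordered pairs, so parallel
#' relations never inflate the counts.
#'
#' @param graph A `relation_graph`.
#' @return Data frame `id`, `name`, `style`, `outdegree`, `indegree`,
#'   `degree`.
#' @export
node_degrees <- function(graph) {
  stopifnot(inherits(graph, "relation_graph"))
  ids <- graph$nodes$id
  outd <- table(factor(graph$edges$from, levels = ids))
  ind <- table(factor(graph$edges$to, levels = ids))
  data.frame(id = ids, name = graph$nodes$name, style = graph$nodes$style,
             outdegree = as.integer(outd), indegree = as.integer(ind),
             degree = as.integer(outd) + as.integer(ind),
             stringsAsFactors = FALSE)
}

#' Rank hub nodes by degree
#'
#' Sorts degree records by degree descending, breaking ties by outdegree
#' descending and then node id ascending, and returns the top rows —
#' the style/outdegree/indegree/degree layout of a published hub table.
#'
#' @param records Degree records from [node_degrees()].
#' @param top Number of rows to keep (clamped to the node count).
#' @return The top rows of `records`, re-ordered.
#' @export
rank_hubs <- function(records, top = 10L) {
  stopifnot(is.data.frame(records),
            all(c("degree", "outdegree", "id") %in% names(records)))
  if (top < 1) stop("top must be >= 1")
  ord <- order(-records$degree, -records$outdegree, records$id)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top)
}

#' Per-pathway DEG membership overlay
#'
#' For each pathway gene set, lists and counts the up- and down-regulated
#' DEG members — the tabular equivalent of coloring DEGs on a pathway map.
#'
#' @param pathway_sets List of term records (`id`, `name`, `genes`).
#' @param degs A `deg_table`.
#' @return Data frame `term_id`, `name`, `n_up`, `n_down`, `up_genes`,
#'   `down_genes` (member lists collapsed with `;`).
#' @export
pathway_deg_overlay <- function(pathway_sets, degs) {
  stopifnot(is.data.frame(degs), !is.null(degs$direction))
  up <- degs$gene_id[degs$direction == "up"]
  down <- degs$gene_id[degs$direction == "down"]
  rows <- lapply(pathway_sets, function(s) {
    u <- sort(intersect(s$genes, up))
    d <- sort(intersect(s$genes, down))
    data.frame(term_id = s$id, name = s$name,
               n_up = length(u), n_down = length(d),
               up_genes = paste(u, collapse = ";"),
               down_genes = paste(d, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert a relation graph to igraph
#'
#' @param graph A `relation_graph`.
#' @return An [igraph::graph][igraph] directed graph with `style` vertex
#'   attributes and `types` edge attributes.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "relation_graph"))
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = graph$nodes)
}

#' Export a relation graph as GraphML or SIF
#'
#' GraphML goes through igraph; SIF (simple interaction format) writes one
#' `source type target` line per edge using the merged type string.
#'
#' @param graph A `relation_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_sif <- function(graph, path) {
  lines <- if (nrow(graph$edges))
    sprintf("%s\t%s\t%s", graph$edges$from, graph$edges$types,
            graph$edges$to) else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write a hub table TSV
#'
#' Column layout mirrors published hub tables: name, style, outdegree,
#' indegree, degree.
#'
#' @param records Output of [rank_hubs()] / [node_degrees()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_hub_table <- function(records, path) {
  utils::write.table(records[, c("id", "name", "style", "outdegree",
                                 "indegree", "degree")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
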