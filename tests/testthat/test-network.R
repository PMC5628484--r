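test_that("the KGML parser handles empty, single and multi-id relations", {
  ents <- list(list(id = 1, name = "hsa:10", type = "gene"),
               list(id = 2, name = "hsa:20", type = "gene"),
               list(id = 3, name = "hsa:30 hsa:31", type = "gene"),
               list(id = 4, name = "hsa:40 hsa:41 hsa:42", type = "gene"),
               list(id = 5, name = "path:x02", type = "map"))

  empty <- parse_kgml(kgml_fixture(ents, list()))
  expect_equal(nrow(empty), 0)

  one <- parse_kgml(kgml_fixture(
    ents, list(list(e1 = 1, e2 = 2, subtype = "activation"))))
  expect_equal(nrow(one), 1)
  expect_identical(one$source, "hsa:10")
  expect_identical(one$target, "hsa:20")
  expect_identical(one$type, "activation")
  expect_identical(one$level, "gene")

  cross <- parse_kgml(kgml_fixture(
    ents, list(list(e1 = 3, e2 = 4, subtype = "inhibition"))))
  expect_equal(nrow(cross), 6)   # 2 x 3 id cross product
  expect_setequal(cross$source, c("hsa:30", "hsa:31"))
  expect_setequal(cross$target, c("hsa:40", "hsa:41", "hsa:42"))

  maplink <- parse_kgml(kgml_fixture(
    ents, list(list(e1 = 1, e2 = 5, subtype = "maplink"))))
  expect_identical(maplink$level, "pathway")
  expect_identical(maplink$source, "path:test01")  # document's own pathway
  expect_identical(maplink$target, "path:x02")
  expect_identical(maplink$type, "maplink")

  expect_warning(
    odd <- parse_kgml(kgml_fixture(
      ents, list(list(e1 = 1, e2 = 2, subtype = "teleportation")))),
    "teleportation")
  expect_identical(odd$type, "other")

  expect_error(parse_kgml("<pathway><entry></pathway>"), "malformed")
})

test_that("signal-net keeps only DEG-DEG edges and merges duplicates", {
  degs <- data.frame(
    gene_id = c("A", "B", "C", "D", "E"),
    fc = c(3, 3, 0.2, 3, 1),
    adj_p = c(0.01, 0.01, 0.01, 0.01, 0.5))
  degs <- call_degs(degs)
  rel <- data.frame(
    level = "gene",
    source = c("A", "B", "A", "X", "A", "A"),
    target = c("B", "C", "C", "Y", "B", "A"),
    type = c("activation", "binding", "inhibition", "activation",
             "phosphorylation", "binding"),
    document = "d1", stringsAsFactors = FALSE)
  g <- build_signal_net(degs, rel)
  expect_setequal(g$nodes$id, c("A", "B", "C"))   # D isolated, E not called
  expect_equal(nrow(g$edges), 3)                  # A->B deduplicated, A->A dropped
  ab <- g$edges[g$edges$from == "A" & g$edges$to == "B", ]
  expect_equal(ab$n_relations, 2)                 # type multiset of size 2
  expect_identical(ab$types, "activation,phosphorylation")
  expect_identical(g$nodes$style[g$nodes$id == "C"], "down")

  none <- build_signal_net(degs[degs$gene_id == "E", ], rel)
  expect_equal(nrow(none$nodes), 0)
  expect_equal(nrow(none$edges), 0)
})

test_that("pathway-net keeps only edges between significant pathways", {
  sig <- data.frame(term_id = c("path:a", "path:b", "path:c"),
                    style = c("up", "down", "up_down"))
  rel <- data.frame(
    level = c("pathway", "pathway", "pathway", "gene"),
    source = c("path:a", "path:b", "path:z", "path:a"),
    target = c("path:b", "path:c", "path:a", "path:b"),
    type = "maplink", document = "d", stringsAsFactors = FALSE)
  g <- build_pathway_net(sig, rel)
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$edges), 2)   # path:z edge excluded; gene-level ignored
  expect_false("path:z" %in% c(g$edges$from, g$edges$to))

  iso <- build_pathway_net(sig, rel[0, ])
  expect_equal(nrow(iso$nodes), 3)
  expect_equal(nrow(iso$edges), 0)
  expect_true(all(node_degrees(iso)$degree == 0))
})

test_that("degrees count distinct neighbors; brute force and igraph agree", {
  set.seed(61)
  for (rep in 1:5) {
    n <- sample(20:120, 1)
    ids <- sprintf("N%03d", seq_len(n))
    m <- sample(50:400, 1)
    rel <- data.frame(level = "gene",
                      source = sample(ids, m, replace = TRUE),
                      target = sample(ids, m, replace = TRUE),
                      type = "activation", document = "d",
                      stringsAsFactors = FALSE)
    degs <- call_degs(data.frame(gene_id = ids, fc = 4,
                                 adj_p = 0.001))
    g <- build_signal_net(degs, rel)
    d <- node_degrees(g)
    expect_identical(d$degree, d$outdegree + d$indegree)
    # brute force over the deduplicated edge list
    o <- oracle_degrees(d$id, g$edges$from, g$edges$to)
    expect_identical(d$outdegree, o$outdegree)
    expect_identical(d$indegree, o$indegree)
    # sum of outdegrees = sum of indegrees = edge count
    expect_equal(sum(d$outdegree), nrow(g$edges))
    expect_equal(sum(d$indegree), nrow(g$edges))
    if (nrow(g$edges)) {
      ig <- as_igraph(g)
      expect_equal(d$outdegree[match(igraph::V(ig)$name, d$id)],
                   unname(igraph::degree(ig, mode = "out")))
      expect_equal(d$indegree[match(igraph::V(ig)$name, d$id)],
                   unname(igraph::degree(ig, mode = "in")))
    }
  }
})

test_that("graphs are invariant to relation-document order", {
  cfg <- tiny_config(seed = 67)
  sim <- simulate_study(cfg)
  rel1 <- parse_kgml_set(sim$kgml)
  rel2 <- parse_kgml_set(rev(sim$kgml))
  degs <- call_degs(data.frame(gene_id = unique(sim$probes$gene_id),
                               fc = 4, adj_p = 0.001))
  expect_identical(build_signal_net(degs, rel1),
                   build_signal_net(degs, rel2))
})

test_that("hub ranking orders by degree, outdegree, then id", {
  rec <- data.frame(id = c("Apoptosis", "MAPK", "Cancer"),
                    name = c("Apoptosis", "MAPK", "Cancer"),
                    style = "down",
                    outdegree = c(20L, 27L, 0L),
                    indegree = c(2L, 3L, 21L))
  rec$degree <- rec$outdegree + rec$indegree
  expect_identical(rank_hubs(rec, 3)$id, c("MAPK", "Apoptosis", "Cancer"))
  # all-equal degrees fall back to outdegree then lexicographic id
  tie <- data.frame(id = c("b", "a", "c"), name = c("b", "a", "c"),
                    style = "up", outdegree = c(1L, 1L, 2L),
                    indegree = c(2L, 2L, 1L))
  tie$degree <- 3L
  expect_identical(rank_hubs(tie, 5)$id, c("c", "a", "b"))
  expect_equal(nrow(rank_hubs(tie, 100)), 3)   # clamped
  expect_error(rank_hubs(tie, 0), "top")
})

test_that("the pathway overlay counts up/down members exactly", {
  degs <- call_degs(data.frame(
    gene_id = sprintf("g%02d", 1:20),
    fc = c(rep(4, 7), rep(0.2, 8), rep(1, 5)),
    adj_p = 0.001))
  sets <- list(list(id = "P1", name = "p one",
                    genes = sprintf("g%02d", 1:20)),
               list(id = "P2", name = "p two",
                    genes = c("g16", "g17", "zz")))
  ov <- pathway_deg_overlay(sets, degs)
  expect_equal(ov$n_up[ov$term_id == "P1"], 7)
  expect_equal(ov$n_down[ov$term_id == "P1"], 8)
  expect_equal(ov$n_up[ov$term_id == "P2"] + ov$n_down[ov$term_id == "P2"],
               0)
  # brute-force set intersections
  up <- degs$gene_id[degs$direction == "up"]
  expect_equal(ov$n_up, vapply(sets, function(s)
    length(intersect(s$genes, up)), 1L))
})

test_that("SIF and GraphML exports round-trip the edge set", {
  sig <- data.frame(term_id = c("path:a", "path:b"), style = c("up", "down"))
  rel <- data.frame(level = "pathway", source = "path:a",
                    target = "path:b", type = "maplink", document = "d",
                    stringsAsFactors = FALSE)
  g <- build_pathway_net(sig, rel)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(g, sif)
  expect_identical(readLines(sif), "path:a\tmaplink\tpath:b")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), 1)
  expect_setequal(igraph::V(back)$name, c("path:a", "path:b"))
})
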