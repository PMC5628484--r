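test_that("planted effects are exact in the zero-noise limit", {
  cfg <- tiny_config(noise_sd = 1e-9, effect_log2fc = 2, frac_deg = 0.1)
  sim <- simulate_expression(cfg)
  log2mat <- log2(sim$probes$intensity)
  gene_means <- rowsum(log2mat, sim$probes$gene_id) /
    as.vector(table(sim$probes$gene_id)[sort(unique(sim$probes$gene_id))])
  diff <- rowMeans(gene_means[, sim$groups == "KD"]) -
    rowMeans(gene_means[, sim$groups == "NC"])
  truth <- sim$truth$deg
  expect_equal(unname(diff[truth$gene_id]), truth$log2fc, tolerance = 1e-6)
  others <- setdiff(names(diff), truth$gene_id)
  expect_lt(max(abs(diff[others])), 1e-6)
})

test_that("the planted DEG count follows frac_deg exactly", {
  sim <- simulate_expression(sim_config(n_genes = 5000, frac_deg = 0.02,
                                        seed = 1))
  expect_equal(nrow(sim$truth$deg), 100L)
  expect_true(all(sim$truth$deg$gene_id %in% sim$probes$gene_id))
  # up/down split is the neutral 50/50 default
  expect_equal(sum(sim$truth$deg$direction == "up"), 50L)
})

test_that("a positive frac_deg that plants no genes errors; zero is a valid null", {
  expect_error(simulate_expression(tiny_config(n_genes = 100,
                                               frac_deg = 0.001)),
               "no DEGs plantable")
  sim <- simulate_expression(tiny_config(frac_deg = 0))
  expect_equal(nrow(sim$truth$deg), 0L)
})

test_that("the full bundle is deterministic, including written bytes", {
  cfg <- tiny_config()
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$probes$intensity, s2$probes$intensity)
  expect_identical(s1$terms, s2$terms)
  expect_identical(s1$kgml, s2$kgml)
  expect_identical(s1$truth, s2$truth)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(s1, d1); write_study(s2, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f1))))
})

test_that("annotation respects cardinality, the null case, and set sizes", {
  cfg <- tiny_config(n_terms = 50, frac_enriched_terms = 0)
  sim <- simulate_annotation(cfg, simulate_expression(cfg))
  go <- Filter(function(t) t$category == "GO", sim$terms)
  expect_length(go, 50)
  expect_equal(nrow(sim$truth$enriched_terms), 0L)
  sizes <- lengths(lapply(go, `[[`, "genes"))
  expect_true(all(sizes >= cfg$term_size_range[1] &
                    sizes <= cfg$term_size_range[2]))
  # members are unique gene ids from the universe
  expect_true(all(vapply(go, function(t) !anyDuplicated(t$genes),
                         logical(1))))

  expect_error(
    simulate_annotation(tiny_config(term_size_range = c(500L, 600L)),
                        simulate_expression(cfg)),
    "exceeds the gene universe")
})

test_that("planted enriched terms over-sample one DEG direction and stand out", {
  cfg <- tiny_config(n_genes = 400, frac_deg = 0.25,
                     frac_enriched_terms = 0.2, n_terms = 20,
                     term_size_range = c(20L, 20L))
  sim <- simulate_annotation(cfg, simulate_expression(cfg))
  truth <- sim$truth$enriched_terms
  expect_gt(nrow(truth), 0)
  deg_dir <- split(sim$truth$deg$gene_id, sim$truth$deg$direction)
  universe <- unique(sim$probes$gene_id)
  go <- Filter(function(t) t$category == "GO", sim$terms)
  ids <- vapply(go, `[[`, "", "id")
  p_of <- function(t) {
    k <- length(intersect(t$genes, unlist(deg_dir)))
    oracle_fisher(k, length(t$genes), length(unlist(deg_dir)),
                  length(universe))
  }
  go_truth <- truth[truth$category == "GO", ]
  for (i in seq_len(nrow(go_truth))) {
    term <- go[[match(go_truth$term_id[i], ids)]]
    core <- intersect(term$genes, deg_dir[[go_truth$direction[i]]])
    expect_gte(length(core), length(term$genes) / 2)
  }
  planted_p <- vapply(go[ids %in% go_truth$term_id], p_of, 1)
  null_p <- vapply(go[!ids %in% go_truth$term_id], p_of, 1)
  expect_lt(max(planted_p), median(null_p))
})

test_that("relation documents round-trip through the parser", {
  cfg <- tiny_config(n_pathway_links = 10)
  sim <- simulate_relations(cfg, simulate_expression(cfg))
  expect_equal(sum(sim$truth$edges$type == "maplink"), 10L)

  parsed <- parse_kgml_set(sim$kgml)
  key <- function(df) sort(paste(df$level, df$source, df$target, df$type))
  expect_identical(key(parsed), key(sim$truth$edges))

  # empty relation case: documents still carry entries but no relations
  cfg0 <- tiny_config(n_gene_relations = 0, n_pathway_links = 0)
  sim0 <- simulate_relations(cfg0, simulate_expression(cfg0))
  expect_equal(nrow(sim0$truth$edges), 0L)
  parsed0 <- parse_kgml_set(sim0$kgml)
  expect_equal(nrow(parsed0), 0L)
  expect_true(all(grepl("<entry", sim0$kgml)))
})

test_that("qPCR Ct tables encode the planted fold changes", {
  cfg <- tiny_config(frac_deg = 0.1, noise_sd = 0.25)
  sim <- simulate_qpcr(cfg, simulate_expression(cfg), ct_sd = 1e-4)
  rel <- qpcr_relative(sim$qpcr)
  truth <- sim$truth$deg
  hit <- intersect(rel$gene, truth$gene_id)
  expect_gt(length(hit), 0)
  expect_equal(log2(rel$rel_expr[match(hit, rel$gene)]),
               truth$log2fc[match(hit, truth$gene_id)], tolerance = 0.01)
})
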