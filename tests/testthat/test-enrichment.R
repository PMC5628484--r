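test_that("two-sided Fisher p hits closed forms and the enumeration oracle", {
  expect_equal(fisher_two_sided(2, 4, 4, 8), 1.0)
  expect_equal(fisher_two_sided(7, 7, 7, 7), 1.0)
  expect_equal(fisher_two_sided(5, 10, 50, 1000),
               oracle_fisher(5, 10, 50, 1000), tolerance = 1e-12)
  expect_error(fisher_two_sided(5, 4, 10, 100), "inconsistent")
  expect_error(fisher_two_sided(3, 10, 4, 8), "inconsistent")
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(51)
  for (rep in 1:30) {
    N <- sample(10:200, 1)
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    sup <- max(0, K + n - N):min(K, n)
    k <- sup[sample.int(length(sup), 1)]
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
    expect_equal(fisher_two_sided(k, K, n, N),
                 fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher p is invariant under row and column swaps", {
  set.seed(52)
  for (rep in 1:20) {
    N <- sample(8:60, 1)
    K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    sup <- max(0, K + n - N):min(K, n)
    k <- sup[sample.int(length(sup), 1)]
    p <- fisher_two_sided(k, K, n, N)
    # swap columns: DEG list <-> complement
    expect_equal(fisher_two_sided(K - k, K, N - n, N), p, tolerance = 1e-12)
    # swap rows: term <-> complement
    expect_equal(fisher_two_sided(n - k, N - K, n, N), p, tolerance = 1e-12)
  }
})

test_that("chi-square companion matches the closed-form statistic", {
  flat <- chi2_test(10, 20, 20, 40)   # identical row proportions
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  sym <- chi2_test(10, 20, 20, 40)
  expect_equal(sym$p, 1)

  # table (8,2; 12,78): a=8, b=2, c=12, d=78
  res <- chi2_test(8, 10, 20, 100)
  a <- 8; b <- 2; c <- 12; d <- 78; N <- 100
  stat <- N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(res$statistic, stat, tolerance = 1e-10)
  expect_equal(res$p, pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_error(chi2_test(0, 0, 5, 10), "degenerate")
})

test_that("enrich_direction builds correct contingencies and drops orphans", {
  bg <- sprintf("g%02d", 1:40)
  db <- list(list(id = "T1", name = "t1", category = "GO",
                  genes = bg[1:10]),
             list(id = "T2", name = "t2", category = "GO",
                  genes = bg[5:20]),
             list(id = "T3", name = "t3", category = "GO",
                  genes = c("zz1", "zz2")))
  expect_warning(res <- enrich_direction(bg, db, bg), "dropped")
  expect_equal(nrow(res), 2)             # orphan term gone
  expect_true(all(res$k == res$K))       # saturation: every term fully hit
  expect_true(all(res$p == 1))

  res2 <- suppressWarnings(enrich_direction(bg[1:8], db, bg))
  r1 <- res2[res2$term_id == "T1", ]
  expect_equal(r1$k, 8); expect_equal(r1$K, 10)
  expect_equal(r1$n, 8); expect_equal(r1$N, 40)
  expect_equal(r1$p, oracle_fisher(8, 10, 8, 40), tolerance = 1e-12)
  expect_equal(r1$neg_lg_p, -log10(r1$p))
  expect_equal(res2$adj_p, oracle_bh(res2$p))
  expect_error(enrich_direction(bg[1:2], db, character(0)), "background")
  expect_error(enrich_direction(c(bg[1], "nope"), db, bg), "subset")
})

test_that("style assignment merges the two directional runs", {
  expect_identical(assign_style(c("A", "B"), c("B", "C")),
                   data.frame(term_id = c("A", "B", "C"),
                              style = c("up", "up_down", "down"),
                              stringsAsFactors = FALSE))
  expect_equal(nrow(assign_style(character(0), character(0))), 0)
  # disjoint runs of sizes 111 and 125 style exactly 236 terms
  sty <- assign_style(sprintf("up%03d", 1:111), sprintf("dn%03d", 1:125))
  expect_equal(nrow(sty), 236)
  expect_equal(sum(sty$style == "up"), 111)
  expect_equal(sum(sty$style == "down"), 125)
})

test_that("null enrichment keeps false positives at the FDR level", {
  cfg <- tiny_config(n_genes = 500, frac_deg = 0.1,
                     frac_enriched_terms = 0, n_terms = 100, seed = 23)
  sim <- simulate_annotation(cfg, simulate_expression(cfg))
  bg <- unique(sim$probes$gene_id)
  fake_deg <- sim$truth$deg$gene_id
  res <- enrich_direction(fake_deg,
                          Filter(function(t) t$category == "GO", sim$terms),
                          bg)
  expect_lte(sum(res$significant), 0.05 * nrow(res) + 2)
})

test_that("planted enriched terms are recovered at FDR 0.05", {
  cfg <- sim_config(n_genes = 2000, frac_deg = 0.05,
                    frac_enriched_terms = 0.15, n_terms = 60,
                    term_size_range = c(15L, 40L), seed = 29)
  sim <- simulate_annotation(cfg, simulate_expression(cfg))
  bg <- unique(sim$probes$gene_id)
  deg <- sim$truth$deg
  go <- Filter(function(t) t$category == "GO", sim$terms)
  sig_up <- enrich_direction(deg$gene_id[deg$direction == "up"], go, bg)
  sig_down <- enrich_direction(deg$gene_id[deg$direction == "down"], go, bg)
  sty <- assign_style(sig_up, sig_down)
  planted <- sim$truth$enriched_terms
  planted <- planted[planted$category == "GO", ]
  recov <- mean(planted$term_id %in% sty$term_id)
  expect_gte(recov, 0.9)
})
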