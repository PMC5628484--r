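# Independent oracles used across the suite. Each is deliberately written
# from the definition, not by calling the implementation it checks.

# Two-sided Fisher p by explicit enumeration over the hypergeometric
# support, point probabilities from binomial-coefficient arithmetic.
oracle_fisher <- function(k, K, n, N) {
  sup <- max(0, K + n - N):min(K, n)
  lp <- lchoose(K, sup) + lchoose(N - K, n - sup) - lchoose(N, n)
  pr <- exp(lp)
  min(1, sum(pr[pr <= pr[sup == k] * (1 + 1e-7)]))
}

# Brute-force Benjamini-Hochberg: adj(i) = min over j with p_j >= p_i of
# p_(j) * n / rank(j), quadratic time straight from the step-up definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# Independent median polish: literal alternating row/column median sweeps.
oracle_medpolish <- function(x, eps = 1e-6, maxiter = 10L) {
  overall <- 0
  row_eff <- rep(0, nrow(x))
  col_eff <- rep(0, ncol(x))
  r <- x
  oldsum <- 0
  for (it in seq_len(maxiter)) {
    rmed <- apply(r, 1, median)
    r <- r - rmed
    row_eff <- row_eff + rmed
    cmed <- median(col_eff)
    overall <- overall + cmed
    col_eff <- col_eff - cmed
    cmed2 <- apply(r, 2, median)
    r <- r - matrix(cmed2, nrow(x), ncol(x), byrow = TRUE)
    col_eff <- col_eff + cmed2
    rmed2 <- median(row_eff)
    overall <- overall + rmed2
    row_eff <- row_eff - rmed2
    newsum <- sum(abs(r))
    if (newsum == 0 || abs(newsum - oldsum) < eps * newsum) break
    oldsum <- newsum
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = r)
}

# Quantile normalization by sort / average / unsort, no tie handling needed
# when inputs are generated without ties.
oracle_quantile_norm <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) out[, j] <- ref[rank(x[, j])]
  out
}

# Degree counts straight off an edge list of distinct ordered pairs.
oracle_degrees <- function(ids, from, to) {
  data.frame(
    id = ids,
    outdegree = vapply(ids, function(i) length(unique(to[from == i])), 1L),
    indegree = vapply(ids, function(i) length(unique(from[to == i])), 1L),
    stringsAsFactors = FALSE)
}

# Small simulation config used by several files.
tiny_config <- function(...) {
  defaults <- list(n_genes = 120, n_probes_per_gene = 3, n_terms = 15,
                   term_size_range = c(5L, 15L), n_pathways = 6,
                   n_pathway_links = 8, n_gene_relations = 25, seed = 99L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Minimal KGML document builder for parser fixtures.
kgml_fixture <- function(entries, relations, pathway = "path:test01") {
  ent <- paste(sprintf('<entry id="%s" name="%s" type="%s"/>',
                       as.character(sapply(entries, `[[`, "id")),
                       as.character(sapply(entries, `[[`, "name")),
                       as.character(sapply(entries, `[[`, "type"))),
               collapse = "\n")
  rel <- paste(vapply(relations, function(r) {
    sub <- if (is.null(r$subtype)) "" else
      sprintf('<subtype name="%s" value="-"/>', r$subtype)
    sprintf('<relation entry1="%s" entry2="%s" type="PPrel">%s</relation>',
            r$e1, r$e2, sub)
  }, ""), collapse = "\n")
  sprintf('<?xml version="1.0"?>\n<pathway name="%s">\n%s\n%s\n</pathway>',
          pathway, ent, rel)
}
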