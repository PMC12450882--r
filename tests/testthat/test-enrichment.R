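test_that("hypergeometric overrepresentation matches exhaustive enumeration", {
  # universe of 20, one term of 5 genes, query of 5 with overlap 4:
  # P(X >= 4) = (C(5,4)C(15,1) + C(5,5)C(15,0)) / C(20,5) = 76/15504
  genes <- sprintf("g%02d", 1:20)
  ann <- flat_annotation(list("GO:0000001" = genes[1:5]))
  query <- c(genes[1:4], genes[10])
  res <- ora(query, ann, universe = genes)
  expect_equal(res$p_value, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$statistic, 4L)

  # zero overlap: P(X >= 0) = 1
  res0 <- ora(genes[10:14], ann, universe = genes)
  expect_equal(res0$p_value, 1)
})

test_that("overrepresentation p-values agree with brute-force draws", {
  # enumerate every C(N, nq) query of a small universe and count draws with
  # an overlap at least as large as observed
  set.seed(202)
  for (rep in 1:100) {
    N <- sample(8:12, 1)
    K <- sample(3:(N - 2), 1)
    nq <- sample(2:5, 1)
    genes <- sprintf("g%02d", seq_len(N))
    term_genes <- sample(genes, K)
    query <- sample(genes, nq)
    ov <- length(intersect(query, term_genes))
    draws <- utils::combn(N, nq)
    hits <- apply(draws, 2L, function(ix) {
      sum(genes[ix] %in% term_genes) >= ov
    })
    p_brute <- mean(hits)
    ann <- flat_annotation(stats::setNames(list(term_genes), "GO:0000001"))
    cfg <- enrichment_config(min_set_size = 1L)
    res <- ora(query, ann, universe = genes, config = cfg)
    expect_equal(res$p_value, p_brute, tolerance = 1e-12,
                 info = sprintf("N=%d K=%d nq=%d ov=%d", N, K, nq, ov))
  }
})

test_that("a single planted term at odds 10 ranks first in nearly all draws", {
  set.seed(303)
  n_first <- 0L
  for (rep in 1:20) {
    genes <- sprintf("g%04d", 1:2000)
    sets <- lapply(1:50, function(i) sample(genes, 30))
    names(sets) <- sprintf("GO:%07d", 1:50)
    planted <- names(sets)[[1L]]
    w <- ifelse(genes %in% sets[[planted]], 10, 1)
    query <- sample(genes, 100, prob = w)
    ann <- flat_annotation(sets)
    res <- ora(query, ann, universe = genes)
    if (res$term_id[[1L]] == planted) n_first <- n_first + 1L
  }
  expect_gte(n_first, 18L)
})

test_that("ORA null p-values are super-uniform (conservative type-I error)", {
  cfg <- synthetic_config(seed = 1)
  g <- parse_obo(generate_ontology(cfg)$obo)
  ann <- suppressMessages(generate_annotation(g, cfg))$annotation
  set.seed(404)
  ps <- unlist(lapply(1:200, function(i) {
    ora(sample(ann$universe, 50), ann)$p_value
  }))
  expect_lte(mean(ps <= 0.05), 0.07)
})

test_that("enrichment scores hit the analytic edge cases", {
  genes <- sprintf("g%02d", 1:10)
  fc <- seq(5, 0.5, length.out = 10)
  rk <- make_ranked(genes, fc)
  # set = top-ranked gene only: full normalized weight at position 1
  top <- gsea_enrichment_score(rk, genes[[1L]])
  expect_equal(top$es, 1.0)
  expect_identical(top$leading_edge, genes[[1L]])
  # set = every ranked gene: no misses, the sum reaches 1 at the end
  all_g <- gsea_enrichment_score(rk, genes)
  expect_equal(all_g$es, 1.0)
  # disjoint set: warning sentinel, not a crash
  expect_warning(res <- gsea_enrichment_score(rk, c("zz1", "zz2")),
                 "no gene")
  expect_null(res)
})

test_that("enrichment scores equal an independent step-by-step loop", {
  set.seed(505)
  for (rep in 1:100) {
    genes <- sprintf("g%02d", 1:10)
    fc <- round(stats::rnorm(10), 3)
    k <- sample(1:9, 1)
    gs <- sample(genes, k)
    q <- sample(c(0, 1), 1)
    rk <- make_ranked(genes, fc)
    es_pkg <- gsea_enrichment_score(rk, gs, weight_exponent = q)$es
    expect_es_equal(es_pkg, loop_extrema(genes, fc, gs, q = q),
                    info = sprintf("rep=%d k=%d q=%d", rep, k, q))
    expect_lte(abs(es_pkg), 1)
  }
})

test_that("enrichment scores agree with an independent GSEA implementation", {
  # cross-check against fgsea's statistic on random instances
  set.seed(606)
  for (rep in 1:25) {
    n <- 50L
    genes <- sprintf("g%03d", seq_len(n))
    fc <- stats::rnorm(n)
    gs <- sample(genes, 8L)
    rk <- make_ranked(genes, fc)
    es_pkg <- gsea_enrichment_score(rk, gs)$es
    stats_sorted <- stats::setNames(rk$fold_change, rk$gene_id)
    es_ref <- fgsea::calcGseaStat(stats_sorted,
                                  selectedStats = which(rk$gene_id %in% gs),
                                  gseaParam = 1)
    expect_equal(es_pkg, es_ref, tolerance = 1e-9, info = paste("rep", rep))
  }
})

test_that("gsea is deterministic for a fixed seed and input order", {
  cfg <- synthetic_config(seed = 3, n_terms = 60L, n_genes = 400L)
  g <- parse_obo(generate_ontology(cfg)$obo)
  ann <- suppressMessages(generate_annotation(g, cfg))$annotation
  rl <- generate_ranked_list(ann, cfg)
  econf <- enrichment_config(n_permutations = 200L, seed = 11L)

  r1 <- gsea(rl$ranked, ann$term_genes, config = econf)
  r2 <- gsea(rl$ranked, ann$term_genes, config = econf)
  expect_identical(r1, r2)

  # permuting the input rows of the DE table changes nothing
  perm <- sample(nrow(rl$ranked))
  rk_perm <- ranked_gene_list(rl$ranked$gene_id[perm],
                              rl$ranked$fold_change[perm],
                              condition_label = attr(rl$ranked, "condition_label"))
  r3 <- gsea(rk_perm, ann$term_genes, config = econf)
  expect_identical(as.data.frame(r1), as.data.frame(r3))

  # shuffling the collection changes nothing either
  shuf <- sample(length(ann$term_genes))
  r4 <- gsea(rl$ranked, ann$term_genes[shuf], config = econf)
  expect_identical(as.data.frame(r1), as.data.frame(r4))
})

test_that("gsea stays deterministic under fully tied fold changes", {
  genes <- sprintf("g%02d", 1:30)
  rk1 <- make_ranked(genes, rep(0, 30))
  rk2 <- make_ranked(rev(genes), rep(0, 30))
  coll <- list("GO:0000001" = genes[1:8], "GO:0000002" = genes[10:20])
  econf <- enrichment_config(n_permutations = 100L, seed = 5L)
  r1 <- gsea(rk1, coll, config = econf)
  r2 <- gsea(rk2, coll, config = econf)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_true(all(abs(r1$statistic) <= 1))
})

test_that("planted terms are recovered by gsea at the study threshold", {
  cfg <- synthetic_config(seed = 2)
  g <- parse_obo(generate_ontology(cfg)$obo)
  ann <- suppressMessages(generate_annotation(g, cfg))$annotation
  rl <- generate_ranked_list(ann, cfg)
  res <- suppressWarnings(gsea(rl$ranked, ann$term_genes,
                               config = enrichment_config(seed = 2L)))
  sel <- select_significant(res, 0.25)
  expect_true(all(rl$truth$planted_terms %in% sel$terms))
})

test_that("null ranked lists yield few terms below the selection threshold", {
  # bounded sanity check on realised FDR behaviour under delta = 0
  n_sig <- integer(0)
  for (s in 1:3) {
    cfg <- synthetic_config(seed = s, effect_shift = 0)
    g <- parse_obo(generate_ontology(cfg)$obo)
    ann <- suppressMessages(generate_annotation(g, cfg))$annotation
    rl <- generate_ranked_list(ann, cfg)
    res <- suppressWarnings(gsea(rl$ranked, ann$term_genes,
                                 config = enrichment_config(seed = s)))
    n_sig <- c(n_sig, sum(res$fdr < 0.25))
  }
  expect_lte(max(n_sig / 195), 0.15)
})

test_that("strictly-below selection and empty records behave as specified", {
  df <- data.frame(term_id = sprintf("GO:%07d", 1:3), set_size = 10L,
                   statistic = 0.5, normalized_statistic = 1.5,
                   p_value = c(0.01, 0.02, 0.03), fdr = c(0.24, 0.25, 0.26),
                   genes = "", stringsAsFactors = FALSE)
  rec <- aoplink:::.enrichment_result(df, "gsea", "UFP 20h")
  sel <- select_significant(rec, 0.25)
  expect_identical(sel$terms, "GO:0000001")   # 0.25 itself is excluded
  expect_identical(sel$source_label, "UFP 20h")
  sel0 <- select_significant(rec[0, ], 0.25)
  expect_equal(sel0$unique_count, 0L)
})

test_that("duplicate gene ids collapse to the largest absolute fold change", {
  expect_message(
    rk <- ranked_gene_list(c("a", "b", "a"), c(1, 2, -3)),
    "duplicate")
  expect_equal(nrow(rk), 2L)
  expect_equal(rk$fold_change[rk$gene_id == "a"], -3)
})

test_that("enrichment configuration validates its permutation budget", {
  expect_error(enrichment_config(n_permutations = 0L), "positive")
  expect_warning(enrichment_config(n_permutations = 50L), "100")
  expect_error(enrichment_config(fdr_threshold = 0), "fdr_threshold")
})
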