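test_that("every generator is a pure function of its seed", {
  cfg <- synthetic_config(seed = 9, n_terms = 80L, n_genes = 300L)
  o1 <- generate_ontology(cfg); o2 <- generate_ontology(cfg)
  expect_identical(o1, o2)
  g <- parse_obo(o1$obo)
  a1 <- suppressMessages(generate_annotation(g, cfg))
  a2 <- suppressMessages(generate_annotation(g, cfg))
  expect_identical(a1, a2)
  r1 <- generate_ranked_list(a1$annotation, cfg)
  r2 <- generate_ranked_list(a1$annotation, cfg)
  expect_identical(r1, r2)
  d1 <- generate_disease_genes(a1$annotation, cfg)
  d2 <- generate_disease_genes(a1$annotation, cfg)
  expect_identical(d1, d2)
  e1 <- generate_event_mappings(g, cfg)
  e2 <- generate_event_mappings(g, cfg)
  expect_identical(e1, e2)
})

test_that("generator streams are isolated from each other and the session", {
  cfg <- synthetic_config(seed = 9, n_terms = 80L, n_genes = 300L)
  g <- parse_obo(generate_ontology(cfg)$obo)
  ann <- suppressMessages(generate_annotation(g, cfg))$annotation
  d_before <- generate_disease_genes(ann, cfg)
  invisible(generate_ranked_list(ann, cfg))   # interleaved call
  d_after <- generate_disease_genes(ann, cfg)
  expect_identical(d_before, d_after)

  # the session RNG state is left untouched
  set.seed(123); x1 <- stats::runif(3)
  set.seed(123); invisible(generate_ontology(cfg)); x2 <- stats::runif(3)
  expect_identical(x1, x2)
})

test_that("the smallest ontology is a root with one child", {
  cfg <- synthetic_config(seed = 1, n_terms = 2L)
  out <- generate_ontology(cfg)
  g <- parse_obo(out$obo)
  expect_equal(nrow(g$terms), 2L)
  expect_equal(nrow(g$edges), 1L)
  expect_identical(g$edges$parent, "GO:0000001")
})

test_that("parsing a generated ontology recovers the manifest exactly", {
  cfg <- synthetic_config(seed = 5, n_terms = 100L)
  out <- generate_ontology(cfg)
  g <- parse_obo(out$obo)
  expect_identical(sort(g$terms$term_id), sort(out$manifest$terms))
  expect_equal(nrow(g$edges), nrow(out$manifest$edges))
  # descendant closures equal the manifest's independent counts
  for (t in sample(out$manifest$terms, 20L)) {
    expect_length(go_descendants(g, t),
                  unname(out$manifest$n_descendants[[t]]))
  }
  # max_children cap respected for primary attachments (each child's first
  # edge in the manifest is its primary parent)
  primary <- out$manifest$edges[!duplicated(out$manifest$edges$child), ]
  expect_lte(max(table(primary$parent)), cfg$max_children)
})

test_that("true-path propagation equals the manifest's gene sets", {
  cfg <- synthetic_config(seed = 6, n_terms = 80L, n_genes = 300L)
  g <- parse_obo(generate_ontology(cfg)$obo)
  out <- suppressMessages(generate_annotation(g, cfg))
  expect_identical(out$annotation$term_genes, out$manifest$term_genes)
  # a gene annotated to a term is annotated to every ancestor of it
  tg <- out$annotation$term_genes
  some <- sample(names(tg), 10L)
  for (t in some) {
    for (a in go_ancestors(g, t)) {
      expect_true(all(tg[[t]] %in% tg[[a]]), info = paste(t, "->", a))
    }
  }
  # the root carries the whole annotated universe
  expect_identical(tg[["GO:0000001"]], out$annotation$universe)
})

test_that("extreme planted effects push planted genes to the top ranks", {
  cfg <- synthetic_config(seed = 4, n_terms = 80L, n_genes = 300L,
                          effect_shift = 5, noise_sd = 0.01)
  g <- parse_obo(generate_ontology(cfg)$obo)
  ann <- suppressMessages(generate_annotation(g, cfg))$annotation
  rl <- generate_ranked_list(ann, cfg)
  k <- length(rl$truth$planted_genes)
  expect_setequal(rl$ranked$gene_id[seq_len(k)], rl$truth$planted_genes)
})

test_that("uncontaminated disease lists are exactly the planted genes", {
  cfg <- synthetic_config(seed = 4, n_terms = 80L, n_genes = 300L,
                          disease_gene_contamination = 0)
  g <- parse_obo(generate_ontology(cfg)$obo)
  ann <- suppressMessages(generate_annotation(g, cfg))$annotation
  dg <- generate_disease_genes(ann, cfg)
  planted_union <- sort(unique(unlist(ann$term_genes[dg$truth$planted_terms])))
  expect_identical(dg$genes, planted_union)
  expect_length(dg$truth$contaminants, 0L)

  cfg2 <- synthetic_config(seed = 4, n_terms = 80L, n_genes = 300L,
                           disease_gene_contamination = 0.2)
  dg2 <- generate_disease_genes(ann, cfg2)
  expect_equal(length(dg2$genes), length(planted_union))
  expect_gt(length(dg2$truth$contaminants), 0L)
})

test_that("event mappings round-trip through the loader and dedup counts", {
  cfg <- synthetic_config(seed = 8, n_terms = 80L)
  out <- generate_ontology(cfg)
  g <- parse_obo(out$obo)
  em <- generate_event_mappings(g, cfg)
  expect_equal(nrow(em$table), cfg$n_events)

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(em$tsv, path)
  ev <- load_event_mappings(path, graph = g)
  expect_equal(nrow(ev), cfg$n_events)
  expect_identical(unlist(strsplit(em$table$go_terms, ";")),
                   unlist(ev$mapped_terms))

  s <- derive_aop_term_set(ev, g)
  expect_equal(s$raw_count, em$manifest$raw_count)
  expect_equal(s$unique_count, em$manifest$unique_count)
  expect_identical(s$terms, em$manifest$unique_terms)
})

test_that("planted term selection is shared between generators", {
  cfg <- synthetic_config(seed = 10, n_terms = 80L, n_genes = 300L)
  g <- parse_obo(generate_ontology(cfg)$obo)
  ann <- suppressMessages(generate_annotation(g, cfg))$annotation
  rl <- generate_ranked_list(ann, cfg)
  dg <- generate_disease_genes(ann, cfg)
  expect_identical(rl$truth$planted_terms, dg$truth$planted_terms)
  expect_identical(pick_planted_terms(ann, cfg), rl$truth$planted_terms)
  # explicit planting is honoured and validated
  cfg2 <- synthetic_config(seed = 10, n_terms = 80L, n_genes = 300L,
                           planted_terms = rl$truth$planted_terms[1:2])
  expect_identical(pick_planted_terms(ann, cfg2),
                   sort(rl$truth$planted_terms[1:2]))
  cfg3 <- synthetic_config(seed = 10, planted_terms = "GO:0999999")
  expect_error(pick_planted_terms(ann, cfg3), "not in annotation")
})
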