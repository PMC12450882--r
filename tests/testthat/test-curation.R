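chain3 <- function() parse_obo(obo_chain(c("GO:0000001", "GO:0000002",
                                           "GO:0000003")))

test_that("event-mapping tables load, normalize and deduplicate", {
  tab <- data.frame(aop_id = "AOP 39", event_id = "Event ID: 1911",
                    event_type = "MIE", go_terms = "GO:0007165;go:6915",
                    stringsAsFactors = FALSE)
  ev <- load_event_mappings(tab)
  expect_s3_class(ev, "aop_events")
  expect_equal(nrow(ev), 1L)
  expect_identical(ev$mapped_terms[[1L]], c("GO:0007165", "GO:0006915"))

  dup <- rbind(tab, tab)
  expect_warning(ev2 <- load_event_mappings(dup), "duplicated")
  expect_equal(nrow(ev2), 1L)

  expect_error(load_event_mappings(tab[, -4L]), "go_terms")
  bad <- tab; bad$event_type <- "XX"
  expect_error(load_event_mappings(bad), "event_type")

  empty <- tab; empty$go_terms <- ""
  expect_message(ev3 <- load_event_mappings(empty), "no GO mapping")
  expect_length(ev3$mapped_terms[[1L]], 0L)
})

test_that("AOP term sets expand, count raw vs unique, and ignore event order", {
  g <- chain3()
  ev <- load_event_mappings(data.frame(
    aop_id = c("AOP 1", "AOP 1"), event_id = c("E1", "E2"),
    event_type = c("MIE", "KE"),
    go_terms = c("GO:0000002", "GO:0000003"), stringsAsFactors = FALSE))
  s <- derive_aop_term_set(ev, g)
  # E1 expands to {2,3}, E2 to {3}: raw 3, unique 2
  expect_equal(s$raw_count, 3L)
  expect_equal(s$unique_count, 2L)
  expect_identical(s$terms, c("GO:0000002", "GO:0000003"))
  expect_identical(s$provenance, "aop_curated")

  s_rev <- derive_aop_term_set(ev[2:1, ], g)
  expect_identical(s$terms, s_rev$terms)
  expect_equal(s$raw_count, s_rev$raw_count)

  # two events mapping the same parent: union idempotent
  ev2 <- load_event_mappings(data.frame(
    aop_id = c("A", "B"), event_id = c("E1", "E2"),
    event_type = c("MIE", "MIE"),
    go_terms = c("GO:0000001", "GO:0000001"), stringsAsFactors = FALSE))
  s2 <- derive_aop_term_set(ev2, g)
  expect_equal(s2$unique_count, 3L)
  expect_equal(s2$raw_count, 6L)

  # disjoint leaves
  d <- random_dag_edges(10L, 5L)
  gg <- parse_obo(obo_dag(d$ids, d$edges))
  leaves <- setdiff(d$ids, d$edges$parent)[1:2]
  ev3 <- load_event_mappings(data.frame(
    aop_id = c("A", "A"), event_id = c("E1", "E2"),
    event_type = c("MIE", "KE"),
    go_terms = leaves, stringsAsFactors = FALSE))
  s3 <- derive_aop_term_set(ev3, gg)
  expect_equal(s3$raw_count, 2L)
  expect_equal(s3$unique_count, 2L)
})

test_that("terms absent from the graph are skipped or raise in strict mode", {
  g <- chain3()
  ev <- load_event_mappings(data.frame(
    aop_id = "A", event_id = "E1", event_type = "MIE",
    go_terms = "GO:0000002;GO:0099999", stringsAsFactors = FALSE))
  expect_warning(s <- derive_aop_term_set(ev, g), "absent")
  expect_identical(s$terms, c("GO:0000002", "GO:0000003"))
  expect_error(suppressWarnings(derive_aop_term_set(ev, g, strict = TRUE)),
               "absent")
})

test_that("merging term sets is a union with idempotence and identity", {
  s <- go_term_set(c("GO:0000001", "GO:0000002"), "aop_curated", "LFD")
  e <- go_term_set(character(0), "disgenet_derived", "LFD")
  m_ss <- merge_term_sets(s, s)
  expect_identical(m_ss$terms, s$terms)
  expect_equal(m_ss$raw_count, 2L * s$unique_count)
  m_es <- merge_term_sets(e, s)
  expect_identical(m_es$terms, s$terms)
  expect_identical(m_es$provenance, "merged")

  t1 <- go_term_set("GO:0000003", "aop_curated")
  left <- merge_term_sets(merge_term_sets(s, e), t1)
  right <- merge_term_sets(s, merge_term_sets(e, t1))
  expect_identical(left$terms, right$terms)
})

test_that("vocabulary coverage reproduces the published one-decimal share", {
  expect_equal(vocabulary_coverage(2205, 27047), 8.1)
  s <- go_term_set(sprintf("GO:%07d", 1:37), "disgenet_derived")
  expect_equal(vocabulary_coverage(s, 37), 100.0)
  expect_equal(vocabulary_coverage(1, 1000), 0.1)
  expect_error(vocabulary_coverage(5, 0), "positive")
  expect_error(vocabulary_coverage(10, 5), "smaller")
})

test_that("gene-disease tables validate scores and deduplicate pairs", {
  tab <- data.frame(gene_id = c("A", "A", "B"),
                    disease_id = c("D1", "D1", "D1"),
                    score = c(0.2, 0.8, 0.5), stringsAsFactors = FALSE)
  gd <- read_gene_disease(tab)
  expect_equal(nrow(gd), 2L)
  expect_equal(gd$score[gd$gene_id == "A"], 0.8)  # keeps the best-scored pair
  gd2 <- read_gene_disease(tab, min_score = 0.6)
  expect_identical(gd2$gene_id, "A")
  bad <- tab; bad$score[1] <- 1.5
  expect_error(read_gene_disease(bad), "\\[0, 1\\]")
})

test_that("disease term sets recover every planted term across seeds", {
  # power property at generator defaults: contaminated disease gene lists
  # still pinpoint the planted processes at FDR 0.05
  for (s in seq_len(20L)) {
    cfg <- synthetic_config(seed = s)
    onto <- generate_ontology(cfg)
    g <- parse_obo(onto$obo)
    ann <- suppressMessages(generate_annotation(g, cfg))$annotation
    dg <- generate_disease_genes(ann, cfg)
    ds <- derive_disease_term_set(dg$genes, ann,
                                  config = enrichment_config(fdr_threshold = 0.05),
                                  source_label = "synthetic disease")
    expect_identical(ds$provenance, "disgenet_derived")
    expect_true(all(dg$truth$planted_terms %in% ds$terms),
                info = paste("seed", s))
  }
})

test_that("querying an empty or unmappable gene list errors clearly", {
  ann <- flat_annotation(list("GO:0000001" = sprintf("g%02d", 1:10)))
  expect_error(ora(c("zz1", "zz2"), ann), "identifiers")
})
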