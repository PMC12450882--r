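# Shared in-code fixtures: tiny OBO texts and annotation tables.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear chain: ids[1] is the root, each later term is_a its predecessor.
obo_chain <- function(ids, namespace = "biological_process") {
  stanzas <- vapply(seq_along(ids), function(i) {
    paste(c("[Term]",
            paste0("id: ", ids[[i]]),
            paste0("name: term ", i),
            paste0("namespace: ", namespace),
            if (i > 1L) paste0("is_a: ", ids[[i - 1L]]),
            ""), collapse = "\n")
  }, character(1))
  paste(c("format-version: 1.2", "", stanzas), collapse = "\n")
}

# Arbitrary DAG from an edge list (child -> parent), all BP.
obo_dag <- function(ids, edges, extra = character(0)) {
  stanzas <- vapply(ids, function(id) {
    isa <- edges$parent[edges$child == id]
    paste(c("[Term]",
            paste0("id: ", id),
            paste0("name: ", id),
            "namespace: biological_process",
            if (length(isa)) paste0("is_a: ", isa),
            ""), collapse = "\n")
  }, character(1))
  paste(c("format-version: 1.2", "", stanzas, extra), collapse = "\n")
}

# Random DAG over n terms: each non-root picks 1-2 parents among earlier terms.
random_dag_edges <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("GO:%07d", seq_len(n))
  child <- character(0); parent <- character(0)
  for (i in 2:n) {
    k <- min(i - 1L, sample(1:2, 1))
    for (p in sample(seq_len(i - 1L), k)) {
      child <- c(child, ids[[i]]); parent <- c(parent, ids[[p]])
    }
  }
  list(ids = ids, edges = data.frame(child = child, parent = parent,
                                     stringsAsFactors = FALSE))
}

# Independent breadth-first descendant closure straight from an edge list.
bfs_descendants <- function(edges, root) {
  seen <- character(0)
  frontier <- root
  while (length(frontier)) {
    seen <- unique(c(seen, frontier))
    frontier <- setdiff(edges$child[edges$parent %in% frontier], seen)
  }
  sort(seen)
}

# Small flat annotation: n_terms disjoint sets of sizes over a gene universe.
flat_annotation <- function(sets) {
  gene <- unlist(sets, use.names = FALSE)
  term <- rep(names(sets), lengths(sets))
  annotation_table(gene, term)
}

make_ranked <- function(genes, fc, label = "cond") {
  ranked_gene_list(genes, fc, condition_label = label)
}

# Reference GSEA running-sum computed by a plain element-by-element loop,
# independent of the package's vectorised path. Returns the maximal and
# minimal running-sum deviations.
loop_extrema <- function(gene_ids, fold_changes, gene_set, q = 1) {
  ord <- order(-fold_changes, gene_ids, method = "radix")
  g <- gene_ids[ord]; s <- fold_changes[ord]
  hit <- g %in% gene_set
  N <- length(g); Nh <- sum(hit)
  if (Nh == 0) return(NULL)
  w <- abs(s)^q
  denom <- sum(w[hit])
  run <- 0; mx <- 0; mn <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      run <- run + (if (denom > 0) w[i] / denom else 1 / Nh)
    } else {
      run <- run - 1 / (N - Nh)
    }
    if (run > mx) mx <- run
    if (run < mn) mn <- run
  }
  list(mx = mx, mn = mn)
}

# Compare an enrichment score against the loop reference. When the two
# extrema tie in magnitude (possible under the unweighted statistic) only
# the magnitude is compared, since the sign then rests on floating-point
# noise.
expect_es_equal <- function(es, ref, tolerance = 1e-12, info = NULL) {
  if (abs(ref$mx + ref$mn) < 1e-9) {
    expect_equal(abs(es), ref$mx, tolerance = tolerance, info = info)
  } else {
    expected <- if (ref$mx >= -ref$mn) ref$mx else ref$mn
    expect_equal(es, expected, tolerance = tolerance, info = info)
  }
}
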