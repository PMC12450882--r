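#' Configuration for the synthetic-data generators
#'
#' Defines the simulated study conditions: a toy BP ontology, gene
#' annotations on its leaves, AOP event mappings, a disease gene list and
#' per-condition ranked fold-change tables with planted enrichment.
#' Defaults give a 200-term ontology over 2000 genes with five planted
#' terms whose member genes receive an additive fold-change shift of 1.5
#' against unit Gaussian noise.
#'
#' @param seed integer master seed; every generator derives its own RNG
#'   stream from it, so adding one generator call never perturbs another's
#'   draws.
#' @param n_terms number of ontology terms (default 200).
#' @param max_children maximum children per term (default 4).
#' @param n_genes gene universe size (default 2000).
#' @param genes_per_leaf_term length-2 range of genes assigned per leaf
#'   term (default 5-50).
#' @param planted_terms character vector of term ids to plant, or a count
#'   to auto-pick deterministically (default 5).
#' @param planted_size_range length-2 range of gene-set sizes eligible for
#'   planting (default 20-50): the planted biological programs are
#'   moderately sized leaf processes, large enough to carry a detectable
#'   coordinated shift.
#' @param effect_shift additive shift applied to planted genes' fold
#'   changes (default 1.5).
#' @param noise_sd standard deviation of the fold-change noise (default 1).
#' @param disease_gene_contamination fraction of the disease gene list
#'   replaced by random universe genes (default 0.2).
#' @param n_events number of AOP events generated (default 10).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_terms = 200L, max_children = 4L,
                             n_genes = 2000L, genes_per_leaf_term = c(5L, 50L),
                             planted_terms = 5L, planted_size_range = c(20L, 50L),
                             effect_shift = 1.5,
                             noise_sd = 1.0, disease_gene_contamination = 0.2,
                             n_events = 10L) {
  stopifnot(n_terms >= 2L, max_children >= 1L, n_genes >= 1L,
            length(genes_per_leaf_term) == 2L,
            genes_per_leaf_term[[1L]] <= genes_per_leaf_term[[2L]],
            length(planted_size_range) == 2L,
            planted_size_range[[1L]] <= planted_size_range[[2L]],
            noise_sd >= 0,
            disease_gene_contamination >= 0, disease_gene_contamination < 1,
            n_events >= 1L)
  structure(
    list(seed = as.integer(seed), n_terms = as.integer(n_terms),
         max_children = as.integer(max_children), n_genes = as.integer(n_genes),
         genes_per_leaf_term = as.integer(genes_per_leaf_term),
         planted_terms = planted_terms,
         planted_size_range = as.integer(planted_size_range),
         effect_shift = effect_shift,
         noise_sd = noise_sd,
         disease_gene_contamination = disease_gene_contamination,
         n_events = as.integer(n_events)),
    class = "synthetic_config"
  )
}

# Run fn() under a dedicated L'Ecuyer-CMRG stream derived from (seed, index),
# restoring the caller's RNG state afterwards. Stream indices are fixed per
# generator so the draws of one module never shift another's.
.with_stream <- function(seed, index, fn) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else set.seed(NULL)
  }, add = TRUE)
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv())
  for (i in seq_len(index)) s <- parallel::nextRNGStream(s)
  assign(".Random.seed", s, globalenv())
  fn()
}

.gene_ids <- function(n) sprintf("G%04d", seq_len(n))
.term_ids <- function(n) sprintf("GO:%07d", seq_len(n))

# Descendant sets from an edge list alone (children have larger index than
# parents by construction), independent of the ontology module's traversal.
.manifest_descendants <- function(n_terms, child_idx, parent_idx) {
  desc <- vector("list", n_terms)
  kids <- split(child_idx, parent_idx)
  for (i in rev(seq_len(n_terms))) {
    k <- kids[[as.character(i)]]
    desc[[i]] <- sort(unique(c(i, unlist(desc[k], use.names = FALSE))))
  }
  desc
}

#' Generate a toy GO-like ontology
#'
#' Builds a rooted DAG of `is_a` edges in the biological_process namespace
#' (every non-root term has one parent, some a second, each parent capped
#' at `max_children` primary children), emits it as OBO text, and returns
#' a manifest (term list, edge list, per-term descendant counts) that
#' serves as an independent oracle for the parser and for descendant
#' closures.
#'
#' @param config a [synthetic_config].
#' @return list with `obo` (single OBO-format string) and `manifest`
#'   (list: `terms`, `edges` data.frame, `n_descendants` named integer).
#' @export
generate_ontology <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_terms
  .with_stream(config$seed, 1L, function() {
    ids <- .term_ids(n)
    n_children <- integer(n)
    child_idx <- integer(0)
    parent_idx <- integer(0)
    for (i in seq(2L, n)) {
      eligible <- which(n_children[seq_len(i - 1L)] < config$max_children)
      if (!length(eligible)) eligible <- which.min(n_children[seq_len(i - 1L)])
      p <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
      n_children[[p]] <- n_children[[p]] + 1L
      child_idx <- c(child_idx, i)
      parent_idx <- c(parent_idx, p)
      # occasional second parent makes it a genuine DAG, not a tree
      if (i > 2L && stats::runif(1) < 0.15) {
        others <- setdiff(seq_len(i - 1L), p)
        if (length(others)) {
          p2 <- if (length(others) == 1L) others else sample(others, 1L)
          child_idx <- c(child_idx, i)
          parent_idx <- c(parent_idx, p2)
        }
      }
    }
    desc <- .manifest_descendants(n, child_idx, parent_idx)
    stanzas <- vapply(seq_len(n), function(i) {
      isa <- parent_idx[child_idx == i]
      paste(c("[Term]",
              paste0("id: ", ids[[i]]),
              paste0("name: synthetic process ", i),
              "namespace: biological_process",
              if (length(isa)) paste0("is_a: ", ids[isa],
                                      " ! synthetic process ", isa),
              ""), collapse = "\n")
    }, character(1))
    obo <- paste(c("format-version: 1.2",
                   "ontology: synthetic-go", "", stanzas), collapse = "\n")
    manifest <- list(
      terms = ids,
      edges = data.frame(child = ids[child_idx], relation = "is_a",
                         parent = ids[parent_idx], stringsAsFactors = FALSE),
      n_descendants = stats::setNames(lengths(desc), ids)
    )
    list(obo = obo, manifest = manifest)
  })
}

#' Generate gene annotations for a synthetic ontology
#'
#' Assigns genes to leaf terms (set sizes drawn from
#' `genes_per_leaf_term`) and propagates them by the true-path rule.
#' Genes are dealt to leaves from a shuffled circular deck, so every gene
#' is annotated, coverage is balanced (each gene belongs to one or two
#' leaves), and the gene sets of unrelated leaves barely overlap - which
#' keeps planted enrichment signal identifiable instead of smearing it
#' across random terms. The manifest lists every term's final gene set,
#' computed directly from the edge list so it can serve as an oracle for
#' the annotation machinery.
#'
#' @param graph a [go_ontology] parsed from [generate_ontology()] output.
#' @param config a [synthetic_config].
#' @return list with `annotation` (an [annotation_table]) and `manifest`
#'   (list: `leaf_genes`, `term_genes`).
#' @export
generate_annotation <- function(graph, config = synthetic_config()) {
  stopifnot(inherits(graph, "go_ontology"), inherits(config, "synthetic_config"))
  genes <- .gene_ids(config$n_genes)
  leaves <- sort(go_leaves(graph))
  .with_stream(config$seed, 2L, function() {
    sizes <- sample(seq(config$genes_per_leaf_term[[1L]],
                        config$genes_per_leaf_term[[2L]]),
                    length(leaves), replace = TRUE)
    # deal from independently reshuffled decks so no two leaves share an
    # aligned block of genes
    n_cycles <- ceiling(sum(sizes) / length(genes))
    deck <- unlist(lapply(seq_len(n_cycles), function(i) sample(genes)),
                   use.names = FALSE)[seq_len(sum(sizes))]
    offsets <- cumsum(c(0L, sizes[-length(sizes)]))
    leaf_genes <- lapply(seq_along(leaves), function(i) {
      sort(unique(deck[offsets[[i]] + seq_len(sizes[[i]])]))
    })
    names(leaf_genes) <- leaves

    # independent propagation straight from the edge list
    idx <- match(graph$edges$child, graph$terms$term_id)
    pidx <- match(graph$edges$parent, graph$terms$term_id)
    desc <- .manifest_descendants(nrow(graph$terms), idx, pidx)
    ids <- graph$terms$term_id
    term_genes <- lapply(seq_along(ids), function(i) {
      l <- intersect(ids[desc[[i]]], leaves)
      sort(unique(unlist(leaf_genes[l], use.names = FALSE)))
    })
    names(term_genes) <- ids
    term_genes <- term_genes[lengths(term_genes) > 0L]

    pair_gene <- unlist(leaf_genes, use.names = FALSE)
    pair_term <- rep(names(leaf_genes), lengths(leaf_genes))
    annotation <- annotation_table(pair_gene, pair_term, graph = graph,
                                   propagate = TRUE)
    attr(annotation, "leaf_terms") <- leaves
    list(annotation = annotation,
         manifest = list(leaf_genes = leaf_genes, term_genes = term_genes))
  })
}

#' Deterministically pick the planted terms
#'
#' Chooses the enrichment ground truth shared by [generate_ranked_list()]
#' and [generate_disease_genes()]: leaf terms (falling back to terms whose
#' gene-set size lies within the `genes_per_leaf_term` range when the
#' annotation does not record its leaves) sampled under a dedicated RNG
#' stream, so both generators agree on the truth for a given seed.
#' Planting at leaves means the shift applies to exactly one term's gene
#' set; enrichment is still expected to spread to the ancestors of a
#' planted leaf, which genuinely contain its genes under the true-path
#' rule.
#'
#' @param annotation an [annotation_table].
#' @param config a [synthetic_config]; `config$planted_terms` may already
#'   name the terms, in which case they are validated and returned.
#' @return character vector of term ids.
#' @export
pick_planted_terms <- function(annotation, config = synthetic_config()) {
  sizes <- lengths(annotation$term_genes)
  if (is.character(config$planted_terms)) {
    terms <- config$planted_terms
    missing <- setdiff(terms, names(sizes))
    if (length(missing)) stop("planted term(s) not in annotation: ",
                              paste(missing, collapse = ", "))
    return(sort(terms))
  }
  k <- as.integer(config$planted_terms)
  pool <- attr(annotation, "leaf_terms")
  if (is.null(pool)) pool <- names(sizes)
  pool <- pool[sizes[pool] >= config$planted_size_range[[1L]] &
               sizes[pool] <= config$planted_size_range[[2L]]]
  if (length(pool) < k) stop("not enough leaf-scale terms to plant ", k)
  .with_stream(config$seed, 3L, function() sort(sample(pool, k)))
}

#' Generate a ranked fold-change list with planted enrichment
#'
#' Every gene's fold change is Gaussian noise; genes belonging to any
#' planted term receive an additional additive shift `effect_shift`. With
#' the default shift of 0 the list is a pure null.
#'
#' @param annotation an [annotation_table].
#' @param config a [synthetic_config].
#' @param condition_label label for the resulting [ranked_gene_list].
#' @param condition_index 1-based index of the condition; each condition
#'   draws from its own RNG substream.
#' @return list with `ranked` (a [ranked_gene_list]) and `truth` (list:
#'   `planted_terms`, `planted_genes`, `genes_by_term`).
#' @export
generate_ranked_list <- function(annotation, config = synthetic_config(),
                                 condition_label = "synthetic condition",
                                 condition_index = 1L) {
  stopifnot(inherits(annotation, "annotation_table"))
  planted <- pick_planted_terms(annotation, config)
  genes_by_term <- annotation$term_genes[planted]
  small <- lengths(genes_by_term) < 5L
  if (any(small)) {
    stop("planted term(s) with fewer than 5 genes: ",
         paste(planted[small], collapse = ", "))
  }
  planted_genes <- sort(unique(unlist(genes_by_term, use.names = FALSE)))
  genes <- .gene_ids(config$n_genes)
  .with_stream(config$seed, 10L + as.integer(condition_index), function() {
    fc <- stats::rnorm(length(genes), 0, config$noise_sd) +
      config$effect_shift * (genes %in% planted_genes)
    list(ranked = ranked_gene_list(genes, fc, condition_label = condition_label),
         truth = list(planted_terms = planted, planted_genes = planted_genes,
                      genes_by_term = genes_by_term))
  })
}

#' Generate a disease gene list from the planted truth
#'
#' Subsamples the union of planted-term genes at rate
#' `1 - disease_gene_contamination` and pads with random non-planted
#' universe genes, emulating a gene-disease association list whose signal
#' points at the planted processes.
#'
#' @inheritParams generate_ranked_list
#' @return list with `genes` (character) and `truth` (list:
#'   `planted_terms`, `kept_genes`, `contaminants`).
#' @export
generate_disease_genes <- function(annotation, config = synthetic_config()) {
  stopifnot(inherits(annotation, "annotation_table"))
  planted <- pick_planted_terms(annotation, config)
  planted_genes <- sort(unique(unlist(annotation$term_genes[planted],
                                      use.names = FALSE)))
  m <- length(planted_genes)
  n_keep <- max(1L, round((1 - config$disease_gene_contamination) * m))
  n_pad <- m - n_keep
  other <- setdiff(.gene_ids(config$n_genes), planted_genes)
  .with_stream(config$seed, 4L, function() {
    kept <- sort(sample(planted_genes, n_keep))
    pad <- if (n_pad > 0L) sort(sample(other, min(n_pad, length(other))))
           else character(0)
    list(genes = sort(c(kept, pad)),
         truth = list(planted_terms = planted, kept_genes = kept,
                      contaminants = pad))
  })
}

#' Generate a synthetic AOP event-mapping table
#'
#' Emits `n_events` events (an initiating event plus key events per
#' synthetic AOP), each mapped to 1-3 parent terms drawn from a small pool
#' of internal ontology terms so that terms recur across events; the
#' manifest records the expected pre-dedup (sum of closure sizes) and
#' unique (union of closures) counts for [derive_aop_term_set()], computed
#' straight from the edge list.
#'
#' @param graph a [go_ontology] from [generate_ontology()] output.
#' @param config a [synthetic_config].
#' @return list with `table` (data.frame with columns `aop_id`,
#'   `event_id`, `event_type`, `go_terms`), `tsv` (the same as TSV text)
#'   and `manifest` (list: `events`, `raw_count`, `unique_count`,
#'   `unique_terms`).
#' @export
generate_event_mappings <- function(graph, config = synthetic_config()) {
  stopifnot(inherits(graph, "go_ontology"), inherits(config, "synthetic_config"))
  ids <- graph$terms$term_id
  leaves <- go_leaves(graph)
  internal <- setdiff(ids, c(leaves, ids[[1L]]))  # neither leaves nor the root
  if (!length(internal)) internal <- setdiff(ids, ids[[1L]])
  idx <- match(graph$edges$child, ids)
  pidx <- match(graph$edges$parent, ids)
  desc <- .manifest_descendants(length(ids), idx, pidx)
  names(desc) <- ids
  .with_stream(config$seed, 5L, function() {
    pool <- sample(internal, min(length(internal),
                                 max(3L, ceiling(config$n_events / 2))))
    n_aops <- max(1L, ceiling(config$n_events / 3))
    aop_of <- sort(rep_len(seq_len(n_aops), config$n_events))
    rows <- lapply(seq_len(config$n_events), function(i) {
      k <- sample(1:3, 1L)
      terms <- sort(unique(sample(pool, min(k, length(pool)), replace = TRUE)))
      first_of_aop <- i == match(aop_of[[i]], aop_of)
      data.frame(aop_id = sprintf("AOP %d", aop_of[[i]]),
                 event_id = sprintf("Event ID: %d", 1000L + i),
                 event_type = if (first_of_aop) "MIE" else "KE",
                 go_terms = paste(terms, collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    mapped <- strsplit(tab$go_terms, ";", fixed = TRUE)
    closures <- lapply(mapped, function(ts) lapply(ts, function(t) ids[desc[[t]]]))
    raw <- sum(vapply(closures, function(cl) sum(lengths(cl)), numeric(1)))
    uniq <- sort(unique(unlist(closures, use.names = FALSE)))
    tsv <- paste(c(paste(names(tab), collapse = "\t"),
                   apply(tab, 1L, paste, collapse = "\t")), collapse = "\n")
    list(table = tab, tsv = tsv,
         manifest = list(events = tab, raw_count = as.integer(raw),
                         unique_count = length(uniq), unique_terms = uniq))
  })
}
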