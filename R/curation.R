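#' Load expert-curated AOP event to GO mapping tables
#'
#' Reads a tab-separated table with one row per AOP event (molecular
#' initiating event, key event or adverse outcome) and its mapped GO
#' term(s). Required columns: `aop_id`, `event_id`, `event_type`,
#' `go_terms` (semicolon-separated accessions). Optional columns `label`
#' and `cascade_position` are carried through. Exact duplicate rows are
#' collapsed with a warning; rows with empty `go_terms` are kept (with an
#' empty mapping) and logged.
#'
#' @param path path to the TSV file, or a data.frame with the same columns.
#' @param graph optional [go_ontology] for alias resolution of term ids.
#' @return data.frame of class `aop_events` with columns `aop_id`,
#'   `event_id`, `event_type`, `label`, `cascade_position` and a list
#'   column `mapped_terms` of normalized term ids.
#' @export
load_event_mappings <- function(path, graph = NULL) {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("aop_id", "event_id", "event_type", "go_terms")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("event-mapping table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_type <- setdiff(unique(tab$event_type), c("MIE", "KE", "AO"))
  if (length(bad_type)) {
    stop("event_type must be one of MIE, KE, AO; found: ",
         paste(bad_type, collapse = ", "))
  }
  dup <- duplicated(tab[required])
  if (any(dup)) {
    warning("collapsed ", sum(dup), " duplicated event row(s)")
    tab <- tab[!dup, , drop = FALSE]
  }
  empty <- !nzchar(trimws(tab$go_terms))
  if (any(empty)) {
    message(sum(empty), " event(s) carry no GO mapping; kept with empty mapping")
  }
  mapped <- lapply(tab$go_terms, function(s) {
    s <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
    s <- s[nzchar(s)]
    if (!length(s)) character(0) else normalize_term_id(s, graph)
  })
  out <- data.frame(
    aop_id = tab$aop_id,
    event_id = tab$event_id,
    event_type = tab$event_type,
    label = if ("label" %in% names(tab)) tab$label else NA_character_,
    cascade_position = if ("cascade_position" %in% names(tab))
      tab$cascade_position else NA_character_,
    stringsAsFactors = FALSE
  )
  out$mapped_terms <- mapped
  class(out) <- c("aop_events", "data.frame")
  out
}

#' Derive a disease GO BP term set from curated AOP events
#'
#' Expands each event's mapped terms with their descendant closure
#' ("primary GO and child GO terms"), takes the union over events and
#' removes duplicates. The pre-dedup count (the sum of per-event expanded
#' list lengths) is preserved, mirroring reporting of the form
#' "N parent + M child terms, K unique after deduplication". Terms from
#' non-BP namespaces are filtered out with a logged count; terms absent
#' from the graph are skipped with a warning (or raise an error in strict
#' mode).
#'
#' @param events an `aop_events` table from [load_event_mappings()].
#' @param graph a [go_ontology].
#' @param relations relations traversed for expansion (default `is_a`).
#' @param mode `"descendants"` (full closure) or `"children"` (direct only).
#' @param strict error (rather than skip) on terms absent from the graph.
#' @param source_label label stored on the resulting set.
#' @return a [go_term_set] with `provenance = "aop_curated"`.
#' @export
derive_aop_term_set <- function(events, graph, relations = "is_a",
                                mode = c("descendants", "children"),
                                strict = FALSE, source_label = "AOP") {
  stopifnot(inherits(graph, "go_ontology"))
  mode <- match.arg(mode)
  if (!nrow(events)) stop("no AOP events supplied")
  bp <- graph$terms$term_id[graph$terms$namespace == "biological_process"]
  n_dropped_ns <- 0L
  raw <- 0L
  acc <- character(0)
  for (i in seq_len(nrow(events))) {
    for (t in events$mapped_terms[[i]]) {
      t <- normalize_term_id(t, graph)
      if (!t %in% graph$terms$term_id) {
        if (strict) stop("mapped term absent from ontology: ", t)
        warning("mapped term absent from ontology, skipped: ", t)
        next
      }
      if (!t %in% bp) {
        n_dropped_ns <- n_dropped_ns + 1L
        next
      }
      ex <- go_descendants(graph, t, relations = relations, mode = mode)
      raw <- raw + length(ex)
      acc <- c(acc, ex)
    }
  }
  if (n_dropped_ns > 0L) {
    message("filtered ", n_dropped_ns,
            " mapped term(s) outside the biological_process namespace")
  }
  go_term_set(acc, provenance = "aop_curated", source_label = source_label,
              raw_count = raw)
}

#' Read a gene-disease association table
#'
#' DisGeNET-style TSV with columns `gene_id`, `disease_id` and optional
#' `score` in `[0, 1]`. Duplicate (gene, disease) pairs are collapsed
#' keeping the highest score.
#'
#' @param path TSV path or equivalent data.frame.
#' @param min_score optional lower bound on the association score; rows
#'   without a score are kept (no default cut-off is applied).
#' @return data.frame with columns `gene_id`, `disease_id`, `score`.
#' @export
read_gene_disease <- function(path, min_score = NULL) {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "disease_id")
  if (!all(need %in% names(tab))) {
    stop("gene-disease table needs columns gene_id, disease_id")
  }
  if (!"score" %in% names(tab)) tab$score <- NA_real_
  tab$score <- as.numeric(tab$score)
  if (any(!is.na(tab$score) & (tab$score < 0 | tab$score > 1))) {
    stop("association scores must lie in [0, 1]")
  }
  ord <- order(tab$gene_id, tab$disease_id, -xtfrm(tab$score))
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(tab[c("gene_id", "disease_id")]), , drop = FALSE]
  if (!is.null(min_score)) {
    tab <- tab[!is.na(tab$score) & tab$score >= min_score, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab[c("gene_id", "disease_id", "score")]
}

#' Derive a disease GO BP term set from disease genes by overrepresentation
#'
#' Runs hypergeometric overrepresentation of the disease gene list against
#' the annotation's term gene sets (the gene-centred route that complements
#' expert AOP curation) and retains terms below the configured FDR.
#'
#' @param genes character vector of disease gene ids.
#' @param annotation an [annotation_table].
#' @param config an [enrichment_config]; `config$fdr_threshold` is the
#'   selection cut-off.
#' @param source_label label stored on the resulting set (disease name).
#' @return a [go_term_set] with `provenance = "disgenet_derived"`.
#' @export
derive_disease_term_set <- function(genes, annotation,
                                    config = enrichment_config(),
                                    source_label = "disease") {
  res <- ora(genes, annotation, config = config)
  keep <- res$fdr < config$fdr_threshold
  go_term_set(res$term_id[keep], provenance = "disgenet_derived",
              source_label = source_label)
}
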