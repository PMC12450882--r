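#' Build an annotation table from gene-term pairs
#'
#' Stores the term -> gene-set mapping used by both enrichment engines.
#' When an ontology graph is supplied, annotations are propagated by the
#' true-path rule: a gene annotated to a term is annotated to every
#' ancestor of that term within the biological_process namespace.
#'
#' @param gene_id,term_id equal-length character vectors of annotation pairs.
#' @param graph optional [go_ontology]; enables true-path propagation and
#'   restriction to the BP namespace.
#' @param propagate apply the true-path rule (default `TRUE` when a graph
#'   is given).
#' @return an object of class `annotation_table`: list with `term_genes`
#'   (named list term -> character vector of genes), `universe` (all
#'   annotated genes) and `propagated` (logical).
#' @export
annotation_table <- function(gene_id, term_id, graph = NULL,
                             propagate = !is.null(graph)) {
  stopifnot(length(gene_id) == length(term_id))
  if (!length(gene_id)) stop("empty annotation")
  gene_id <- as.character(gene_id)
  term_id <- normalize_term_id(term_id, graph)
  if (!is.null(graph)) {
    bp <- graph$terms$term_id[graph$terms$namespace == "biological_process"]
    keep <- term_id %in% bp
    if (!all(keep)) {
      message("dropped ", sum(!keep), " annotation(s) outside biological_process")
      gene_id <- gene_id[keep]; term_id <- term_id[keep]
    }
    if (!length(gene_id)) stop("no biological_process annotations left")
    if (propagate) {
      anc <- new.env(parent = emptyenv())
      get_anc <- function(t) {
        if (is.null(anc[[t]])) assign(t, go_ancestors(graph, t), envir = anc)
        anc[[t]]
      }
      expanded <- lapply(unique(term_id), get_anc)
      names(expanded) <- unique(term_id)
      reps <- lengths(expanded[term_id])
      gene_id <- rep(gene_id, reps)
      term_id <- unlist(expanded[term_id], use.names = FALSE)
    }
  }
  tg <- lapply(split(gene_id, term_id), function(g) sort(unique(g)))
  structure(
    list(term_genes = tg[sort(names(tg))],
         universe = sort(unique(gene_id)),
         propagated = isTRUE(propagate)),
    class = "annotation_table"
  )
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("Annotation table:", length(x$term_genes), "terms,",
      length(x$universe), "genes",
      if (x$propagated) "(true-path propagated)" else "", "\n")
  invisible(x)
}

#' Read gene annotations from a GAF 2.x file or a two-column TSV
#'
#' For GAF input only the DB Object Symbol (column 3), GO ID (column 5)
#' and Aspect (column 9, `P` rows kept) are used. Plain TSVs must have
#' columns `gene_id` and `term_id`.
#'
#' @param path file path.
#' @param graph optional [go_ontology] passed to [annotation_table()].
#' @param format `"auto"` (GAF if the file carries a `!gaf-version` header),
#'   `"gaf"` or `"tsv"`.
#' @inheritParams annotation_table
#' @return an [annotation_table].
#' @export
read_annotation <- function(path, graph = NULL, format = c("auto", "gaf", "tsv"),
                            propagate = !is.null(graph)) {
  format <- match.arg(format)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (format == "auto") {
    format <- if (startsWith(first, "!")) "gaf" else "tsv"
  }
  if (format == "gaf") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "!")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(fields) >= 9L
    if (!all(ok)) stop("malformed GAF record(s) with fewer than 9 columns")
    gene <- vapply(fields, `[[`, character(1), 3L)
    term <- vapply(fields, `[[`, character(1), 5L)
    aspect <- vapply(fields, `[[`, character(1), 9L)
    keep <- aspect == "P"
    annotation_table(gene[keep], term[keep], graph = graph, propagate = propagate)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "term_id") %in% names(tab))) {
      stop("annotation TSV needs columns gene_id and term_id")
    }
    annotation_table(tab$gene_id, tab$term_id, graph = graph,
                     propagate = propagate)
  }
}

#' Read a gene-set collection in GMT format
#'
#' @param path GMT file path (set name, description, then member genes,
#'   tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stop("GMT line ", bad[[1L]], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(!is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[[i]], description[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a ranked gene list for one exposure condition
#'
#' Orders records by descending fold change with a deterministic
#' lexicographic tie-break on gene id. Duplicate gene ids keep the record
#' with the largest absolute fold change (probe-collapse convention) and
#' are logged.
#'
#' @param gene_id character vector of gene ids.
#' @param fold_change signed numeric fold changes (log-ratios or ratios,
#'   used as supplied).
#' @param condition_label text label, e.g. a chemical plus exposure time.
#' @return object of class `ranked_gene_list`: data.frame with columns
#'   `gene_id`, `fold_change` in ranked order; attribute `condition_label`.
#' @export
ranked_gene_list <- function(gene_id, fold_change, condition_label = "") {
  stopifnot(length(gene_id) == length(fold_change))
  if (!length(gene_id)) stop("empty ranked list")
  gene_id <- as.character(gene_id)
  fold_change <- as.numeric(fold_change)
  if (anyNA(fold_change)) stop("fold changes contain NA")
  if (anyDuplicated(gene_id)) {
    ord <- order(gene_id, -abs(fold_change), method = "radix")
    keep <- !duplicated(gene_id[ord])
    n_dup <- sum(!keep)
    gene_id <- gene_id[ord][keep]
    fold_change <- fold_change[ord][keep]
    message("collapsed ", n_dup,
            " duplicate gene id(s), keeping the largest |fold change|")
  }
  ord <- order(-fold_change, gene_id, method = "radix")
  out <- data.frame(gene_id = gene_id[ord], fold_change = fold_change[ord],
                    stringsAsFactors = FALSE)
  attr(out, "condition_label") <- condition_label
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}

#' Read a differential-expression table as a ranked gene list
#'
#' Expects the two-column supplementary-sheet dialect: a header with
#' `Gene ID` and `Fold Change Value` (or `gene_id` / `fold_change`),
#' tab-separated.
#'
#' @param path TSV path.
#' @param condition_label condition label; defaults to the file name.
#' @return a [ranked_gene_list].
#' @export
read_ranked_list <- function(path, condition_label = NULL) {
  if (is.null(condition_label)) {
    condition_label <- tools::file_path_sans_ext(basename(path))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(gsub("[^a-z]", "", tolower(names(tab))))
  gi <- which(nm %in% c("geneid", "gene"))[1L]
  fc <- which(nm %in% c("foldchangevalue", "foldchange", "fc"))[1L]
  if (is.na(gi) || is.na(fc)) {
    stop("DE table needs 'Gene ID' and 'Fold Change Value' columns: ", path)
  }
  ranked_gene_list(tab[[gi]], tab[[fc]], condition_label = condition_label)
}
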