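#' Construct a provenance-tagged GO term set
#'
#' The core currency of the pipeline: a deduplicated set of canonical GO
#' identifiers tagged with where it came from (AOP curation, disease-gene
#' enrichment, toxicogenomics enrichment, or a merge).
#'
#' @param terms character vector of term identifiers (normalized, deduplicated
#'   and sorted on construction).
#' @param provenance one of `"aop_curated"`, `"disgenet_derived"`,
#'   `"enrichment_derived"`, `"merged"`.
#' @param source_label free-text disease or chemical/condition name.
#' @param raw_count pre-deduplication size; defaults to `length(terms)`.
#' @return an object of class `go_term_set` with elements `terms`,
#'   `provenance`, `source_label`, `raw_count`, `unique_count`.
#' @export
go_term_set <- function(terms, provenance = c("aop_curated", "disgenet_derived",
                                              "enrichment_derived", "merged"),
                        source_label = "", raw_count = NULL) {
  provenance <- match.arg(provenance)
  terms <- sort(unique(as.character(terms)))
  if (is.null(raw_count)) raw_count <- length(terms)
  stopifnot(raw_count >= length(terms))
  structure(
    list(terms = terms, provenance = provenance, source_label = source_label,
         raw_count = as.integer(raw_count), unique_count = length(terms)),
    class = "go_term_set"
  )
}

#' @export
print.go_term_set <- function(x, ...) {
  cat("GO term set [", x$provenance, "] ", x$source_label, "\n", sep = "")
  cat("  ", x$unique_count, " unique terms (", x$raw_count, " before dedup)\n",
      sep = "")
  if (x$unique_count) {
    cat("  ", paste(utils::head(x$terms, 5L), collapse = ", "),
        if (x$unique_count > 5L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Merge two GO term sets
#'
#' Set union with duplicates removed; the merged set records the sum of the
#' inputs' unique sizes as its pre-dedup count, so the amount of redundancy
#' between the sources stays visible.
#'
#' @param a,b [go_term_set] objects.
#' @return a [go_term_set] with `provenance = "merged"`.
#' @export
merge_term_sets <- function(a, b) {
  stopifnot(inherits(a, "go_term_set"), inherits(b, "go_term_set"))
  lab <- paste(unique(c(a$source_label, b$source_label)), collapse = " + ")
  go_term_set(union(a$terms, b$terms), provenance = "merged",
              source_label = lab,
              raw_count = a$unique_count + b$unique_count)
}

#' Share of an ontology vocabulary covered by a term set
#'
#' Reports `100 * unique_count / vocabulary_size` as a percentage, rounded
#' down to one decimal so that the quoted share never overstates coverage.
#'
#' @param set a [go_term_set], or an integer count of unique terms.
#' @param vocabulary_size total number of terms in the vocabulary (e.g., all
#'   GO Biological Process terms of a given release).
#' @return percentage (one decimal).
#' @examples
#' vocabulary_coverage(2205, 27047)  # 8.1
#' @export
vocabulary_coverage <- function(set, vocabulary_size) {
  n <- if (inherits(set, "go_term_set")) set$unique_count else as.integer(set)
  vocabulary_size <- as.numeric(vocabulary_size)
  if (length(vocabulary_size) != 1L || is.na(vocabulary_size) ||
      vocabulary_size <= 0) {
    stop("vocabulary_size must be a positive number")
  }
  if (vocabulary_size < n) stop("vocabulary_size smaller than the term set")
  floor(1000 * n / vocabulary_size + 1e-9) / 10
}
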