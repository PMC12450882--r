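#' Jaccard index of two sets
#'
#' `J(A,B) = |A intersect B| / |A union B|`, a size-normalized similarity
#' in `[0, 1]`: 0 means no overlap, 1 complete overlap. The degenerate
#' case of two empty sets is defined as 0 (with a warning), avoiding a
#' spurious "complete overlap".
#'
#' @param a,b character vectors or [go_term_set] objects; duplicates are
#'   ignored (sets, never multisets).
#' @return numeric scalar in `[0, 1]`.
#' @examples
#' jaccard(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
jaccard <- function(a, b) {
  a <- unique(.term_vec(a))
  b <- unique(.term_vec(b))
  u <- length(union(a, b))
  if (u == 0L) {
    warning("Jaccard of two empty sets is undefined; returning 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

.term_vec <- function(x) {
  if (inherits(x, "go_term_set")) x$terms else as.character(x)
}

#' Overlap between an exposure term set and a disease term set
#'
#' Full Venn accounting for one exposure x disease comparison: set sizes,
#' intersection and union sizes, Jaccard index, and the sorted
#' intersection membership. When an `aop_events` table is supplied, each
#' intersecting term is back-mapped to the curated event(s) whose
#' expansion could have contributed it.
#'
#' @param exposure_set,disease_set [go_term_set] objects (or character
#'   vectors of term ids).
#' @param events optional `aop_events` table for back-mapping.
#' @param graph optional [go_ontology] used for the back-mapping expansion.
#' @return object of class `overlap_result`.
#' @export
go_overlap <- function(exposure_set, disease_set, events = NULL, graph = NULL) {
  a <- unique(.term_vec(exposure_set))
  b <- unique(.term_vec(disease_set))
  if (!length(a) || !length(b)) {
    message("overlap with an empty term set (sizes ",
            length(a), ", ", length(b), ")")
  }
  inter <- sort(intersect(a, b))
  uni <- union(a, b)
  back <- NULL
  if (!is.null(events) && !is.null(graph) && length(inter)) {
    back <- lapply(inter, function(t) {
      hit <- vapply(seq_len(nrow(events)), function(i) {
        any(vapply(events$mapped_terms[[i]], function(m) {
          t %in% go_descendants(graph, m)
        }, logical(1)))
      }, logical(1))
      events$event_id[hit]
    })
    names(back) <- inter
  }
  structure(
    list(
      exposure_label = if (inherits(exposure_set, "go_term_set"))
        exposure_set$source_label else "",
      disease_label = if (inherits(disease_set, "go_term_set"))
        disease_set$source_label else "",
      set_a_size = length(a), set_b_size = length(b),
      intersection_size = length(inter), union_size = length(uni),
      jaccard = if (length(uni)) length(inter) / length(uni) else 0,
      intersection_terms = inter,
      exposure_terms = sort(a),
      event_backmap = back
    ),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Overlap ", x$exposure_label, " vs ", x$disease_label, ": ",
      x$intersection_size, " of ", x$set_b_size,
      " disease terms shared (exposure set ", x$set_a_size,
      "); Jaccard = ", format(x$jaccard, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Cross-chemical common GO signature
#'
#' Intersects per-chemical overlap results against one disease to extract
#' the terms shared by every chemical: either the terms each chemical's
#' enriched set shares with the disease (`mode = "intersection"`) or the
#' full exposure sets themselves (`mode = "exposure"`). A term x chemical
#' membership matrix is emitted for UpSet-style reporting.
#'
#' @param overlaps list of [go_overlap()] results sharing a disease label
#'   (at least two).
#' @param mode `"intersection"` (default) or `"exposure"`.
#' @return object of class `signature_result`: list with `chemicals`,
#'   `common_terms`, `membership` (logical matrix, rows = union of terms),
#'   `signature_size`.
#' @export
common_signature <- function(overlaps, mode = c("intersection", "exposure")) {
  mode <- match.arg(mode)
  stopifnot(length(overlaps) >= 2L,
            all(vapply(overlaps, inherits, logical(1), "overlap_result")))
  diseases <- unique(vapply(overlaps, `[[`, character(1), "disease_label"))
  if (length(diseases) != 1L) {
    stop("overlaps compare against different diseases: ",
         paste(diseases, collapse = ", "))
  }
  chems <- vapply(overlaps, `[[`, character(1), "exposure_label")
  if (any(!nzchar(chems))) chems[!nzchar(chems)] <-
    paste0("condition_", which(!nzchar(chems)))
  per_chem <- lapply(overlaps, `[[`,
                     if (mode == "intersection") "intersection_terms"
                     else "exposure_terms")
  names(per_chem) <- chems
  common <- sort(Reduce(intersect, per_chem))
  all_terms <- sort(unique(unlist(per_chem, use.names = FALSE)))
  membership <- vapply(per_chem, function(t) all_terms %in% t,
                       logical(length(all_terms)))
  if (length(all_terms) == 1L) membership <- matrix(membership, nrow = 1L,
                                                    dimnames = list(all_terms, chems))
  else rownames(membership) <- all_terms
  structure(
    list(chemicals = chems, common_terms = common,
         membership = membership, signature_size = length(common),
         mode = mode, disease_label = diseases),
    class = "signature_result"
  )
}

#' @export
print.signature_result <- function(x, ...) {
  cat("Common GO signature across ", length(x$chemicals), " chemicals (",
      paste(x$chemicals, collapse = ", "), ") vs ", x$disease_label, ":\n",
      "  ", x$signature_size, " shared term(s)\n", sep = "")
  invisible(x)
}

#' Overlap matrix over many exposure conditions
#'
#' One row per condition with the Venn sizes and Jaccard index against a
#' single disease set; the tabular twin of a panel of per-condition Venn
#' diagrams. Rows keep the input condition order.
#'
#' @param conditions list of [go_term_set] objects (one per condition).
#' @param disease_set a [go_term_set].
#' @return data.frame with columns `condition`, `n_condition`, `n_disease`,
#'   `n_intersection`, `n_union`, `jaccard`.
#' @export
overlap_matrix <- function(conditions, disease_set) {
  if (!length(conditions)) {
    return(data.frame(condition = character(0), n_condition = integer(0),
                      n_disease = integer(0), n_intersection = integer(0),
                      n_union = integer(0), jaccard = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(conditions, function(cs) {
    ov <- go_overlap(cs, disease_set)
    data.frame(condition = if (nzchar(ov$exposure_label)) ov$exposure_label
               else "condition",
               n_condition = ov$set_a_size, n_disease = ov$set_b_size,
               n_intersection = ov$intersection_size, n_union = ov$union_size,
               jaccard = ov$jaccard, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
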