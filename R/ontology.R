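#' Normalize GO term identifiers
#'
#' Coerces any common dialect of a GO accession (`"GO:0007165"`,
#' `"go:7165"`, `"go_0007165"`, surrounding whitespace) to the canonical
#' `"GO:"` + 7 zero-padded digits form. When an ontology graph is supplied,
#' secondary (`alt_id`) accessions are resolved to their canonical term.
#'
#' @param raw character vector of raw identifiers.
#' @param graph optional [go_ontology] object used for `alt_id` resolution.
#' @return character vector of canonical term identifiers.
#' @examples
#' normalize_term_id(c("GO:0007165", "go:7165"))
#' @export
normalize_term_id <- function(raw, graph = NULL) {
  if (length(raw) == 0L) return(character(0))
  x <- trimws(as.character(raw))
  m <- regmatches(x, regexec("^[Gg][Oo][:_ ]?([0-9]{1,7})$", x))
  num <- vapply(m, function(g) if (length(g) == 2L) g[[2L]] else NA_character_,
                character(1))
  if (anyNA(num)) {
    bad <- unique(x[is.na(num)])
    stop("not a GO term identifier: ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  id <- sprintf("GO:%07d", as.integer(num))
  if (!is.null(graph)) {
    stopifnot(inherits(graph, "go_ontology"))
    hit <- match(id, names(graph$alt_id))
    id[!is.na(hit)] <- unname(graph$alt_id[hit[!is.na(hit)]])
  }
  id
}

#' Parse a Gene Ontology OBO file
#'
#' Reads OBO 1.2/1.4 flat-file text into an in-memory GO graph holding
#' non-obsolete terms, `is_a` and `part_of` edges, and an `alt_id` map.
#' Obsolete terms are dropped with a warning; `alt_id` accessions resolve
#' silently to their canonical term via [normalize_term_id()].
#'
#' @param path path to an OBO file, or a character vector of OBO lines.
#' @return an object of class `go_ontology`: a list with elements
#'   `terms` (data.frame: `term_id`, `name`, `namespace`, `obsolete`),
#'   `edges` (data.frame: `child`, `relation`, `parent`),
#'   `alt_id` (named character, alt -> canonical), and
#'   `namespace_counts` (named integer).
#' @export
parse_obo <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else if (length(path) == 1L && grepl("\n", path)) {
    strsplit(path, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(path)
  }

  in_term <- FALSE
  cur <- NULL
  terms <- list()
  edges_child <- character(0)
  edges_rel <- character(0)
  edges_parent <- character(0)
  alt_map <- character(0)
  obsolete_ids <- character(0)

  flush_term <- function(cur) {
    if (is.null(cur$id)) {
      stop("malformed OBO stanza ending before line ", cur$line_end,
           ": [Term] without an id")
    }
    cur
  }

  stanzas <- list()
  for (i in seq_along(lines)) {
    line <- sub("!.*$", "", lines[[i]])   # strip trailing OBO comments
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[", line)) {
      if (in_term && !is.null(cur)) {
        cur$line_end <- i
        stanzas[[length(stanzas) + 1L]] <- flush_term(cur)
      }
      in_term <- identical(line, "[Term]")
      cur <- if (in_term) list(line_start = i, alt_id = character(0),
                               is_a = character(0), part_of = character(0))
             else NULL
      next
    }
    if (!in_term) next
    kv <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1L]]
    if (length(kv) != 3L) {
      stop("malformed OBO tag-value pair at line ", i, ": ", lines[[i]])
    }
    key <- kv[[2L]]; val <- trimws(kv[[3L]])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "alt_id") cur$alt_id <- c(cur$alt_id, val)
    else if (key == "is_a") cur$is_a <- c(cur$is_a, strsplit(val, "\\s")[[1L]][1L])
    else if (key == "is_obsolete") cur$obsolete <- identical(tolower(val), "true")
    else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[[1L]] == "part_of") {
        cur$part_of <- c(cur$part_of, parts[[2L]])
      }
    }
  }
  if (in_term && !is.null(cur)) {
    cur$line_end <- length(lines)
    stanzas[[length(stanzas) + 1L]] <- flush_term(cur)
  }

  ids <- character(0)
  rows <- list()
  for (st in stanzas) {
    id <- normalize_term_id(st$id)
    if (isTRUE(st$obsolete)) {
      obsolete_ids <- c(obsolete_ids, id)
      next
    }
    if (id %in% ids) stop("duplicate canonical term id in OBO input: ", id)
    ids <- c(ids, id)
    rows[[id]] <- data.frame(
      term_id = id,
      name = if (is.null(st$name)) NA_character_ else st$name,
      namespace = if (is.null(st$namespace)) "biological_process" else st$namespace,
      obsolete = FALSE,
      stringsAsFactors = FALSE
    )
    for (a in st$alt_id) {
      alt_map[[normalize_term_id(a)]] <- id
    }
    for (p in st$is_a) {
      edges_child <- c(edges_child, id)
      edges_rel <- c(edges_rel, "is_a")
      edges_parent <- c(edges_parent, normalize_term_id(p))
    }
    for (p in st$part_of) {
      edges_child <- c(edges_child, id)
      edges_rel <- c(edges_rel, "part_of")
      edges_parent <- c(edges_parent, normalize_term_id(p))
    }
  }
  if (length(obsolete_ids)) {
    warning("dropped ", length(obsolete_ids), " obsolete term(s): ",
            paste(utils::head(obsolete_ids, 3L), collapse = ", "),
            if (length(obsolete_ids) > 3L) ", ..." else "")
  }

  terms_df <- if (length(rows)) do.call(rbind, unname(rows)) else
    data.frame(term_id = character(0), name = character(0),
               namespace = character(0), obsolete = logical(0))
  edges_df <- data.frame(child = edges_child, relation = edges_rel,
                         parent = edges_parent, stringsAsFactors = FALSE)
  # edges referencing obsolete parents are dropped with the parent
  keep <- edges_df$parent %in% terms_df$term_id & edges_df$child %in% terms_df$term_id
  edges_df <- edges_df[keep, , drop = FALSE]
  rownames(edges_df) <- NULL

  graph <- structure(
    list(terms = terms_df, edges = edges_df, alt_id = alt_map,
         namespace_counts = c(table(terms_df$namespace))),
    class = "go_ontology"
  )
  graph$children <- .adjacency(graph, direction = "down")
  graph$parents <- .adjacency(graph, direction = "up")
  graph
}

# Named list: node -> data.frame(to, relation) in the requested direction.
.adjacency <- function(graph, direction = c("down", "up")) {
  direction <- match.arg(direction)
  e <- graph$edges
  from <- if (direction == "down") e$parent else e$child
  to <- if (direction == "down") e$child else e$parent
  split(data.frame(to = to, relation = e$relation, stringsAsFactors = FALSE), from)
}

#' @export
print.go_ontology <- function(x, ...) {
  cat("GO ontology graph:", nrow(x$terms), "terms,", nrow(x$edges), "edges\n")
  ns <- x$namespace_counts
  for (n in names(ns)) cat("  ", n, ": ", ns[[n]], "\n", sep = "")
  if (length(x$alt_id)) cat("  alt_id aliases:", length(x$alt_id), "\n")
  invisible(x)
}

.check_term <- function(graph, term_id) {
  if (!term_id %in% graph$terms$term_id) {
    stop("term not in ontology: ", term_id)
  }
  term_id
}

.term_namespace <- function(graph, term_id) {
  graph$terms$namespace[match(term_id, graph$terms$term_id)]
}

#' Descendant closure of a GO term
#'
#' Returns the reflexive transitive closure of a term over the chosen
#' relations ("primary GO and child GO terms"), restricted to the term's
#' namespace. The term itself is always a member. `mode = "children"`
#' restricts the expansion to direct children (plus the term itself).
#'
#' @param graph a [go_ontology] object.
#' @param term_id a single canonical term identifier (aliases accepted).
#' @param relations subset of `c("is_a", "part_of")` to traverse;
#'   defaults to `is_a` only.
#' @param mode `"descendants"` (full closure, default) or `"children"`.
#' @return character vector of term identifiers (sorted).
#' @export
go_descendants <- function(graph, term_id,
                           relations = "is_a",
                           mode = c("descendants", "children")) {
  stopifnot(inherits(graph, "go_ontology"), length(term_id) == 1L)
  mode <- match.arg(mode)
  relations <- match.arg(relations, c("is_a", "part_of"), several.ok = TRUE)
  term_id <- .check_term(graph, normalize_term_id(term_id, graph))
  ns <- .term_namespace(graph, term_id)

  step <- function(id) {
    kids <- graph$children[[id]]
    if (is.null(kids)) return(character(0))
    kids <- kids$to[kids$relation %in% relations]
    kids[.term_namespace(graph, kids) == ns]
  }
  if (mode == "children") {
    return(sort(unique(c(term_id, step(term_id)))))
  }
  seen <- character(0)
  frontier <- term_id
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(lapply(frontier, step), use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  sort(unique(seen))
}

#' Ancestor closure of a GO term
#'
#' Reflexive transitive closure towards the roots, used for true-path
#' propagation of gene annotations. Restricted to the term's namespace.
#'
#' @inheritParams go_descendants
#' @return character vector of term identifiers (sorted).
#' @export
go_ancestors <- function(graph, term_id, relations = "is_a") {
  stopifnot(inherits(graph, "go_ontology"), length(term_id) == 1L)
  relations <- match.arg(relations, c("is_a", "part_of"), several.ok = TRUE)
  term_id <- .check_term(graph, normalize_term_id(term_id, graph))
  ns <- .term_namespace(graph, term_id)
  step <- function(id) {
    par <- graph$parents[[id]]
    if (is.null(par)) return(character(0))
    par <- par$to[par$relation %in% relations]
    par[.term_namespace(graph, par) == ns]
  }
  seen <- character(0)
  frontier <- term_id
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(lapply(frontier, step), use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  sort(unique(seen))
}

#' Leaf terms of an ontology namespace
#'
#' Terms with no children over the chosen relations, within one namespace.
#'
#' @inheritParams go_descendants
#' @param namespace ontology namespace to restrict to.
#' @return character vector of term identifiers.
#' @export
go_leaves <- function(graph, namespace = "biological_process",
                      relations = "is_a") {
  ids <- graph$terms$term_id[graph$terms$namespace == namespace]
  has_child <- vapply(ids, function(id) {
    kids <- graph$children[[id]]
    !is.null(kids) && any(kids$relation %in% relations)
  }, logical(1))
  ids[!has_child]
}
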