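#' Assemble a workflow run configuration
#'
#' Collects the file paths and analysis settings for an end-to-end run.
#' Can be built directly or read from a YAML/JSON file via
#' [read_run_config()].
#'
#' @param ontology path to the OBO ontology file.
#' @param annotation path to the gene annotation (GAF or 2-column TSV).
#' @param events path to the AOP event-mapping TSV.
#' @param de_tables named character vector/list of per-condition
#'   differential-expression TSV paths (names are condition labels).
#' @param disease_genes optional path to a gene-disease TSV (required for
#'   `disease_source = "aop+genes"`).
#' @param concentrations optional path to a concentration-record TSV.
#' @param disease_label label for the disease term set.
#' @param disease_source `"aop"` (expert-curated AOP terms only) or
#'   `"aop+genes"` (augmented with the gene-centred enrichment route).
#' @param expand_mode `"descendants"` or `"children"` for the AOP term
#'   expansion.
#' @param enrichment an [enrichment_config].
#' @param outdir report output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(ontology, annotation, events, de_tables,
                       disease_genes = NULL, concentrations = NULL,
                       disease_label = "disease",
                       disease_source = c("aop", "aop+genes"),
                       expand_mode = c("descendants", "children"),
                       enrichment = enrichment_config(),
                       outdir = NULL) {
  disease_source <- match.arg(disease_source)
  expand_mode <- match.arg(expand_mode)
  de_tables <- unlist(de_tables)
  if (is.null(names(de_tables)) || any(!nzchar(names(de_tables)))) {
    names(de_tables) <- tools::file_path_sans_ext(basename(de_tables))
  }
  paths <- c(ontology = ontology, annotation = annotation, events = events,
             de_tables, disease_genes = disease_genes,
             concentrations = concentrations)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  if (disease_source == "aop+genes" && is.null(disease_genes)) {
    stop("disease_source 'aop+genes' needs a disease_genes table")
  }
  structure(
    list(ontology = ontology, annotation = annotation, events = events,
         de_tables = de_tables, disease_genes = disease_genes,
         concentrations = concentrations, disease_label = disease_label,
         disease_source = disease_source, expand_mode = expand_mode,
         enrichment = enrichment, outdir = outdir),
    class = "run_config"
  )
}

#' Read a workflow configuration from YAML or JSON
#'
#' File keys mirror the [run_config()] arguments; `enrichment` is a
#' mapping of [enrichment_config()] arguments. Relative paths are resolved
#' against the configuration file's directory.
#'
#' @param path configuration file (`.yml`, `.yaml` or `.json`).
#' @return a [run_config].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    out <- ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
    stats::setNames(out, names(p))
  }
  enr <- do.call(enrichment_config, as.list(cfg$enrichment %||% list()))
  run_config(
    ontology = resolve(cfg$ontology), annotation = resolve(cfg$annotation),
    events = resolve(cfg$events), de_tables = resolve(unlist(cfg$de_tables)),
    disease_genes = resolve(cfg$disease_genes),
    concentrations = resolve(cfg$concentrations),
    disease_label = cfg$disease_label %||% "disease",
    disease_source = cfg$disease_source %||% "aop",
    expand_mode = cfg$expand_mode %||% "descendants",
    enrichment = enr, outdir = cfg$outdir
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the exposure-to-disease linkage workflow end to end
#'
#' Orchestrates the full pipeline: parse the ontology, load and propagate
#' annotations, derive the disease GO BP set from curated AOP events
#' (optionally augmented with the gene-centred enrichment route), run
#' GSEA per exposure condition with the FDR-below-threshold selection
#' rule, compute per-condition overlaps and the cross-chemical common
#' signature, and (when concentration records are given) the in vitro vs
#' in vivo dosimetry comparison. Every number in the bundle equals what
#' the corresponding stage function returns when called directly.
#'
#' @param config a [run_config].
#' @return object of class `workflow_bundle`: list with `disease_set`,
#'   `aop_set`, `enrichment` (per condition), `enriched_sets`, `overlaps`,
#'   `overlap_matrix`, `signature` (or `NULL`), `dosimetry` (or `NULL`)
#'   and `meta` (seed, settings, package version).
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  enr <- config$enrichment

  graph <- .stage("ontology", parse_obo(config$ontology))
  message("[ontology] ", nrow(graph$terms), " terms, ", nrow(graph$edges), " edges")

  annotation <- .stage("annotation",
                       read_annotation(config$annotation, graph = graph))
  message("[annotation] ", length(annotation$term_genes), " terms, ",
          length(annotation$universe), " genes")

  events <- .stage("curation", load_event_mappings(config$events, graph = graph))
  aop_set <- .stage("curation",
                    derive_aop_term_set(events, graph, mode = config$expand_mode,
                                        source_label = config$disease_label))
  message("[curation] AOP set: ", aop_set$raw_count, " terms pre-dedup, ",
          aop_set$unique_count, " unique")

  disease_set <- aop_set
  if (config$disease_source == "aop+genes") {
    gd <- .stage("curation", read_gene_disease(config$disease_genes))
    dis_set <- .stage("curation",
                      derive_disease_term_set(unique(gd$gene_id), annotation,
                                              config = enr,
                                              source_label = config$disease_label))
    message("[curation] gene-derived set: ", dis_set$unique_count, " terms")
    disease_set <- merge_term_sets(aop_set, dis_set)
    disease_set$source_label <- config$disease_label
    message("[curation] merged disease set: ", disease_set$unique_count, " unique")
  }

  enrichment <- list()
  enriched_sets <- list()
  overlaps <- list()
  for (cond in names(config$de_tables)) {
    ranked <- .stage("enrichment",
                     read_ranked_list(config$de_tables[[cond]],
                                      condition_label = cond))
    res <- .stage("enrichment", gsea(ranked, annotation$term_genes, config = enr))
    sel <- select_significant(res, enr$fdr_threshold)
    message("[enrichment] ", cond, ": ", nrow(res), " terms tested, ",
            sel$unique_count, " below FDR ", enr$fdr_threshold)
    ov <- .stage("overlap", go_overlap(sel, disease_set))
    message("[overlap] ", cond, ": ", ov$intersection_size, " out of ",
            ov$set_b_size, " disease terms overlapping (Jaccard ",
            format(ov$jaccard, digits = 4), ")")
    enrichment[[cond]] <- res
    enriched_sets[[cond]] <- sel
    overlaps[[cond]] <- ov
  }

  signature <- if (length(overlaps) >= 2L) {
    .stage("signature", common_signature(overlaps))
  } else NULL
  if (!is.null(signature)) {
    message("[signature] ", signature$signature_size,
            " term(s) common to all ", length(overlaps), " conditions")
  }

  dosimetry <- if (!is.null(config$concentrations)) {
    .stage("dosimetry",
           compare_concentrations(read_concentrations(config$concentrations)))
  } else NULL

  structure(
    list(disease_set = disease_set, aop_set = aop_set,
         enrichment = enrichment, enriched_sets = enriched_sets,
         overlaps = overlaps,
         overlap_matrix = overlap_matrix(enriched_sets, disease_set),
         signature = signature, dosimetry = dosimetry,
         meta = list(seed = enr$seed,
                     fdr_threshold = enr$fdr_threshold,
                     n_permutations = enr$n_permutations,
                     weight_exponent = enr$weight_exponent,
                     disease_source = config$disease_source,
                     expand_mode = config$expand_mode,
                     package_version = as.character(utils::packageVersion("aoplink")),
                     config_checksum = .config_checksum(config))),
    class = "workflow_bundle"
  )
}

.config_checksum <- function(config) {
  canon <- jsonlite::toJSON(config[setdiff(names(config), "enrichment")],
                            auto_unbox = TRUE)
  canon <- paste0(canon, jsonlite::toJSON(unclass(config$enrichment),
                                          auto_unbox = TRUE))
  sum(utf8ToInt(canon) * (seq_len(nchar(canon)) %% 997)) %% 1e9
}

#' @export
print.workflow_bundle <- function(x, ...) {
  cat("Workflow bundle:", length(x$enriched_sets), "condition(s) vs",
      x$disease_set$source_label, "\n")
  print(x$overlap_matrix)
  invisible(x)
}

.write_tsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    df[[j]] <- ifelse(is.na(df[[j]]), "",
                      formatC(df[[j]], digits = digits, format = "g"))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the report bundle of a workflow run
#'
#' Emits a deterministic, stably ordered file set: `overlap_matrix.tsv`,
#' `intersection_terms.tsv`, `signature_membership.tsv` (when a signature
#' exists), per-condition `enrichment_<condition>.tsv`,
#' `dosimetry_comparisons.tsv` (when computed) and a `summary.json`
#' mirroring every figure-level number, with run metadata embedded. Two
#' runs with the same configuration and seed produce byte-identical files.
#'
#' @param bundle a `workflow_bundle` from [run_workflow()].
#' @param directory output directory (created if needed).
#' @return character vector of the files written (invisibly).
#' @export
write_report <- function(bundle, directory) {
  stopifnot(inherits(bundle, "workflow_bundle"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(directory)) stop("cannot create directory: ", directory)
  }
  if (file.access(directory, mode = 2L) != 0L) {
    stop("directory not writable: ", directory)
  }
  files <- character(0)
  add <- function(p) files <<- c(files, p)

  add(.write_tsv(bundle$overlap_matrix,
                 file.path(directory, "overlap_matrix.tsv")))

  inter <- do.call(rbind, lapply(names(bundle$overlaps), function(cond) {
    ov <- bundle$overlaps[[cond]]
    if (!length(ov$intersection_terms)) return(NULL)
    data.frame(condition = cond, term_id = ov$intersection_terms,
               stringsAsFactors = FALSE)
  }))
  if (is.null(inter)) {
    inter <- data.frame(condition = character(0), term_id = character(0))
  }
  add(.write_tsv(inter, file.path(directory, "intersection_terms.tsv")))

  for (cond in names(bundle$enrichment)) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", cond)
    add(.write_tsv(as.data.frame(bundle$enrichment[[cond]]),
                   file.path(directory, paste0("enrichment_", safe, ".tsv"))))
  }

  if (!is.null(bundle$signature)) {
    mem <- data.frame(term_id = rownames(bundle$signature$membership),
                      bundle$signature$membership * 1L,
                      common = rownames(bundle$signature$membership) %in%
                        bundle$signature$common_terms * 1L,
                      check.names = FALSE, stringsAsFactors = FALSE)
    add(.write_tsv(mem, file.path(directory, "signature_membership.tsv")))
  }

  if (!is.null(bundle$dosimetry)) {
    add(.write_tsv(bundle$dosimetry,
                   file.path(directory, "dosimetry_comparisons.tsv")))
  }

  summary <- list(
    meta = bundle$meta,
    disease_set = list(label = bundle$disease_set$source_label,
                       provenance = bundle$disease_set$provenance,
                       unique_count = bundle$disease_set$unique_count,
                       raw_count = bundle$disease_set$raw_count),
    aop_set = list(unique_count = bundle$aop_set$unique_count,
                   raw_count = bundle$aop_set$raw_count),
    overlap_matrix = bundle$overlap_matrix,
    signature = if (!is.null(bundle$signature)) list(
      chemicals = bundle$signature$chemicals,
      signature_size = bundle$signature$signature_size,
      common_terms = bundle$signature$common_terms) else NULL,
    dosimetry = bundle$dosimetry
  )
  json_path <- file.path(directory, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  add(json_path)
  invisible(files)
}
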