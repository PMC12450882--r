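#' Enrichment configuration
#'
#' Bundles the tunable parameters shared by the two enrichment engines.
#' The selection rule follows the study design: terms with FDR strictly
#' below the threshold (default 0.25) are retained.
#'
#' @param fdr_threshold selection cut-off, in (0, 1]; default 0.25.
#' @param n_permutations gene-set permutations for the GSEA null; default 1000.
#' @param weight_exponent exponent on |fold change| in the running sum;
#'   1 gives the canonical weighted statistic, 0 the classic
#'   Kolmogorov-Smirnov variant.
#' @param min_set_size,max_set_size gene-set size window (default 5-2000).
#' @param seed integer seed driving the permutation null.
#' @return an object of class `enrichment_config`.
#' @export
enrichment_config <- function(fdr_threshold = 0.25, n_permutations = 1000L,
                              weight_exponent = 1, min_set_size = 5L,
                              max_set_size = 2000L, seed = 1L) {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1,
            weight_exponent >= 0, min_set_size <= max_set_size)
  n_permutations <- as.integer(n_permutations)
  if (n_permutations == 0L) stop("n_permutations must be positive")
  if (n_permutations < 100L) {
    warning("fewer than 100 permutations gives a coarse empirical null")
  }
  structure(
    list(fdr_threshold = fdr_threshold, n_permutations = n_permutations,
         weight_exponent = weight_exponent,
         min_set_size = as.integer(min_set_size),
         max_set_size = as.integer(max_set_size), seed = as.integer(seed)),
    class = "enrichment_config"
  )
}

.enrichment_result <- function(df, method, condition_label = "") {
  rownames(df) <- NULL
  attr(df, "method") <- method
  attr(df, "condition_label") <- condition_label
  class(df) <- c("enrichment_result", "data.frame")
  df
}

#' Overrepresentation analysis (hypergeometric test)
#'
#' Tests each annotation term for overrepresentation of a query gene list
#' against a background universe: one-sided hypergeometric upper-tail
#' probability of an overlap at least as large as observed, with
#' Benjamini-Hochberg FDR across the tested terms. The default universe is
#' every gene carrying at least one BP annotation (after propagation);
#' an explicit background may be supplied instead.
#'
#' @param query character vector of query gene ids.
#' @param annotation an [annotation_table].
#' @param universe optional explicit background gene set; defaults to
#'   `annotation$universe`.
#' @param config an [enrichment_config] (size window and FDR threshold used).
#' @param case_insensitive match gene symbols case-insensitively (default).
#' @return an `enrichment_result` data.frame sorted by p then term id, with
#'   columns `term_id`, `set_size`, `statistic` (overlap count),
#'   `normalized_statistic` (odds ratio), `p_value`, `fdr`, `genes`
#'   (comma-separated overlapping genes).
#' @export
ora <- function(query, annotation, universe = NULL,
                config = enrichment_config(), case_insensitive = TRUE) {
  stopifnot(inherits(annotation, "annotation_table"))
  if (is.null(universe)) universe <- annotation$universe
  universe <- unique(as.character(universe))
  norm <- if (case_insensitive) toupper else identity
  uni_n <- norm(universe)
  q <- unique(norm(as.character(query)))
  q <- q[q %in% uni_n]
  if (!length(q)) {
    stop("no query genes map into the universe; check gene identifiers")
  }
  N <- length(universe)
  nq <- length(q)

  sets <- lapply(annotation$term_genes, function(g) unique(norm(g)[norm(g) %in% uni_n]))
  sizes <- lengths(sets)
  keep <- sizes >= config$min_set_size & sizes <= config$max_set_size
  if (!any(keep)) {
    warning("no term passes the set-size filter; empty result")
    return(.enrichment_result(
      data.frame(term_id = character(0), set_size = integer(0),
                 statistic = integer(0), normalized_statistic = numeric(0),
                 p_value = numeric(0), fdr = numeric(0), genes = character(0),
                 stringsAsFactors = FALSE), method = "ora"))
  }
  sets <- sets[keep]
  sizes <- sizes[keep]
  ov_genes <- lapply(sets, function(g) sort(g[g %in% q]))
  ov <- lengths(ov_genes)
  p <- stats::phyper(ov - 1L, sizes, N - sizes, nq, lower.tail = FALSE)
  # odds ratio of the 2x2 query/set table (Inf allowed for saturated cells)
  or <- (ov / (nq - ov)) / ((sizes - ov) / (N - sizes - nq + ov))
  res <- data.frame(
    term_id = names(sets), set_size = as.integer(sizes),
    statistic = as.integer(ov), normalized_statistic = or,
    p_value = p, fdr = stats::p.adjust(p, method = "BH"),
    genes = vapply(ov_genes, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$p_value, res$term_id, method = "radix"), , drop = FALSE]
  .enrichment_result(res, method = "ora")
}

#' @export
print.enrichment_result <- function(x, n = 10L, ...) {
  cat("Enrichment result [", attr(x, "method"), "] ",
      attr(x, "condition_label"), ": ", nrow(x), " terms\n", sep = "")
  print.data.frame(utils::head(x, n))
  invisible(x)
}

# Weighted running-sum enrichment score from hit positions in a ranked list.
# absw: |fold change|^weight in rank order; pos: sorted 1-based hit positions.
# Returns list(es, i_extreme) without materialising the N-long profile.
.es_positions <- function(absw, pos) {
  N <- length(absw)
  k <- length(pos)
  w <- absw[pos]
  if (sum(w) == 0) w <- rep(1, k)   # all-zero weights: fall back to classic KS
  w <- w / sum(w)
  if (k == N) return(list(es = 1, i_extreme = k))   # no misses
  miss <- 1 / (N - k)
  cw <- cumsum(w)
  after <- cw - (pos - seq_len(k)) * miss
  before <- after - w
  i_max <- which.max(after)
  i_min <- which.min(before)
  if (after[i_max] >= -before[i_min]) {
    list(es = after[i_max], i_extreme = i_max)
  } else {
    list(es = before[i_min], i_extreme = i_min)
  }
}

#' GSEA enrichment score for one gene set
#'
#' Computes the weighted Kolmogorov-Smirnov-like running sum over a ranked
#' gene list: genes in the set increment the sum by their normalized
#' |fold change|^weight, genes outside decrement it by 1/(N - N_hits); the
#' enrichment score (ES) is the extremum of largest absolute deviation.
#' The leading edge contains the member genes at or before the extremum
#' (ES > 0) or at or after it (ES < 0).
#'
#' @param ranked a [ranked_gene_list].
#' @param gene_set character vector of member gene ids.
#' @param weight_exponent exponent on |fold change| (default 1).
#' @return list with `es`, `running_sum` (length-N profile), `hits`
#'   (logical length N), `leading_edge` (character); or `NULL` (with a
#'   warning) when the set shares no gene with the ranked list.
#' @export
gsea_enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_gene_list"))
  hits <- ranked$gene_id %in% gene_set
  if (!any(hits)) {
    warning("gene set shares no gene with the ranked list; skipped")
    return(NULL)
  }
  N <- nrow(ranked)
  absw <- abs(ranked$fold_change)^weight_exponent
  pos <- which(hits)
  es <- .es_positions(absw, pos)
  k <- length(pos)
  w <- absw[pos]
  if (sum(w) == 0) w <- rep(1, k)
  w <- w / sum(w)
  incr <- numeric(N)
  incr[pos] <- w
  if (k < N) incr[-pos] <- -1 / (N - k)
  profile <- cumsum(incr)
  p_star <- pos[es$i_extreme]
  leading <- if (es$es >= 0) ranked$gene_id[pos[pos <= p_star]]
             else ranked$gene_id[pos[pos >= p_star]]
  list(es = es$es, running_sum = profile, hits = hits, leading_edge = leading)
}

#' Gene set enrichment analysis over a collection
#'
#' Ranked-list GSEA with a gene-set permutation null: for each gene-set
#' size in the collection, `n_permutations` random same-size gene sets are
#' drawn from the ranked genes (seeded), giving null enrichment scores.
#' NES divides ES by the mean |null ES| of the same sign and size;
#' empirical p-values are one-sided within sign; FDR follows the pooled-NES
#' procedure (null and observed NES tail fractions). Results are
#' deterministic for a fixed seed and invariant to input row order.
#'
#' @param ranked a [ranked_gene_list].
#' @param collection named list of gene sets (term id -> gene ids), e.g.
#'   `annotation$term_genes` or a GMT from [read_gmt()].
#' @param config an [enrichment_config].
#' @return an `enrichment_result` data.frame with columns `term_id`,
#'   `set_size`, `statistic` (ES), `normalized_statistic` (NES),
#'   `p_value`, `fdr`, `genes` (leading edge, comma-separated), sorted by
#'   p then term id.
#' @export
gsea <- function(ranked, collection, config = enrichment_config()) {
  stopifnot(inherits(ranked, "ranked_gene_list"), !is.null(names(collection)))
  N <- nrow(ranked)
  absw <- abs(ranked$fold_change)^config$weight_exponent

  collection <- collection[order(names(collection), method = "radix")]
  pos_list <- lapply(collection, function(g) which(ranked$gene_id %in% g))
  sizes <- lengths(pos_list)
  skipped <- sizes == 0L
  if (any(skipped)) {
    warning(sum(skipped), " gene set(s) share no gene with the ranked list; skipped")
  }
  keep <- !skipped & sizes >= config$min_set_size & sizes <= config$max_set_size
  pos_list <- pos_list[keep]
  sizes <- sizes[keep]
  if (!length(pos_list)) {
    warning("no gene set passes the size filter; empty result")
    return(.enrichment_result(
      data.frame(term_id = character(0), set_size = integer(0),
                 statistic = numeric(0), normalized_statistic = numeric(0),
                 p_value = numeric(0), fdr = numeric(0), genes = character(0),
                 stringsAsFactors = FALSE),
      method = "gsea", condition_label = attr(ranked, "condition_label")))
  }

  scored <- lapply(pos_list, function(p) .es_positions(absw, p))
  es <- vapply(scored, `[[`, numeric(1), "es")

  # permutation null: one ES sample per (unique size, permutation)
  usize <- sort(unique(sizes))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(config$seed)
  null_es <- es_null_cpp(absw, usize, config$n_permutations)  # B x length(usize)
  colnames(null_es) <- as.character(usize)

  B <- config$n_permutations
  p_value <- numeric(length(es))
  nes <- numeric(length(es))
  null_nes <- null_es  # normalized in place, size by size
  for (j in seq_along(usize)) {
    nv <- null_es[, j]
    mpos <- mean(nv[nv >= 0]); mneg <- mean(abs(nv[nv < 0]))
    null_nes[, j] <- ifelse(nv >= 0,
                            if (is.nan(mpos) || mpos == 0) 0 else nv / mpos,
                            if (is.nan(mneg) || mneg == 0) 0 else nv / mneg)
    idx <- which(sizes == usize[[j]])
    for (i in idx) {
      if (es[[i]] >= 0) {
        p_value[[i]] <- (1 + sum(nv >= es[[i]])) / (1 + sum(nv >= 0))
        nes[[i]] <- if (is.nan(mpos) || mpos == 0) 0 else es[[i]] / mpos
      } else {
        p_value[[i]] <- (1 + sum(nv <= es[[i]])) / (1 + sum(nv < 0))
        nes[[i]] <- if (is.nan(mneg) || mneg == 0) 0 else es[[i]] / mneg
      }
    }
  }

  pooled <- as.numeric(null_nes)
  n_pool_pos <- sum(pooled >= 0)
  n_pool_neg <- sum(pooled < 0)
  n_obs_pos <- sum(nes >= 0)
  n_obs_neg <- sum(nes < 0)
  fdr <- vapply(nes, function(s) {
    if (s >= 0) {
      num <- if (n_pool_pos) sum(pooled >= s) / n_pool_pos else 0
      den <- if (n_obs_pos) sum(nes >= s) / n_obs_pos else 1
    } else {
      num <- if (n_pool_neg) sum(pooled <= s) / n_pool_neg else 0
      den <- if (n_obs_neg) sum(nes <= s) / n_obs_neg else 1
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  leading <- vapply(seq_along(pos_list), function(i) {
    p <- pos_list[[i]]
    p_star <- p[scored[[i]]$i_extreme]
    g <- if (es[[i]] >= 0) ranked$gene_id[p[p <= p_star]]
         else ranked$gene_id[p[p >= p_star]]
    paste(g, collapse = ",")
  }, character(1))

  res <- data.frame(
    term_id = names(pos_list), set_size = as.integer(sizes),
    statistic = es, normalized_statistic = nes,
    p_value = p_value, fdr = fdr, genes = leading,
    stringsAsFactors = FALSE
  )
  res <- res[order(res$p_value, res$term_id, method = "radix"), , drop = FALSE]
  .enrichment_result(res, method = "gsea",
                     condition_label = attr(ranked, "condition_label"))
}

#' Select significantly enriched terms
#'
#' Applies the study's selection rule: terms with FDR strictly below the
#' threshold ("below 0.25") are retained as an enrichment-derived term set.
#'
#' @param records an `enrichment_result` from [gsea()] or [ora()].
#' @param fdr_threshold strict upper bound on FDR (default 0.25).
#' @return a [go_term_set] with `provenance = "enrichment_derived"` and the
#'   condition label as `source_label`.
#' @export
select_significant <- function(records, fdr_threshold = 0.25) {
  stopifnot(inherits(records, "enrichment_result"))
  keep <- records$fdr < fdr_threshold
  go_term_set(records$term_id[keep], provenance = "enrichment_derived",
              source_label = attr(records, "condition_label") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
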