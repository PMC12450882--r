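#' Read a concentration record table
#'
#' Tab-separated records of in vitro test concentrations and in vivo
#' internal-concentration estimates (PBK predictions or biomonitoring).
#' Required columns: `chemical`, `cas`, `context`, `medium`, `value`,
#' `unit`, `provenance`. The packaged fixture
#' `system.file("extdata", "sensitiser_concentrations.tsv", package = "aoplink")`
#' reproduces the published comparison table for the five respiratory
#' sensitisers verbatim.
#'
#' @param path TSV path or equivalent data.frame.
#' @return data.frame of class `concentration_records`.
#' @export
read_concentrations <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chemical", "cas", "context", "medium", "value", "unit", "provenance")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("concentration table lacks column(s): ", paste(miss, collapse = ", "))
  }
  tab$value <- as.numeric(tab$value)
  if (any(is.na(tab$value) | tab$value <= 0)) {
    stop("concentration values must be positive numbers")
  }
  tab$unit <- .normalize_unit(tab$unit)
  ctx <- c("in_vitro_epithelial", "in_vitro_dendritic",
           "in_vivo_predicted", "in_vivo_biomonitoring")
  bad <- setdiff(unique(tab$context), ctx)
  if (length(bad)) {
    stop("unknown context value(s): ", paste(bad, collapse = ", "))
  }
  class(tab) <- c("concentration_records", "data.frame")
  tab
}

.allowed_units <- c("uM", "mM", "ug/m3", "ug/mL", "umol/mmol-creatinine")

.normalize_unit <- function(unit) {
  u <- gsub("µ|μ", "u", trimws(unit))   # micro sign / Greek mu
  u <- sub("³", "3", u)
  bad <- setdiff(unique(u), .allowed_units)
  if (length(bad)) {
    stop("unit(s) outside the allowed vocabulary (",
         paste(.allowed_units, collapse = ", "), "): ",
         paste(bad, collapse = ", "))
  }
  u
}

#' Convert a concentration to micromolar
#'
#' Canonicalises molar and mass-based concentrations to uM. Mass-based
#' units need a molar mass; creatinine-normalised urinary concentrations
#' need an assumed urinary creatinine concentration (mmol per litre of
#' urine). Air concentrations (ug/m3) describe an external exposure
#' scenario, not an internal dose, and are deliberately not convertible
#' here: translating them into tissue concentrations is the job of a
#' kinetic (PBK) model upstream of this comparator.
#'
#' @param value positive numeric concentration.
#' @param unit one of `uM`, `mM`, `ug/mL`, `umol/mmol-creatinine`
#'   (micro-sign spellings accepted).
#' @param molar_mass g/mol, required for mass-based units.
#' @param creatinine_mmol_per_l assumed urinary creatinine concentration,
#'   required for creatinine-normalised units.
#' @return value in uM, with the conversion recorded in attribute `"trace"`.
#' @examples
#' to_micromolar(1, "mM")                                   # 1000
#' to_micromolar(14, "umol/mmol-creatinine",
#'               creatinine_mmol_per_l = 8.2)               # 114.8
#' @export
to_micromolar <- function(value, unit, molar_mass = NULL,
                          creatinine_mmol_per_l = NULL) {
  stopifnot(length(value) == 1L, length(unit) == 1L)
  if (!is.finite(value) || value <= 0) stop("concentration must be positive")
  unit <- .normalize_unit(unit)
  out <- switch(unit,
    "uM" = structure(value, trace = "uM (identity)"),
    "mM" = structure(value * 1000, trace = "mM * 1000 -> uM"),
    "ug/mL" = {
      if (is.null(molar_mass)) {
        stop("molar mass (g/mol) required to convert ug/mL to uM")
      }
      structure(value * 1000 / molar_mass,
                trace = sprintf("ug/mL * 1000 / %g g/mol -> uM", molar_mass))
    },
    "umol/mmol-creatinine" = {
      if (is.null(creatinine_mmol_per_l)) {
        stop("assumed urinary creatinine concentration (mmol/L) required ",
             "to convert umol/mmol-creatinine to uM")
      }
      structure(value * creatinine_mmol_per_l,
                trace = sprintf("umol/mmol-creatinine * %g mmol/L -> umol/L",
                                creatinine_mmol_per_l))
    },
    "ug/m3" = stop("ug/m3 is an external air concentration; internal-dose ",
                   "conversion requires a PBK model and is out of scope")
  )
  out
}

#' Fold ratio between an in vitro and an in vivo concentration
#'
#' @param in_vitro_uM,in_vivo_uM positive concentrations, both in uM.
#' @return `in_vitro_uM / in_vivo_uM` (unrounded; see [format_fold()] for
#'   the reporting convention).
#' @examples
#' fold_ratio(40, 0.023)   # ~1739
#' @export
fold_ratio <- function(in_vitro_uM, in_vivo_uM) {
  if (!all(is.finite(c(in_vitro_uM, in_vivo_uM))) ||
      any(c(in_vitro_uM, in_vivo_uM) <= 0)) {
    stop("fold_ratio needs positive concentrations")
  }
  in_vitro_uM / in_vivo_uM
}

#' Orders of magnitude of a fold ratio
#'
#' @param fold positive fold ratio.
#' @return `log10(fold)`.
#' @export
orders_of_magnitude <- function(fold) {
  if (!all(is.finite(fold)) || any(fold <= 0)) stop("fold must be positive")
  log10(fold)
}

#' Report-layer rounding of fold ratios
#'
#' Folds of 100 and above are quoted as integers, smaller folds to one
#' decimal, matching how such ratios are conventionally reported.
#'
#' @param fold numeric fold ratio(s).
#' @return rounded numeric vector.
#' @examples
#' format_fold(c(40 / 0.023, 2730 / 150, 150 / 40))  # 1739, 18.2, 3.8
#' @export
format_fold <- function(fold) {
  ifelse(is.na(fold), NA_real_,
         ifelse(fold >= 100, round(fold), round(fold, 1)))
}

#' In vitro vs in vivo concentration comparison table
#'
#' For each chemical, crosses every in vitro record with every in vivo
#' record and reports the fold ratio and its order of magnitude (all
#' values in uM). Chemicals lacking any quantitative in vivo estimate are
#' emitted as a single row with an absent fold and the reason (e.g.
#' qualitative biomarker evidence only).
#'
#' @param records a `concentration_records` table ([read_concentrations()]).
#' @return data.frame of class `exposure_comparison` with columns
#'   `chemical`, `in_vitro_context`, `in_vitro_uM`, `in_vivo_medium`,
#'   `in_vivo_uM`, `fold`, `fold_reported`, `orders_of_magnitude`, `note`.
#' @export
compare_concentrations <- function(records) {
  stopifnot(inherits(records, "concentration_records"))
  if (any(records$unit != "uM")) {
    stop("compare_concentrations expects records already in uM; ",
         "convert with to_micromolar() first")
  }
  rows <- list()
  for (chem in unique(records$chemical)) {
    r <- records[records$chemical == chem, , drop = FALSE]
    vitro <- r[startsWith(r$context, "in_vitro"), , drop = FALSE]
    vivo <- r[startsWith(r$context, "in_vivo"), , drop = FALSE]
    if (!nrow(vivo)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chemical = chem, in_vitro_context = NA_character_,
        in_vitro_uM = NA_real_, in_vivo_medium = NA_character_,
        in_vivo_uM = NA_real_, fold = NA_real_, fold_reported = NA_real_,
        orders_of_magnitude = NA_real_,
        note = "no quantitative in vivo estimate",
        stringsAsFactors = FALSE)
      next
    }
    for (i in seq_len(nrow(vitro))) for (j in seq_len(nrow(vivo))) {
      f <- fold_ratio(vitro$value[[i]], vivo$value[[j]])
      rows[[length(rows) + 1L]] <- data.frame(
        chemical = chem, in_vitro_context = vitro$context[[i]],
        in_vitro_uM = vitro$value[[i]], in_vivo_medium = vivo$medium[[j]],
        in_vivo_uM = vivo$value[[j]], fold = f,
        fold_reported = format_fold(f),
        orders_of_magnitude = orders_of_magnitude(f),
        note = "", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("exposure_comparison", "data.frame")
  out
}
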