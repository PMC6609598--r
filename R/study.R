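#' Study-level metadata table
#'
#' Builds the one-row-per-study metadata tibble used by [filter_eligible()]
#' and carried by every [expr_study] object. Sample counts refer to the
#' case-control contrast the study contributes to the mega-analysis.
#'
#' @param study_id Accession string (e.g. a GEO series id).
#' @param n_control,n_case Non-negative sample counts per group.
#' @param country Country of the study population.
#' @param year Publication year (1990-2100).
#' @param organism Organism name; eligibility requires `"Homo sapiens"`.
#' @param assay Assay type; one of `"array_rna"` or `"other"`.
#' @param design Study design; one of `"case_vs_control"` or `"other"`.
#'
#' @return A tibble with one row per study and columns `study_id`,
#'   `n_control`, `n_case`, `country`, `year`, `organism`, `assay`, `design`.
#' @export
#' @examples
#' study_meta("GSE1420", n_control = 8, n_case = 8,
#'            country = "U.S.A.", year = 2004)
study_meta <- function(study_id, n_control, n_case, country = NA_character_,
                       year = NA_integer_, organism = "Homo sapiens",
                       assay = "array_rna", design = "case_vs_control") {
  meta <- tibble(
    study_id = as.character(study_id),
    n_control = as.integer(n_control),
    n_case = as.integer(n_case),
    country = as.character(country),
    year = as.integer(year),
    organism = as.character(organism),
    assay = as.character(assay),
    design = as.character(design)
  )
  validate_study_meta(meta)
  meta
}

validate_study_meta <- function(meta) {
  stopifnot(is.data.frame(meta))
  required <- c("study_id", "n_control", "n_case", "country", "year",
                "organism", "assay", "design")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    abort(paste0("study metadata is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(meta$n_control < 0, na.rm = TRUE) ||
      any(meta$n_case < 0, na.rm = TRUE)) {
    abort("sample counts must be non-negative")
  }
  bad_year <- !is.na(meta$year) & (meta$year < 1990 | meta$year > 2100)
  if (any(bad_year)) {
    abort("publication year must lie in [1990, 2100]")
  }
  invisible(meta)
}

#' Labelled expression study
#'
#' A light container for one study's log2 expression matrix together with
#' per-sample case/control labels and study metadata. Rows are unique gene
#' (or probe) symbols, columns are samples. All stored values are assumed to
#' be on the log2 scale; ingestion functions apply the log-scale heuristic
#' before construction.
#'
#' @param values Numeric matrix, genes x samples, with non-empty unique
#'   rownames (gene symbols) and column names (sample ids).
#' @param labels Character vector, one of `"case"`/`"control"` per column.
#' @param meta One-row metadata tibble, as from [study_meta()].
#'
#' @return An object of class `expr_study` (a named list with elements
#'   `values`, `labels`, `meta`).
#' @export
expr_study <- function(values, labels, meta) {
  stopifnot(is.matrix(values), is.numeric(values))
  labels <- as.character(labels)
  if (length(labels) != ncol(values)) {
    abort("one label per sample column is required")
  }
  if (!all(labels %in% c("case", "control"))) {
    abort("labels must be 'case' or 'control'")
  }
  genes <- rownames(values)
  if (is.null(genes) || any(!nzchar(genes)) || anyDuplicated(genes)) {
    abort("rownames must be non-empty, unique gene symbols")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  validate_study_meta(meta)
  structure(list(values = values, labels = labels, meta = meta),
            class = "expr_study")
}

#' @export
print.expr_study <- function(x, ...) {
  cat(sprintf("<expr_study> %s: %d genes x %d samples (%d case / %d control)\n",
              x$meta$study_id, nrow(x$values), ncol(x$values),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' Filter candidate studies by the mega-analysis eligibility criteria
#'
#' Retains human case-vs-control array RNA studies whose total sample size
#' (cases plus controls) reaches `min_samples`, preserving input order. This
#' is the metadata screen applied before any expression data are read.
#'
#' @param candidates Study metadata tibble (see [study_meta()]).
#' @param min_samples Minimum total sample size; default 10.
#'
#' @return The eligible subset of `candidates`, a tibble in input order.
#' @export
#' @examples
#' meta <- dplyr::bind_rows(
#'   study_meta("GSE1420", 8, 8, "U.S.A.", 2004),
#'   study_meta("tiny", 5, 4, "U.S.A.", 2010)
#' )
#' filter_eligible(meta) # retains only GSE1420
filter_eligible <- function(candidates, min_samples = 10) {
  validate_study_meta(candidates)
  candidates |>
    filter(
      .data$organism == "Homo sapiens",
      .data$assay == "array_rna",
      .data$design == "case_vs_control",
      .data$n_case + .data$n_control >= min_samples
    )
}
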