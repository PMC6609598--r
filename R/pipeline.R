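#' Run the full mega-analysis pipeline from a config
#'
#' Orchestrates ingest -> effects -> pooling/model selection ->
#' significance screen -> covariate regression (and optional gene-set
#' overlap / enrichment), writing every intermediate table as TSV plus a
#' machine-readable JSON run report. Outputs are pure functions of the
#' inputs and the seedless deterministic stages, so a rerun over the same
#' config is byte-identical.
#'
#' The config is an R list (or path to a YAML file) with elements:
#' \describe{
#'   \item{studies}{List of per-study entries, each with either
#'     `series_matrix` (path) plus `label_rule`, or `matrix` + `labels`
#'     paths; optional `annot` path; optional `study_id`.}
#'   \item{metadata}{Path to the study metadata TSV (columns `study_id`,
#'     `n_control`, `n_case`, `country`, `year`, `organism`, `assay`,
#'     `design`), used for eligibility filtering and covariates.}
#'   \item{min_samples, p_max, lfc_min, rule, alpha_q, analysis_year}{
#'     Thresholds and model-selection rule; defaults 10, 1e-7, 1.0,
#'     `"isq_zero"`, 0.05, 2019.}
#'   \item{candidate_genes}{Optional path to a gene list applied before
#'     pooling.}
#'   \item{overlap}{Optional list with `set_a`, `set_b` (gene-list paths)
#'     and `universe_size`.}
#'   \item{enrich}{Optional list with `query` (gene-list path), `gmt`
#'     (collection path) and `universe_size`.}
#'   \item{outdir}{Output directory.}
#' }
#'
#' @param config List or YAML file path as described above.
#' @return Invisibly, a list with the stage tables (`meta`, `effects`,
#'   `mega`, `significant`, `mlr`, optional `overlap`, `enrichment`) and
#'   the run `report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$outdir),
            !is.null(config$studies))
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  p_max <- config$p_max %||% 1e-7
  lfc_min <- config$lfc_min %||% 1.0
  min_samples <- config$min_samples %||% 10
  rule <- config$rule %||% "isq_zero"
  alpha_q <- config$alpha_q %||% 0.05
  analysis_year <- config$analysis_year %||% 2019
  stopifnot(p_max > 0, lfc_min > 0, min_samples > 0)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  meta <- stage("metadata", {
    m <- readr::read_tsv(config$metadata, show_col_types = FALSE)
    validate_study_meta(m)
    filter_eligible(m, min_samples = min_samples)
  })

  studies <- stage("ingest", {
    loaded <- purrr::map(config$studies, function(entry) {
      annot <- if (!is.null(entry$annot)) {
        readr::read_tsv(entry$annot, show_col_types = FALSE)
      } else NULL
      st <- if (!is.null(entry$series_matrix)) {
        read_series_matrix(entry$series_matrix,
                           label_rule = entry$label_rule, annot = annot)
      } else {
        read_study_matrix(entry$matrix, entry$labels, annot = annot)
      }
      sid <- entry$study_id %||% st$meta$study_id
      row <- filter(meta, .data$study_id == sid)
      if (nrow(row) == 1) st$meta <- row
      st
    })
    keep <- vapply(loaded, function(st)
      st$meta$study_id %in% meta$study_id, logical(1))
    loaded[keep]
  })
  if (length(studies) == 0) abort("no eligible studies after filtering")

  candidates <- if (!is.null(config$candidate_genes)) {
    read_gene_list(config$candidate_genes)
  } else NULL

  effects <- stage("effects",
                   compute_effects_all(studies, genes = candidates))
  if (!is.null(candidates) && length(candidates) == 0) {
    warn("empty candidate gene list: mega-analysis output will be empty")
  }
  mega <- stage("mega", mega_analyze(effects, rule = rule,
                                     alpha_q = alpha_q))
  signif <- significance_filter(mega, p_max = p_max, lfc_min = lfc_min)

  covariates <- encode_covariates(meta, analysis_year = analysis_year)
  mlr <- if (nrow(signif) > 0) {
    stage("mlr", fit_mlr_all(
      filter(effects, .data$gene %in% signif$gene), covariates,
      analysis_year = analysis_year))
  } else tibble()
  forest <- if (nrow(signif) > 0) {
    forest_data(effects, signif)
  } else tibble()

  overlap <- if (!is.null(config$overlap)) {
    stage("overlap", overlap_test(
      read_gene_list(config$overlap$set_a),
      read_gene_list(config$overlap$set_b),
      universe_size = config$overlap$universe_size))
  } else NULL
  enrichment <- if (!is.null(config$enrich)) {
    stage("enrich", enrich(
      read_gene_list(config$enrich$query),
      read_gmt(config$enrich$gmt),
      universe_size = config$enrich$universe_size))
  } else NULL

  write_tbl <- function(tbl, name) {
    path <- file.path(outdir, paste0(name, ".tsv"))
    if (is.null(tbl)) return(invisible(NULL))
    out <- tbl
    if ("weights" %in% names(out)) {
      out$weights <- vapply(out$weights, function(w)
        paste(sprintf("%s=%.6g", names(w), w), collapse = ";"),
        character(1))
    }
    readr::write_tsv(out, path)
    path
  }
  write_tbl(meta, "eligible_studies")
  write_tbl(effects, "effects")
  write_tbl(mega, "mega_analysis")
  write_tbl(signif, "significant_genes")
  if (nrow(signif) > 0) {
    write_tbl(mlr, "mlr_analysis")
    write_tbl(forest, "forest_data")
  }
  if (!is.null(overlap)) write_tbl(overlap, "overlap")
  if (!is.null(enrichment)) write_tbl(enrichment, "enrichment")

  report <- list(
    package_version = as.character(utils::packageVersion("megaexpr")),
    thresholds = list(p_max = p_max, lfc_min = lfc_min,
                      min_samples = min_samples, rule = rule,
                      alpha_q = alpha_q, analysis_year = analysis_year),
    counts = list(
      studies_eligible = nrow(meta),
      studies_loaded = length(studies),
      genes_with_effects = dplyr::n_distinct(effects$gene),
      genes_pooled = nrow(mega),
      genes_significant = nrow(signif)
    )
  )
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(meta = meta, effects = effects, mega = mega,
                 significant = signif, mlr = mlr, forest = forest,
                 overlap = overlap, enrichment = enrichment,
                 report = report))
}
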