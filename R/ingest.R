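#' Label samples by substring rules
#'
#' A label rule is a list with character vectors `case`, `control` and
#' optionally `exclude`; each element is matched case-insensitively as a
#' fixed substring against a sample's descriptive text (title plus any
#' characteristics fields). A sample matching both a case and a control
#' pattern is an error rather than a silent choice; samples matching an
#' exclude pattern, or nothing at all, are dropped.
#'
#' @param texts Character vector of per-sample descriptive strings.
#' @param label_rule List with elements `case`, `control`, optionally
#'   `exclude`, each a character vector of substrings.
#'
#' @return Character vector the length of `texts` with values `"case"`,
#'   `"control"` or `NA` (dropped).
#' @export
apply_label_rule <- function(texts, label_rule) {
  stopifnot(is.list(label_rule))
  if (is.null(label_rule$case) || is.null(label_rule$control)) {
    abort("label_rule must supply both 'case' and 'control' patterns")
  }
  match_any <- function(patterns) {
    if (length(patterns) == 0) return(rep(FALSE, length(texts)))
    hits <- vapply(patterns, function(p) {
      stringr::str_detect(texts, stringr::fixed(p, ignore_case = TRUE))
    }, logical(length(texts)))
    if (length(texts) == 1L) hits <- matrix(hits, nrow = 1L)
    apply(hits, 1, any)
  }
  is_excl <- match_any(label_rule$exclude %||% character())
  is_case <- match_any(label_rule$case) & !is_excl
  is_ctrl <- match_any(label_rule$control) & !is_excl
  both <- which(is_case & is_ctrl)
  if (length(both) > 0) {
    abort(paste0("sample(s) match both case and control rules: ",
                 paste(head(texts[both], 3), collapse = "; ")))
  }
  out <- rep(NA_character_, length(texts))
  out[is_case] <- "case"
  out[is_ctrl] <- "control"
  out
}

# Heuristic separating linear-scale (MAS5-style) from log2 matrices:
# a 99th percentile above 50 is implausible for log2 intensities.
maybe_log2 <- function(values) {
  finite <- values[is.finite(values)]
  if (length(finite) == 0) return(list(values = values, transformed = FALSE))
  if (stats::quantile(finite, 0.99, names = FALSE) > 50) {
    list(values = log2(values + 1), transformed = TRUE)
  } else {
    list(values = values, transformed = FALSE)
  }
}

# Average log2 values across probes mapping to one symbol; unannotated
# probes are dropped. Deterministic and order-independent.
collapse_probes <- function(values, annot) {
  stopifnot(is.data.frame(annot))
  names(annot)[1:2] <- c("probe_id", "gene_symbol")
  annot <- annot |>
    mutate(gene_symbol = trimws(as.character(.data$gene_symbol))) |>
    filter(!is.na(.data$gene_symbol), nzchar(.data$gene_symbol))
  keep <- intersect(rownames(values), annot$probe_id)
  if (length(keep) == 0) abort("no probes match the annotation table")
  sym <- setNames(annot$gene_symbol, annot$probe_id)[keep]
  sub <- values[keep, , drop = FALSE]
  out <- rowsum(sub, group = sym, na.rm = TRUE)
  counts <- rowsum((!is.na(sub)) * 1, group = sym)
  out <- out / counts
  out[counts == 0] <- NA_real_
  out[order(rownames(out)), , drop = FALSE]
}

parse_numeric_cells <- function(raw, genes, samples) {
  raw <- trimws(raw)
  raw[raw %in% c("", "null", "NULL", "NA")] <- NA
  values <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & is.na(values))
  if (length(bad) > 0) {
    i <- bad[1]
    row <- ((i - 1) %% length(genes)) + 1
    col <- ((i - 1) %/% length(genes)) + 1
    abort(sprintf("non-numeric expression cell '%s' at gene %s, sample %s",
                  raw[i], genes[row], samples[col]))
  }
  matrix(values, nrow = length(genes),
         dimnames = list(genes, samples))
}

#' Read a GEO Series Matrix file into a labelled expression study
#'
#' Parses the header (`!`-prefixed key-value lines) and the sample table
#' between `!series_matrix_table_begin` and `!series_matrix_table_end`.
#' Per-sample text used for labelling is the concatenation of the sample
#' title and all characteristics fields. Expression values are placed on the
#' log2 scale automatically: if the 99th percentile of finite values exceeds
#' 50 the matrix is treated as linear and `log2(x + 1)` is applied, otherwise
#' values are kept as-is. Blank or `"null"` cells become missing. When a
#' probe-to-symbol annotation is supplied, probe rows are collapsed to gene
#' symbols by averaging.
#'
#' @param path Path to a Series Matrix TXT file, plain or gzip-compressed.
#' @param label_rule Substring labelling rule; see [apply_label_rule()].
#' @param annot Optional two-column data frame (`probe_id`, `gene_symbol`).
#' @param meta Optional one-row metadata tibble ([study_meta()]); when
#'   omitted, minimal metadata are derived from the header, with group sizes
#'   from the labelling.
#'
#' @return An [expr_study] whose columns are the samples labelled case or
#'   control; excluded and unmatched samples are dropped.
#' @export
read_series_matrix <- function(path, label_rule, annot = NULL, meta = NULL) {
  lines <- readr::read_lines(path)
  is_hdr <- startsWith(lines, "!")
  tbl_begin <- which(lines == "!series_matrix_table_begin")
  tbl_end <- which(lines == "!series_matrix_table_end")
  if (length(tbl_begin) != 1 || length(tbl_end) != 1 || tbl_end <= tbl_begin) {
    abort("malformed Series Matrix: missing or misordered table begin/end markers")
  }
  hdr_lines <- lines[is_hdr & seq_along(lines) < tbl_begin]
  bad_hdr <- hdr_lines[!grepl("^![A-Za-z_][A-Za-z0-9_]*(\t|$)", hdr_lines)]
  if (length(bad_hdr) > 0) {
    abort(paste0("malformed header line: ", bad_hdr[1]))
  }
  hdr <- strsplit(hdr_lines, "\t", fixed = TRUE)
  keys <- vapply(hdr, `[[`, character(1), 1)
  vals <- lapply(hdr, function(x) gsub('^"|"$', "", x[-1]))

  sample_fields <- keys %in% c("!Sample_title", "!Sample_source_name_ch1") |
    startsWith(keys, "!Sample_characteristics")
  texts <- if (any(sample_fields)) {
    parts <- vals[sample_fields]
    n <- max(lengths(parts))
    m <- vapply(parts, function(v) {
      length(v) <- n
      replace(v, is.na(v), "")
    }, character(n))
    if (n == 1L) m <- matrix(m, nrow = 1L)
    apply(m, 1, paste, collapse = " | ")
  } else character(0)

  tbl <- lines[(tbl_begin + 1):(tbl_end - 1)]
  cells <- strsplit(tbl, "\t", fixed = TRUE)
  header_row <- gsub('^"|"$', "", cells[[1]])
  samples <- header_row[-1]
  body <- cells[-1]
  genes <- vapply(body, function(x) gsub('^"|"$', "", x[[1]]), character(1))
  raw <- unlist(lapply(body, function(x) {
    x <- gsub('^"|"$', "", x[-1])
    length(x) <- length(samples)
    x
  }))
  values <- matrix(trimws(raw), nrow = length(samples)) |> t()
  values <- parse_numeric_cells(as.vector(values), genes, samples)

  if (length(texts) == 0) texts <- samples
  if (length(texts) != length(samples)) {
    abort("header sample fields do not match the table's sample columns")
  }
  labels <- apply_label_rule(texts, label_rule)
  keep <- !is.na(labels)
  if (sum(labels[keep] == "case") == 0 || sum(labels[keep] == "control") == 0) {
    abort("labelling produced zero case or zero control samples")
  }
  values <- values[, keep, drop = FALSE]
  labels <- labels[keep]

  step <- maybe_log2(values)
  values <- step$values
  if (!is.null(annot)) values <- collapse_probes(values, annot)

  if (is.null(meta)) {
    sid <- if (any(keys == "!Series_geo_accession")) vals[[which(keys == "!Series_geo_accession")[1]]][1] else "unknown"
    meta <- study_meta(sid, n_control = sum(labels == "control"),
                      n_case = sum(labels == "case"))
  }
  expr_study(values, labels, meta)
}

#' Read a plain TSV expression matrix plus a label file
#'
#' The matrix has a header row of sample ids and a first column of gene (or
#' probe) ids; the label file has two columns (`sample_id`,
#' `case`/`control`). The same log-scale heuristic and optional probe
#' collapsing as [read_series_matrix()] apply.
#'
#' @param matrix_path,labels_path TSV file paths.
#' @param annot Optional probe annotation data frame.
#' @param meta Optional one-row metadata tibble.
#' @return An [expr_study].
#' @export
read_study_matrix <- function(matrix_path, labels_path, annot = NULL,
                              meta = NULL) {
  mat_df <- readr::read_tsv(matrix_path, col_types = readr::cols(
    .default = readr::col_character()))
  genes <- mat_df[[1]]
  samples <- names(mat_df)[-1]
  values <- parse_numeric_cells(unlist(mat_df[-1], use.names = FALSE),
                                genes, samples)
  lab_df <- readr::read_tsv(labels_path,
                            col_names = c("sample_id", "label"),
                            col_types = "cc")
  labels <- setNames(lab_df$label, lab_df$sample_id)[samples]
  if (anyNA(labels)) abort("label file is missing some matrix samples")
  keep <- labels %in% c("case", "control")
  values <- values[, keep, drop = FALSE]
  labels <- unname(labels[keep])
  step <- maybe_log2(values)
  values <- step$values
  if (!is.null(annot)) values <- collapse_probes(values, annot)
  if (is.null(meta)) {
    meta <- study_meta("unknown", n_control = sum(labels == "control"),
                      n_case = sum(labels == "case"))
  }
  expr_study(values, labels, meta)
}

#' Write an expression study as a plain matrix, label and metadata TSV trio
#'
#' Values are serialised with 17 significant digits so that reading the trio
#' back with [read_study_matrix()] reproduces genes, labels and values
#' exactly.
#'
#' @param study An [expr_study].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; defaults to the study id.
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_study <- function(study, dir, prefix = study$meta$study_id) {
  stopifnot(inherits(study, "expr_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, paste0(prefix, "_matrix.tsv")),
    labels = file.path(dir, paste0(prefix, "_labels.tsv")),
    meta = file.path(dir, paste0(prefix, "_meta.tsv"))
  )
  vals <- study$values
  chr <- matrix(sprintf("%.17g", vals), nrow = nrow(vals))
  chr[is.na(vals)] <- ""
  lines <- c(
    paste(c("gene", colnames(vals)), collapse = "\t"),
    vapply(seq_len(nrow(vals)), function(i) {
      paste(c(rownames(vals)[i], chr[i, ]), collapse = "\t")
    }, character(1))
  )
  readr::write_lines(lines, paths["matrix"])
  readr::write_tsv(tibble(sample_id = colnames(vals), label = study$labels),
                   paths["labels"], col_names = FALSE)
  readr::write_tsv(study$meta, paths["meta"])
  invisible(paths)
}
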