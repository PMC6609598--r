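#' Per-gene effect sizes for one study
#'
#' Computes, for every gene with sufficient data, the log2 fold change
#' (mean log2 case minus mean log2 control) and its within-study variance
#' `s_case^2 / n_case + s_control^2 / n_control` (unbiased group variances;
#' the delta-method variance of a difference of means). Genes with fewer
#' than two non-missing case or control samples are omitted — this is what
#' makes a gene "absent" from a study and lets it contribute to fewer than
#' all datasets downstream.
#'
#' Variances are floored at `var_floor` so that degenerate
#' constant-expression genes keep finite inverse-variance weights.
#'
#' @param study An [expr_study] with at least two case and two control
#'   samples.
#' @param var_floor Lower clamp for the within-study variance; default 1e-8.
#'
#' @return A tibble with columns `gene`, `study_id`, `lfc`, `variance`,
#'   `n_case`, `n_control`, one row per retained gene.
#' @export
#' @examples
#' vals <- rbind(A = c(6, 7, 4, 5))
#' colnames(vals) <- paste0("S", 1:4)
#' st <- expr_study(vals, c("case", "case", "control", "control"),
#'                  study_meta("demo", 2, 2))
#' compute_effects(st)  # lfc = 2, variance = 0.5
compute_effects <- function(study, var_floor = 1e-8) {
  stopifnot(inherits(study, "expr_study"))
  is_case <- study$labels == "case"
  if (sum(is_case) < 2 || sum(!is_case) < 2) {
    abort("effect computation needs at least two case and two control samples")
  }
  vals <- study$values
  case <- vals[, is_case, drop = FALSE]
  ctrl <- vals[, !is_case, drop = FALSE]
  n_case <- rowSums(!is.na(case))
  n_ctrl <- rowSums(!is.na(ctrl))
  keep <- n_case >= 2 & n_ctrl >= 2

  row_var <- function(m, mu, n) {
    ss <- rowSums((m - mu)^2, na.rm = TRUE)
    ifelse(n >= 2, ss / (n - 1), NA_real_)
  }
  mu_case <- rowMeans(case, na.rm = TRUE)
  mu_ctrl <- rowMeans(ctrl, na.rm = TRUE)
  v <- row_var(case, mu_case, n_case) / n_case +
    row_var(ctrl, mu_ctrl, n_ctrl) / n_ctrl

  tibble(
    gene = rownames(vals)[keep],
    study_id = study$meta$study_id,
    lfc = unname((mu_case - mu_ctrl)[keep]),
    variance = unname(pmax(v[keep], var_floor)),
    n_case = unname(as.integer(n_case[keep])),
    n_control = unname(as.integer(n_ctrl[keep]))
  )
}

#' Effect sizes across a list of studies
#'
#' Convenience wrapper binding [compute_effects()] results over several
#' studies into one long table, optionally restricted to a candidate gene
#' list before any pooling happens.
#'
#' @param studies List of [expr_study] objects.
#' @param genes Optional character vector restricting the output.
#' @inheritParams compute_effects
#' @return Long tibble of per-gene, per-study effects.
#' @export
compute_effects_all <- function(studies, genes = NULL, var_floor = 1e-8) {
  out <- purrr::map(studies, compute_effects, var_floor = var_floor) |>
    bind_rows()
  if (!is.null(genes)) out <- filter(out, .data$gene %in% genes)
  out
}
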