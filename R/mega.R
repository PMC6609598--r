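two_sided_p <- function(z) 2 * pnorm(-abs(z))

# Label extreme p-values the way underflowed MATLAB output prints them.
format_p <- function(p) {
  ifelse(p < 1e-320, "<1.00e-320", sprintf("%.2e", p))
}

check_one_gene <- function(effects) {
  stopifnot(is.data.frame(effects))
  need <- c("gene", "study_id", "lfc", "variance")
  if (!all(need %in% names(effects))) {
    abort("effects must have columns gene, study_id, lfc, variance")
  }
  if (nrow(effects) == 0) abort("effects for a gene must be non-empty")
  if (dplyr::n_distinct(effects$gene) != 1) {
    abort("effects passed to a pooling step must share one gene")
  }
  if (any(effects$variance <= 0)) abort("all variances must be positive")
  invisible(effects)
}

pool_with_weights <- function(effects, w, tau2, model) {
  sw <- sum(w)
  pooled <- sum(w * effects$lfc) / sw
  se <- sqrt(1 / sw)
  z <- pooled / se
  tibble(
    gene = effects$gene[1],
    model = model,
    k = nrow(effects),
    pooled_lfc = pooled,
    se = se,
    z = z,
    p = two_sided_p(z),
    tau2 = tau2,
    weights = list(setNames(w / sw, effects$study_id))
  )
}

#' Fixed-effect inverse-variance pooling for one gene
#'
#' Weights each study by the reciprocal of its within-study variance. The
#' pooled log2 fold change is the weighted mean, its standard error is
#' `sqrt(1 / sum(w))`, and the p-value is the two-sided standard-normal test
#' of `pooled / se`.
#'
#' @param effects Effect rows for a single gene (columns `gene`,
#'   `study_id`, `lfc`, `variance`); at least one row.
#'
#' @return One-row tibble with `gene`, `model`, `k`, `pooled_lfc`, `se`,
#'   `z`, `p`, `tau2` (zero here) and a list-column `weights` of normalized
#'   per-study weights.
#' @export
#' @examples
#' eff <- tibble::tibble(gene = "G", study_id = c("s1", "s2"),
#'                       lfc = c(1, 2), variance = c(0.25, 0.25))
#' pool_fixed(eff)  # pooled_lfc 1.5, se sqrt(1/8)
pool_fixed <- function(effects) {
  check_one_gene(effects)
  pool_with_weights(effects, 1 / effects$variance, tau2 = 0, model = "fixed")
}

#' Cochran's Q heterogeneity statistics for one gene
#'
#' `Q` is the inverse-variance weighted sum of squared deviations of study
#' effects from the fixed-effect pooled estimate, referred to a chi-square
#' distribution with `df = k - 1`. `q_p` is the upper-tail probability that
#' a Q at least this large arises from within-study variation alone. The
#' heterogeneity percentage is `isq = 100 * (Q - df) / Q`, set to 0 whenever
#' `Q <= df`. A single-study input is a documented degenerate case, not an
#' error: `Q = 0, df = 0, q_p = 1, isq = 0`.
#'
#' @inheritParams pool_fixed
#' @return One-row tibble with columns `Q`, `df`, `q_p`, `isq`.
#' @export
heterogeneity <- function(effects) {
  check_one_gene(effects)
  k <- nrow(effects)
  if (k < 2) {
    return(tibble(Q = 0, df = 0L, q_p = 1, isq = 0))
  }
  w <- 1 / effects$variance
  pooled <- sum(w * effects$lfc) / sum(w)
  Q <- sum(w * (effects$lfc - pooled)^2)
  df <- k - 1L
  tibble(
    Q = Q,
    df = df,
    q_p = pchisq(Q, df, lower.tail = FALSE),
    isq = if (Q <= df) 0 else 100 * (Q - df) / Q
  )
}

#' Random-effects pooling for one gene (DerSimonian-Laird)
#'
#' Estimates the between-study variance by the method-of-moments
#' DerSimonian-Laird formula `tau2 = max(0, (Q - df) / (S1 - S2 / S1))` with
#' `S1 = sum(w)`, `S2 = sum(w^2)` over the fixed-effect weights, then pools
#' with weights `1 / (variance + tau2)`. When `Q <= df` the estimate
#' truncates to zero and the result coincides numerically with
#' [pool_fixed()] (apart from the model label).
#'
#' @inheritParams pool_fixed
#' @return One-row tibble in the same shape as [pool_fixed()].
#' @export
pool_random <- function(effects) {
  check_one_gene(effects)
  if (nrow(effects) < 2) {
    abort("random-effects pooling needs at least two studies")
  }
  w <- 1 / effects$variance
  het <- heterogeneity(effects)
  s1 <- sum(w)
  s2 <- sum(w^2)
  tau2 <- max(0, (het$Q - het$df) / (s1 - s2 / s1))
  pool_with_weights(effects, 1 / (effects$variance + tau2),
                    tau2 = tau2, model = "random")
}

#' Mega-analysis: pool every gene across studies with model selection
#'
#' For each gene the available studies are pooled (genes measured on fewer
#' platforms are pooled over their available studies only, so `k` varies by
#' gene). Heterogeneity statistics decide the model: under the default
#' `"isq_zero"` rule the fixed-effect model is used exactly when the
#' truncated heterogeneity percentage is zero (`Q <= df`), otherwise the
#' random-effects model; under `"q_p_threshold"` the fixed model is used
#' when the Q test is non-significant (`q_p > alpha_q`). Single-study genes
#' are reported as fixed-model results equal to their one study's effect.
#'
#' A Benjamini-Hochberg FDR column (`fdr`) is included as supplementary
#' output; the conventional significance screen ([significance_filter()])
#' uses the raw p-values.
#'
#' @param effects Long effects table over all studies (from
#'   [compute_effects_all()]).
#' @param rule Model-selection rule, `"isq_zero"` (default) or
#'   `"q_p_threshold"`.
#' @param alpha_q Q-test significance level for the `"q_p_threshold"` rule.
#' @param genes Optional candidate gene list applied before pooling.
#'
#' @return A tibble of class `mega_result` with one row per gene: `gene`,
#'   `model`, `k`, `pooled_lfc`, `se`, `z`, `p`, `p_label`, `fdr`, `Q`,
#'   `df`, `q_p`, `isq`, `tau2`, and the normalized `weights` list-column.
#'   Sorted by ascending p.
#' @export
mega_analyze <- function(effects, rule = c("isq_zero", "q_p_threshold"),
                         alpha_q = 0.05, genes = NULL) {
  rule <- match.arg(rule)
  if (!is.null(genes)) effects <- filter(effects, .data$gene %in% genes)
  if (nrow(effects) == 0) {
    warn("no effects to pool; returning an empty mega-analysis table")
    empty <- tibble(
      gene = character(), model = character(), k = integer(),
      pooled_lfc = double(), se = double(), z = double(), p = double(),
      p_label = character(), fdr = double(), tau2 = double(),
      weights = list(), Q = double(), df = integer(), q_p = double(),
      isq = double()
    )
    return(structure(empty, class = c("mega_result", class(empty))))
  }
  res <- effects |>
    dplyr::group_split(.data$gene) |>
    purrr::map(function(eff) {
      het <- heterogeneity(eff)
      use_fixed <- nrow(eff) < 2 ||
        (rule == "isq_zero" && het$isq == 0) ||
        (rule == "q_p_threshold" && het$q_p > alpha_q)
      pooled <- if (use_fixed) pool_fixed(eff) else pool_random(eff)
      bind_cols(pooled, het)
    }) |>
    bind_rows() |>
    mutate(
      p_label = format_p(.data$p),
      fdr = p.adjust(.data$p, method = "BH")
    ) |>
    arrange(.data$p, .data$gene) |>
    relocate("p_label", "fdr", .after = "p")
  structure(res, class = c("mega_result", class(res)))
}

#' Significance screen on pooled results
#'
#' Retains results with `p < p_max` and `|pooled_lfc| > lfc_min` (strict
#' inequalities), preserving order. The defaults correspond to a raw
#' p-value below 1e-7 together with an expression change greater than
#' two-fold in either direction.
#'
#' @param results A [mega_analyze()] table.
#' @param p_max Raw p-value cutoff; default `1e-7`.
#' @param lfc_min Minimum absolute pooled log2 fold change; default 1.
#' @return The retained subset, same columns and class.
#' @export
significance_filter <- function(results, p_max = 1e-7, lfc_min = 1.0) {
  out <- filter(results, .data$p < p_max, abs(.data$pooled_lfc) > lfc_min)
  structure(out, class = unique(c("mega_result", class(out))))
}

#' Per-study forest-plot quantities
#'
#' Expands pooled results into per gene-by-study rows holding each study's
#' effect, its 95% confidence interval and its normalized weight in
#' percent — the quantities drawn in a standard forest plot.
#'
#' @param effects Long effects table used for the pooling.
#' @param results The corresponding [mega_analyze()] table.
#' @param conf_level Interval coverage; default 0.95.
#' @return Tibble of class `mega_forest`: `gene`, `study_id`, `lfc`,
#'   `ci_low`, `ci_high`, `weight_percent`, plus the pooled `pooled_lfc`,
#'   `pooled_ci_low`, `pooled_ci_high` repeated per gene.
#' @export
forest_data <- function(effects, results, conf_level = 0.95) {
  zc <- qnorm(1 - (1 - conf_level) / 2)
  weights_tbl <- results |>
    select("gene", "weights") |>
    mutate(weights = purrr::map(.data$weights, ~ tibble(
      study_id = names(.x), weight_percent = 100 * unname(.x)))) |>
    tidyr::unnest("weights")
  out <- effects |>
    filter(.data$gene %in% results$gene) |>
    mutate(
      ci_low = .data$lfc - zc * sqrt(.data$variance),
      ci_high = .data$lfc + zc * sqrt(.data$variance)
    ) |>
    left_join(weights_tbl, by = c("gene", "study_id")) |>
    left_join(
      results |>
        mutate(pooled_ci_low = .data$pooled_lfc - zc * .data$se,
               pooled_ci_high = .data$pooled_lfc + zc * .data$se) |>
        select("gene", "model", "pooled_lfc", "pooled_ci_low",
               "pooled_ci_high"),
      by = "gene"
    ) |>
    select("gene", "study_id", "lfc", "ci_low", "ci_high", "weight_percent",
           "model", "pooled_lfc", "pooled_ci_low", "pooled_ci_high")
  structure(out, class = unique(c("mega_forest", class(out))))
}
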