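#' Forest plot of per-study and pooled effects
#'
#' Draws, per gene, each study's log2 fold change with its 95% interval
#' (point area proportional to the pooling weight) and the pooled estimate
#' as a diamond-coloured summary row.
#'
#' @param object A `mega_forest` tibble from [forest_data()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mega_forest <- function(object, ...) {
  pooled <- object |>
    distinct(.data$gene, .data$pooled_lfc, .data$pooled_ci_low,
             .data$pooled_ci_high) |>
    mutate(study_id = "Pooled", lfc = .data$pooled_lfc,
           ci_low = .data$pooled_ci_low, ci_high = .data$pooled_ci_high,
           weight_percent = NA_real_, row_kind = "pooled")
  dat <- object |>
    mutate(row_kind = "study") |>
    bind_rows(pooled) |>
    mutate(study_id = factor(.data$study_id,
                             levels = rev(unique(.data$study_id))))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$lfc, y = .data$study_id)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight_percent,
                                     colour = .data$row_kind),
                        na.rm = TRUE) +
    ggplot2::geom_point(data = dplyr::filter(dat, .data$row_kind == "pooled"),
                        shape = 18, size = 4, colour = "#b2182b") +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene), scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(study = "#2166ac",
                                            pooled = "#b2182b"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change (case vs control)", y = NULL,
                  size = "Weight (%)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mega_forest
#' @param effects,results Passed to [forest_data()] for convenience.
#' @export
plot_forest <- function(effects, results) {
  autoplot(forest_data(effects, results))
}

#' Volcano plot of a mega-analysis
#'
#' Pooled log2 fold change against -log10 p, with the significance screen
#' thresholds drawn as reference lines.
#'
#' @param results A [mega_analyze()] table.
#' @param p_max,lfc_min Thresholds to display; defaults mirror
#'   [significance_filter()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, p_max = 1e-7, lfc_min = 1.0) {
  dat <- results |>
    mutate(
      neg_log10_p = -log10(pmax(.data$p, 1e-320)),
      significant = .data$p < p_max & abs(.data$pooled_lfc) > lfc_min
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pooled_lfc,
                                    y = .data$neg_log10_p,
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dotted") +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min),
                        linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "pooled log2 fold change", y = "-log10 p",
                  colour = "significant") +
    ggplot2::theme_minimal()
}
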