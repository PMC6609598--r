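#' Encode study covariates for effect-size regression
#'
#' Builds the per-study design covariates: total sample size, an ordinal
#' region code, and study age in years. The region code is a deterministic
#' alphabetical country-to-integer table — with a handful of studies an
#' ordinal code is the only encoding the degrees of freedom can support,
#' though one-hot dummies are available via `one_hot = TRUE`.
#'
#' @param meta Study metadata tibble with `study_id`, `n_case`,
#'   `n_control`, `country`, `year`.
#' @param analysis_year Reference year for study age; default 2019.
#' @param one_hot Emit one dummy column per country instead of the ordinal
#'   code.
#' @return Tibble with `study_id`, `sample_size`, `study_age` and either
#'   `region_code` or `region_<country>` dummies.
#' @export
encode_covariates <- function(meta, analysis_year = 2019, one_hot = FALSE) {
  stopifnot(all(c("study_id", "n_case", "n_control", "country", "year")
                %in% names(meta)))
  out <- tibble(
    study_id = meta$study_id,
    sample_size = meta$n_case + meta$n_control,
    study_age = analysis_year - meta$year
  )
  if (any(out$study_age < 0, na.rm = TRUE)) {
    abort("analysis_year precedes a study's publication year")
  }
  countries <- sort(unique(meta$country))
  if (one_hot) {
    for (ct in countries[-1]) {
      out[[paste0("region_", gsub("[^A-Za-z0-9]+", "_", ct))]] <-
        as.integer(meta$country == ct)
    }
  } else {
    out$region_code <- match(meta$country, countries)
  }
  relocate(out, "study_id", "sample_size",
           dplyr::starts_with("region"), "study_age")
}

#' Regress a gene's per-study effect sizes on study covariates
#'
#' Ordinary least squares of the per-study log2 fold change on sample size,
#' region code and study age (one observation per study), with t-based
#' p-values and 95% confidence intervals per coefficient. Constant
#' (rank-deficient) predictor columns are dropped and recorded. When no
#' residual degrees of freedom remain — for example four studies against
#' three predictors plus an intercept — the fit is reported with status
#' `"insufficient_df"` and missing statistics rather than fabricated
#' p-values.
#'
#' @param gene_effects Effect rows for one gene: columns `study_id`, `lfc`
#'   (a `gene` column, if present, names the result).
#' @param covariates Covariate tibble from [encode_covariates()], or a raw
#'   metadata table with `study_id`, `sample_size`/`n_case` + `n_control`,
#'   `country`, `year` which is encoded on the fly.
#' @param analysis_year Passed to [encode_covariates()] when encoding.
#' @param conf_level Confidence level; default 0.95.
#'
#' @return An object of class `mlr_fit` with [tidy()] and [glance()]
#'   methods; `tidy()` yields one row per term (`term`, `estimate`,
#'   `p_value`, `ci_low`, `ci_high`).
#' @export
fit_mlr <- function(gene_effects, covariates, analysis_year = 2019,
                    conf_level = 0.95) {
  stopifnot(all(c("study_id", "lfc") %in% names(gene_effects)))
  gene <- if ("gene" %in% names(gene_effects)) {
    unique(gene_effects$gene)
  } else NA_character_
  if (length(gene) != 1) abort("fit_mlr expects effects for a single gene")
  if (!"sample_size" %in% names(covariates)) {
    covariates <- encode_covariates(covariates, analysis_year = analysis_year)
  }
  missing_ids <- setdiff(gene_effects$study_id, covariates$study_id)
  if (length(missing_ids) > 0) {
    abort(paste0("no covariate row for study: ",
                 paste(missing_ids, collapse = ", ")))
  }
  dat <- left_join(gene_effects, covariates, by = "study_id")
  terms <- setdiff(names(covariates), "study_id")
  constant <- terms[vapply(terms, function(t)
    dplyr::n_distinct(dat[[t]]) < 2, logical(1))]
  used <- setdiff(terms, constant)

  fml <- stats::reformulate(if (length(used) > 0) used else "1",
                            response = "lfc")
  fit <- lm(fml, data = dat)
  residual_df <- fit$df.residual
  status <- if (residual_df >= 1) "ok" else "insufficient_df"

  coefs <- coef(fit)
  if (status == "ok") {
    sm <- summary(fit)$coefficients
    ci <- confint(fit, level = conf_level)
    tidy_tbl <- tibble(
      term = rownames(sm),
      estimate = unname(sm[, "Estimate"]),
      std_error = unname(sm[, "Std. Error"]),
      p_value = unname(sm[, "Pr(>|t|)"]),
      ci_low = unname(ci[rownames(sm), 1]),
      ci_high = unname(ci[rownames(sm), 2])
    )
  } else {
    tidy_tbl <- tibble(
      term = names(coefs),
      estimate = unname(coefs),
      std_error = NA_real_,
      p_value = NA_real_,
      ci_low = NA_real_,
      ci_high = NA_real_
    )
  }
  tidy_tbl <- mutate(tidy_tbl,
                     term = ifelse(.data$term == "(Intercept)",
                                   "intercept", .data$term))
  structure(
    list(gene = gene, fit = fit, coefficients = tidy_tbl,
         residual_df = residual_df, status = status,
         dropped_terms = constant, n_studies = nrow(dat),
         conf_level = conf_level),
    class = "mlr_fit"
  )
}

#' @export
print.mlr_fit <- function(x, ...) {
  cat(sprintf("<mlr_fit> gene %s: %d studies, residual df %d, status %s\n",
              x$gene, x$n_studies, x$residual_df, x$status))
  if (length(x$dropped_terms) > 0) {
    cat("dropped constant term(s):", paste(x$dropped_terms, collapse = ", "),
        "\n")
  }
  print(x$coefficients)
  invisible(x)
}

#' Tidy a study-covariate regression
#'
#' @param x An `mlr_fit`.
#' @param ... Unused.
#' @return One row per model term with estimate, standard error, p-value
#'   and confidence bounds (all missing when the model saturates).
#' @exportS3Method generics::tidy
#' @export
tidy.mlr_fit <- function(x, ...) {
  mutate(x$coefficients, gene = x$gene, .before = 1)
}

#' One-line summary of a study-covariate regression
#'
#' @param x An `mlr_fit`.
#' @param ... Unused.
#' @return One-row tibble with fit-level statistics.
#' @exportS3Method generics::glance
#' @export
glance.mlr_fit <- function(x, ...) {
  r2 <- if (x$status == "ok") summary(x$fit)$r.squared else NA_real_
  sigma <- if (x$status == "ok") summary(x$fit)$sigma else NA_real_
  tibble(
    gene = x$gene, n_studies = x$n_studies,
    residual_df = x$residual_df, r_squared = r2, sigma = sigma,
    status = x$status,
    dropped_terms = paste(x$dropped_terms, collapse = ",")
  )
}

#' Covariate regressions for many genes at once
#'
#' Maps [fit_mlr()] over each gene of a long effects table and row-binds
#' the tidied coefficients.
#'
#' @param effects Long effects table (`gene`, `study_id`, `lfc`).
#' @inheritParams fit_mlr
#' @return Tidied coefficient tibble with `gene`, `term`, `estimate`,
#'   `p_value`, `ci_low`, `ci_high`, `residual_df`, `status`.
#' @export
fit_mlr_all <- function(effects, covariates, analysis_year = 2019,
                        conf_level = 0.95) {
  effects |>
    dplyr::group_split(.data$gene) |>
    purrr::map(function(eff) {
      fit <- fit_mlr(eff, covariates, analysis_year = analysis_year,
                     conf_level = conf_level)
      mutate(tidy(fit), residual_df = fit$residual_df, status = fit$status)
    }) |>
    bind_rows()
}
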