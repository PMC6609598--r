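# Shared fixture builders. Everything is generated in code; no stored data.

# A minimal hand-written Series Matrix file: 3 genes x 4 samples, two
# "tumor" and two "normal" samples. `values` is a 3x4 matrix of strings so
# callers can plant linear-scale or log2-scale numbers.
write_tiny_series_matrix <- function(path, values = NULL) {
  if (is.null(values)) {
    values <- matrix(sprintf("%.1f", c(
      5.1, 5.3, 4.0, 4.2,
      8.0, 8.1, 8.2, 7.9,
      2.0, 2.5, 6.0, 6.1
    )), nrow = 3, byrow = TRUE)
  }
  q <- function(x) paste0('"', x, '"')
  rows <- vapply(1:3, function(i) {
    paste(c(q(paste0("G", i)), values[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(
    '!Series_title\t"tiny fixture"',
    '!Series_geo_accession\t"TINY1"',
    paste(c("!Sample_title", q(c("tumor rep1", "tumor rep2",
                                 "normal rep1", "normal rep2"))),
          collapse = "\t"),
    '!series_matrix_table_begin',
    paste(c(q("ID_REF"), q(paste0("GSM", 1:4))), collapse = "\t"),
    rows,
    '!series_matrix_table_end'
  ), path)
  path
}

tumor_normal_rule <- list(case = "tumor", control = "normal")

# Random per-gene effect tables for pooling oracles.
random_effects <- function(k, gene = "G1") {
  tibble::tibble(
    gene = gene,
    study_id = sprintf("S%02d", seq_len(k)),
    lfc = stats::rnorm(k, 0, 1.5),
    variance = stats::runif(k, 0.01, 1)
  )
}

# Small labelled study built directly from a matrix.
make_study <- function(values, labels, id = "TEST1") {
  expr_study(values, labels,
             study_meta(id, n_control = sum(labels == "control"),
                        n_case = sum(labels == "case"),
                        country = "U.S.A.", year = 2010))
}

# Independent hypergeometric right tail via binomial coefficients only.
hyper_tail_bruteforce <- function(n_overlap, n_a, n_b, universe) {
  ks <- n_overlap:min(n_a, n_b)
  sum(choose(n_a, ks) * choose(universe - n_a, n_b - ks)) /
    choose(universe, n_b)
}
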