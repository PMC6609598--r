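test_that("series matrix parsing labels tumor/normal samples and keeps values", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_tiny_series_matrix(path)
  st <- read_series_matrix(path, tumor_normal_rule)
  expect_s3_class(st, "expr_study")
  expect_equal(st$labels, c("case", "case", "control", "control"))
  expect_equal(rownames(st$values), c("G1", "G2", "G3"))
  # max value 8.2 < 50: already log2, stored unchanged
  expect_equal(unname(st$values["G1", ]), c(5.1, 5.3, 4.0, 4.2))
  expect_equal(st$meta$study_id, "TINY1")
})

test_that("linear-scale matrices get log2(x+1); log2-scale ones do not", {
  linear <- matrix(sprintf("%g", c(
    100, 200, 50, 25,
    18432, 9000, 4500, 2250,
    10, 20, 30, 40
  )), nrow = 3, byrow = TRUE)
  path <- withr::local_tempfile(fileext = ".txt")
  write_tiny_series_matrix(path, values = linear)
  st <- read_series_matrix(path, tumor_normal_rule)
  expect_equal(unname(st$values["G2", ]),
               log2(c(18432, 9000, 4500, 2250) + 1))

  log2_vals <- matrix(sprintf("%.1f", c(
    14.2, 13.0, 9.9, 10.1,
    8.0, 8.1, 8.2, 7.9,
    2.0, 2.5, 6.0, 6.1
  )), nrow = 3, byrow = TRUE)
  write_tiny_series_matrix(path, values = log2_vals)
  st2 <- read_series_matrix(path, tumor_normal_rule)
  expect_equal(unname(st2$values["G1", ]), c(14.2, 13.0, 9.9, 10.1))
})

test_that("probe collapsing averages shared symbols and drops unannotated probes", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_tiny_series_matrix(path)
  annot <- tibble::tibble(probe_id = c("G1", "G2"),
                          gene_symbol = c("SYM1", "SYM1"))
  st <- read_series_matrix(path, tumor_normal_rule, annot = annot)
  expect_equal(rownames(st$values), "SYM1")
  expect_equal(unname(st$values["SYM1", ]),
               colMeans(rbind(c(5.1, 5.3, 4.0, 4.2),
                              c(8.0, 8.1, 8.2, 7.9))))
})

test_that("labelling and format failures raise informative errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_tiny_series_matrix(path)
  expect_error(
    read_series_matrix(path, list(case = "rep", control = "normal")),
    "both case and control"
  )
  expect_error(
    read_series_matrix(path, list(case = "tumor", control = "biopsy")),
    "zero case or zero control"
  )
  bad <- matrix("5.0", nrow = 3, ncol = 4)
  bad[2, 3] <- "not_a_number"
  write_tiny_series_matrix(path, values = bad)
  expect_error(read_series_matrix(path, tumor_normal_rule),
               "non-numeric expression cell.*G2")

  lines <- readLines(write_tiny_series_matrix(path))
  writeLines(lines[!grepl("table_end", lines)], path)
  expect_error(read_series_matrix(path, tumor_normal_rule),
               "table begin/end")
})

test_that("blank and null cells become missing values", {
  vals <- matrix("5.0", nrow = 3, ncol = 4)
  vals[1, 1] <- "null"
  vals[3, 4] <- ""
  path <- withr::local_tempfile(fileext = ".txt")
  write_tiny_series_matrix(path, values = vals)
  st <- read_series_matrix(path, tumor_normal_rule)
  expect_true(is.na(st$values[1, 1]))
  expect_true(is.na(st$values[3, 4]))
  expect_equal(sum(is.na(st$values)), 2)
})

test_that("eligibility filter enforces organism, assay, design and total n >= 10", {
  six <- dplyr::bind_rows(
    study_meta("GSE1420", 8, 8, "U.S.A.", 2004),
    study_meta("GSE13898", 75, 28, "U.S.A.", 2011),
    study_meta("GSE19529", 5, 5, "United Kingdom", 2010),
    study_meta("GSE28302", 9, 23, "Australia", 2011),
    study_meta("GSE74553", 13, 52, "U.S.A.", 2016),
    study_meta("GSE92396", 10, 12, "U.S.A.", 2016)
  )
  expect_equal(filter_eligible(six)$study_id, six$study_id)

  extra <- dplyr::bind_rows(
    six,
    study_meta("small", 5, 4, "U.S.A.", 2015),               # total 9 < 10
    study_meta("mouse", 25, 25, "U.S.A.", 2015, organism = "Mus musculus"),
    study_meta("seq", 30, 30, "U.S.A.", 2015, assay = "other"),
    study_meta("cohort", 30, 30, "U.S.A.", 2015, design = "other")
  )
  kept <- filter_eligible(extra)
  expect_equal(kept$study_id, six$study_id)
  # idempotent and a subsequence of its input
  expect_identical(filter_eligible(kept), kept)
  expect_true(all(diff(match(kept$study_id, extra$study_id)) > 0))
})

test_that("plain-matrix round trip reproduces genes, labels and values exactly", {
  set.seed(11)
  vals <- matrix(rnorm(5 * 6, 8, 2), nrow = 5,
                 dimnames = list(paste0("GENE", 1:5), paste0("S", 1:6)))
  vals[2, 3] <- NA
  st <- make_study(vals, rep(c("case", "control"), each = 3))
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  back <- read_study_matrix(paths["matrix"], paths["labels"],
                            meta = st$meta)
  expect_identical(back$values, st$values)
  expect_identical(back$labels, st$labels)
})

test_that("series-matrix writer round-trips through the parser", {
  set.seed(12)
  vals <- matrix(rnorm(4 * 8, 8, 2), nrow = 4,
                 dimnames = list(paste0("GENE", 1:4), paste0("S", 1:8)))
  st <- make_study(vals, rep(c("case", "control"), each = 4))
  path <- withr::local_tempfile(fileext = ".txt")
  write_series_matrix(st, path)
  back <- read_series_matrix(path, tumor_normal_rule, meta = st$meta)
  expect_identical(back$values, st$values)
  expect_identical(back$labels, st$labels)
})
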