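eff_tbl <- function(lfc, variance, gene = "G1") {
  tibble::tibble(
    gene = gene,
    study_id = sprintf("S%02d", seq_along(lfc)),
    lfc = lfc, variance = variance
  )
}

test_that("fixed-effect pooling matches hand inverse-variance arithmetic", {
  one <- pool_fixed(eff_tbl(1.3, 0.04))
  expect_equal(one$pooled_lfc, 1.3)
  expect_equal(one$se, 0.2)
  expect_equal(one$k, 1L)
  expect_equal(one$model, "fixed")

  two <- pool_fixed(eff_tbl(c(1, 2), c(0.25, 0.25)))
  expect_equal(two$pooled_lfc, 1.5)
  expect_equal(two$se, sqrt(1 / 8))
  expect_equal(sum(two$weights[[1]]), 1)

  set.seed(401)
  six <- eff_tbl(rnorm(6), rep(0.3, 6))
  pooled <- pool_fixed(six)
  expect_equal(pooled$pooled_lfc, mean(six$lfc))
  expect_equal(pooled$se, sqrt(0.3 / 6))
})

test_that("pooling rejects empty, mixed-gene and non-positive-variance input", {
  expect_error(pool_fixed(eff_tbl(numeric(0), numeric(0))), "non-empty")
  mixed <- dplyr::bind_rows(eff_tbl(1, 0.1, gene = "A"),
                            eff_tbl(2, 0.1, gene = "B"))
  expect_error(pool_fixed(mixed), "one gene")
  expect_error(pool_fixed(eff_tbl(c(1, 2), c(0.1, 0))), "positive")
})

test_that("heterogeneity statistics follow the truncated I-squared formula", {
  # identical effects: no dispersion at all
  het0 <- heterogeneity(eff_tbl(rep(1.2, 3), rep(0.2, 3)))
  expect_equal(het0$Q, 0)
  expect_equal(het0$isq, 0)
  expect_equal(het0$q_p, 1)

  # two studies, w = 10 each: Q = 10*(0-1)^2/... = 20, df = 1, isq = 95
  het <- heterogeneity(eff_tbl(c(0, 2), c(0.1, 0.1)))
  expect_equal(het$Q, 20)
  expect_equal(het$df, 1L)
  expect_equal(het$isq, 100 * (20 - 1) / 20)
  expect_equal(het$q_p, pchisq(20, 1, lower.tail = FALSE))

  # single study: documented degenerate result, not an error
  het1 <- heterogeneity(eff_tbl(0.5, 0.1))
  expect_equal(unlist(het1), c(Q = 0, df = 0, q_p = 1, isq = 0))
})

test_that("isq truncates exactly at Q = df and matches the formula above it", {
  # random instances: recompute Q from scratch and apply the printed rule
  set.seed(402)
  for (rep in 1:200) {
    eff <- random_effects(sample(2:8, 1))
    het <- heterogeneity(eff)
    w <- 1 / eff$variance
    pooled <- sum(w * eff$lfc) / sum(w)
    Q <- sum(w * (eff$lfc - pooled)^2)
    df <- nrow(eff) - 1
    expect_equal(het$Q, Q)
    expect_equal(het$isq, if (Q <= df) 0 else 100 * (Q - df) / Q)
    expect_gte(het$isq, 0)
    expect_lt(het$isq, 100)
  }
})

test_that("DerSimonian-Laird pooling matches the hand-derived oracle", {
  # two studies (0, 0.1) and (2, 0.1): Q = 20, S1 = 20, S2 = 200,
  # tau2 = (20 - 1) / (20 - 200/20) = 1.9; w* = 1/2 each -> se = 1
  res <- pool_random(eff_tbl(c(0, 2), c(0.1, 0.1)))
  expect_equal(res$tau2, 1.9)
  expect_equal(res$pooled_lfc, 1)
  expect_equal(res$se, 1)
  expect_equal(res$model, "random")
})

test_that("DL truncation at zero reduces random pooling to fixed pooling", {
  eff <- eff_tbl(c(1.0, 1.01, 0.99), rep(0.5, 3))  # Q well below df
  fixed <- pool_fixed(eff)
  random <- pool_random(eff)
  expect_equal(random$tau2, 0)
  expect_equal(random$pooled_lfc, fixed$pooled_lfc)
  expect_equal(random$se, fixed$se)
})

test_that("equal-variance random pooling returns the unweighted mean", {
  eff <- eff_tbl(c(-1, 0, 2.5), rep(0.2, 3))
  res <- pool_random(eff)
  expect_gt(res$tau2, 0)
  expect_equal(res$pooled_lfc, mean(eff$lfc))
})

test_that("random-effects intervals are never narrower than fixed ones", {
  set.seed(403)
  for (rep in 1:200) {
    eff <- random_effects(sample(2:8, 1))
    expect_gte(pool_random(eff)$se, pool_fixed(eff)$se - 1e-12)
  }
})

test_that("both pooling models agree with metafor as an independent check", {
  set.seed(404)
  for (rep in 1:25) {
    eff <- random_effects(sample(2:8, 1))
    fe <- metafor::rma(yi = eff$lfc, vi = eff$variance, method = "FE")
    dl <- metafor::rma(yi = eff$lfc, vi = eff$variance, method = "DL")
    expect_equal(pool_fixed(eff)$pooled_lfc, as.numeric(fe$beta),
                 tolerance = 1e-10)
    expect_equal(pool_fixed(eff)$se, fe$se, tolerance = 1e-10)
    res <- pool_random(eff)
    expect_equal(res$tau2, dl$tau2, tolerance = 1e-10)
    expect_equal(res$pooled_lfc, as.numeric(dl$beta), tolerance = 1e-10)
    expect_equal(res$se, dl$se, tolerance = 1e-10)
  }
})

test_that("mega_analyze pools available studies only and selects models by rule", {
  eff <- dplyr::bind_rows(
    eff_tbl(rep(0.8, 6), rep(0.05, 6), gene = "EVERYWHERE"),
    eff_tbl(rep(-1.1, 4), rep(0.05, 4), gene = "PARTIAL"),   # absent from 2
    eff_tbl(c(-2, 0, 2, 4, -3, 3), rep(0.01, 6), gene = "HETERO")
  )
  res <- mega_analyze(eff)
  expect_equal(res$k[res$gene == "EVERYWHERE"], 6L)
  expect_equal(res$k[res$gene == "PARTIAL"], 4L)
  expect_equal(res$model[res$gene == "EVERYWHERE"], "fixed")  # Q = 0
  expect_equal(res$model[res$gene == "HETERO"], "random")
  expect_true(all(abs(vapply(res$weights, sum, numeric(1)) - 1) < 1e-12))

  # the Q-test rule flips genes whose q_p clears the threshold
  res_q <- mega_analyze(eff, rule = "q_p_threshold", alpha_q = 0.05)
  expect_equal(res_q$model[res_q$gene == "EVERYWHERE"], "fixed")
  expect_equal(res_q$model[res_q$gene == "HETERO"], "random")

  # candidate-gene restriction applies before pooling
  res_sub <- mega_analyze(eff, genes = "PARTIAL")
  expect_equal(res_sub$gene, "PARTIAL")
})

test_that("extreme pooled p-values carry the underflow sentinel label", {
  res <- mega_analyze(eff_tbl(c(40, 40), c(1e-4, 1e-4)))
  expect_equal(res$p, 0)
  expect_equal(res$p_label, "<1.00e-320")
  mild <- mega_analyze(eff_tbl(c(0.2, 0.3), c(0.04, 0.04)))
  expect_match(mild$p_label, "e-0?[0-9]+")
})

test_that("the significance screen applies strict p and |LFC| cutoffs in order", {
  res <- tibble::tibble(
    gene = c("KEEP", "WEAK_LFC", "BOUNDARY_P", "BOUNDARY_LFC", "KEEP2"),
    pooled_lfc = c(1.06, 0.9, 1.5, 1.0, -1.27),
    p = c(1e-8, 1e-12, 1e-7, 1e-9, 4.3e-11)
  )
  kept <- significance_filter(res)
  expect_equal(kept$gene, c("KEEP", "KEEP2"))
})

test_that("forest data carries per-study intervals and weights that sum to 100", {
  eff <- dplyr::bind_rows(
    eff_tbl(c(1.0, 1.2, 0.9), c(0.05, 0.1, 0.02), gene = "A")
  )
  res <- mega_analyze(eff)
  fd <- forest_data(eff, res)
  expect_equal(nrow(fd), 3)
  expect_equal(sum(fd$weight_percent), 100)
  expect_equal(fd$ci_low, fd$lfc - qnorm(0.975) * sqrt(eff$variance))
  expect_true(all(fd$pooled_lfc == res$pooled_lfc))
})
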