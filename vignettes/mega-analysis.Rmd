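---
title: "Mega-analysis of case-control expression studies: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mega-analysis of case-control expression studies: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megaexpr)
library(dplyr)
```

# The problem

Individual case-control expression studies of the same disease are small,
run on different platforms, and drawn from different populations. A
"mega-analysis" treats each study's per-gene differential expression as an
effect-size estimate and pools these estimates across studies with
inverse-variance weighting, so that a gene's association with disease is
judged on the combined evidence rather than on any one cohort. megaexpr
implements that pipeline end to end for esophageal-adenocarcinoma-style
compendia: ingesting GEO Series Matrix files, screening studies for
eligibility, computing per-study log2 fold changes, pooling them under
fixed- and random-effects models with heterogeneity-driven model selection,
regressing effect sizes on study-level covariates, and comparing
literature-derived disease gene sets.

# Effect sizes

For a gene in one study, the effect size is the log2 fold change

$$ y_i = \bar{x}^{case}_i - \bar{x}^{ctrl}_i $$

of mean log2 expression between cases and controls, with within-study
variance taken as the Welch (delta-method) variance of a difference of
means,

$$ v_i = s^2_{case}/n_{case} + s^2_{ctrl}/n_{ctrl}, $$

using unbiased group variances. The source material that this package
models reports only the pooled effect and its standard error, not the
within-study variance formula, so the Welch form was chosen as the standard
companion of inverse-variance pooling; an equal-variance (pooled s²)
alternative would change weights only marginally at the group sizes
involved. No empirical-Bayes moderation is applied — there is no indication
of it in the original analysis, and moderation would change the meaning of
the pooled standard error.

Two numerical guards matter in practice:

* **Zero-variance floor.** A gene constant within both groups has $v_i = 0$
  and would receive infinite weight; variances are clamped below at
  $\varepsilon = 10^{-8}$. Real array data never hits the floor; degenerate
  synthetic fixtures do.
* **Missingness rule.** A cell that is blank or `null` is missing; a gene
  needs at least two non-missing case and two non-missing control samples
  in a study to yield an effect there, otherwise it is treated as absent
  from that study. This is the mechanism by which a gene can contribute to
  only 4 of 6 datasets (platform coverage), and the pooled `k` reports how
  many studies actually contributed.

# Pooling and heterogeneity

Fixed-effect pooling weights each study by $w_i = 1/v_i$:

$$ \hat\mu = \frac{\sum w_i y_i}{\sum w_i}, \qquad
   \mathrm{SE}(\hat\mu) = \Big(\sum w_i\Big)^{-1/2}, $$

with a two-sided standard-normal test of $z = \hat\mu/\mathrm{SE}$.
Cochran's heterogeneity statistic is

$$ Q = \sum_i w_i (y_i - \hat\mu)^2, \qquad df = k - 1, $$

and `q_p` is the upper $\chi^2_{df}$ tail at $Q$ — the probability that the
total variance arises from within-study variation alone. The heterogeneity
percentage is

$$ I^2 = 100\% \times \frac{Q - df}{Q}, $$

truncated to 0 whenever $Q \le df$. The random-effects model estimates the
between-study variance by the DerSimonian–Laird moment formula

$$ \hat\tau^2 = \max\!\left(0,\; \frac{Q - df}{S_1 - S_2/S_1}\right),
   \quad S_r = \sum_i w_i^r, $$

and re-pools with weights $w^*_i = 1/(v_i + \hat\tau^2)$. DL was chosen
because it is the canonical non-iterative estimator and the only one
consistent with the Q-based framing of the analysis being reproduced;
REML or Paule–Mandel are deliberately out of scope. Random-effects
intervals are never narrower than fixed ones (a property the test suite
checks), and when $Q \le df$ the DL estimate truncates to zero and the two
models coincide numerically.

## Model selection

Two selection rules are provided:

* `isq_zero` (default): use the fixed-effect model exactly when the
  truncated $I^2$ is zero, i.e. $Q \le df$. This is the rule stated in the
  methods of the original analysis, and the default follows it.
* `q_p_threshold`: use the fixed model when the Q test is non-significant
  (`q_p > alpha_q`, default 0.05). The original results section reasons
  this way ("no significant between-study variance"), and the rule is
  offered because `isq_zero` is strict: under perfect homogeneity
  $P(Q > df)$ is roughly half, so about half of truly homogeneous genes
  are pooled under the random-effects model. That is conservative, not
  wrong — their $\hat\tau^2$ is small and the pooled estimate barely moves
  — but users wanting the results-section behaviour should select
  `q_p_threshold`.

The significance screen keeps genes with raw $p < 10^{-7}$ and
$|\mathrm{LFC}| > 1$ (strict inequalities; an LFC beyond ±1 means more than
a two-fold expression change). No multiplicity correction is applied to the
screen, matching the analysis being reproduced; a BH-FDR column is emitted
alongside for users who prefer it. P-values that underflow double precision
are labelled `<1.00e-320` in the `p_label` column while the numeric column
carries 0; the label mirrors the underflow-sentinel convention of the
original MATLAB output.

Single-study genes (`k = 1`) are reported as fixed-model results equal to
the study's own effect, with `Q = 0, df = 0, q_p = 1` as a documented
degenerate case — the pipeline pools over whatever studies measured the
gene rather than imposing a minimum `k`.

# Study covariate regression

To ask whether study-level factors drive the observed effect sizes, the
per-study LFCs of a gene are regressed by OLS on three covariates: total
sample size, an ordinal region code, and study age (analysis year minus
publication year, default analysis year 2019). The response is the
per-study effect because it is the only per-study quantity available to
match per-study covariates. Design choices where the original description
is silent:

* **Region encoding** is a deterministic alphabetical country→integer
  table. With only a handful of studies, one-hot dummies would consume the
  entire degrees of freedom; `one_hot = TRUE` is available when the design
  can support it.
* **"Study date"** is interpreted as years elapsed (study age), matching
  the output column naming of the analysis being reproduced.
* **Saturated fits are reported honestly.** With four studies and three
  predictors plus an intercept there are zero residual degrees of freedom;
  `fit_mlr()` returns `status = "insufficient_df"` with missing p-values
  and intervals rather than fabricating extreme significance. Coefficients
  are still reported (the fit interpolates the data). Constant predictors
  are dropped and recorded, and the fit proceeds on the rest.

# Gene-set statistics

Two set-level questions are supported. The overlap of two disease gene
sets against a stated universe is tested with the right-tail Fisher exact
test (equivalently the upper hypergeometric tail including the observed
intersection), reported with the full 2×2 table, the sample odds ratio,
and the share of the smaller set covered. Over-representation of a query
list in a GMT pathway collection uses the same hypergeometric tail per
pathway with Benjamini–Hochberg adjustment across pathways; this is an
over-representation analysis, not rank-based GSEA, because the natural
input here is an unranked gene list.

The background universe size is a required argument with no default: a
literature-mining platform's internal gene universe is not recoverable,
and an overlap p-value quoted without its universe is not reproducible.
Consequently this package does not attempt to reproduce any specific
published overlap p-value — only the overlap arithmetic (counts and
percentages), which is universe-free.

# The synthetic compendium

`simulate_studies()` draws data from exactly the generative model the
pooling assumes: per-study true effects
$\theta_{gi} = \mathrm{LFC}_g + u_{gi} + x_i^\top\beta$ with
$u_{gi} \sim N(0, \tau^2)$, Gaussian log2 expression around per-gene
baselines, independent gene×study Bernoulli dropout for platform coverage,
and deterministic synthetic metadata so covariates are reproducible. It
emulates: between-study heterogeneity, varying group sizes, genes missing
from some platforms, and covariate structure on the effect size. It does
**not** emulate probe-level annotation, correlated genes, batch or scanner
effects, intensity-dependent variance, or non-Gaussian tails — so green
tests demonstrate the estimators are correct under their own assumptions,
not that those assumptions hold in any given GEO series.

`make_fixture_suite()` freezes one such compendium for tests and the
walk-through: six studies with per-arm sizes between 12 and 32, 200 genes,
log2 noise sd 0.12, two planted signals — +1.06 present in all six
studies, −1.27 removed from two studies so it pools over `k = 4` — and all
other genes null. The noise level comes from an a-priori power
calculation against the full screen: the binding constraint is the +1.06
effect sitting only 0.06 above the LFC cutoff, and with pooled standard
error ≈ $0.12/\sqrt{55}$ ≈ 0.016 the cutoff lies ≈ 3.7 SE below the
planted value, so both genes pass the screen with probability > 0.999
while null genes (which would need a 60-SE excursion to reach |LFC| > 1)
never do.

# Problem sizes and calibration checks

The validation suite uses simulation sizes chosen to give tight Monte
Carlo error at desk scale: 2,000 genes for the Q-test type-I check
(standard error of the rejection fraction ≈ 0.005), 1,000 genes for the
τ² = 1 model-selection check, 200 replicate genes for unbiasedness and 95%
CI coverage, and 200 twenty-study replicates for MLR coefficient coverage.
One observed behaviour worth naming: with Welch variances estimated from
20+20 samples, the Q test is mildly anticonservative — the null rejection
rate at the 0.05 level sits near 0.06–0.07 rather than 0.050, the expected
consequence of referring a statistic built on estimated variances to the
asymptotic χ² reference. The package reports `q_p` as defined; users
drawing inference from Q itself at small group sizes should treat its
p-values as approximate.

# Worked example

```{r example, eval = FALSE}
fixdir <- file.path(tempdir(), "compendium")
manifest <- make_fixture_suite(fixdir)

sim <- attr(manifest, "sim")
effects <- compute_effects_all(sim$studies)
results <- mega_analyze(effects)            # default rule: isq_zero
hits <- significance_filter(results)        # p < 1e-7 and |LFC| > 1
hits |> select(gene, model, k, pooled_lfc, se, p_label, isq)

# study covariates and per-gene regression
fit <- fit_mlr(filter(effects, gene == "UGT2B17L"), sim$covariates)
tidy(fit)
glance(fit)

# forest plot of the significant genes
autoplot(forest_data(effects, hits))
```

The same computation is driven from files by `run_pipeline()`, which reads
a config (R list or YAML) naming the series-matrix files, label rules and
metadata table, applies the eligibility screen (human, array RNA,
case-vs-control, total n ≥ 10), and writes every intermediate table plus a
JSON run report. The package deliberately ships no shell executable: its
users drive analyses from R, and the pipeline function together with
`scripts/acceptance.R` covers scripted use.

# Known limitations

* Cross-platform probe annotation is reduced to an optional two-column
  probe→symbol table with mean collapsing; no sequence-level re-mapping.
* The log-scale heuristic (99th percentile > 50 ⇒ apply `log2(x+1)`) can
  in principle misclassify exotic pre-processed matrices; the threshold is
  far from both typical log2 ranges (< 20) and linear ranges (> 1000).
* Meta-regression with inverse-variance weights is not implemented; the
  covariate model is plain OLS on per-study effects, as in the analysis
  this package reproduces.
* DerSimonian–Laird is the only τ² estimator; no Hartung–Knapp adjustment
  or publication-bias diagnostics.
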