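---
title: "Phylogenetic neighborhood models of seedling survival: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic neighborhood models of seedling survival: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the model it implements,
the choices made where the design was genuinely open, and what its tests
do and do not establish. It states no empirical result that the test
suite does not itself compute.

## The model

A focal seedling alive at the start of a census interval either survives
to the end (1) or dies (0); death is absorbing, so a multi-year outcome
is the product of the annual ones. Survival is modeled on the logit
scale with nine fixed effects and two crossed random intercepts:

$$\mathrm{logit}\,P = \beta_0 + \beta^\top x + u_{quadrat} + v_{species},
\qquad u \sim N(0,\sigma_q^2),\; v \sim N(0,\sigma_s^2).$$

The covariates $x$, all measured at the interval-start census and
standardized (centered, divided by 1 SD; height log-transformed first):

* **log height** (cm) — size advantage of established seedlings.
* **S_con** — count of other alive conspecific seedlings in the focal's
  2 × 2 m quadrat. Conspecific crowding in the seedling layer.
* **A_con** $= \sum_i BA_i/d_i$ (cm² m⁻¹) — conspecific adults within
  20 m of the quadrat center, basal area discounted by distance.
* **one phylogenetic index pair** — the chosen variant (TOTPd, AVEPd,
  APd′ or NTPd′) for the seedling-layer and adult-layer neighbor
  profiles. Larger values mean less related neighbors.
* **light** — canopy openness (%), kept out of the PCA and entered
  directly.
* **PCA1–3** — leading components of a correlation-matrix PCA of 13
  habitat variables (elevation, convexity, slope + 10 soil variables).

Fitting is maximum likelihood with the Laplace approximation
(`lme4::glmer`), Wald z tests per coefficient, and AIC with
$k = 12$ (intercept, 9 slopes, 2 variance components). Conditional
$R^2$ uses the logistic residual variance $\pi^2/3$:
$(\sigma_f^2+\sigma_q^2+\sigma_s^2) /
(\sigma_f^2+\sigma_q^2+\sigma_s^2+\pi^2/3)$, with $\sigma_f^2$ the
variance of the fixed-effect predictor over the data rows. Candidate
models (one per index variant) are compared per (interval, window) cell
by $\Delta AIC_i = AIC_i - \min AIC$; models with $\Delta AIC \le 2$ are
judged equally valid. No multiple-testing correction is applied across
the scan — classification (significant $p<.05$ / marginal
$.05 \le p <.1$) is per-coefficient, by design.

## The null model behind APd′ and NTPd′

The standardized indices measure departure of the observed AVEPd / MINPd
from a null in which species identities are shuffled on the phylogeny,
holding the profile's abundance structure and the focal's slot fixed.
Implementation notes that matter:

* The shuffle operates on the patristic matrix by permuting the
  label-to-row assignment — mathematically identical to relabeling tips,
  O(1) per lookup. Only the permuted identities of the focal and the
  profile species affect the statistic, so each draw samples
  $k+1$ distinct labels from the pool instead of materializing a full
  permutation; the tests verify this against exhaustive enumeration of
  all label permutations on small trees.
* The pool is the **full** tip set of the supplied tree, focal included,
  as in standard taxa-shuffle null models.
* The null SD is the sample (n−1) SD over the 999 draws; the observed
  value is not added to the null distribution. If the null SD is 0 (a
  star phylogeny) or the profile is empty, the SES is missing and the
  row is dropped (and counted) when datasets are built.
* AVEPd and MINPd nulls are evaluated on the same draws (paired nulls) —
  cheaper, and statistically identical marginally.
* Reproducibility: one RNG stream per unique (layer, year, focal
  species, quadrat) profile, seeded from the master seed and that key.
  Conspecific focals in the same quadrat have identical profiles, so
  they deliberately share draws and cache entries; results are
  independent of evaluation order and of which focals are present.

## Geometry and habitat choices

* Coordinates: origin at the plot's SW corner, x east, y north, meters.
  Subplot (r, c) spans [20c, 20c+20) × [20r, 20r+20).
* Quadrat placement: quadrats sit at each subplot's NE ("top right")
  corner. The exact offset is not fixed by the field protocol, so the
  rule is configurable: `"inset"` (default; 2 m in from the corner,
  center at 20c+17) or `"flush"` (center at 20c+19). Quadrats relocated
  around obstacles are supported by explicit center overrides in the
  quadrat table, and keep their subplot assignment.
* Neighborhoods use a closed 20 m ball with **no edge correction**; the
  truncated neighborhood near plot boundaries is used as-is. A distance
  floor of 0.1 m guards `A_con` against stems mapped onto the quadrat
  center. The adult census is static across the seedling censuses.
* Topography is computed from quadrat corner elevations: elevation =
  corner mean; slope = mean angular deviation of the four corner-triple
  planes; convexity = focal elevation minus the mean of the eight
  neighboring cells on the subplot grid. Edge cells use the available
  neighbors plus the cell's own corners (the conventional fallback where
  the eight-neighbor stencil is incomplete) and are flagged.
* PCA: correlation-matrix PCA of the 13 variables; light stays out.
  Component signs are fixed so each component's largest-|loading| entry
  is positive (deterministic across eigen-solvers). Scores are computed
  once on the full plot and **subset, not recomputed**, at smaller
  spatial scales, so habitat axes mean the same thing across windows.
* Spatial windows (1 ha = 100 × 100, 2 ha = 200 × 100, 4 ha = full
  plot, SW-anchored by default) truncate the neighbor pools as well as
  the focal quadrats, emulating a genuinely smaller plot; a flag
  restores full-plot neighborhoods if wanted. Multi-year intervals take
  covariates from the interval-start census only.
* Missing heights of alive seedlings are carried forward from the last
  measurement and flagged; rows with any missing covariate are dropped
  with a logged count. Standardization constants are computed per
  analysis dataset (per interval × window × variant) and emitted.

## The synthetic plot: what it emulates, and what it does not

The generator reproduces the statistical structure the analysis
assumes, with known ground truth: a pure-birth phylogeny scaled to
200 units depth; log-series species abundances; Thomas-cluster adult
maps (clusters of ~25 stems, 15 m spread); lognormal DBH (≥ 1 cm);
seedlings (height ≥ 20 cm) placed preferentially near conspecific
adults through an exponential dispersal kernel (10 m scale), which is
what gives S_con, A_con and the indices realistic nonzero variance; a
smooth elevation surface (west-east trend + Gaussian bumps) and 10 soil
variables as linear mixtures of 3 latent spatial factors plus noise, so
the 13-variable PCA has a recoverable low-rank structure; lognormal
canopy openness. Survival is drawn from the logit model above using
**the same covariate-construction code as the analysis** — a deliberate
choice: under the default configuration the fitted model is correctly
specified, making parameter recovery a clean acceptance surface.
Defaults follow the emulation targets: 95 adult species, ~10,546 stems,
56-species seedling pool, ~900 initial seedlings, 100 quadrats, four
annual censuses, ~90% annual survival (intercept 2.2), true effects
+0.5 on the seedling-layer APd′, +0.3 on light, −0.2 on PCA2,
$\sigma_q = \sigma_s = 0.5$.

It does **not** emulate: mechanistic enemies or pathogens (phylogenetic
density dependence exists only through the index coefficients),
growth/recruitment dynamics beyond simple height growth and Poisson
recruitment, soil assay error structure, interannual climate, or
observation error in the stem map. A green recovery test therefore
establishes that the estimation machinery is unbiased and calibrated
*when the model is true* — not that the model is true of any forest.

## Numerical and testing choices

* Tolerances: patristic/index oracles are exact (same arithmetic, two
  routes); geometry oracles to 1e-9 degrees; the zero-variance GLMM
  limit matches an independent IRLS fit to 1e-3 (the fit is re-done
  with the variance parameters pinned at zero in the Laplace deviance,
  optimizing fixed effects only).
* Sampled-null checks use 3 Monte-Carlo standard errors (delta-method
  SE for the SD), with the exact moments from exhaustive enumeration.
* Compute-budget scaling in multi-replicate suites: the recovery and
  type-I suites use 1,500 adults, 50/30-species pools, 99 null shuffles
  and one census interval, keeping the stated n ≈ 1000 rows, true
  coefficients and RE SDs; single-run tests use full-scale defaults.
* Correct specification requires the analysis to see the same SES
  covariates the generator used, so `simulate_plot` returns its index
  tables and the seed of their null streams; recovery tests consume
  them directly, and the scan self-consistency test seeds the scan's
  index recomputation with that stream. Re-measuring the SES with an
  independent null stream is a different (attenuated,
  errors-in-variables) regime that the recovery thresholds do not
  describe.
* The scan self-consistency suite also needs a world where the
  correctly specified variant is statistically separable: the
  standardized APd′ and AVEPd covariates are strongly collinear
  (r ≈ 0.95+ — the null mean of AVEPd is profile-independent, so APd′
  differs from a z-scored AVEPd mainly through profile-size variation
  in the null SD), and at ~90% survival the binomial information at
  desk-scale n cannot distinguish them (expected
  ΔAIC ≈ n·p(1−p)·β²(1−r²) ≈ 1–2). That suite therefore simulates a
  strong signal (β = 1 on the seedling APd′, ~60% survival); a
  power-driven design choice for the self-consistency check, not a
  change to the package defaults.
* ΔAIC: the conventional $AIC_i - \min AIC$ is used; a "maximum minus
  minimum" reading would contradict the ΔAIC ≤ 2 validity rule.

## Known limitations

* Polytomy-rich or star-like phylogenies drive the null SD toward zero
  and produce missing SES values by design.
* Wald p-values and the Laplace approximation are the standard but
  approximate contract; profile-likelihood or parametric-bootstrap
  intervals are out of scope.
* No spatial autocorrelation structure beyond the quadrat intercept; no
  edge correction of neighborhoods; no model averaging.
* `read_plot` validates referential integrity and status monotonicity
  but does not reconcile tag histories across re-censuses.
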