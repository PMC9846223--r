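---
title: "Methods: recursive GSEM path analysis and mediation for neonatal care-seeking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recursive GSEM path analysis and mediation for neonatal care-seeking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsempath)
```

## The model

`gsempath` implements a fully recursive generalized structural equation
model over observed survey variables: a directed acyclic graph whose
endogenous nodes each carry one link-scale regression equation, fitted on
the subpopulation the analysis declares for it. There are no latent
variables and no feedback loops, so the joint likelihood factorizes over
equations and each can be estimated by ordinary maximum likelihood in
topological order.

The built-in diagram, `careseeking_diagram()`, encodes six equations for
the determinants of qualified care-seeking for sick newborns:

1. 4+ qualified ANC visits (binomial/logit) on seven background factors
   (mother's age, education, wealth quintile, number of living children,
   history of child death, distance to the nearest facility, CHW home
   visit);
2. facility delivery on ANC plus the seven;
3. qualified PNC on facility delivery, ANC and the seven;
4. care-seeking for the last maternal complication on PNC, facility
   delivery, ANC and the seven — restricted to mothers who had a
   complication;
5. danger-sign knowledge (gaussian/identity on the 0–22 count) on PNC,
   facility delivery, ANC, the background factors except distance, and
   post-delivery danger-sign counseling;
6. the outcome, qualified neonatal care-seeking, on knowledge (as the
   banded factor 0 / 1–4 / 5+), complication care-seeking, PNC, facility
   delivery, ANC, all background factors, newborn sex, distance, CHW
   visit and counseling.

A parent enters an equation exactly where the reference analysis reports
an adjusted coefficient for it; the packaged coefficient fixture and the
diagram's edge set are asserted to match one-for-one in the test suite.
All equations are fitted on the sick-neonate subpopulation; equation (4)
additionally on the complication subpopulation.

### Dual coding of the knowledge score

Knowledge is measured as a 0–22 count and modeled as gaussian, but enters
downstream equations as a three-level factor (0 / 1–4 / 5+, reference 0)
through the companion column `knowledge_cat`. Both codings live on one
`variable_spec` via `predictor_encoding = "as_levels"`. When knowledge
acts as a *mediator*, its effect on the outcome is taken as the 5+-vs-0
log-odds coefficient by default (`knowledge_level = "5+"`); this is the
only single consistent choice that reproduces the recoverable
knowledge-mediated cells of the published decomposition, and it is
configurable.

### Structurally missing predictors

Care-seeking for a maternal complication is only defined for mothers who
had one, yet it is a parent of the outcome equation, whose published
sample size equals the full sick-neonate subset. Complete-case dropping
cannot produce that sample size, so the package recodes the structurally
missing cells to the reference level ("no care sought") whenever a
parent's subpopulation is strictly narrower than the child equation's —
in generation and fitting alike. This is stated here explicitly because
it is the only reading consistent with the published equation sizes.

## Estimation

Binomial equations are fitted by IRLS (`stats::glm`, convergence epsilon
1e-10, at most 100 iterations), the gaussian equation by least squares.
Perfect separation (diagnosed by a runaway coefficient, threshold 12 on
the log-odds scale), rank deficiency, and empty factor cells are errors
naming the offending term — not silent repairs.

Standard errors are robust sandwich estimates computed in-package from
per-observation scores: $A^{-1} B A^{-1}$ with $A$ the observed
information (binomial) or $X^\top X$ (gaussian) and $B$ the sum of score
outer products, with the HC1 factor $n/(n-k)$ at observation level or
$G/(G-1)\cdot(n-1)/(n-k)$ when clustering on the survey cluster. The
reference analysis says only "robust standard error"; observation-level
HC1 is the default and cluster-robust is available
(`covariance = "cluster"`) because the clustering level is not stated.

The joint covariance across equations is block-diagonal by default: the
recursive likelihood factorizes, and the per-path intervals of the
published table are reproducible without cross-equation covariance. A
`stacked_sandwich` mode fills cross-equation meat blocks from score
cross-products over shared observations, for sensitivity analysis; its
cross blocks carry no small-sample factor.

## The mediation calculus

All effects are reported in log odds (LOD), where they are additive.

* **Average relative effect.** A multi-categorical exposure is
  summarized as the arithmetic mean of its per-level link-scale
  coefficients. The default averages only levels significant at the
  two-sided 5% Wald level (the printed stars, when the source is the
  transcribed table); `mode = "all_levels"` averages every non-reference
  level. Significant-levels averaging is the default because it is the
  unique mode that reproduces the recoverable education, age,
  number-of-children and wealth-via-ANC cells of the published
  decomposition. An exposure with no significant level in an equation has
  an *undefined* effect there, rendered as a dash — this is also how
  "no direct effect" rows arise.
* **Path indirect effect.** The product of the first-leg average relative
  effect and the link-scale coefficients of the remaining legs. Paths are
  enumerated by depth-first search (`enumerate_paths()`), single-mediator
  by default; longer chains are available via `max_mediators` but are
  excluded from totals by default because every published path is a
  single-mediator product.
* **Mediators on restricted subpopulations** (complication care-seeking)
  are excluded from enumeration by default: a product of coefficients
  through a variable undefined on most of the outcome population has no
  population-level interpretation. This yields the three ANC pathways and
  two facility-delivery pathways of the reference analysis.
* **Delta-method intervals.** Every effect carries a gradient with
  respect to the coefficients it references; $\mathrm{SE} =
  \sqrt{g^\top \Sigma g}$ with $\Sigma$ the joint covariance (diagonal,
  from the printed CI widths, when the source is the transcribed table).
  The additive identities — total indirect equals the sum of path
  indirects, total equals direct plus total indirect — hold exactly by
  construction, not up to rounding.
* **Presentation.** Effects are rounded to 2 decimals, proportions to 1,
  half away from zero; internal arithmetic never rounds.

## The transcribed fixtures and their inconsistencies

The survey microdata is access-restricted, so the package ships verbatim
transcriptions of the published coefficient table, decomposition table
and descriptive marginals, each cell with its CI and significance stars.
Recomputing the decomposition from the coefficients
(`compare_reference()`) reproduces 40 cells at the printed precision. The
remainder are flagged `curated = FALSE` in the fixture, each with a note;
the notable cases:

* *PNC-via-knowledge (0.34) and counseling-via-knowledge (0.08)* are
  about twice what any single knowledge-to-outcome coefficient consistent
  with the coefficient table yields (0.46 × 0.36 ≈ 0.17; 0.12 × 0.36 ≈
  0.04), while two other knowledge-mediated cells match 0.36 exactly.
* *Wealth-via-PNC (0.12)* recomputes to 0.05 under either averaging mode.
* Several cells (facility-via-PNC 0.60, PNC direct 0.16, child-death
  direct −0.18, CHW-via-ANC 0.24, knowledge direct 0.37, and two
  borderline cells at 0.005 of a rounding boundary) differ by exactly a
  2-dp rounding step: the published table was computed from unrounded
  model coefficients, the fixture recomputes from the printed ones.
* The published *maternal-age row* lists only two mediators (facility
  delivery, knowledge) although the coefficient table shows significant
  age levels on the ANC and PNC equations; full enumeration under the
  significance rule adds those two paths. `reference_decomposition()`
  therefore computes on the *published row layout* (mediator sets as
  printed, all values recomputed), and `layout = "enumerated"` shows the
  difference.
* *Mediation proportions* are validated as the internal identity
  100 × total indirect / total on the printed totals, because several
  printed totals are themselves not recoverable from the printed
  coefficients.
* The descriptive table's maternal-complication care-seeking row is
  internally inconsistent (its counts sum to the full sample, its stated
  denominator is the complication subset); it is transcribed verbatim
  with a note, and the simulator uses the conditional 65.0%.

## The synthetic survey generator

`generate_population()` emulates the analysis-relevant structure of a
two-stage cluster survey: 14 districts × 120 clusters with ~10 records
each (`n_total` spreads an arbitrary total evenly), exogenous covariates
drawn independently from the published overall category shares,
endogenous variables drawn through the DAG in topological order with the
published link-scale coefficients as truth, an illness flag at prevalence
8765/17251, and a complication flag whose prevalence is conditional on
illness (2993/8765 among sick, 1720/8486 among healthy — the published
subpopulation counts cannot be matched by a single unconditional
prevalence, and imply this association). The generator is a pure function
of (diagram, parameters, design): a fixed seed gives byte-identical
output and the caller's RNG state is untouched.

Choices that matter:

* **Knowledge noise model.** Latent gaussian with residual SD 1.5
  (score units), rounded to the nearest integer and clipped to the
  instrument's 0–22 support. The reference analysis reports no residual
  variance; 1.5 together with a target mean of 3.2 places roughly 3–4% of
  mothers at 0 and about a fifth at 5+, near the published banded shares
  (3.3% / 20.3%). The target mean is a calibration choice made once; it
  is not a published quantity.
* **Intercepts** are free parameters calibrated by `calibrate_intercepts()`:
  walking the DAG in topological order over a 200,000-record calibration
  population, each binomial intercept is found by monotone root-finding
  (`uniroot` on [−25, 25], tolerance 1e-10) so the simulated marginal
  matches the published prevalence within ±0.005; the gaussian intercept
  is closed-form. Calibration targets condition on the variable's defined
  subpopulation (complication care-seeking: 65.0% of complication
  mothers; outcome: 36.5% of sick-neonate mothers).
* **Cluster effects** default to zero (the reference analysis models
  none); `cluster_effect_sd` adds link-scale cluster intercept noise for
  cluster-robust-SE experiments.
* **Independence of exogenous covariates.** Wealth, education, distance
  etc. are drawn independently; real surveys correlate them. Independence
  does not bias coefficient recovery (the fitted equations condition on
  the same covariates) but makes the synthetic marginals of *fitted*
  subgroups cleaner than reality.

### What passing tests do and do not show

The simulator reproduces the published *coefficient structure*, marginal
prevalences, subpopulation sizes and the measurement support of each
variable. It does not reproduce covariate correlations, cluster-level
dependence (by default), non-response, or any selection upstream of the
analysis set. Parameter-recovery results on synthetic data therefore
validate the estimation and decomposition machinery — not the substantive
correctness of the hypothesized DAG on real data, which no reanalysis of
transcribed tables can establish.

## Numerical and testing choices

* Wald intervals use z = 1.959964 throughout; significance stars are
  two-sided Wald at 5% (`*`) and 1% (`**`).
* The delta method is first-order. For a product of two independent
  estimates the exact variance adds a $\sigma_1^2\sigma_2^2$ term that
  first-order calculus omits; across the built-in diagram's paths the
  worst understatement is about 3–4% of the SE (paths whose both legs
  have relative SEs near 0.4). The test suite bounds the disagreement
  against a 10,000-draw parametric simulation at 5% per path, with the
  simulation seeded deterministically per path.
* Parameter recovery is exercised at the survey's own scale: 150
  replicates of n = 17,251 (about half a minute), checking per-coefficient
  95% CI coverage against [0.88, 1.00] and absolute bias below 0.05 for
  coefficients of magnitude below 1.5. The knowledge equation's
  coefficients are very slightly attenuated (≤ 0.01) by the
  round-and-clip measurement model; this is visible as coverage a point
  or two under nominal there, and is inherent to modeling a bounded count
  as gaussian.
* Intercept calibration, path enumeration determinism, fixture/diagram
  agreement, additive identities and all closed-form oracles (2×2 logit,
  OLS interpolation, brute-force sandwich scores, two-term delta SE) are
  asserted in the unit suite.

## Limitations

The calculus is pure product-of-coefficients on the link scale, matching
the reference analysis: it is not a counterfactual (natural
direct/indirect) decomposition, assumes no exposure–mediator interaction,
and inherits the non-collapsibility of odds ratios. Cross-sectional data
cannot confirm the direction of the hypothesized arrows; the package
takes the DAG as given. The published-table layer can only be as
consistent as the published tables themselves — where they disagree with
their own coefficients, the package recomputes and documents rather than
matches.
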