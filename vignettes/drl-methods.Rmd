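---
title: "Methods: the differentially regulated link statistic and its pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the differentially regulated link statistic and its pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drlink)
```

This vignette documents the statistical model behind `drlink`, the reasoning
for its default parameters, and — just as importantly — what the package's
guarantees do *not* cover.

## 1. The model

### Crosstalk genes

Each disease contributes a case/control expression cohort (log₂ scale,
genes × samples). After probe collapsing, cohort merging, and empirical-Bayes
batch correction, differential expression is assessed with a moderated
t-test: per-gene variances are shrunk toward a pooled prior, which stabilizes
inference when one cohort is small (the default MDD design has 30 cases vs 33
controls). A gene is a **crosstalk gene** when it passes the per-disease
threshold rule in *both* diseases.

The two preset rules are deliberately asymmetric, reflecting common practice
when one cohort is much smaller than the other:

- `preset_thresholds("mdd")`: raw p < 0.05, any nonzero log₂ fold change
  (|log2FC| > 0, strict).
- `preset_thresholds("pd")`: raw p < 0.05 and |log2FC| ≥ 0.5 (boundary
  inclusive).

Both comparisons of the thresholds are implemented literally — the MDD rule
is strict in the fold change, the PD rule inclusive — and the unit tests pin
the boundary behavior (a gene with log2FC exactly 0 is `ns` under the MDD
rule; exactly 0.5 passes the PD rule).

### The DRL statistic

For a crosstalk gene $x$ and a panel gene $y$ within one disease, fit
ordinary least squares lines separately in cases and controls:

$$y = \beta_{case} x + \beta^0_{case}, \qquad
  y = \beta_{ctrl} x + \beta^0_{ctrl}.$$

With $sd$ the standard error of each slope
($sd^2 = \hat\sigma^2 / S_{xx}$, $\hat\sigma^2 = RSS/(n-2)$), the
differentially regulated link score is

$$\mathrm{DRL} = \frac{\beta_{case} - \beta_{ctrl}}
  {\sqrt{sd_{case}^2 + sd_{ctrl}^2}} + CC_{all},$$

where $CC_{all}$ is the Pearson correlation between $x$ and $y$ over all
samples of that disease. The first term is a Wald-type contrast of the two
regression slopes; the second anchors it to the overall co-expression.

**Interpretation and a caveat.** A large positive DRL indicates regulation
that is consistent in direction and stronger in cases; a negative DRL flags a
pair whose case and control slopes disagree. Note the internal tension of the
composite score: a genuine sign flip ($\beta_{case}>0>\beta_{ctrl}$) tends to
*attenuate* $CC_{all}$, so the two terms can pull in opposite directions, and
the statistic has no reference distribution — it is a ranking score, not a
test. `drl_sign_class()` exposes only the sign, which is the robust part of
the message.

Edge cases are handled explicitly: if exactly one group's slope is estimated
without error ($sd = 0$), the contrast is still defined; if both are zero the
statistic is undefined and `compute_drl()` refuses rather than returning
±Inf.

### Pair screening

Before fitting regressions, pairs are screened by Pearson correlation with a
strict cutoff, $|r| > 0.5$ by default. The screen is applied to the
**case-group** correlation by default (`screen_on = "case"`), with
`screen_on = "all"` available; screening on cases targets links active in the
disease state. Pairs with a zero-variance gene yield `NA` correlations (with
a warning) and are dropped by the screen rather than silently passed on.

### Networks

Protein–protein interaction context uses two extractions: **direct pairs**
(a crosstalk gene adjacent to a neuropeptide) and **bridge triples**
(crosstalk–bridge–neuropeptide paths of length two, where the bridge is
neither a crosstalk gene nor a panel gene). Topology metrics for the bridge
subgraph are degree, normalized betweenness ($2/((N-1)(N-2))$ scaling),
closeness computed on reachable nodes, average shortest path, and the
shared-neighbor topological coefficient
$TC(n) = \mathrm{avg}_m\, J(n,m)/k(n)$ with $J$ counting shared neighbors
plus direct adjacency. All five are validated against brute-force
re-implementations (Floyd–Warshall distances, explicit path counting) on
random graphs.

### Marker screening

Candidate markers from the panel are screened per disease by
cross-validated lasso logistic regression (`glmnet`), with stratified fold
assignment so both classes appear in every fold, and the per-disease
selections intersected. Single-gene follow-up uses the rank-statistic AUC
(Mann–Whitney with midrank ties — exactly the trapezoidal area under the
empirical ROC, a property the tests assert to 1e-12) and Wilcoxon rank-sum
group comparisons with boundary-inclusive significance stars
(`ns/*/**/***/****` at 0.05/0.01/0.001/0.0001).

## 2. Defaults and why

| Parameter | Default | Rationale |
| --- | --- | --- |
| `cc_cut` | 0.5 (strict) | screens to strongly co-expressed pairs before slope fitting; strict inequality pins the boundary |
| `screen_on` | `"case"` | links active in the disease state are the objects of interest |
| `lambda` | `"min"` | screening favors sensitivity; `"1se"` available when a sparser, more conservative panel is wanted |
| `cv_loss` | `"deviance"` | the natural loss for logistic cross-validation; `"mse"` kept for continuity with linear screens |
| lasso folds | 10 | standard bias/variance compromise at n ≈ 60–570 |
| enrichment | raw p, `adjust = FALSE` | mirrors common over-representation reporting; BH adjustment is one switch away |
| `protect_group` | `TRUE` | keeps case/control signal out of the batch estimates; perfectly confounded designs are rejected rather than silently absorbed |

## 3. The synthetic study generator

`simulate_study()` emulates the two-disease design end to end and returns a
**truth ledger** alongside the data, so that every downstream claim can be
checked against what was planted. The default configuration is the demo
study: 2,000 genes; MDD with 30/33 samples in 2 batches; PD with 430/139 in
3 batches; additive per-(gene, batch) shifts of SD 1 plus multiplicative
noise-scale effects; 35 planted shared DE genes (25 up, 10 down, |lfc| = 2);
a 102-gene neuropeptide panel with 13 couplings (slope +1.5 in cases, −0.5
in controls) and 4 predictive markers; an Erdős–Rényi PPI background with 20
planted bridge paths; 30 pathway sets of which 5 are forced to mix crosstalk
and panel genes.

Three design decisions deserve explanation because they make exact recovery
testable:

1. **All planted differential expression concentrates in the shared set for
   the demo defaults.** The MDD preset filters on raw p only, so any
   truly-null or disease-specific DE gene enters the MDD DEG list with ≈5%
   probability; with disease-specific DE genes present, the intersection
   would acquire chance members and "exactly the planted set" would be a
   flaky claim. At the PD cohort's size, the |log2FC| ≥ 0.5 filter makes a
   chance double-positive astronomically unlikely, so the demo intersection
   is exact. Smaller configurations (as in the unit tests) *do* plant
   disease-specific DE and accordingly assert recovery-with-possible-extras,
   not exactness.
2. **Predictive markers shift by 2 panel-noise SDs (0.4 on the default
   scale), below the PD fold-change cutoff.** The panel should be screened by
   the lasso, not swept into the crosstalk gene set; the shift size keeps the
   planted markers strongly separable (population AUC $\Phi(\sqrt 2) \approx
   0.92$) while leaving the DEG machinery untouched.
3. **Couplings use a group-centered predictor.** The coupled response is
   $y = \mu + \beta_g\,(x - \bar x_g) + \varepsilon$ with $\beta_g$ the
   per-group slope. Centering within group means coupling to a DE gene does
   not shift the panel gene's group means — the planted slopes are recovered
   by `fit_group_regressions()` without contaminating the DE layer.

## 4. What passing tests do not show

- **Batch effects induce gene–gene correlations.** In a multi-batch cohort,
  shared per-batch shifts correlate otherwise independent genes; an
  "uncoupled panel yields no screened pairs" property only holds on
  batch-free data. This is exactly why the pipeline screens pairs *after*
  ComBat correction — and why correlation analyses on uncorrected multi-batch
  data are untrustworthy in general.
- **The DRL score has no calibrated null.** The suite verifies the formula,
  its equivariances (group-swap antisymmetry of the slope contrast, scale
  invariance), and planted-coupling recovery; it does not, and cannot,
  certify a false-positive rate for DRL itself.
- **ComBat exactness is asymptotic.** A pure constant batch shift is removed
  almost exactly, but the empirical-Bayes priors are estimated across genes;
  with degenerate across-gene variance the parametric priors are undefined.
  The tests use a numerically negligible jitter (SD 1e-8) to keep the prior
  fits well-posed — a property of the method, not of the implementation.
- **Lasso path monotonicity is a trend, not a law.** Coordinate-descent
  solutions occasionally drop a variable as the penalty decreases; the tests
  assert trend-level monotonicity (never falling more than 2 below the
  running maximum) rather than strict monotonicity.

## 5. Numerical choices

- Per-group OLS uses the closed form ($\beta = S_{xy}/S_{xx}$,
  $sd^2 = RSS/((n-2)S_{xx})$) rather than `lm()` in the inner loop; `lm()`
  serves as an independent oracle in the tests (agreement to 1e-10).
- The AUC is computed from rank sums with midrank ties, not from a
  discretized curve; the ROC curve is reported separately and its
  trapezoidal area equals the rank statistic identically.
- Hypergeometric enrichment uses the survival form
  `phyper(k - 1, K, N - K, n, lower.tail = FALSE)` for $P(X \ge k)$, checked
  against exhaustive subset enumeration on small universes.
- All stochastic components (generator, fold assignment) are seeded
  explicitly; `run_pipeline()` re-seeds each stochastic stage from its single
  `seed` argument, and two runs with equal inputs produce byte-identical
  output files.

## 6. Problem sizes exercised in the tests

Unit tests run on scaled-down configurations (300 genes, 30-gene panel,
63–100 samples) for speed; the acceptance layer exercises the full demo
scale (2,000 genes, 569-sample PD cohort), 10,000-gene null calibration,
10,000-draw formula oracles, 50 random graphs against brute-force metrics,
and a 10-seed lasso recovery experiment at n = 100 per group. Total suite
runtime is about a minute on one CPU.
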