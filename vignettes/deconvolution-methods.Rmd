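---
title: "Per-gene cell type-specific differential expression: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-gene cell type-specific differential expression: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrcde)
```

## The model

Bulk expression of a mixed-cell sample is modelled as the
proportion-weighted sum of cell type-specific expression. Within one
study group, for gene $j$ over the group's $M$ samples:

$$\mathbf{y}_j = X\,\boldsymbol\beta_j + \boldsymbol\varepsilon, \qquad
\boldsymbol\varepsilon \sim N(0, \sigma_j^2 I),$$

with $X$ the $M \times P$ matrix of measured cell proportions. There is
no intercept: a sample with no cells has no signal. The least-squares
solution $\hat\beta_j = (X'X)^{-1}X'\mathbf{y}_j$ gives cell
type-specific expression estimates; their estimated covariance is
$s_j^2 (X'X)^{-1}$ with $s_j^2 = \mathrm{RSS}_j/(M-P)$, the per-gene
residual mean squared error. Internally the coefficients are computed
through one QR factorisation of $X$ shared by all genes (numerically
preferable to forming normal equations when $X$ is ill-conditioned);
$(X'X)^{-1}$ is still materialised once per group because the
covariance needs it.

Two groups are fitted separately ("controls", "cases"); the per-cell
effect size is $\hat\delta_{kj} = \hat\beta^{cases}_{kj} -
\hat\beta^{controls}_{kj}$. Each effect is tested with a Welch
two-sample statistic built from the regression variances,

$$t = \frac{\hat\delta}{\sqrt{v_1 + v_2}}, \qquad
\nu = \frac{(v_1+v_2)^2}{v_1^2/\nu_1 + v_2^2/\nu_2},$$

where $v_g$ is the corresponding diagonal entry of group $g$'s
coefficient covariance and $\nu_g = M_g - P$. This is the only standard
reading of a Welch test on regression coefficients; the variances are
not pooled because the two groups need not share residual variance or
proportion structure. p-values are two-sided central-t probabilities;
multiplicity adjustment is Bonferroni over the full gene-by-cell table
(matching a single corrected threshold across all cell types), with
`none` available.

**Detection power.** Per test, with $t_{crit}$ the two-sided critical
value at level $\alpha$ (default 0.05): if $|t| < t_{crit}$ the power is
reported as the floor $\alpha$; otherwise it is
$P(T_\nu > t_{crit} - |t|)$ — the sampling mass of the estimate on the
rejection side of the critical point. The boundary is included in the
rejection region so the power function is continuous there (value 0.5).
This is a *post-hoc*, observed-statistic quantity (a shifted central t,
not a noncentral-t power curve): it summarises how firmly an observed
difference clears the threshold, per gene, and it is the per-iteration
"sensitivity" aggregated (mean over truly changed genes) in the
condition-number experiment.

## Condition diagnostics

The condition number used throughout is the eigenvalue ratio of the
symmetric matrix $X'X$ — the square of the SVD-based condition number
of $X$ itself. Because complete proportions sum to a constant across
cell types, the columns of $X$ are inherently collinear and this number
is large for realistic compositions. `X'X` is declared numerically
singular when its smallest eigenvalue falls below
$10^3 \cdot \epsilon_{mach}$ times the largest (scale-free); condition
numbers above 1000 are flagged on fits because coefficient estimates
become unstable under small perturbations of the proportions.

The remedy studied here is dropping the $k$ cell types with the
smallest mean proportions (ties broken by input order). Remaining rows
are deliberately **not** renormalised — the retained proportions are
kept as measured so the retained coefficients keep their
interpretation; renormalisation is available behind a flag but changes
the estimand.

## The simulator

`assemble_study()` builds a two-group study in three steps, entirely
determined by a `sim_config()` (every random draw derives from the
master seed):

1. **Proportions.** An $M \times P$ matrix with rows summing to 1
   exactly, the target cell's column having exactly the requested SD
   (on the fraction scale), and the condition number of $X'X$ matched
   to its target within 10 % by bisection on a noise scale, inside a
   deterministic accept/reject loop over redraws. Both groups share the
   same matrix, so the per-group regressions are comparable.
2. **Cell expression.** Baselines drawn uniformly on
   $[5, 10]$ per gene and cell type, identical in both groups — a
   plausible log2-intensity range. A seeded shuffle selects
   $\mathrm{round}(J \cdot \texttt{frac\_changed})$ genes; their
   case-group target-cell expression is incremented by an evenly spaced
   grid from `effect_lo` to `effect_hi` (default 0.001–1.0). The grid
   is deterministic rather than uniformly random so sensitivity is
   estimable per effect size; setting the endpoints equal gives a fixed
   effect.
3. **Mixing.** $Y = B X' + \varepsilon$ with
   $\varepsilon \sim N(0, \texttt{mse\_target})$. No calibration search
   is needed: under the correctly specified model
   $E[\mathrm{RSS}/(M-P)] = \sigma^2$, so the refitted MSE matches the
   target in expectation (verified in the tests to within
   $[1.40, 1.60]$ at a target of 1.5).

### Why the design matrix is on the percent scale

Proportions sum to 1 "or 100 %"; the simulator emits the design matrix
on the percent scale (rows summing to 100) while specifying and
reporting the target-cell SD on the fraction scale. This choice is
statistical, not cosmetic. For any design with rows summing to 1 and
entries in $[0,1]$, $\mathrm{trace}(X'X) \le M$, hence
$[(X'X)^{-1}]_{kk} \ge 1/M$ and
$se(\hat\delta) \ge \sqrt{2\,\mathrm{MSE}/M}$ — every Welch statistic
would be capped at $|\delta|\sqrt{M/(2\,\mathrm{MSE})}$ regardless of
the proportion structure. At the benchmark conditions (effects below
1.0, MSE 1.5, ten to twenty-eight samples per group) that cap pins the
whole analysis to the non-detectable regime. On the percent scale the
same bound relaxes by a factor of 100, placing sub-unit expression
effects in the regime where sample size, proportion variability, MSE
and conditioning all visibly modulate detection — the regime this
package exists to study. The condition number is invariant to the
unit, the noise-free effect recovery is exact on either scale, and
`unit = "fraction"` is available.

### How a target condition number is met

Once the random deviations are drawn, the condition number is a smooth,
monotone-decreasing function of a single noise scale $s$ over the
searched range, so bisection on $s$ hits any attainable target; a draw
whose attainable range excludes the target is rejected and redrawn
deterministically. Two constructions are used:

* **Coupled** (preferred): a dominant reciprocal pair — the target cell
  plus a noiseless "partner" that absorbs its deviations one-for-one,
  as neutrophils and lymphocytes trade off in blood — and a tail of
  minor cells of comparable abundance carrying small noise (the rarest
  cell relatively the quietest). The pair is exactly collinear with the
  constant vector, so the near-null directions of $X'X$ involve the
  target cell: its coefficient variance *grows* with the condition
  number. This is what makes the condition-number experiment
  non-trivial: re-simulating at a fixed high condition number makes
  per-iteration sensitivity fluctuate, and dropping minor cells
  restores it.
* **Flat** (fallback): flat minor-cell means with proportional
  absorption. A positivity/mass-budget argument shows the coupled
  construction cannot reach low condition numbers at high target SD
  (e.g. 100 at SD 0.2 with $M = 10$): any positive column with mean
  $m$ can carry at most $\sim (m/2)^2$ variance, capping the smallest
  eigenvalues. Proportional absorption makes the target column
  orthogonal to the near-null directions, so flat designs are
  well-behaved for the target cell at any condition number — which is
  also why sensitivity saturates in those settings.

### What the simulator does and does not emulate

It emulates: the sum-to-one constraint, controlled target-cell
variability, controlled conditioning, two-group designs with shared
proportions, additive effects on a known grid, and homoscedastic
Gaussian residuals calibrated in expectation. It does **not** emulate:
proportion measurement error (proportions are treated as exact,
deliberately — the "gold standard" setting), count-based mean-variance
relationships, gene-gene correlation, batch structure, or compositional
noise in the non-simulated sense. Passing tests therefore demonstrate
correctness of the estimator and the qualitative parameter directions
under the model's own assumptions, not performance on real microarray
or RNA-seq data.

## The permutation cut-point FDR comparator

The comparator re-estimates significance from a global null: group
labels are permuted (group sizes preserved), both regressions refitted,
and permuted effect sizes collected. Per cell type — and separately for
positive and negative effects, following the comparator convention; a
magnitude-only mode is a flag — 100 cut points are spaced evenly from
zero to the largest observed magnitude. At each cut the number of
observed effects exceeding it ("calls") is compared with the average
number of permuted effects exceeding it; the capped ratio is the raw
FDR, made non-increasing in the cut by a running minimum in ascending
cut order, and each gene receives the FDR of the greatest cut below its
magnitude. Degenerate corners: zero effects get FDR 1; a cut with no
calls gets 0 if it also has no permuted exceedances, else 1. The
default of 200 permutations gives stable estimates at 1000 genes within
desk-scale runtime.

## Experiment drivers and their configurations

* `parameter_sweep()` — sensitivity (TPR of truly changed genes in the
  target cell) against significance thresholds, for one varied
  parameter at a time; defaults match the standard benchmark (1000
  genes, $M = 14$, condition number 100, SD 0.1, MSE 1.5). Threshold
  grids: p-values 0–0.1 and FDR 0–0.3, 101 points each. Each swept
  value gets its own derived seed.
* `cd_perturbation_experiment()` — per-iteration sensitivity (mean
  detection power over changed genes; a TPR summary is a flag) across
  independently redrawn proportion matrices at fixed SD and condition
  number. The published configuration uses SD 0.2, $M = 10$, MSE 0.1
  and a fixed effect of 0.2; where the sources disagree on the effect
  size (0.2 in the procedure text, 0.1 in the figure caption) the
  procedure value 0.2 is the default, the other a configuration away.
* `cell_dropping_experiment()` — one study at a high-condition-number
  configuration (SD 0.1, condition number 75000, $M = 10$, MSE 1.5),
  re-analysed after dropping the $k$ lowest-mean cells for each
  requested $k$.

Problem sizes used by the test suite and the acceptance script — 1000
genes, 25–100 perturbation iterations, 100–200 permutations, three
master seeds for the FDR target — keep every run in seconds to a few
minutes while leaving Monte-Carlo error well inside the stated
tolerances.

## Numerical choices

* Near-singularity refusal at reciprocal condition below
  $10^3 \epsilon_{mach}$ (relative); the error message carries the
  condition number.
* Zero-variance Welch corner (noise-free data): equal estimates give
  $t = 0,\ p = 1$; unequal give $|t| = \infty,\ p = 0$, df
  $\nu_1 + \nu_2$.
* Bonferroni over genes × cells; `p_adj >= p` always.
* Dropping ties: earliest column first (stable order).
* The log2 transform is `log2(x + 1)`: the offset maps zero to zero and
  keeps the transform monotone and invertible. It defaults to off —
  simulated studies are analysed on their native scale, since passing
  additively injected effects through a log nonlinearity would compress
  effects and noise together without changing their ratio informatively.
* No non-negativity constraint on coefficients (plain least squares);
  negative estimates are flagged in the table rather than altered.

## Known limitations

* The detection power is an observed-statistic quantity; it should not
  be read as a prospective design power.
* The Welch degrees of freedom on regression coefficients are an
  approximation; type-I calibration is verified by simulation (the
  rejection rate at $\alpha = 0.05$ on null data sits within
  [0.035, 0.065] at 1000 genes).
* In the cell-dropping experiment, dropping a *single* minor cell
  trades a small residual-variance increase (the dropped cell's
  de-collinearizing noise moves into the residual, inflating the MSE by
  roughly $E[\beta^2]\,\lambda_{min}/M$) against the removal of its
  share of the target's conditioned variance; at the published
  configuration this trade can go either way from seed to seed, while
  dropping down to the well-conditioned reciprocal pair ($k = 3$)
  restores sensitivity robustly. The package reports both the condition
  numbers and the curves so the trade is visible per dataset.
* Real-data concerns — measurement error in proportions, scale of the
  expression matrix, probe-level artefacts — are outside the model; the
  condition-number diagnostics are the intended first check on real
  proportion matrices.
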