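---
title: "Methods: standardized chromatographic lipophilicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardized chromatographic lipophilicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromlip)
```

## The measurement model

Reversed-phase chromatographic retention is a surrogate for octanol–water
partitioning. `chromlip` models one retention experiment as a chain of three
linear maps:

1. **Transform.** A TLC retardation factor $R_F \in (0,1)$ becomes the
   lipophilicity index $R_M = \log_{10}(1/R_F - 1)$; an HPLC retention time
   becomes $\log k = \log_{10}((t_R - t_0)/t_0)$. Both are base-10 —
   the universal convention of the lipophilicity literature, where log P
   itself is decimal.
2. **Extrapolate.** Under the linear solvent-strength assumption the index
   is linear in the modifier volume fraction $\varphi$:
   $R_M = R_{MW} - S\varphi$ and $\log k = \log k_W - S\varphi$. OLS per
   compound × system gives the fully aqueous intercept ($R_{MW}$ or
   $\log k_W$) and the slope magnitude $S$. We report $S$ with the sign
   convention of the solvent-strength equation, i.e. the negative of the
   fitted OLS slope, so a well-behaved hydrophobic compound has $S > 0$.
3. **Calibrate.** Per system, the literature log P of a panel of reference
   standards is regressed on their intercepts,
   $\log P_{EXP} = a X + b$; test compounds are then predicted from their
   own intercepts. The default panel is six standards with literature log P
   0.62–3.5 (2-aminophenol through diphenylamine).

The key assumptions are (i) linearity of the index in $\varphi$ over the
measured window — true to good approximation for isocratic reversed-phase
systems over 20–30% modifier spans, and checked per fit via $r^2$; and
(ii) a common linear relation between intercept and log P across the
chemistry spanned by standards and test compounds.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_r2` | 0.9 | extrapolation quality threshold (dimensionless) |
| `noise_sd` | 0.02 | generator noise sd on the retention index |
| `replicates` | 3 | replicate measurements per plate/injection |
| `t0` | 1.0 min | HPLC dead time (125 × 4 mm column, 1 mL/min) |
| `slope_jitter` | 0.9–1.1 | multiplicative spread of true slopes |
| `distance`, `linkage` | euclidean, ward.D2 | clustering options |
| `scale` (PCA) | `TRUE` | correlation-matrix PCA |

`min_r2` is deliberately a *warning*, not a gate: an $r^2$ of 0.9 is the
conventional statement of acceptable solvent-strength linearity, but
discarding a compound × system automatically would silently unbalance the
drugs × methods table downstream. Flagged fits carry `"low_r2"` in their
`flags` column and the decision is left to the analyst.

## Numerical and procedural choices

**Replicates are averaged on the raw observable, before the index
transform.** The logit-type $R_M$ transform is nonlinear, so the mean of
transformed replicates differs from the transform of the mean (Jensen gap).
The measured quantity — and the quantity whose error is approximately
symmetric — is $R_F$ (or $t_R$), so averaging happens there. The test suite
pins this ordering.

**$\varphi$ is stored as a fraction in (0,1).** File input accepts
`phi_percent` and converts on read. Only the magnitude of $S$ depends on
this choice (a percent-scale fit divides $S$ by 100 and leaves the intercept
unchanged — a tested invariance); all downstream quantities are unaffected.

**Out-of-range observables are errors, not clipped.** An $R_F$ at 0 or 1 has
no finite index; clipping would bias the extrapolated intercept. Validation
reports the offending row numbers.

**Degenerate fits.** A perfectly constant response across $\varphi$ has an
undefined $r^2$; it is reported as 0 with a `"degenerate"` flag. A perfect
calibration line has $F = \infty$ and $p = 0$ (rather than a spurious large
finite value).

**Regression diagnostics.** We report $r$ (Pearson), the standard error of
estimate $s = \sqrt{SSE/(n-2)}$, the Fisher statistic
$F = (n-2)\,r^2/(1-r^2)$, and $p$ as the upper tail of $F(1, n-2)$ —
equivalent to the two-sided t-test on $r$. The $F$/$r$/$s$ identities are
asserted on every fit in the test suite. Published compilations of such
diagnostics occasionally contain $F$ values inconsistent with their own $r$
at the stated $n$; `chromlip` always reports the identity-consistent value.

**No extrapolation guard on predictions.** Test drugs routinely exceed the
standards' log P range (here up to ≈ 5.9 against a calibrated 0.62–3.5);
predictions outside the calibrated index range are returned and can be
flagged (`flag_range = TRUE`) rather than refused.

## Chemometric comparison

The drugs × methods log P table is compared three ways:

- **Correlation matrix** (Pearson, full precision internally; 4 decimals is
  the conventional reporting precision and is applied only at output).
- **Pairwise regression statistics** for strongly correlated pairs
  ($|r| \ge 0.97$ by default): $r$, $F$, $p$, and $s$ from the OLS of the
  second scale on the first.
- **Hierarchical clustering** of methods (each method = its per-drug log P
  vector) and **PCA** with drugs as observations and methods as standardized
  variables.

Clustering defaults to Euclidean distance with Ward (`ward.D2`) linkage —
the most common chemometric pairing — with correlation distance ($1-r$)
available, since method similarity is often better captured on the
correlation scale when scales differ in offset and gain. Columns are sorted
lexicographically before clustering, which makes the tree deterministic and
resolves exact distance ties toward the lexicographically smallest pair.
PCA signs follow a fixed convention (largest-magnitude loading of each
component positive) so scores are reproducible across BLAS builds.

A caution from the packaged example data: the iLOGP and Consensus.LogP
correlations published alongside these tables are not reproducible from the
published log P values themselves (e.g. the experimental columns correlate
*strongly* with Consensus.LogP as printed, r ≈ 0.96, where the published
matrix shows ≈ −0.13). Consequently the published two-cluster dendrogram —
experimental systems plus five computational models in one cluster, iLOGP
and Consensus.LogP in the other — does not emerge from the printed tables
under any distance/linkage combination we examined. The package computes
from the data it is given; tests assert determinism and oracle agreement of
the clustering, not that historical figure.

## The synthetic-data generator

`generate_dataset()` emulates the full measurement design: for every
compound × system × $\varphi$ × replicate it draws
$X_{true} - S\varphi + \mathcal{N}(0, \sigma)$ on the index scale and
converts back to the raw observable ($R_F$ by inverting the index
transform; $t_R = t_0(1 + 10^{\log k})$). Choices worth knowing:

- **Noise lives on the index scale** because the solvent-strength model
  posits linearity (and homoscedasticity) there. $\sigma = 0.02$ index
  units reflects the replicate-level precision of a well-run isocratic
  system.
- **True intercepts come from inverting each system's calibration line**,
  $X_{true} = (\log P - b)/a$, using the published per-system coefficients,
  so synthetic data occupy the same retention regime as the real
  experiments. True drug log P defaults to the published mean experimental
  values of the five gliflozins.
- **True slopes are tied to the intercept through the grid midpoint**,
  $S = X_{true}/\bar\varphi$ with a seeded ±10% jitter. This keeps every
  compound eluting inside its system's measured window (as real
  concentration windows are chosen to do) and mirrors the slope–intercept
  collinearity characteristic of congeneric series.
- **Out-of-range TLC draws are redrawn** (bounded at 100 attempts,
  counted and reported) rather than truncated, so the index distribution
  stays unbiased. Under the default configuration the redraw count is zero.
- The 12 default systems use the practical modifier windows for this
  compound class (e.g. TLC RP18 with methanol: 60–85% in 5% steps).

What the generator does **not** emulate: inter-laboratory and inter-plate
effects, temperature drift, peak asymmetry, curvature of the index–$\varphi$
relation at extreme modifier fractions, and correlated replicate errors.
Recovery results on synthetic data therefore certify the *statistical
pipeline* — transform, fit, calibrate, predict — not the chromatography.

## Validation by parameter recovery

With $\sigma = 0$ the pipeline is an exact inverse of the generator; the
suite requires round-trip agreement of every drug log P to $10^{-9}$. The
stochastic benchmark runs 50 seeded replications at $\sigma = 0.02$ with
6 standards, 7-point $\varphi$ grids and triplicates, and requires per-drug
|bias| < 0.05 log P units; typical RMSE per drug × system is ≈ 0.07. These
problem sizes (11 compounds × 12 systems × 7 fractions × 3 replicates per
replication) keep the whole benchmark in the tens of seconds while leaving
Monte-Carlo error well below the bias bound.

All OLS paths are additionally cross-checked against an explicit
normal-equation oracle (hand-coded $S_{xx}$/$S_{xy}$ sums) on hundreds of
randomized instances, and the PCA eigenvalues against a
characteristic-polynomial root-finding oracle.

## Limitations

- The calibration is strictly linear; no weighting or errors-in-variables
  (Deming) option. With six standards the leverage of the extreme standards
  is high; the back-fit residual table (`backfit_residuals()`) is the
  intended diagnostic.
- Ionizable compounds: retention reflects the distribution coefficient at
  the mobile-phase pH, not necessarily the neutral-species log P; the
  package does not model ionization.
- The computational log P columns are consumed as given; the package does
  not implement the underlying prediction algorithms.
- LLE uses the mean experimental log P per drug; per-system LLE can be
  assembled from `predict_dataset()` output if a single preferred system is
  desired.
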