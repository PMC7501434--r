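---
title: "Partial-correlation network modelling and group classification across attention load"
author: "fcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-correlation network modelling and group classification across attention load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

Functional connectivity (FC) studies of clinical cohorts ask whether the
coupling structure among brain network nodes differs between patients and
controls, and how it reorganizes with cognitive state. The design `fcnet`
targets is a two-group (stroke patients vs healthy controls), three-condition
(rest, and two load levels of continuous attentive tracking, L1 and L2)
repeated-measures design. Each subject contributes one node-by-time matrix
per condition; nodes are spatial components from a group decomposition, and
an edge is the regularized partial correlation between two nodes' time
series. With $K = 30$ nodes there are $K(K-1)/2 = 435$ unique edges.

The package implements the full chain as testable units:

1. **Synthetic cohort generation** with known, controllable group, condition
   and nodal-variability effects (`makeGroundTruth`, `generateCohort`).
2. **Dual regression** mapping group spatial maps to subject time series and
   subject maps, with an optional lesion-mask regressor
   (`stage1SpatialRegression`, `stage2TemporalRegression`,
   `dropLesionComponent`), plus a frame-to-frame RMS head-motion metric
   (`meanRelativeRms`).
3. **Network estimation**: graphical-lasso partial correlations with
   cross-validated penalty selection (`estimatePrecision`, `selectLambda`,
   `cohortEdges`).
4. **Multivariate classification**: shrinkage LDA with leave-one-subject-out
   cross-validation, balanced control subsampling and permutation inference
   (`fitShrinkageLda`, `losoCv`, `balancedGroupClassification`,
   `permutationTest`).
5. **Univariate statistics**: edgewise and nodewise mixed-design ANOVA with
   BH-FDR, nodal signal variability (SDSA), and summary-statistic group
   tests (`mixedAnova`, `edgewiseAnova`, `computeSdsa`, `welchTFromSummary`,
   `chi2Independence`).

## The generative model

For each design cell (group $g$, condition $c$) the generator holds a sparse
precision matrix $\Theta_{gc}$. Targets are specified as partial
correlations $\rho_{ij}$; the unit-diagonal construction
$\Theta_{ij} = -\rho_{ij}$ realizes them exactly because partial correlations
are $-\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}$. Positive definiteness is
enforced by a uniform rescaling of $\Theta$ (the fixed point of
diagonal-loading followed by re-boosting the off-diagonal targets), chosen
because scaling a precision matrix leaves its partial correlations
invariant; the smallest eigenvalue is lifted to 0.1. Targets that are not
jointly realizable (the unit-diagonal matrix is not positive definite) are
rejected with an error naming the strongest edge.

Frames are i.i.d. draws from $\mathcal{N}(0, \Sigma_{gc})$ with
$\Sigma_{gc} = D_{gc} R_{gc} D_{gc}$, where $R_{gc}$ is the correlation
implied by $\Theta_{gc}^{-1}$ and $D_{gc}$ carries nodal SDs — the ground
truth for SDSA. An optional AR(1) coefficient adds temporal autocorrelation;
the default is 0 because the edge definition uses only contemporaneous
correlation.

**Default effect calibration.** Where no empirical edge-strength
distribution is available, the defaults are desk-scale choices fixed once:

* background connectivity: 10% of edges at $|\rho| \in [0.1, 0.3]$;
* condition effects: $\approx 2K/3$ edges whose rest-to-L1 shift is
  $|\Delta\rho| \in [0.1, 0.3]$ (same in both groups), with the heavier
  load L2 extending the shift by a further 0.05–0.15 in the same direction
  — condition modulation is load-graded, matching the monotone
  rest < L1 < L2 profile of task-modulated connectivity;
* one group-offset edge (nodes 23–27 when $K = 30$) with
  $\Delta\rho = 0.1$ for patients in every condition, on a task-increasing
  base (rest 0.10, L1 0.20, L2 0.25);
* SDSA: a 20% task-related SD decrease on 4 "task-negative" nodes.

Sample sizes default to the study design: 44 patients, 100 controls, 200
rest frames and 152 task frames per run.

**What the generator does not emulate:** hemodynamic response, realistic
fMRI noise spectra, head motion, scanner drift, lesion-induced signal
dropout, or between-subject variability in the spatial maps. Passing tests
therefore demonstrate the statistical machinery is correct and calibrated
under the assumed Gaussian graphical model, not that the pipeline is robust
to every artifact of real data.

## Dual regression and the lesion regressor

Stage 1 regresses the demeaned group maps (columns of a voxels-by-components
matrix) into each subject's voxels-by-time data, one multiple regression per
frame, producing one time series per component. Stage 2 regresses those
(demeaned) time series back into the same data, one regression per voxel,
producing subject-specific maps. Regressors are demeaned but not
variance-normalized by default, matching the common dual-regression
convention; normalization is an option. When a binary lesion mask is
supplied it is appended as component $K+1$ in stage 1 so that variance
shared with the lesion is assigned to the lesion's own time course, which is
then discarded (`dropLesionComponent`); the node time series that go forward
have exactly $K$ columns.

The motion metric averages, over consecutive frame pairs, the RMS
displacement of a sphere of radius $R$ under the relative rigid transform:
$\sqrt{R^2/5\,\mathrm{tr}(M^\top M) + t^\top t}$ with $M$ the linear part
minus the identity and $t$ the relative translation. $R$ defaults to 80 mm,
the conventional radius that makes values comparable across studies.
Rotations are interpreted as small-angle Euler angles applied in x, y, z
order; this convention is recorded here because realignment tools differ.

## Network estimation

Per run, node time series are standardized (SDSA is computed upstream of
this step, since standardization would erase it) and the precision matrix
maximizes the $\ell_1$-penalized Gaussian log-likelihood
$\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda \sum_{i \neq j}
|\Theta_{ij}|$ via block coordinate descent (graphical lasso, authored in
C++ inside the package; the diagonal is unpenalized). Edges are
$-\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}$, vectorized in row-major
upper-triangle order `(1,2), (1,3), ..., (K-1,K)` — the ordering is fixed
and recorded in every output header because downstream modules must agree
on it.

The penalty is selected per run by 5-fold cross-validation over 20
log-spaced values in $[0.01, 1]$, scoring held-out Gaussian log-likelihood
on contiguous frame blocks (blocks rather than random folds so that any
temporal autocorrelation cannot leak across the split). Ties break toward
less shrinkage. At $\lambda = 0$ (and $T > K$) the estimate equals the
inverse sample correlation and is computed directly. A ridge variant
(`method = "ridge"`) shrinking $S$ toward the identity is provided behind
the same interface as a sensitivity check. Whether the penalty should be
estimated per run, per subject or globally is a genuinely open design
point; per run is the default because run lengths differ between rest and
task.

## Classification

The classifier is linear discriminant analysis on the pooled within-class
covariance shrunk toward its diagonal,
$\Sigma^\ast = (1-\gamma)\,\hat\Sigma + \gamma\,\mathrm{diag}(\hat\Sigma)$,
with $\gamma$ the analytic optimal intensity (ratio of summed sampling
variances of the off-diagonal entries to their summed squares), clipped to
$[0,1]$. For $\gamma > 0$ the estimate is invertible even with 435 features
and a few dozen subjects. Edges estimated as exactly zero in every training
run have zero pooled variance and no discriminative signal; they receive a
tiny positive variance so the matrix stays positive definite.

Cross-validation is leave-one-*subject*-out: a subject's three runs are
dependent, so row-level leave-one-out would leak identity into training.
The summary accuracy is the mean of per-class accuracies. Group
classification, with 44 patients against 100 controls, would otherwise be
biased by the size imbalance, so controls are repeatedly subsampled to the
patient count (100 iterations at study scale, 25 at desk scale) and
accuracies averaged. Significance uses permutation: group labels permuted
at the subject level, condition labels within subject, with the add-one
convention $p = (1 + \#\{\text{null} \geq \text{obs}\})/(n+1)$ — a valid
finite-sample p that is never exactly zero. The analytic chance level
$1/L$ is reported alongside (33.3% for the three-condition task).

## Univariate statistics

Each edge (or node, for SDSA) is analyzed with a split-plot ANOVA: group is
tested against subject-within-group; condition and group-by-condition
against condition-by-subject-within-group. With unequal group sizes the
within-stratum effects use exact Type III (sum-contrast model-comparison)
sums of squares, the convention for unbalanced factorial designs; for the
single between factor Type I and Type III coincide. No sphericity
correction is applied by default, matching the plain F tests the analysis
reports. Degenerate (zero-variance) inputs report $F = 0$ with a flag
rather than NaN. The implementation is a closed-form decomposition
vectorized across edges; tests verify it against `aov()` error strata on
balanced data and an explicit least-squares oracle on unbalanced data to
1e-8.

FDR control is Benjamini–Hochberg at $q = 0.05$, applied separately per
effect, via `p.adjust`. SDSA is the sample SD (denominator $T-1$) of each
node's unstandardized time series.

Group comparisons of scalar summaries use the Welch (unequal-variance) t
statistic computed from means, SDs and group sizes; Welch rather than
pooled t because it reproduces the published table values recomputed from
their printed summaries. Two response-time rows of that table print SDs
with only one significant decimal, which is too coarse to reproduce the
printed t; those rows are excluded from the reproduction checks, as is a
handedness chi-square row that is internally inconsistent as printed.

## Numerical and scale choices

* Graphical-lasso convergence: mean absolute change in the working
  covariance below `1e-7` times the mean off-diagonal of $S$, 200-sweep cap,
  warm starts along the penalty grid; non-convergence is flagged, not
  fatal.
* Problem sizes in the test-suite property checks are chosen to keep a
  desk-scale run practical while retaining power: the condition-classifier
  check uses 20+20 subjects and $K = 10$ with strong condition effects; the
  group-null check uses the full 44/100 design at $K = 10$ with a fixed
  penalty; null calibration uses $10^4$ simulated edges; the
  single-group-edge recovery check uses 50 replicate cohorts at full design
  scale with a fixed penalty of 0.1.
* The pipeline's desk-scale defaults (25 subsampling iterations, 100
  permutations) are reachable overrides of the study-scale 100/10,000 via
  `defaultRunConfig(paperScale = TRUE)`.
* All randomness flows from explicit integer seeds; cohort manifests and
  table headers record the seed and a hash of the scientific configuration,
  and reruns are byte-identical.

## Known limitations

* Edge-strength effect sizes are calibration choices; no published empirical
  edge distribution exists to match.
* The graphical-lasso zero pattern is not guaranteed to be nested across
  penalties in pathological inputs, though it is on the sparse-truth data
  the tests use.
* The balanced-subsampling report averages per-class accuracies across
  iterations; its confusion matrix is a sum over iterations, not an
  independent sample.
* Group ICA is out of scope: ground-truth or user-supplied maps play the
  role of the group components.

## A minimal session

```{r, eval = FALSE}
library(fcnet)
model <- makeGroundTruth(nNodes = 10, sparsity = 0.1, seed = 1)
cohort <- generateCohort(model, nPatients = 10, nControls = 10,
                         frames = c(rest = 152, L1 = 152, L2 = 152), seed = 1)
edges <- cohortEdges(cohort)                    # CV-selected penalty per run
report <- losoCv(conditionDataset(edges))       # 3-class condition decoding
report
anova <- edgewiseAnova(edges)                   # group/condition/interaction
head(anova[order(-anova$F_condition), c("edge", "F_condition", "p_condition")])
```
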