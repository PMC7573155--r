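---
title: "Predicting treatment response from challenge-induced connectivity change: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting treatment response from challenge-induced connectivity change: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcresponse)
```

# The problem

Antidepressant response is heterogeneous, and candidate imaging markers are
often reported as in-sample correlations that collapse under honest
validation. `fcresponse` implements a multistage design for testing whether
the *short-term* effect of a pharmacological challenge (drug vs. saline,
within subject) on resting-state functional connectivity (FC) predicts the
*long-term* change in depressive symptoms:

1. **Psychometrics.** Questionnaire items (a 17-item clinician rating and a
   21-item self-rating layout) are summarized by orthogonal latent factors
   fitted on pre-treatment scores only; post-treatment scores are projected
   with the stored weights so treatment response cannot leak into the factor
   definition.
2. **Connectivity.** Per subject and condition, ROI time series (voxel means
   over non-overlapping 10 mm spheres) are cleaned by simultaneous nuisance
   regression and band-pass filtering, Pearson-correlated and Fisher-z
   transformed. The verum-minus-placebo difference matrix is the analysis
   input.
3. **Network-based statistics (NBS).** An edge-wise GLM of the difference
   matrices on the score change (with sex, age, mean connectivity and an
   intercept) pre-selects factors with connected suprathreshold networks,
   using a max-component permutation null for family-wise error control.
4. **Prediction.** Edge weights (|partial correlation| with the score
   change, SD-scaled), a weighted-average FC predictor, robust bisquare
   regression, and two resampling schemes (LOOCV; repeated 3-fold CV
   without role reversal) estimate generalizable predictive power —
   alongside a deliberately circular variant that demonstrates the
   double-dipping inflation.

Because the motivating study's clinical and imaging data are not publicly
deposited, the package is organized around a synthetic-data generator with
known ground truth; every stage is tested against that truth or against
independent brute-force oracles.

# The synthetic generator as study stand-in

`synth_spec()` fixes the study conditions; the generators derive everything
from an explicit seed (scoped RNG, bit-identical reruns).

**Questionnaire.** Items are `loading_matrix %*% factors + noise` with
orthogonal standard-normal latent factors. The default 17-item, 6-factor
matrix uses simple structure (three markers per factor, one two-marker
factor, primary loadings 0.75/0.8) — the item count and factor count of the
clinician-rated layout. Item noise defaults to the variance left over by
the common factors, so items have unit variance. Scores are discretized by
rounding and clipping to the declared range (mean at mid-range, SD a
quarter of the range); the continuous values are returned for calibration
tests since the discretization attenuates correlations slightly.
Post-treatment items come from latent factors shifted by `factor_shift`
plus subject noise `shift_sd`, and the true shifts are returned.

**Connectivity.** Each condition's z-matrix is symmetric zero-diagonal
Gaussian background noise with SD `background_sd` (default 0.1 z-units, a
realistic scale for Fisher-z edge noise differences). The noise is drawn
*independently per condition*, so the difference matrix has variance on
every edge — a literal "verum = placebo + effect" construction would give
zero-variance null edges and make the edge GLM (and any null calibration)
degenerate. The planted effect enters only the verum condition, on a
connected edge set, scaled so that the *marginal* population correlation
between the planted-edge difference and the score change equals
`effect_rho` (covariate effects, when requested, are folded into the
scaling; `|effect_rho| = 1` switches to a noiseless construction). Age is
uniform on 20–55 years and sex balanced binary — the covariate roles in the
design matrices, without inventing distributions the design does not pin
down.

**Imaging fixture.** A small 2 mm grid with planted ROI signals inside the
spheres, shared nuisance components inside user-suppliable tissue masks and
white noise everywhere; used to exercise extraction and cleaning exactly.
The generator does not model hemodynamics, motion, or scanner artifacts —
passing tests show the *pipeline arithmetic* is right, not that real fMRI
noise is this tame.

# Psychometric model

The fitting loop mirrors standard exploratory practice: compute KMO/MSA
from anti-image partial correlations; while KMO ≤ 0.5, drop the
lowest-MSA item (ties broken by original item order — a determinism choice
the procedure itself does not dictate); set the factor count by the Kaiser
criterion (eigenvalues of R strictly above 1); extract by principal axis
factoring (communalities initialized at squared multiple correlations,
iterated on the reduced correlation matrix, tolerance 1e-6, at most 1,000
iterations); a non-converging extraction removes the next-lowest-MSA item
and restarts. Heywood cases are clipped to communality 1 and flagged with
the item. The converged solution is Varimax-rotated with Kaiser row
normalization (`stats::varimax`), and scores use the Anderson–Rubin
construction — Bartlett-type weights symmetrically orthogonalized through
R, computed via the SVD of `chol(R) %*% Psi^-1 %*% Lambda` for stability
when uniquenesses are tiny — which makes the fitting-sample score
covariance exactly the identity, hence exactly uncorrelated pre-score
factors.

Correlations are pairwise-complete Pearson on the raw integer scores;
polychoric alternatives are deliberately out of scope. Standardization
stores pre-sample means and SDs (sample SD, n−1 — the package's recorded
convention) so that post-scores are projections, never re-fits. Sum scores
always sum *all* original items, including any dropped from the factor
solution. Clinical dichotomization: remission is post-total ≤ 7; response
is a total reduction of at least 50%. A missing visit total is linearly
interpolated from the adjacent visits and rounded *up* (ceiling), because
scores are integers.

# Connectivity construction

Sphere membership is center-within-5 mm (inclusive; on a 2 mm lattice no
point sits at exactly 5 mm, so inclusivity is provably irrelevant), with
overlapping claims resolved to the nearer center and ties to the lower node
id; an unmasked grid-aligned sphere contains 81 voxels, and subject-mask
conjunction can only shrink that. Tissue nuisance is summarized by the top
five principal components per tissue class (unit variance, deterministic
sign).

Cleaning follows the one-model principle: nuisance regression and
band-pass filtering (0.01–0.10 Hz at the study's TR of 2.44 s) are a
single joint regression. Censored frames are dropped from estimation and
output. The filter is implemented as regression on a discrete Fourier
basis built on the *full-run* frequency grid and evaluated at the retained
frame times: out-of-band cosines/sines are regressors (so out-of-band
variation is removed exactly on the full grid), and the nuisance columns
are first band-limited by projection on the in-band basis, which makes the
residuals exactly orthogonal to the filtered nuisance set. An FFT path is
provided for uncensored data and agrees with the regression path to
numerical precision; censoring precludes plain `filtfilt`-style filtering,
which is why the regression form is the default. Heavy censoring is
rejected when the joint model would exhaust the residual degrees of
freedom. Matrices are `atanh` (Fisher-z) of Pearson correlations with zero
diagonal; zero-variance nodes and |r| = 1 pairs are hard errors. The
mean-connectivity covariate is the pooled upper-triangle mean over both
conditions.

# Network-based statistics

Per edge, OLS of the difference stack on (intercept, sex, age, mean
connectivity, score change); the statistic is the score-change t with
n − p degrees of freedom. Edges pass at the one-sided t quantile for
p ≤ 0.001, separately per contrast direction — no cross-direction pooling.
Components are maximal node-connected subgraphs of the suprathreshold
graph; extent is the edge count, intensity the summed excess of the
direction-signed t over the threshold. Both statistics are computed every
run.

The permutation null uses Freedman–Lane residual permutation: fit the
reduced (covariates-only) model, permute its residual rows, re-add the
reduced fit, recompute every edge's t (via the Frisch–Waugh identity, so
each permutation costs one projection), and record the maximum component
statistic. This is the accepted default for GLMs with nuisance covariates
and reduces to simple permutation when covariates are absent; the scheme
is recorded in the result object since the original analysis does not
state its choice. FWER p-values use the +1-smoothed estimator,
`p = (1 + #{null ≥ obs}) / (1 + n_perm)`, so the smallest attainable value
is `1/(n_perm + 1)`. The pre-selection stage deliberately applies no
multiplicity correction across factors.

Two practical notes on calibration. First, extent is integer-valued and,
at desk-scale connectomes (tens of nodes), its attainable FWER p-values
are far apart, which makes extent-based rejection conservative; intensity
is continuous, so the package's calibration checks assess the intensity
statistic (both are always reported). Second, residual permutation with
nuisance covariates is only asymptotically exact: the permuted responses
are doubly projected through the covariate space, which at n = 30 with
four nuisance columns inflates the rejection rate by a few percentage
points. With no covariates the scheme reduces to exact simple permutation
of centered rows, so the calibration checks use the covariate-free
global-null design; the acceptance script reports the covariate-design
rate alongside so the approximation is visible rather than hidden.

# Prediction and validation

Training-set edge weights are |partial Pearson correlation| between the
edge difference and the score change, residualizing both on the covariates
plus intercept (plain Pearson in the reduced, covariate-free models),
scaled by the sample SD of all absolute correlations in the training set.
The FC predictor is the weighted average of the masked edge differences.
Because a weighted mean is invariant to uniform weight rescaling, the SD
scaling cannot change predictions — it is implemented and stored because
weight *magnitudes* are reported and compared across folds. In signed mode
the correlation signs are kept and the denominator is the sum of absolute
weights (the plain sum could vanish under mixed signs); unsigned mode is
untouched by this choice.

Three selection strategies: (A) edges of the significant components of a
full-sample NBS run — retained *only* to demonstrate circularity, since
the selection saw every subject's outcome; (B) edges passing the NBS
t threshold in the stated direction, recomputed on each training set with
the training fold's degrees of freedom; (C) all edges. The response model
is IRLS with Tukey's bisquare (tuning 4.685, 95% Gaussian efficiency — the
conventional default), MAD/0.6745 scale re-estimated per iteration,
least-squares start, delegated to `MASS::rlm`; an exactly collinear fit
short-circuits to least squares (the robust fixed point). Non-convergence
is flagged, and degenerate folds (empty selection, zero-variance
predictor, single-class test outcome) are recorded and excluded rather
than failing the run.

LOOCV reports the Pearson correlation of the pooled held-out predictions.
Repeated 3-fold CV draws a random 3-partition per redraw and evaluates on
*one* randomly chosen fold without role reversal — the most literal
reading of "3-fold CV without role reversal"; the summary is the median
per-redraw correlation (1,000 redraws at study scale). Whether a
"LOOCV median" should instead be a median over resampled LOOCV subsets is
ambiguous in the source design; the pooled correlation is reported as the
primary LOOCV summary and the per-redraw table makes alternative
summaries trivial. Sidak correction `1 − (1 − p)^m` with m = 7 (six
factors plus the sum) adjusts per questionnaire.

Median weight matrices take the per-edge median over folds/redraws with
unselected edges as zero — an edge selected in under half the redraws has
median zero, which is why thresholded 3-fold weight maps are mostly empty.
Post-hoc classification applies the clinical cutoffs to the threshold-free
predictions: AUC is the Mann–Whitney rank statistic of the predicted
*reduction* against each outcome (ties one half), and balanced accuracy
uses predicted post = pre − predicted reduction (remission cutoff 7;
response cutoff half the pre-score). The decision rule for BAC is one
defensible reading of an underdetermined step and is labeled as such in
the function documentation.

## The circularity demonstration

On *null* data, the strategy-A pipeline with selection from a full-sample
NBS run produces strongly positive CV correlations while honest strategy-C
LOOCV stays near zero. The demonstration runs the full-sample NBS at edge
threshold p = 0.05 with every observed component treated as selected
(`alpha = 1`): conditioning on formal FWER significance at the study's
trend level would discard most null replicates without changing the
mechanism being demonstrated, which is that the *selection* — significant
or not — already saw the test subjects' outcomes. The package's acceptance
checks require the circular-minus-honest median gap to exceed 0.3, the
qualitative mirror of the original contrast between circular estimates
near 0.9 and honest ones near 0.4.

# Problem sizes in the test-suite and acceptance script

The shipped simulations use scaled-down but structurally faithful
conditions, chosen as the smallest sizes at which the properties under
test are cleanly visible: global-null FWER calibration over 200 replicate
studies (n = 30 subjects, 60 nodes, 500 permutations, α = 0.05 checked
against the exact binomial band); power over 100 replicates (planted
10-edge path, effect ρ = 0.6, n = 40, detection = at least half the
planted edges recovered); circularity and null-CV calibration over 50
replicate studies (n = 30, 46 nodes ≈ 1,000 edges, 100 3-fold redraws).
The acceptance script repeats these at similar sizes and adds a planted
demonstration study (n = 60, ρ = −0.6 keyed to the questionnaire sum-score
change) whose LOOCV correlation and post-hoc AUC/BAC land in the ranges a
real study of this design reports.

# Known limitations

* The generator's edges are independent Gaussians; real connectomes have
  spatial and network-structured covariance, so permutation-null behavior
  on real data may differ from the calibration shown here.
* Discretized items are a stand-in; the original item-level score
  distributions are not public, and no claim is made about them.
* Oblique rotations, polychoric correlations, LASSO-style joint selection
  and nonlinear connectivity estimators are out of scope by design.
* The censored-frame spectral regression drops frames rather than
  interpolating them; the retained-frame count is recorded per subject.
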