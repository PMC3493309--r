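---
title: "Serum SELDI-TOF MS biomarker discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum SELDI-TOF MS biomarker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Surface-enhanced laser desorption/ionization time-of-flight mass
spectrometry (SELDI-TOF MS) profiles the low-molecular-weight serum
proteome on chromatographic chip surfaces. A typical clinical discovery
design measures a few dozen patients — here 12 outcome-positive versus 48
outcome-negative — in duplicate spots on two chip chemistries (CM10 weak
cation exchange and copper-loaded IMAC30), each acquired over a low
(< 10 kDa) and a high (10–100 kDa) mass range, four spectrum *streams* in
total. The analysis task is to turn these traces into a panel of aligned
peak candidates, test them for class differences, and estimate how well a
classifier built on the top-ranked peaks predicts the clinical outcome.

`seldiflow` implements this workflow end to end, together with a synthetic
cohort generator so that every stage is testable against known ground truth
(raw clinical SELDI spectra of this kind are generally not publicly
deposited).

# The synthetic cohort generator

A stream is simulated on a log-uniform m/z grid (default 2,000 points,
chosen for desk-scale runtime) as

$$I(m) \;=\; s \Big[ A\, e^{-(m - m_\text{min})/\tau}
 \;+\; \sum_k h_k\, G\!\big(m;\, \mu_k (1+\delta),\, w_k\big) \Big]
 \;+\; \varepsilon(m),$$

where $A e^{-(m-m_\text{min})/\tau}$ is a decaying chemical/matrix
baseline, $G$ is a unit-height Gaussian, $w_k$ is a full width at half
maximum proportional to m/z (`resolution_fwhm_rel`, default 0.3% — the
simplest line shape consistent with constant relative TOF resolution),
$\delta$ is a per-sample relative calibration shift
(`mz_jitter_rel`, SD 0.1%, mimicking the notoriously poor mass accuracy of
the platform), $s$ is a per-spot log-normal intensity scale
(`tic_scale_sd` = 0.1), and $\varepsilon$ is white Gaussian noise
(`noise_sd` = 0.5 against peak heights of 20–70). Replicate spots of one
sample share the biology — peak heights and calibration shift — and differ
only in noise and a fresh spot scale, as duplicate spots of one depleted
serum aliquot would.

Class structure enters through *planted* peaks: a positive-class sample has
each discriminatory peak's height multiplied by $e^{\text{effect}}$. The
default design plants one discriminatory peak at m/z 2,698.9 on the IMAC30
low-mass stream with a log-fold effect of 3 and a biological CV of 5%,
among 18 non-discriminatory peaks (CV 15%) spread over the four streams.
The marker's baseline height is deliberately low (4, versus 20–70 for the
background panel): serum biomarkers of interest are typically
low-abundance species, and a high-abundance 20-fold marker would dominate
the total ion current of positive samples and turn the outlier-spectrum
rule into an accidental class filter.

No quantitative noise or reproducibility figures are available for the
original instrument runs, so these defaults are stated, not fitted; they
are chosen once as a realistic operating point and are not tuned against
test outcomes. The generator does **not** simulate isotope envelopes,
adducts, matrix clusters or detector saturation, so a pass on synthetic
data demonstrates correctness of the analysis logic, not robustness to
every artifact of real spectra.

# Preprocessing

Per stream (chip × mass range — the two protocols use different matrices
and laser energies, so their intensity scales are not comparable):

1. **Baseline subtraction.** The baseline is a running minimum over
   windows of $2h+1$ grid points followed by a running mean of the same
   width — a morphological opening-style estimate (the original vendor
   software documents no algorithm). Default $h = 25$: much wider than a
   peak (a few grid points at the default resolution) and much narrower
   than the baseline decay. Windows are truncated at the spectrum edges,
   and the subtracted intensity is clipped at zero.
2. **Total ion current (TIC) normalization.** Each spectrum is divided by
   `TIC_i / mean(TIC)`; afterwards every spectrum in the stream carries
   the stream-mean TIC exactly.
3. **Outlier spectra.** A spot whose normalization factor deviates more
   than 2 standard deviations (denominator $n-1$) from the stream mean is
   excluded. The choice to apply the rule per stream rather than globally
   is ours; the original description does not say.
4. **Replicate averaging.** Surviving replicates of a sample are averaged
   pointwise; a sample that loses all its spots in one stream is dropped
   from that stream with a warning, and downstream stages work on the
   samples present in every stream.

# Peak detection, filtering and alignment

Detection smooths the trace with a short running mean (half-width 2) and
takes sign changes of the discrete first derivative from positive to
negative; plateaus report their midpoint. Because smoothing can displace
the sign change by a grid step or two on narrow peaks, the apex is then
snapped to the unsmoothed local maximum within the smoothing window; the
reported apex intensity is always the unsmoothed value.

Filtering applies the local noise rule: a peak is kept iff its apex
exceeds `median + 5 * MAD` of the intensities in a 201-point window
centred on the apex (clipped at the edges). The MAD is deliberately
**unscaled** (no 1.4826 factor), following the rule's verbatim definition.
The window default (201 points, ~10% of a stream) is wide enough that a
peak cannot dominate its own threshold.

Alignment is agglomerative complete-linkage clustering of the peak m/z
values of one stream. In one dimension complete-linkage clusters are
contiguous intervals of the sorted m/z axis, and the complete-linkage
distance between adjacent intervals is the span of their union; the
implementation exploits this, and the test suite verifies it against a
naive all-pairs agglomeration oracle. Because the tolerance is *relative*
(a fraction of m/z), "smallest distance" is interpreted in relative terms:
at each step the pair minimizing `span / (tol * union midpoint)` is
merged while that ratio is at most 1. An absolute smallest-distance rule
would let one tight low-m/z pair block legitimate merges three decades
higher. Every output cluster's diameter is therefore at most
`tol * consensus_mz` (consensus = median member m/z); if a sample
contributes two peaks to one cluster, the more intense is kept.

Two tolerance-related defaults deserve justification:

* **`rel_tolerance` = 0.8%.** The tolerance must cover the full
  cross-cohort scatter of one true peak: the span of 60 draws of the 0.1%
  calibration jitter (roughly ±3 SD, i.e. ~0.6%) plus one grid step
  (0.115% at the default grid). At 0.3% — a plausible externally
  calibrated mass accuracy — every planted peak fragments into two or
  three clusters. 0.8% is comfortably below the smallest planted peak
  spacing (> 9%), so distinct species never merge.
* **`min_support_frac` = 0.25** (pipeline level; `cluster_peaks` itself
  defaults to keeping every cluster). White-noise local maxima
  occasionally pass the 5-MAD rule no matter how small the noise is — the
  rule is scale-invariant — and appear as scattered one- or two-sample
  clusters. Requiring support from ≥ 25% of samples is the standard
  remedy in MS peak alignment and removes them without touching genuine
  peaks, which are detected in essentially all samples.

The peak matrix has one row per sample and one column per cluster. A
sample with no member peak in a cluster is re-quantified locally: its
entry is the preprocessed trace value at the grid point nearest the
consensus m/z. Zero-filling instead would fabricate perfect class
separation for rare peaks.

# Statistics

Cluster significance uses the two-sided Wilcoxon rank-sum test. Peak
ranking uses the normal approximation with tie-corrected variance and
continuity correction (ties are unavoidable after re-quantification); the
exact mode, which enumerates the full rank-sum null distribution for
untied samples of up to 25 observations, is retained for verification.
Significant clusters (raw p < 0.05, pooled over all four streams) are
ranked by ascending p, ties broken by ascending consensus m/z. No
multiple-testing correction is applied on the main path — the original
analysis worked with raw p-values — and this is a faithful-reproduction
choice, not a statistical recommendation.

Cohort characteristics tables use Pearson chi-square tests
(`chi_square_test`) — with the Yates continuity correction for 2×2 tables
and without for larger tables, the combination that reproduces all four
published cohort p-values (0.005, 0.665, 0.134, 0.119) from their printed
contingency tables — and the pooled-variance two-sample t test.

# The weighted LS-SVM

The classifier is a weighted least-squares support vector machine: an SVM
variant with squared slacks whose training reduces to one dense linear
system. With labels $y_i \in \{-1,+1\}$, kernel $K$, regularization
$\gamma$ and per-sample weights $v_i$,

$$\begin{pmatrix} 0 & y^\top \\ y & \Omega + D \end{pmatrix}
\begin{pmatrix} b \\ \alpha \end{pmatrix}
= \begin{pmatrix} 0 \\ \mathbf 1 \end{pmatrix},
\qquad \Omega_{ij} = y_i y_j K(x_i, x_j),\;
D = \mathrm{diag}\big(1/(\gamma v_i)\big),$$

and $f(x) = \sum_i \alpha_i y_i K(x, x_i) + b$. Every trained model is
required to satisfy this system to a residual below $10^{-8}$ (asserted at
training time). The weights are class-balancing, $v_i = N / (2 N_{\pm})$
— 2.5 and 0.625 for the 12-vs-48 design — so that the minority class is
not sacrificed; the exact weighting scheme of the original software is not
documented, and this is our documented assumption.

Design choices: the kernel is **linear** by default (with at most 10
selected peaks and 60 samples a linear kernel is the standard choice for
this model family; an RBF kernel is available), features are standardized
to mean 0 / SD 1 **inside the training fold only** (constant features
dropped) to avoid leakage, and the system is solved as one dense
symmetric-bordered solve — at $N = 60$ an iterative solver would be
pointless. The tuning grid is 15 values of $\gamma$ log-spaced in
$[10^{-3}, 10^3]$, spanning under- to over-regularized regimes.

# Leave-one-out validation and its two selection modes

In every leave-one-out iteration the peaks are re-ranked by Wilcoxon
significance on the 59 training samples only, and the top
$k \in \{1,\dots,10\}$ significant peaks (pooled over all four streams, in
order of decreasing significance) feed a weighted LS-SVM at each grid
$\gamma$. If a training fold has no significant peak, that iteration
falls back to the single lowest-p peak, with a warning. The per-iteration
peak count $k_i = \min(k, \#\text{significant})$ can therefore vary across
iterations even for a fixed $k$, which is how a "median number of peaks
per iteration" arises.

Two hyperparameter-selection modes are shipped:

* **paper** — $(k, \gamma)$ is chosen *globally* as the pair maximizing
  the pooled outer LOO AUC, ties broken by the smallest achievable
  balanced error rate, then the largest sensitivity + specificity at the
  operating point, then (our addition, for determinism and parsimony) the
  smaller $k$ and $\gamma$. This mirrors the original procedure — and
  inherits its optimism, because the held-out scores take part in the
  selection.
* **nested** — $(k, \gamma)$ is chosen per iteration by an inner
  leave-one-out AUC within the training fold, and the held-out value is
  recorded once. This is the methodologically clean estimate. The inner
  LOO uses the exact closed-form leave-one-out identity for the LS-SVM
  linear system ($f_{-i}(x_i) = y_i - \alpha'_i / (C^{-1})_{ii}$ in the
  regression parametrization), validated in the tests against explicit
  retraining; within the inner loop the ranking and standardization of
  the outer training fold are reused — the identity requires a fixed
  kernel, and the outer fold never sees its held-out sample.

Both modes are deliberately available: summary numbers of the original
kind (AUC, sensitivity, specificity, median peaks per iteration) are only
*definable* under the first, while the second documents how much of the
apparent performance is selection optimism. On pure-noise features the
nested mode is calibrated (mean AUC ≈ 0.5) while the paper mode scores
systematically higher; the test suite asserts exactly this contrast.

The ROC is computed once over the pooled held-out decision values (with
one sample per fold, pooling is the only coherent option), the AUC by the
pairwise Mann–Whitney estimator with ties counted 0.5, its standard error
by the Hanley–McNeil formula (the original's SE method is unstated), and
the operating point by the Youden criterion with ties broken toward
specificity. Peak *occurrence* — in how many iterations a cluster was
selected — is the stability summary; occurrences always sum to
$\sum_i k_i$.

# Quality control

Pooled-serum control runs are charted on a Shewhart chart (centre = mean,
limits at ±1, 2, 3 sample SDs) and checked against four within-run
Westgard rules: 1:3s (one point beyond 3 SD), 2:2s (two consecutive beyond
2 SD on the same side), 4:1s (four consecutive beyond 1 SD on the same
side) and 10x (ten consecutive strictly on one side of the centre), each
reported at the completing index. The charted metric is configurable; the
pipeline charts the spot TIC, the original description not naming the
quantity. Across-run rule variants and the R4s rule are out of scope.

# Numerical and degenerate-input conventions

* Ties in Wilcoxon p during ranking are broken by ascending consensus m/z;
  a constant cluster column gets p = 1 and is never selected.
* A constant QC series has no defined limits (error); a zero-SD set of
  normalization factors flags nothing.
* Baseline windows and noise windows are clipped at spectrum edges rather
  than erroring.
* `flag_outlier_spectra` with factors (1, 1, 1, 1, 3) flags **nothing**:
  the mean is 1.4, the SD 0.894, and |3 − 1.4| = 1.6 < 1.789. The test
  suite freezes this arithmetic.
* All randomness flows from explicit integer seeds; identical seeds give
  bit-identical cohorts, and the pipeline's CSV artifacts are
  byte-reproducible.

# Problem sizes used in the shipped checks

The package's own validation uses the full default study design (60
samples × 4 streams × 2 spots, 2,000 grid points per stream) for the
parameter-recovery and null-calibration runs — 10 simulation seeds for
recovery, 20 label permutations for the null — and reduced designs
(hundreds of grid points, a dozen samples) for unit-level fixtures. These
sizes are the package's choice of a desk-scale experiment: large enough
that detection, alignment and validation behave as they would on real
cohorts of this shape, small enough to iterate on.

# Known limitations

* The synthetic generator's realism caps what green tests can prove about
  vendor data: no isotope structure, no saturation, no drifting baseline
  chemistry, no within-run m/z nonlinearity.
* The paper-style selection mode is intentionally optimistic; its numbers
  should never be quoted as generalization estimates. Use the nested mode
  for those.
* Raw spectra of the motivating clinical study are not available, so its
  absolute AUC values cannot be — and are not — reproduced; the pipeline
  reproduces the *procedure* and validates it on ground-truth synthetic
  cohorts plus the exactly recomputable published cohort statistics.
* With only 12 positive samples, every validation quantity carries wide
  sampling error; the class-balancing weights mitigate, not remove, the
  imbalance.
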