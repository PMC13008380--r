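---
title: "Benchmarking coupling estimators: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking coupling estimators: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(couplingbench)
```

# What this package computes

Resting-state fMRI studies summarize brain organization as interregional
coupling — a subjects-by-edges matrix per estimator — and then ask two
questions of every estimator: how much residual head-motion artifact does it
carry (QC-FC benchmarking), and how well do its edges predict behavior
(kernel ridge brain-wide association)? `couplingbench` implements that full
evaluation loop for thirteen estimator outputs:

* **Correlation family.** Pearson and Spearman correlation of regional time
  series (Fisher r-to-z transformed by default).
* **Partial-correlation family.** Full partial correlation from the inverse
  sample covariance, `-θ_xy / sqrt(θ_xx θ_yy)`, and its L1-regularized
  version via the graphical lasso.
* **Mutual-information family.** Binned time-domain MI (Freedman–Diaconis
  binning, natural log) and frequency-domain MI, the normalized transform
  `φ = 1 − exp(−2δ)` of the band-integrated log-complement of coherence.
* **Coherence family.** Welch averaged-periodogram magnitude-squared
  coherence and Morlet wavelet coherence, both averaged over 0.008–0.08 Hz.
* **Information decomposition.** Redundancy (the minimum of the two marginal
  past-to-joint-future MIs) and synergy (the joint past-to-future MI minus
  union information), computed from the 4×4 lagged covariance of each region
  pair under a Gaussian model, lag 1 frame.
* **Regression DCM.** Effective connectivity by per-region Bayesian linear
  regression in the frequency domain: the Fourier transform of each region's
  temporal derivative regressed on all regions' spectra under a conjugate
  Gaussian–Gamma variational scheme; reported as the full directed
  off-diagonal set and as the incoming/outgoing triangle views, whose
  feature counts match the undirected estimators.

Because the cohorts such studies use are access-restricted, the package
ships a synthetic-cohort generator that plants every property the
evaluation machinery is meant to detect, making each stage testable end to
end.

# The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions under which all recovery claims are made.

**Latent dynamics.** One ground-truth network per cohort: a stable VAR(1)
system (random off-diagonal couplings at 10% density, spectral radius
rescaled to 0.85) with an SPD innovation covariance. The stationary
covariance solves the discrete Lyapunov equation; the simulator discards a
200-step burn-in, convolves with the canonical double-gamma hemodynamic
response (peak 6 s, undershoot 16 s, peak/undershoot ratio 6, truncated at
32 s), and adds white measurement noise (sd 0.5). Each subject receives a
coupling-gain perturbation (uniform on 0.6–1.4, rescaled if it threatens
stability), so coupling genuinely varies across subjects — without this,
planted brain–behavior effects would have nothing to load on.

**Motion.** Six rigid-body traces per subject: AR(1) drift (coefficient
0.97), a sinusoid at 0.37 Hz — the midpoint of the 0.31–0.43 Hz respiratory
band, so the notch filter demonstrably removes it — and white jitter, jointly
rescaled so the unfiltered mean framewise displacement equals the subject's
severity (drawn uniform on 0.05–0.35 mm).

**Motion artifact.** Edge susceptibility decays with interregional Euclidean
distance, `exp(−d/λ)` with λ = 40 mm by default (centroids uniform in a
140 mm cube give a realistic distance range). A rank-one factorization (the
leading Perron eigenvector of the susceptibility matrix) converts edge
susceptibility to per-region weights; each region receives the standardized
FD shape scaled by the subject's mean FD times the artifact gain. The
severity scaling matters: a purely per-subject-standardized regressor would
inject the same artifact into everyone and no cross-subject QC-FC structure
could exist. At gain 2 the Pearson QC-FC distribution on 200-subject
cohorts has a mean near +0.19 on the most susceptible edge quartile and a
distance dependence near −0.26 — the regime the benchmarking literature
reports for lightly denoised data.

**Sites and families.** Families (20% of subjects in two-member families by
default) are assigned whole to sites; site effects enter as a site-specific
random region-loading pattern on a shared within-subject noise source, which
shifts edge values between sites. Behavior noise carries a family-level
random intercept (ICC 0.3), so family-aware folding genuinely matters.

**Behavior.** Each behavior is a standardized weighted score of the
subjects' clean-series Pearson edges — weights drawn on the 10% of edges
with the largest cross-subject variance, i.e., the gain-modulated true
couplings, so the planted effect is identifiable — scaled to the target
population correlation (default r = 0.15, the small-effect regime typical
of brain-wide association studies), plus noise and modest loadings on age,
sex, and mean FD so confound regression has real signal to remove.

**What the generator does not emulate:** voxel-level structure and spatial
smoothness, scanner drift and physiological noise beyond the stated
components, non-Gaussian coupling, regional HRF variability, longitudinal
structure. Passing recovery tests on these cohorts demonstrates that the
estimators and the evaluation machinery are implemented correctly, not that
any estimator is superior on real data.

# Preprocessing tail

Nuisance regression precedes filtering, in that order. The 24-parameter set
is the six rigid-body parameters, their backward differences, and both sets
squared; a surrogate global signal (the cross-region mean) can be appended.
The bandpass is an ideal (rectangular) Fourier-domain filter over
0.008–0.08 Hz with the DC bin always removed; it is idempotent to 1e−10.

Framewise displacement converts rotations to arc length on a 50 mm sphere —
the conventional radius; the choice only rescales the rotational
contribution. The respiratory filter is implemented as a band-*stop* over
0.31–0.43 Hz: the stated purpose of that operation is the *removal* of
respiratory artifact, so a pass-band reading would invert its intent; both
modes are switchable (`apply_notch`). Exclusion applies three strict
inequalities: mean FD > 0.3 mm, more than 20% of frames above 0.2 mm, any
frame above 5 mm.

# Numerical choices that matter

**Graphical lasso.** Block coordinate descent on the correlation matrix
(series standardized internally), penalizing off-diagonals only; zeros are
exact; convergence when the working covariance changes by < 1e−6, hard
failure at 10,000 sweeps. λ selection follows the two-stage cohort
procedure: a wide logarithmic grid scored per subject on a 20-subject
subset, then a tight re-grid (factor 3 around the stage-1 median, clipped
to the coarse range). The scoring criterion inside the procedure is
extended BIC with γ = 0.5 — the selection criterion is not otherwise pinned
down, and extended BIC is the standard consistent choice for sparse
precision estimation. Tests verify the solution against the KKT conditions
of the convex program rather than against a second solver.

**Welch coherence.** Hann-tapered overlapping segments (default window:
frames/4 rounded down to a power of two, floored at 32 frames so at least
two bins fall in the low-frequency band, capped at 256; 50% overlap). The
1/K independence bias of the averaged periodogram is exact only for
non-overlapping segments, which is how the Monte-Carlo oracle runs.

**Wavelet coherence.** Morlet ω₀ = 6, 12 voices per octave, scale grid
covering the band with a half-octave margin; spectra are scale-normalized
and smoothed in time (Gaussian, sd = scale) and across scales (boxcar over
0.6 octave). Without smoothing the estimator is identically 1 — a smoke
test asserts the smoothed version is not. Cone-of-influence points are
included in the time average; the averaging convention does not exclude
them, and the choice is switchable only by truncating the input.

**Frequency-domain MI.** The band integral of `log(1 − C)` is nonpositive,
so the literal transform gives φ ≤ 0; the package takes the magnitude so
φ ∈ [0, 1), matching the normalized-MI intent, with the verbatim-sign
variant behind `signed = TRUE`. Coherence of exactly 1 is clipped to
1 − 1e−10.

**Binned MI.** Natural log (nats). Freedman–Diaconis width
`2·IQR·n^(−1/3)`; zero IQR falls back to Sturges with a warning; constant
series get one bin and MI 0. The plug-in estimator's positive bias,
`(M_x−1)(M_y−1)/(2n)` nats under independence, is asserted — not corrected.

**Information decomposition.** Gaussian MI from covariance determinants;
lag fixed at 1 frame (configurable); redundancy is the minimum-MI
definition, exactly as stated, not a continuous PID redundancy; the joint
future is the 2-dimensional vector of both regions. Rank-deficient 4×4
covariances (duplicated regions) are ridge-regularized at 1e−8 with a
warning.

**Regression DCM.** Resting-state variant: no driving inputs, the design
holds only region spectra (optional constant column). Priors: off-diagonal
weights N(0, 1), self-connections N(−1, 1) to encourage decay, noise
precision Gamma(2, 1); all exposed. Real and imaginary parts are stacked so
the algebra stays real. The variational free energy is tracked and must not
decrease; with a fixed noise precision the posterior collapses to the
closed-form Bayesian ridge solution, which the tests assert to 1e−8. No
explicit HRF enters the design: under identical regional hemodynamics the
HRF multiplies both sides of the regression and cancels; regionally varying
HRFs are a known caveat of this simplification. "Incoming" and "outgoing"
views are the two directed triangles of the A-matrix, giving each EC view
the same feature count as an undirected estimator.

**ComBat.** Parametric empirical Bayes (normal prior on site locations,
inverse-gamma on site scales), hyperparameters by iterative moment matching
to 1e−6, age centered and sex as an indicator. The implementation returns
the full fitted model (shrunken site effects and hyperpriors); tests verify
it against the reference implementation in `sva` to 1e−4. A single-site
stack passes through unchanged. Harmonization is applied after estimation
and before QC-FC and prediction. Re-harmonizing harmonized data perturbs
values by the EB re-shrinkage noise, which scales as 1/sqrt(subjects per
site) (about 1.6e−3 at 100 per site on the planted-offset fixture, below
1e−3 from about 400 per site).

**QC-FC.** Product-moment correlation per edge across subjects (Spearman by
flag); summary mean and *population* variance (divisor = edge count);
zero-variance edges become NaN and are dropped from summaries with a count.
Distance dependence is the Spearman correlation with centroid distances.
Sparsity matching keeps the top-k edges by *absolute* weight — strong
negative partials are strong connections — with ties broken deterministically
by lower edge index.

**Prediction.** The kernel is the correlation between subjects' coupling
feature vectors (lower triangle for undirected metrics, view vectors for
EC). Folds are family-blocked by greedy bin packing (families shuffled by
seed, sorted by size, each placed into the currently smallest fold); the
behavioral confound regression (age, sex, mean FD) is fit on training rows
only and applied to test rows. The ridge penalty grid is 16 points
log-spaced in [1e−4, 1e4]. The full scheme is 20 outer × 20 inner folds
repeated 20 times with 1,000 permutations at 10 inner/20 outer;
permutations exchange behavior between families of equal size, preserving
exchangeability under the family structure. Multi-penalty solves reuse one
eigendecomposition of the train kernel per fold, which is what makes the
permutation scheme tractable; tests assert bit-equality with the direct
solve. FDR is Benjamini–Hochberg across behaviors within each metric.

# Problem sizes used in the shipped analyses

The shipped analysis scripts and validation suites run at desk scale,
chosen as the smallest sizes at which every planted property is
statistically decidable: estimator oracles at 3–5 regions with up to 50,000
frames where a closed form is asserted; QC cohorts of 200 subjects × 25
regions × 300 frames (20 seeds for the null, 20 for the contaminated
condition); harmonization fixtures of 200–800 subjects × 60–80 edges;
prediction cohorts of 400 subjects × 50 regions with 5 outer/5 inner folds.
The full-cohort scheme (≈300 regions, ≈1,000 subjects, 20/20/20 folding) is
reachable through the same functions with larger arguments.

# Known limitations

* The binned MI and the Gaussian PID are plug-in estimators; their biases
  are characterized, not corrected.
* The wavelet scale grid extends beyond the record length for short series;
  coherence there is smoothing-dominated and contributes conservatively to
  the band average.
* rDCM assumes shared hemodynamics and a linear generative model; its
  recovery guarantees in the tests are for data generated by a linear
  system.
* The generator's site effect is a low-rank loading pattern; real
  multi-site variation includes scale and spectral differences the ComBat
  stage would only partially model.
* Test–retest reliability of the estimators is out of scope.
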