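---
title: "Movement networks from gait data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement networks from gait data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinectome)
```

## The kinectome model

During one gait cycle, every body landmark oscillates in a pattern that is
tightly coordinated with every other landmark. The *kinectome* summarizes
this coordination as a network: nodes are the 21 markers of a clinical
gait protocol (head, trunk, arms, pelvis, legs, feet, with the 10th
thoracic vertebra `T10` on the trunk), and the edge between markers $i$
and $j$ is the Pearson correlation $r_{ij}$ between their acceleration
(or jerk) time series along one laboratory axis — mediolateral (ML),
anteroposterior (AP) or vertical (V). Two kinematic quantities times
three axes give six $21 \times 21$ symmetric matrices per trial, each
with unit diagonal, 420 off-diagonal entries and 210 unique edges.

Correlation (i.e., normalized covariance) rather than raw covariance is
used throughout: the downstream analyses — fingerprinting, modularity on
$|r|$ weights, weighted degree — presuppose bounded, scale-free edge
weights, and correlations are invariant to the affine rescalings (unit
changes, marker amplitude differences) that carry no coordination
information.

### From positions to derivatives

Markers are recorded at 120 frames/s over a single ~1–2 s gait cycle.
Acceleration is the second, jerk the third time derivative of position,
estimated by repeated central differences, which are second-order
accurate and exact on polynomials up to cubic; each derivative order
trims one frame at each end, an acceptable loss (≤ 3 frames) for
single-cycle trials.

Differentiation amplifies the spectral content at frequency $f$ by
$(2\pi f)^{\mathrm{order}}$. Broadband measurement noise therefore
dominates raw second and, especially, third derivatives of optical data:
a noise component at 10 Hz is amplified roughly $1300\times$ more than
the stride-frequency component of the signal in jerk. A zero-phase
(forward–backward) 4th-order Butterworth low-pass on the positions is
consequently not an optional nicety but a structural part of the method.
The pipeline default is a 4 Hz cutoff: the locomotor content of a ~0.9 Hz
stride lies in the first three harmonics (≤ 2.7 Hz), and a 4 Hz passband
transmits them essentially unattenuated while suppressing the
out-of-band noise that would otherwise drown the jerk correlations.
For data with faster cadence or meaningful higher harmonics the cutoff
is a single `filter_policy` parameter. The filter implementation pads by
odd reflection before the forward–backward pass; without padding, the
start/end transients of a short series act as a shared artifact and
inflate every between-marker correlation (we measured spurious
$|r| \approx 0.5$ between orthogonal oscillations on 132-frame trials).

## Analyses

**Modularity.** Community structure is found by Louvain optimization of
Newman's $Q$ with consensus clustering: 100 seeded Louvain runs are
summarized in a co-assignment matrix, entries below the chance level of
label-permuted partitions are zeroed, and the matrix is re-clustered
until co-assignment is binary. Correlations can be negative while
modularity assumes non-negative weights; edges enter as $|r|$ by default
(anti-phase coupling is still coupling), configurable to zeroing.
Per-subject partitions from acceleration and jerk are pooled into one
allegiance matrix per axis — the probability that two markers share a
community across the cohort — and the group-level modules are the
consensus communities of that matrix.

**Fingerprinting.** For each subject the 210-edge vectors of a *test*
and a *retest* trial are compared: the identifiability matrix holds the
Pearson correlation between subject $i$'s test vector and subject $j$'s
retest vector. I-self is the mean diagonal, I-others the mean
off-diagonal, I-diff their difference, and the identification rate (IR)
the fraction of subjects whose self-similarity exceeds *all* their
cross-similarities. Two readings of "all" exist because the matrix is
not symmetric; the default is the strict one (the subject must win along
both its row and its column), configurable to row-only. Ties count as
not identified. Scores are correlations; the percent scale (IR 100%,
I-diff 37.5%) is applied only at the reporting layer.

**Edge selection.** Per-edge reliability is the one-way random-effects
intraclass correlation $r = (MSA - MSW)/(MSA + (k-1)\,MSW)$ with
subjects as clusters and the $k = 2$ sessions as observations. Edges
with zero total variance have no defined ICC and rank last; ties break
by edge index for reproducibility. The IR curve starts from the three
highest-ICC edges and adds one edge per step; 100 null curves from
random edge orderings provide the reference band, and the edges of
interest are the shortest prefix whose IR exceeds 99%. Markers are
flagged when their endpoint count over the pooled ML/AP edge sets
(vertical is excluded, as the axis least informative about individual
impairment) exceeds the 99th percentile of equally sized random edge
subsets.

**Topology and prediction.** The weighted degree
$s_i = \sum_{j \ne i} |r_{ij}|$ summarizes how strongly one marker is
coupled to the rest of the body. Group differences in degree, kinectome
variability and fingerprint scores use permutation tests: the absolute
difference of group means against 10,000 label shuffles, with the
add-one correction $p = (\#\{null \ge obs\} + 1)/(n_{perm} + 1)$ and
Bonferroni correction over the tests actually run (0.05/6 ≈ 0.0083 for
the six kinectome types; 0.05/18 ≈ 0.0028 for three fingerprint scores
× six types). The clinical model is an ordinary least-squares regression
of the motor score on the flagged marker's degree plus age, education
and gender, with variance-inflation factors for collinearity and seeded
5-fold cross-validation; both the in-sample and the pooled out-of-fold
$R^2$ are reported because either could be meant by a single published
number.

## The synthetic cohort generator

No public dataset accompanies the method, so the package ships a
generator that produces exactly the statistical structure the analyses
consume, with known ground truth:

```{r, eval = FALSE}
spec <- cohort_spec(n_subjects = 23, mode = "parkinsonian", seed = 1)
cohort <- generate_cohort(spec)
truth <- cohort$truth # planted couplings, sides, modules
```

Each marker's trajectory is a sum of up to three harmonics of the stride
frequency (cycle 1.1 s, 120 frames/s, 132 frames — matching the ~2 s,
single-cycle recordings of clinical practice). Template amplitudes are a
few centimeters; phases encode gait coordination and a planted
three-module structure on ML (axial sway at the stride frequency; arm
swing in quadrature, antiphase left/right; step-frequency leg
oscillation), contralateral arm–leg pairing on AP, and a common
step-frequency bounce on V. Every series also carries a smaller
higher-harmonic "impact" component (arm h3, axial ML h2, leg AP h2, each
in quadrature to the neighbouring module) standing in for heel-strike
transients: without such content the jerk of a low-harmonic series would
be noise-limited, since differentiation re-weights harmonic $h$ by
$h^3$.

Layered on the template are, in order:

* a **subject signature** — multiplicative amplitude and additive phase
  perturbations (SD 0.15, shared by both trials) — the stable individual
  style that fingerprinting recovers;
* **trial noise** — additive white noise at 5% of each series' SD plus
  stride-to-stride phase jitter of $0.8 \times$ the noise scale in
  radians (~2.3°). The jitter provides the common within-subject
  reliability floor that an ICC ranking presupposes: with noiseless
  phases, near-saturated within-module edges become numerically perfect
  and outrank every discriminative edge;
* in **parkinsonian mode**: left–right asymmetry (the affected side,
  random per subject, loses 25% amplitude and lags 0.125 rad); AP
  signature variance inflated ×2 (between-subject variability of
  anteroposterior progression); and a **trunk–limb coupling**: `T10`
  receives an h2 component at the leg phase on ML and an h1 component at
  the limb phase on AP, scaled by a per-subject coupling weight
  (mean 0.3, SD 0.3, truncated at 0). The entrainment direction —
  trunk driven by the limb rhythm, rather than a trunk component copied
  into limb channels — is what makes the planted effect visible in
  acceleration and jerk: a low-harmonic trunk component injected into
  high-harmonic limb series would all but vanish under differentiation.
  The coupling SD is deliberately comparable to the signature-driven
  edge variability so that coupling edges carry the dominant
  between-subject variance, mirroring the clinical heterogeneity of
  axial involvement;
* a **motor score** $= \max(0, 8 + 40\,c_s + \varepsilon)$,
  $\varepsilon \sim N(0, 2)$, rounded — so the score is driven by the
  same coupling that raises the `T10` degree, with demographics (age,
  sex, education) drawn independently as pure nuisance covariates.

What the generator does *not* emulate: physically consistent joint
kinematics, ground-reaction constraints, soft-tissue artifact,
non-stationarity across the cycle, and any dependence of the score on
demographics. Tests passing on these cohorts therefore demonstrate that
the pipeline recovers the structures it is designed to detect when they
are present at realistic magnitudes — not that real patient cohorts will
show the same effect sizes.

## Numerical choices and conventions

* Edges are stored in row-major upper-triangle order, fixed across the
  package; vectorize/unvectorize round-trip exactly.
* Asymmetry beyond $10^{-9}$ when vectorizing, zero-variance series, and
  derivative orders without frame support are hard errors, not warnings.
* All stochastic steps (Louvain, consensus, permutations, null curves,
  CV folds, cohort generation) take explicit seeds; a master seed spawns
  per-stage seeds, and seeded calls restore the caller's RNG stream.
* Group-level statistics use the test-session kinectome only, keeping
  the retest untouched for fingerprinting; a per-subject average is a
  documented alternative.
* Degenerate consensus inputs (all-zero adjacency) and never-exceeded IR
  thresholds are reported explicitly (error and warning + empty set,
  respectively).
* Problem sizes in the shipped tests — cohorts of 6–23 subjects, 100
  clinical-model replicates, 1000 calibration replicates at 199
  permutations — were chosen as the smallest sizes at which the checked
  properties are stable.

## Known limitations

* A single gait cycle gives ~126–132 frames per series; correlation
  estimates at this length are noisy, which is precisely why the
  reliability-based edge selection exists. Longer recordings would
  change the operating point.
* The C3D reader supports the common Intel/float variant with point
  data only (no analog channels, no integer scaling) — sufficient for
  round-tripping marker trajectories, not a general-purpose C3D library.
* Louvain + consensus is stochastic by nature; results are reproducible
  under a fixed seed but can change under another, especially on graphs
  with genuinely ambiguous structure.
* The clinical model is deliberately plain OLS with k-fold CV; it
  quantifies the predictive content of one nodal feature, and is not a
  competitive clinical predictor.
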