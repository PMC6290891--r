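---
title: "Group resting-state connectivity analysis with fconn: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group resting-state connectivity analysis with fconn: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fconn` implements a complete two-group analysis of resting-state
functional connectivity time series: per-subject denoising, seed-based
and whole-matrix connectivity, cluster-extent inference on lattice
(voxel) maps, large-scale-network aggregation, and density-swept nodal
graph metrics compared between groups with family-wise error control.
Because real subject-level recordings of this kind are rarely shareable,
the package also contains a first-class synthetic-data generator whose
planted effects make every stage of the chain testable against a known
ground truth. This vignette describes the models, the parameters that
matter, the numerical choices, and what the validation suite does and
does not establish.

## The synthetic data model

A configuration (`sim_config()`) describes a two-group study: `n_per_group`
subjects per group (default 14), `n_nodes` regions (default 100),
`n_timepoints` samples (default 296) at sampling interval `tr_seconds`
(default 2 s) — the design of a typical ten-minute resting-state run
after discarding four stabilization volumes. Signals are band-limited to
0.01–0.1 Hz, the conventional resting-state band.

Each group draws its signals from a correlation matrix with unit
diagonal in which a designated seed node correlates with a set of target
nodes at

- group A: $r_A = \texttt{base\_r}$,
- group B: $r_B = \tanh(\operatorname{atanh}(\texttt{base\_r}) + \Delta z)$,

so the group difference is exactly `delta_z` on the Fisher-z scale, the
scale on which group inference operates. Target–target entries are set
to $r^2$, the correlation implied by a common-factor construction
(each target = $r \cdot$ seed $+ \sqrt{1-r^2}\cdot$ noise), which makes
the matrix positive semidefinite by construction; a nearest-PSD
projection (eigenvalue clipping followed by unit-diagonal rescaling) is
still applied as a guard and is a no-op for these configurations.

Subject time series are built by (1) filtering white Gaussian noise with
the same zero-phase Butterworth band-pass the denoising module uses,
(2) multiplying by the symmetric square root of the group correlation
matrix, (3) optionally adding low-rank structured noise (per-subject
component time courses with per-node Gaussian loadings, for exercising
CompCor), (4) adding white measurement noise of standard deviation
`noise_sd`, and (5) adding a constant baseline. Keeping the spectral
shaping before the covariance mixing keeps the two targets independent:
the band limits come from the filter, the correlation structure from the
matrix square root.

Defaults that the underlying study design does not pin down are package
choices, made once: 10 target nodes (a plausible extent for a
seed-driven association network at ~100-node resolution); `base_r = 0.3`
and `delta_z = 0.3` (a moderate baseline and a moderate-to-large planted
effect on the z scale); `noise_sd = 0.5` (node-level SNR of roughly 2:1
against the unit-variance signal, in the range typical of parcel-average
BOLD series); baseline 100 so grand-mean scaling operates on positive
data; no structured noise by default, so that the planted correlations
are exactly recoverable and CompCor tests enable it explicitly. Motion
traces are smooth Gaussian random-walk drifts (increment SD
`drift_sd = 0.02` mm, rotations 100-fold smaller) with one-frame spikes
of 1 mm / 0.01 rad at rate `motion_spike_rate` per transition —
amplitudes chosen to sit clearly above conventional outlier thresholds.

The lattice generator plants a contiguous box of voxels that correlates
with a per-subject seed series at the group-dependent $r$, embedded in
independent band-limited noise, providing ground truth for
cluster-extent inference.

Determinism: one master integer seed; per-subject sub-seeds are drawn
from it in documented order (group A ascending, then group B), so output
is reproducible and independent of any parallelism in the surrounding
code.

**What the generator does not emulate:** hemodynamic response shapes,
physiological (cardiac/respiratory) cycles, spatial autocorrelation of
real BOLD images, scanner drifts, or non-Gaussian artifacts. Passing
tests therefore demonstrate correctness of the statistical machinery
under the stated model, not performance on real scanner data.

## The denoising chain

`denoise_subject()` applies, in fixed order: initial-volume discard
(default 4); framewise displacement and outlier detection; grand-mean
scaling to 100; nuisance regression (intercept + six rigid-body motion
parameters + one indicator per flagged frame); CompCor component
regression; band-pass filtering. The order is logged in the result.

- **Framewise displacement** uses the relative root-mean-square form:
  for the transform between consecutive frames with linear part
  difference $A$ and translation $b$,
  $\mathrm{FD} = \sqrt{\tfrac{R^2}{5}\operatorname{tr}(A^\top A) + b^\top b}$,
  the exact RMS displacement over a solid sphere of radius $R$
  (default 80 mm, the algorithm's conventional head radius). Pure
  translations give FD equal to the translation magnitude.
- **Outlier detection** flags frames whose global-signal z-score exceeds
  3 or whose incoming FD exceeds 0.5 mm — conventional artifact-detection
  defaults; the thresholds are parameters and are echoed in logs.
- **CompCor** extracts principal-component time courses from a
  noise-region matrix (aCompCor) and from the highest-variance rows of
  the data itself (tCompCor; top 2% of rows by default), five of each
  for the default ten components. Components are the right singular
  vectors of the row-centered source matrix: unit-norm, orthogonal
  within each set.
- **Band-pass** is a 4th-order Butterworth applied forward and backward
  (zero phase), 0.01–0.1 Hz at TR = 2 s by default. Rows are demeaned
  first so constant input maps to numerical zero. Because zero-phase
  filtering is linear, the package materializes the filter as a cached
  $T \times T$ operator and filters whole matrices with one
  multiplication; this is exact (equal to per-row filtering to machine
  precision) and is what makes lattice-scale simulation affordable.
- **Global-signal regression is not part of the default chain** — it can
  induce spurious negative correlations in group comparisons — but is
  available behind an explicit flag.

## Connectivity and group inference

Connectivity is Pearson correlation: seed maps (`seed_connectivity_map()`)
and full adjacency matrices (`build_adjacency()`), Fisher-transformed
with $z = \operatorname{atanh}(r)$ and $|r|$ clipped at $1 - 10^{-7}$ so
perfect correlations stay finite while ordering is preserved. Constant
series are flagged and contribute zeros rather than NAs.

Group comparison is the pooled-variance independent-samples t-test
(direction A−B, df $= n_A + n_B - 2$), identical whether applied to raw
samples, per-element maps, ROI means, or summary statistics
(`t_from_summary()`); the latter reproduces a published demographics
table bundled in `inst/extdata`. A Mann-Whitney U test with midranks,
tie-corrected variance, continuity correction and exact enumeration for
$n_1+n_2 \le 12$ covers ordinal measures. The exact and
normal-approximate p agree to about 0.02 in the inferential tail
($p \le 0.2$) for group sizes of three and up; the reported p uses the
exact enumeration whenever it is feasible.

**Cluster-extent inference.** Lattice t-maps are thresholded one-sidedly
at the cluster-forming threshold $p < 0.0075$ (each contrast direction
run separately, matching two-tailed reporting conventions) and grouped
into connected components under 18-connectivity (configurable 6/18/26).
Family-wise control is by permutation of group labels: the null
distribution of the maximum suprathreshold cluster extent gives each
observed cluster
$p_{corr} = (1 + \#\{\text{null max} \ge \text{size}\})/(1 + n_{perm})$.
This is a deliberate design choice over parametric (random-field)
cluster corrections, whose smoothness estimation is image- and
software-specific; permutation gives distribution-free control that can
be validated on synthetic lattices, and the substitution is recorded in
the result metadata. When the requested permutation count reaches the
number of distinct relabelings the test enumerates them exactly (with a
warning).

## Graph metrics over a density sweep

Subject adjacency matrices are thresholded at each connection density
$\delta \in \{0.05, 0.06, \dots, 0.35\}$ by retaining exactly
$\mathrm{round}(\delta N(N-1)/2)$ strongest edges — proportional
thresholding, which fixes the edge count so subjects are compared at
identical density (an absolute weight cutoff would not). Ties are broken
by ascending edge index for platform-independent determinism. Ranking
uses signed weights; if a requested density would force retention of a
non-positive correlation the package raises an error rather than
silently binarizing negative edges.

Per density, four nodal metrics: degree and betweenness centrality and
eigenvector centrality on the binarized graph, strength (sum of retained
weights) on the weighted graph. Betweenness uses exact shortest-path
counting (unnormalized, unordered pairs counted once; disconnected pairs
contribute nothing). Eigenvector centrality is the nonnegative dominant
eigenvector, L2-normalized, computed by power iteration (tolerance
$10^{-10}$, at most 1000 iterations) on $A + I$: the shift leaves
eigenvectors unchanged but guarantees convergence on bipartite graphs,
which sparse thresholds routinely produce (plain iteration on $A$
oscillates between the $\pm\lambda$ pair of a forest). Both conventions
(unnormalized BC; dominant eigenpair of the possibly disconnected graph)
are recorded because the literature varies.

Each node's metric-versus-density curve is summarized by its composite
trapezoidal integral (AUC) over the sweep — a threshold-independent
summary — and strength can be computed on the full weighted matrix by
setting $\delta = 1$.

## Bootstrap max-t inference on AUC

`bootstrap_maxt_test()` compares per-node AUC between groups with strong
family-wise control. The observed statistic is the pooled t per node.
Each of `n_boot` (default 10,000) surrogates resamples all subjects with
replacement from the pooled sample and splits them randomly into groups
of the original sizes; the maximum $|t|$ across nodes per surrogate
forms the null, and
$p_{corr}(j) = (1 + \#\{\max|t^*| \ge |t_{obs}(j)|\})/(1 + n_{boot})$,
with the uncorrected $p_{obs}$ from each node's own surrogate
distribution using the same +1-smoothed estimator (which also avoids
zero p-values at finite resampling). Resampling *with replacement* plus
random relabeling is the literal reading of a bootstrap-style surrogate
scheme; a pure permutation mode is available behind a flag for
sensitivity analysis, and the two agree closely in measured error rates.
Two-sided inference uses $\max |t|$; pooled (not Welch) variance matches
the df = 26 reporting convention of two equal groups of 14. Degenerate
surrogate variances yield $t^* = 0$ and are counted in the result.

By construction $p_{corr} \ge p_{obs}$, ordering nodes by $|t_{obs}|$
orders them inversely by $p_{corr}$, and removing nodes can only lower
the null maxima, hence never raise a remaining node's $p_{corr}$ — all
verified as properties in the test suite.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle
(closed forms, brute-force enumeration, dense eigensolvers, quadrature,
reference flood-fill labeling) and then the chain end to end:

- measured family-wise error of the bootstrap max-t (500 null datasets,
  100 nodes, 14 per group, 1000 resamples) and of the permutation
  cluster correction (500 null 12×12×12 lattices, 8 per group, 200
  permutations) must fall inside the exact binomial 95% interval around
  the nominal 5%;
- under the default planted effect the chain must flag the seed node's
  degree-or-strength AUC in at least 80% of 50 replicates, and recover
  the planted 3×3×3 lattice cluster in at least 95% of 100 replicates;
- with the effect switched off the flag rate must fall back inside the
  binomial interval around 5%.

These sizes keep the full suite under a coffee break on one CPU while
leaving the binomial intervals tight enough to catch calibration errors
of a few percentage points. `scripts/acceptance.R` recomputes the same
quantities from scratch at moderately reduced replicate counts and
writes them as JSON.

## Known limitations

- The generator's stationarity and Gaussianity are idealizations; no
  claim is made about robustness to real-scanner artifacts.
- Proportional thresholding with signed ranking ignores negative
  correlations entirely at the default densities; analyses that treat
  negative edges as meaningful need a different thresholding rule.
- Cluster inference assumes exchangeability of subjects under the null
  (no covariate adjustment is provided; the group analyses it mirrors
  are unadjusted two-sample tests).
- tCompCor estimated from data that is signal everywhere (as in the ROI
  simulator) removes some signal along with noise; its intended use is
  on voxel data where high-variance rows are dominated by physiological
  noise.
- The exact Mann-Whitney enumeration is limited to $n_1+n_2 \le 12$;
  beyond that the tie-corrected normal approximation is used.
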