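---
title: "Methods: depth-video behavioral segmentation and group comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-video behavioral segmentation and group comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`ethoseg` implements an unsupervised pipeline for describing the spontaneous
open-field behavior of a mouse recorded with a top-mounted depth camera, and
for comparing the resulting behavioral statistics between experimental
groups (genotypes, drug treatments, sexes). The pipeline follows the
motion-sequencing paradigm: continuous behavior is modeled as a sequence of
brief stereotyped motifs ("syllables"), each a few hundred milliseconds
long, selected by a probabilistic (Markovian) mechanism. The stages are:

1. **Tracking** (`em_track_session`): extract the animal from each depth
   frame with an EM-fitted 3D Gaussian plus uniform-clutter mixture, read
   the body ellipse off the spatial covariance, and derive per-frame speed
   and height.
2. **Pose embedding** (`crop_align_frames`, `detect_and_fix_flips`,
   `smooth_crops`, `fit_pose_pca`, `project_poses`): rotate an 80 x 80
   crop so the spine lies horizontal with the nose pointing right, denoise,
   and project the flattened crops onto the top 10 principal components
   fitted across all sessions.
3. **Segmentation** (`train_arhmm`): a sticky autoregressive hidden Markov
   model (AR-HMM) over the 10-dimensional pose series, trained by blocked
   Gibbs sampling; each hidden state is one syllable with its own linear
   (vector-autoregressive) pose dynamics.
4. **Statistics** (`usage_profile`, `bigram_matrix`,
   `group_transition_graphs`, `jsd_permutation_test`, `usage_embedding`,
   `distribution_summaries`, `group_totals`, `two_sample_t`): per-session
   syllable usage and transition structure, group-level transition and
   difference graphs, and a permutation test on the Jensen-Shannon
   divergence (JSD) between transition distributions.

Because raw depth recordings of this kind are rarely shared, the package
also contains a first-class synthetic-data generator (`make_cohort`,
`render_depth_session`) that produces ground-truth-labeled sessions at
three levels (syllable labels, pose series, rendered depth video), with the
cohort structure of a crossover drug study. Every downstream stage is
validated against this ground truth.

# The generative model

## Syllable sequence

A `ground_truth_spec` holds an `n_states x n_states` row-stochastic matrix
of *between*-syllable transition probabilities and a `duration_bias`
$\kappa_g \ge 0$. The effective chain is

$$P_{\mathrm{eff}} = \mathrm{rownorm}(P + \kappa_g I),$$

so syllable durations are geometric with mean $1 + \kappa_g$ frames when
$P$ has an empty diagonal. The default $\kappa_g = 10$ gives ~11-frame
(370 ms at 30 Hz) mean durations, the sub-second regime typical of mouse
syllables.

## Pose dynamics

Given the label sequence $z_t$, pose observations follow a switching
vector-autoregression,

$$x_t = \textstyle\sum_{l=1}^{L} A_{z_t,l}\, x_{t-l} + b_{z_t} +
\varepsilon_t, \qquad \varepsilon_t \sim \mathcal N(0, \Sigma_{z_t}),$$

with the first $L$ frames drawn around the current state's bias. The
default per-state parameters (`default_ar_params`) are stable rotations
$A = \rho R$ with $\rho = 0.7$ and well-separated biases, so states differ
in both their fixed points and their local dynamics. Unstable coefficient
sets (companion spectral radius $\ge 1$) are simulated as requested but
produce a warning.

## Depth rendering

`render_depth_session` draws each frame as the arena floor at the camera
distance (520 mm) minus an anisotropic Gaussian height bump at the animal's
position, oriented along its heading ($\sigma_{\parallel} = \ell/4$,
$\sigma_{\perp} = w/4$ for body length $\ell$ and width $w$), with:

* a nose-ward height asymmetry, $h \mapsto h\,(1 + a \tanh(u/\sigma_{\parallel}))$
  with $a = 0.15$ by default, where $u$ is the along-heading coordinate —
  this makes head/tail orientation learnable, as it is for real animals,
  while leaving the height at the blob center exact;
* i.i.d. Gaussian sensor noise (default SD 2 mm, a realistic time-of-flight
  figure at ~0.5 m range);
* a fraction (default 1%) of out-of-range pixels set to the sentinel value
  0 (sensor-dropout convention; valid depths are clipped to $\ge 1$ so the
  sentinel never collides with real data);
* values rounded to integer millimetres in the 16-bit range, matching the
  acquisition format.

The default `arena_spec` keeps the study geometry: a 30 x 30 cm arena
viewed from 52 cm, 640 x 480 px frames at 30 Hz. The test suite and the
acceptance experiments use the same geometry at reduced resolution
(168 x 168 px, 0.5 px/mm) so that rendering and tracking hundreds of
frames stays desk-scale; resolution is an explicit `ArenaSpec` parameter,
not a separate code path.

The default cohort reproduces the crossover design of the motivating
experiment: 17 subjects (10 mutant: 5 male, 5 female; 7 control: 3 male,
4 female), each recorded once under saline and once under drug challenge,
order counterbalanced, 30 min per session at 30 Hz. Planted group effects
are expressed as per-cell `ground_truth_spec` overrides (e.g.
`shift_transition_mass` moves transition probability between two target
syllables without changing usage of the source syllable).

**What the generator does *not* emulate:** articulated limbs and
posture-dependent silhouette changes, body-size variation between animals,
occlusions, wall rearing (a simplified mirrored "ghost" is available via
`reflection_on` for robustness checks), and non-Markovian long-range
structure in real behavior. Passing the recovery tests therefore shows the
*algorithms* are correct and well-calibrated on data obeying the model
assumptions; it cannot certify performance on real recordings.

# Preprocessing choices

* **Cleanup** (`prepare_frames`): frames are cropped to the region of
  interest and sentinel pixels become `NA`, excluded from every downstream
  statistic.
* **Background** (`compute_background`): per-pixel median over frames
  sampled every 500 frames, each sampled frame first passed through a
  3 x 3 spatial median. The pre-median filter is deliberately simple and
  configurable; the stride matches standard practice. Short recordings in
  which the animal barely moves leave a biased background under the animal
  — the tests therefore estimate background either from long roaming
  sessions or from an empty-arena rendering (`render_empty_session`), both
  of which are realistic usage patterns.
* **Height convention**: height = background − frame, clipped at 0. The
  sensor records distance-from-sensor, so this inversion is required.
* **EM tracker**: one 3D Gaussian over (row, col, height) plus a uniform
  clutter component over the arena volume. Pixels below 5 mm height are
  treated as floor and excluded; the clutter component absorbs dust and
  speckle above that. EM runs at most 25 iterations to a log-likelihood
  change below 1e-4, warm-started from the previous frame; the first frame
  initializes from the largest 4-connected component above 10 mm. The
  ellipse uses `scale_factor = 2` times the square-rooted eigenvalues of
  the spatial covariance (~95% mass) and "inside the ellipse" means
  spatial Mahalanobis distance at most 2; both are configurable because
  upstream conventions differ.
* **Coordinates**: (row, col), origin top-left, 0-based, angles
  counter-clockwise from the +column axis; the raw ellipse axis angle
  lives in $[-\pi/2, \pi/2)$ and becomes a heading in $(-\pi, \pi]$ after
  flip resolution.
* **Crop-align**: bilinear sampling of the height image on an 80 x 80 grid
  rotated by the axis angle, centered between the four central pixels so
  crops are mirror-symmetric for symmetric animals. Out-of-frame samples
  are zero and flagged. Bilinear interpolation bounds the
  rotation-equivariance error at a few percent of the peak height for
  body-scale Gaussians; tests assert 5% of the peak.
* **Flip correction** (`detect_and_fix_flips`): the ellipse axis is
  orientation-ambiguous, so per-frame left/right decisions come from a
  classifier over 8 x 8 block-mean features of lightly smoothed crops. The
  procedure is unsupervised: (i) seed scores from the leading principal
  component of the mirror-difference features $f - \mathrm{mirror}(f)$,
  which isolates the orientation-antisymmetric content; (ii) fix the
  global sign by the third-moment convention (a right-facing animal has
  its head/shoulder bulk nose-ward and a longer rearward taper, hence
  negative along-axis skewness); (iii) refine twice with a ridge-regularized
  Fisher discriminant trained on the current labels plus mirrored copies
  (random forest optional via `method = "rf"`); scores are median-filtered
  over 7 frames before thresholding. If the uncentered lag-1
  autocorrelation of the seed scores falls below 0.15 the orientation
  signal is indistinguishable from sensor noise (symmetric animal) and a
  temporal-consistency heuristic with a 5% hysteresis margin takes over:
  decisions are then arbitrary but stable.
* **Denoising** (`smooth_crops`): spatial Gaussian with SDs (3.25, 2.0) px
  (along, across the body axis) followed by a 5-frame per-pixel temporal
  median (167 ms at 30 Hz), spatial first. Edge frames use shrunken median
  windows.
* **Kinematics**: speed is the frame-to-frame displacement of the raw
  ellipse center times the frame rate (frame 0 defined 0); totals use the
  first 30 min. Centroid smoothing before differentiation is available as
  an option but off by default, since the convention upstream is unstated.

# Pose embedding

PCA is fitted on the pooled flattened crops of all sessions (`fit_pose_pca`),
keeping 10 components; missing pixels are zero-filled (mean-filling is a
flag), component signs are fixed by making each component's
largest-magnitude loading positive, and a uniformly strided cap of 2e5
frames bounds memory on long experiments. Scores are plain centered
projections; no whitening is applied before the AR-HMM (a flag exists, but
unwhitened scores keep the emission covariances interpretable in pixel
units). On realistic synthetic data 10 components explain on the order of
85-99% of variance — reported by `print()` as a diagnostic, not asserted,
since the value is data-dependent.

# The AR-HMM and its sampler

The segmentation model is a finite weak-limit approximation of the sticky
hierarchical AR-HMM: a generous state cap (default K = 100) with a sticky
Dirichlet prior on transition rows,

$$\pi_k \sim \mathrm{Dir}(\alpha/K + \kappa\,\delta_k + n_{k\cdot}),$$

(defaults $\alpha = 5$, $\kappa = 100$), and a matrix-normal-inverse-Wishart
(MNIW) prior on each state's AR parameters $(W_k, \Sigma_k)$, with prior
mean persisting the previous frame ($M_0 = [I\;0\;\dots\;0]$), column
precision $K_0 = 0.1 I$, $\nu_0 = d + 2$ and $S_0 = I$. Inference is
blocked Gibbs: forward-filter backward-sampling of each session's state
sequence given the AR parameters (C++ inner loop), conjugate MNIW draws
per state given its assigned frames, and Dirichlet draws of transition
rows. Labels are reported from the final sample by default so a seed fully
determines the output (`modal_over` switches to per-frame modes over the
last samples). Lag order defaults to L = 3 by convention; the recovery
experiments generate and fit L = 1 dynamics, which keeps the planted
states' identifiability transparent. Covariance draws are floored at
eigenvalue 1e-6 to stay positive-definite on degenerate data. Sessions
shorter than L + 1 frames are skipped with a warning; the first L frames
of each labeled session inherit the first sampled state.

Two training diagnostics are built in: the joint log-likelihood trace and
a held-out sequence log-likelihood (`sequence_loglik`, forward algorithm in
log space) evaluated every few sweeps, which should trend upward and then
plateau.

**Syllable validation** (`cross_likelihood_matrix`): entry $(i, j)$ is the
mean per-frame AR log-likelihood of state $i$'s run-interior frames under
state $j$'s parameters minus the same under state $i$'s own parameters —
nats per frame, diagonal exactly 0. The matrix is referenced to the
self-model because the raw per-frame likelihood scale depends on the PCA
score units; strongly negative off-diagonal entries mean syllables are
dynamically distinct. The unreferenced variant is a flag away. Only frames
whose full lag window lies inside one run are scored, so each entry cleanly
attributes dynamics to one state.

Reported syllable counts on real-scale data depend on usage thresholds;
`n_used_states` reports both the raw count and the count above a
configurable occupancy threshold.

# Group statistics

* **Usage profiles**: by run onsets (default; emphasizes sequencing) or by
  frame occupancy.
* **Bigram transition matrices**: self-transitions are removed by
  run-length encoding before counting (the syllable-change convention;
  frame-level counting is a flag), and each row is normalized by the source
  syllable's outgoing count. Rows with no outgoing transitions are all-zero
  and flagged, and are excluded from group-mean rows rather than filled
  uniformly — averaging should not invent transitions.
* **JSD between sessions**: computed on the *joint* bigram distribution
  (counts over total counts), i.e. the conditional matrix weighted by how
  often each source syllable occurs. This is the standard flattening when
  comparing "transition matrices" wholesale; a row-averaged conditional
  variant is available. Base-2 logarithms keep the value in [0, 1].
* **Permutation test**: observed statistic = mean JSD over all cross-group
  session pairs; group labels are reshuffled preserving group sizes
  (default 10,000 times) and the p-value is the plain fraction of permuted
  statistics at or above the observed one, with an add-one estimator as an
  option. The pairwise JSD matrix is computed once, so permutations cost
  only indexing.
* **Usage embeddings**: joint centered PCA of all sessions' usage vectors
  (top 2 scores), and a one-dimensional ridge-regularized Fisher
  discriminant per declared subset with Gaussian KDE (Scott bandwidth) of
  the projected scores — the within-class scatter of usage vectors is
  always near-singular at realistic session counts, hence the ridge.
* **Kinematic summaries**: fixed-bin normalized histograms (speed 0-400
  mm/s in 100 bins, height 0-100 mm in 50 bins by default; binning is
  config-exposed since upstream binning is unstated), log10 masses with
  empty bins reported missing rather than $-\infty$, empirical CDFs at the
  bin edges, and per-group means with SEM = SD/$\sqrt{n}$.
* **Two-sample t**: the pooled-variance (Student) form, from raw samples or
  from published (mean, SEM, n) summaries. Pooled rather than Welch is
  deliberate: it reproduces df = n1 + n2 − 2, the degrees of freedom
  convention of the reference analyses.

# Validation experiments

The acceptance script (`scripts/acceptance.R`) and the test suite rerun
the following experiments end to end; sizes were chosen once as the
smallest that make the checks statistically meaningful:

* t-statistic reconstruction from the published distance and speed group
  summaries (7 vs 10 subjects).
* JSD type-I error: 100 null cohorts, 5 + 5 sessions of 2e4 frames from
  one generator, 500 permutations each.
* JSD power: 50 cohorts with 0.2 transition mass moved on one edge.
* AR-HMM recovery: 3 sessions x 1e4 frames of 3-state, 10-dimensional
  switching-AR data, cap K = 10, 200 sweeps; permutation-aligned frame
  accuracy (alignment by exhaustive injective assignment) and held-out
  log-likelihood improvement.
* Tracker recovery at 2 mm noise and 1% dropout: mean center error on a
  roaming session and mean speed on a planted 90 mm/s translation.
* JSD against an independent KL-decomposition oracle.

# Known limitations

* The tracker assumes a single animal well approximated by one Gaussian;
  it will not handle multi-animal scenes or severe occlusion.
* The weak-limit sampler targets the posterior of a *finite* sticky
  AR-HMM; it does not integrate over the state cap as the full
  nonparametric model would.
* Flip correction is self-supervised from each run's own data; on animals
  with genuinely symmetric depth silhouettes orientation is unidentifiable
  and only temporal consistency is guaranteed.
* Synthetic validation covers algorithmic correctness and calibration, not
  the idiosyncrasies of real depth video (reflections, size variation,
  limb articulation).
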