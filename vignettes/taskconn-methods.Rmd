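---
title: "Models and methods behind taskconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind taskconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taskconn)
```

`taskconn` implements an end-to-end analysis chain for event-related
task fMRI studies of group differences and brain-behavior coupling:
sparse-sampling paradigm generation, synthetic BOLD simulation with
planted ground truth, volume despiking and motion QC, single-subject
GLMs with AR(1) prewhitening, Monte Carlo cluster-extent correction,
generalized psychophysiological interaction (gPPI) connectivity, and
multivariate prediction with permutation inference. This vignette
explains the models, the defaults, and the reasoning behind the design
choices that were genuinely open.

## The sparse-sampling paradigm

The design emulates an auditory study in a pediatric clinical
population: brief vocal stimuli presented in the silent gap of a sparse
acquisition so that scanner noise never overlaps the sounds. The TR is
an exact sum of its parts,

$$\mathrm{TR} = 956 + 300 + 2000 + 300 + 20 = 3576\ \mathrm{ms},$$

a 956 ms stimulus flanked by 300 ms silent buffers, a 2000 ms
compressed volume acquisition, and a 20 ms timing pad. The total silent
period between successive stimuli is therefore
$\mathrm{TR} - 956 = 2620$ ms. Events are locked to TR slots — one
stimulus per TR, no jitter — so every onset is an integer multiple of
3.576 s. A session has 10 runs of 67 volumes (4 min); across the
session each of the three conditions (mother's voice, unfamiliar
voices, environmental sounds) contributes 48 exemplars, i.e. 4–5 per
run, plus 3 catch trials per run that keep a child engaged but carry no
planted activation. The generator takes all of these counts as
parameters because the practical run composition of such designs varies;
the defaults above are the conditions every downstream default assumes.

## The generative BOLD model

For ROI $r$ the latent neural signal at microtime resolution (16 bins
per TR) is

$$ n_r(t) = \sum_c \beta_{rc}\,\psi_c(t)
          + \varepsilon_r(t)
          + \sum_c \sum_s m_c[s,r]\,\psi_c(t)\,z_s(t), $$

where $\psi_c$ is condition $c$'s stimulus boxcar, $\beta_{rc}$ the
planted activation amplitude, $\varepsilon_r$ an intrinsic neural
fluctuation, and $m_c[s,r]$ the condition-specific coupling from seed
$s$ to target $r$ acting on the seed's first-order activity
$z_s = \sum_c \beta_{sc}\psi_c + \varepsilon_s$. The observed series is
the HRF-convolved neural signal sampled at the TR plus a constant
offset, a linear-plus-sinusoidal low-frequency drift, and AR(1)
observation noise — the minimal noise model that the analysis stage
assumes (a first-order autoregressive process plus drift removable by a
high-pass filter).

Two numerical choices deserve comment:

* **Intrinsic activity lives at the acquisition timescale.** The
  intrinsic fluctuation $\varepsilon_r$ is an AR(1) process sampled per
  TR (correlation time 2 s, SD `neural_sd`, default 0.35) and held
  constant within a TR. Fluctuations faster than the sampling bandwidth
  would be unidentifiable from TR-sampled BOLD, so generating them would
  only add unexplainable variance. The intrinsic term is what makes
  condition-specific coupling identifiable at all: with purely
  task-driven seed activity, $\psi_c \cdot z_s$ is collinear with the
  task regressors.
* **HRF scaling.** The canonical double-gamma HRF (peak 6 s, undershoot
  16 s, unit dispersions, undershoot ratio 1/6) is normalized so that a
  1 s block of unit neural activity evokes a unit-peak response. A
  planted $\beta = 1$ therefore produces an event response of about one
  signal unit against an observation noise SD of 0.5 — a
  percent-signal-like scale.

Volumetric simulation spreads each ROI's noiseless BOLD as a Gaussian
blob (SD = ROI radius) at its MNI coordinates inside a 2 mm isotropic
mask and adds spatially independent noise; it exists to exercise the
whole-brain GLM, ROI extraction, and cluster correction paths.

### Cohorts, groups, and behavior scores

A cohort couples everything to known ground truth. Each subject draws a
scale factor $s_i \sim N(1, \texttt{subject\_sd})$ applied to the
planted effects (between-subject heterogeneity); subjects in the ASD
group additionally have every planted activation and coupling entry
shrunk toward zero by the group effect. The behavior score is

$$ \mathrm{score}_i = \mathrm{round}(a + b\,f_i + e_i), \quad
   e_i \sim N(0, \sigma_e), $$

clamped to the integer range [2, 20], where $f_i$ is the subject's mean
absolute planted coupling. With $b < 0$, stronger coupling means a
lower (better) social-communication score, matching the convention of
clinician-rated severity scales. Per-subject seeds derive
deterministically from the cohort seed, so a cohort is bit-reproducible.

### What the generator does and does not emulate

The generator reproduces the design timing, condition-dependent
activation, condition-modulated coupling of the gPPI generative form,
group differences, behavior coupling, AR(1)-plus-drift noise, and
motion/global-signal artifacts. It does **not** emulate spatial
normalization error, intrinsic spatial autocorrelation of physiological
noise, non-spherical hemodynamic variability across regions, or any
acoustic property of the stimuli. Passing recovery tests therefore
demonstrates that the analysis chain is correct and well calibrated
under its own assumptions — not that effects of this size are
detectable in real pediatric fMRI.

## Despiking and quality control

Scan-to-scan displacement is the Euclidean norm of the difference of
successive (x, y, z) translations; rotations are out of scope because
the motion criteria are stated in translational mm. A volume is
repaired when displacement exceeds half an acquisition voxel
(0.5 × 3.125 = 1.5625 mm) or its global signal deviates more than 5%
from the **run median** (the robust reference; a mean-based reference
is nearly indistinguishable on clean runs but less stable when several
volumes spike). Repair is linear interpolation between the nearest
unflagged neighbors, with boundary volumes copied from the nearest
unflagged scan. A run is excluded when maximum displacement reaches
6 mm or more than 15% of volumes were repaired; a subject needs 7
passing runs.

## Single-subject GLM

Design matrices contain, per modeled condition, a stimulus-duration
boxcar convolved with the canonical HRF and with its temporal
derivative, built at microtime resolution and sampled at the TR. The
environmental-sounds condition is deliberately **not** modeled: it is
the implicit baseline, and a contrast "voices versus environmental
sounds" is realized as the voice condition's coefficient itself. Catch
trials are modeled as a nuisance condition so their evoked signal
cannot leak into condition estimates. Low-frequency drift is removed by
a per-run discrete cosine basis up to 0.5 cycles/min (cutoff period
120 s); runs are concatenated with run intercepts and one overall
constant.

Serial correlation is handled by AR(1) prewhitening: $\hat\phi$ is the
lag-1 autocorrelation of OLS residuals pooled within runs and across
series (a single global coefficient: the modeling assumption is a
first-degree autoregressive process, and pooling is far more stable
than per-voxel estimates at 67 volumes/run), the filter
$y_t - \hat\phi y_{t-1}$ (first sample scaled by
$\sqrt{1-\hat\phi^2}$) whitens data and design, and coefficients are
re-estimated. Forcing $\phi = 0$ reproduces OLS exactly, which the
tests exploit as a closed-form oracle.

Contrast weights are specified by condition name and expand to zero on
derivative, drift, and constant columns. t statistics use the whitened
covariance; ROI summaries average a contrast map over voxels whose
centers fall within the sphere radius (5 mm cortical, 2 mm
subcortical).

## Group inference and cluster-extent correction

Second-level inference consumes per-subject contrast values (the
summary-statistics approach): pooled-variance two-sample t for group
comparisons (df = n₁+n₂−2), simple-regression t on the behavior score
(df = n−2) for brain-behavior maps.

The cluster-extent threshold is estimated by Monte Carlo simulation:
each iteration fills the analysis mask with white Gaussian noise,
smooths at the nominal smoothness (6 mm FWHM; the applied smoothing
kernel — intrinsic smoothness estimation is out of scope and a known
source of divergence from any particular published figure),
re-standardizes to zero mean and unit variance in-mask, thresholds
one-tailed at voxel p < 0.005 (group maps are directional), and records
the largest face-connected cluster. Face (6-neighbor) connectivity is
the conservative classic choice. The reported extent is the smallest
size $s$ with $P(\max \ge s) \le 0.05$. On the package's MNI-shaped
2 mm mask (~200,000 voxels) at 6 mm FWHM this lands near 80 voxels;
because the threshold grows with search volume and smoothness, values
reported by any given study depend on their (often unreported) mask.
Small volume correction reruns the identical simulation restricted to
an anatomical search region, which yields strictly smaller extents and
hence sensitivity for small subcortical structures. Cluster-mean t
values convert to effect sizes as $d = t/\sqrt{N/2}$ (two-sample) and
$f = t/\sqrt{N}$ (covariate), so $f = d/\sqrt 2$.

The default is 10,000 iterations for production use; the package's own
tests and acceptance script use 1,000, which bounds the Monte Carlo
error of the 95th percentile at roughly ±3 voxels while keeping the
simulation to a few minutes on one CPU.

## gPPI connectivity

For each seed, the observed series is deconvolved to quasi-neuronal
activity, multiplied by each condition's task waveform, reconvolved
with the HRF, and entered — together with the task main effects, the
raw seed series, run intercepts, and a constant — into a least-squares
model of each target:

$$ \mathrm{target} \sim
   \sum_c \beta^{\mathrm{PPI}}_c\,
   \mathrm{conv}(\mathrm{HRF}, \psi_c \cdot \hat z_{\mathrm{seed}})
   + \text{task} + \mathrm{seed} + \text{constant}. $$

Deconvolution is ridge-regularized least-squares inversion of the HRF
convolution operator with the neural estimate parameterized at one
value per TR. This band limitation is deliberate: temporal structure
above the sampling bandwidth is unidentifiable from TR-sampled data,
and an unrestricted microtime inverse spreads energy into it, which
biases the interaction fits. With the TR parameterization, the
recoverable part of the seed's evoked response that the estimate
misrepresents is proportional to the task regressors and is absorbed by
the task main-effect columns — which is why those columns are included
by default even though the bare interaction+seed+constant form omits
them; a strict mode (`include_task_main_effects = FALSE`) is available
for comparison. The ridge weight defaults to `reg = 0.01` (relative to
the mean diagonal of the Gram matrix); recovery is insensitive to it
over two orders of magnitude because the operator is well conditioned
at TR resolution.

All three task conditions are modeled inside the gPPI GLM — including
the condition that serves as baseline in the activation GLM — because
connectivity contrasts against it are needed. A 16-node network gives
16 × 16 matrices with a masked diagonal; matrices are directional
(seed → target) and not symmetrized. Per-link univariate tests
(two-sample t or Pearson r across subjects) are corrected by
Benjamini–Hochberg FDR over all 240 links.

The package ships a synthetic 16-node network
(`default_voice_network()`, also under `inst/extdata/`) spanning
voice-selective temporal, salience, reward, affective/memory, and
fusiform regions with plausible MNI coordinates; it is simulation
plumbing, not a published coordinate table, and real analyses load
their own network from CSV.

## Multivariate prediction and permutation inference

Classification uses a linear soft-margin SVM (C = 1) on off-diagonal
connectivity features, with stratified 4-fold cross-validation repeated
100 times over random partitions; features are z-scored with
training-fold statistics only (no leakage), and the reported accuracy
is the mean over repeats. Significance comes from permuting labels and
repeating the entire procedure, with the floored estimator
$p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(1 + B)$, so the
smallest attainable p at B = 1000 is 1/1001.

Behavior prediction uses balanced 4-fold cross-validation: partitions
are redrawn until one-way ANOVAs of the dependent variable and every
feature across folds are non-significant at α = 0.05 (up to 10,000
tries, then the best partition is used with a warning). A linear model
is trained on three folds and predicts the fourth; out-of-fold
predictions are summarized as $r(\mathrm{predicted}, \mathrm{observed})$.
Ordinary least squares is the default for low-dimensional ROI features;
linear ε-SVR (C = 1, ε = 0.1) is used when features outnumber training
subjects, where OLS is degenerate. Surrogate datasets for the
permutation test permute the scores against the features with the folds
held fixed.

A confirmatory elastic-net path (`penalized_glm_confirm`, mixing 0.5,
penalty chosen by inner 3-fold cross-validation) mirrors the outer CV
of the primary analyses; since no hyperparameters are dictated by the
problem, this path is faithful by category rather than by setting.

## Validation presets and problem sizes

`default_ground_truth()` plants modest effects — planted coupling on
the order of the single-subject link-estimate noise — and produces the
weak-effect regime typical of clinical cohorts (SVC accuracies around
0.6–0.8). The recovery suite instead uses
`strong_effect_ground_truth()`, designed by power reasoning against the
measured estimation noise of the chain: planted group differences of
2.4–3.4 coupling units against a per-link SD near 1.3, coupling planted
from a single seed (so no pairwise fit carries unmodeled input from
another coupled seed), and quieter non-seed nodes (intrinsic SD 0.12 vs
0.35 for the seeds; the seed's fluctuations carry the coupling signal,
and target-side fluctuations are pure estimation noise). It is a power
check that the chain recovers strong effects, not a claim about
realistic effect sizes.

Test problem sizes are chosen to keep the full suite within a desk-scale
budget: calibration of the two permutation tests uses 200 null cohorts
of 12 subjects with a 6-node network and 39 permutations (the smallest
B at which p ≤ 0.05 is exactly attainable at rank 2/40), recovery
cohorts use the full 21 + 21 subjects and 16 nodes, and Monte Carlo
thresholds use 1,000 iterations.

## Known limitations

* Spatial structure is simplistic: blobs plus independent voxel noise,
  with no intrinsic spatial autocorrelation, so the Monte Carlo
  correction is exercised under its own assumptions only.
* The AR(1) coefficient is global per fit rather than voxel-wise.
* Deconvolution recovers only band-limited neural activity; gPPI
  coefficients for single subjects are noisy (SD ≈ 1 link unit under
  default conditions), as in real data — group-level and multivariate
  analyses are the intended consumers.
* The behavior score model is linear in a single latent brain feature;
  real severity scores are ordinal aggregates of many causes.
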