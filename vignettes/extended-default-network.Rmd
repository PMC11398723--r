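---
title: "Methods: multi-echo connectivity and the extended default network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-echo connectivity and the extended default network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ednet` is a desk-scale, fully simulatable implementation of a multi-echo
resting-state connectivity pipeline built to ask one question: do the
"limbic" parcels (orbitofrontal cortex, temporal pole, ventral anterior
temporal lobe) behave as a distinct network, or as part of an extended
default network once signal quality is good enough to tell? This vignette
documents the generative model, each analysis stage and its assumptions,
the numerical choices, and what a passing test does and does not establish.

## 1. The generative model

Each simulated parcel's signal at echo time $TE_e$ and frame $t$ is

$$S_e(p,t) = S0_p\, e^{-TE_e/T2^*_p}
  \left(1 + \frac{TE_e}{30\,\mathrm{ms}}\, c_{R2}(p,t) + c_{S0}(p,t)\right)
  + \varepsilon,$$

with $\varepsilon \sim N(0, \sigma^2)$ thermal noise. $c_{R2}$ is the
BOLD-like percent-signal series: its percent amplitude grows linearly with
TE, the defining signature of transverse-relaxation ($\Delta R2^*$)
fluctuations, expressed in percent units at the 30 ms reference echo.
$c_{S0}$ is the artifact series: TE-flat, as baseline-intensity
($\Delta S0$) changes are. This is the biophysical contrast the entire
denoising stage relies on.

**Network structure.** $c_{R2}$ is a linear mixture of latent time
courses. Under the default `latent_scheme = "subnetworks"` there is one
latent per 17-network label (15 cortical latents outside the limbic
system); latents belonging to the same coarse system (two visual, two
somatomotor + temporoparietal, two dorsal-attention, two salience, three
frontoparietal, three default subnetworks) share a group factor with
squared loading 0.3, so subnetwork latents within a system correlate at
0.3. That hierarchy is what makes the resolution parameter meaningful:
community detection at $\gamma = 1$ returns coarse systems, higher
$\gamma$ splits subnetworks. A flat `latent_scheme = "groups"` (8
independent latents: one per coarse system, with the default network kept
split in three) exists for configurations that pin exact source counts.

**The hypothesis switch.** In scenario `"merged"` each limbic parcel loads
0.6 on one of the three default-network latents — parcels are assigned
round-robin to three planted sub-clusters tied to DN_A/DN_B/DN_C — plus a
0.2 private residual. In `"distinct"` the limbic parcels instead load 0.6
on a private limbic latent. Everything downstream (community membership,
sub-cluster recovery, map contrasts) is thereby decidable against ground
truth.

**Key generator defaults and why.**

| parameter | default | rationale |
|---|---|---|
| TEs | 13.7 / 30 / 47 ms | standard 3 T multi-echo protocol |
| TR, frames | 3 s, 400 | two 10-minute runs |
| cortical loading | 0.8 | strong but sub-unit network coherence |
| limbic loading | 0.6 (+0.2 private) | recoverable yet non-trivial |
| subcortical loading | 0.5 on DN_A/DN_C/SMN/FPN latents | hippocampus/amygdala/accumbens/basal-forebrain affinity to default network |
| BOLD amplitude | 1% at TE = 30 ms | typical resting fluctuation |
| artifact amplitude | 1.2% per source, 6 sources | artifacts rival or exceed neural variance in practice |
| thermal noise | sd 3 (baseline $S0 \approx 1000$) | single-echo parcel TSNR ~60, denoised ~120 |
| S0, T2\* | ~1000 / 45 ms cortex; ~600 / 22 ms ventral-dropout parcels | susceptibility dropout: both clipped strictly below the non-dropout median |
| AR(1) coefficient | 0.3 | mild temporal smoothness |

**Laplace, not Gaussian, innovations.** Latent and artifact time courses
are AR(1) with unit-variance Laplace innovations. Gaussian sources are not
identifiable by ICA — any rotation of a Gaussian subspace is an equally
good solution — so a Gaussian world would make its own denoising stage
ill-posed. Super-Gaussian, spiky sources are also the more realistic
choice for resting BOLD and for motion/scanner artifacts.

**Subject-specific nuisance topographies.** Artifact maps (and auxiliary
BOLD maps, when requested) are redrawn per subject. Shared nuisance maps
would survive group averaging and install spurious between-network edges;
individually varying nuisance anatomy is both realistic and what keeps the
group matrix an estimate of the shared network structure.

**Motion.** Head position follows a slow random walk (per-frame step sd
0.02 mm / 0.0004 rad), keeping framewise displacement well under the 0.5 mm
threshold. A planted motion spike displaces one frame by 1 mm and
co-injects a 3% TE-flat transient plus a jolt to the BOLD latents, so
displacement and signal disruption co-occur at the same frame — the
premise of the conjunctive FD/DVARS exclusion rule (spin-history and
pulsation effects do disrupt both $S0$ and $R2^*$).

**Planted QC violations** are cohort-level switches: `fd_dvars` plants two
such spikes; `low_tsnr` inflates the BOLD amplitude 15-fold (the TSNR rule
is applied to the *denoised* reconstruction, which removes thermal noise,
so a noise-based violation would not survive denoising — an unstable,
high-fluctuation subject does); `few_components` activates only 9 BOLD
latents. Component-count contrasts are meaningful in the flat `"groups"`
scheme, where detected counts stay at least 2 away from the
fewer-than-10 boundary on both sides; in the `"subnetworks"` scheme
correlated latents make per-subject counts dip unpredictably (ICA may
merge correlated latents), so QC-exactness checks use the flat scheme.

## 2. Echo combination and TSNR

T2\* is estimated per parcel by a log-linear least-squares fit of the
time-averaged echo images (exact on noiseless mono-exponential input),
clipped to [5, 150] ms for robustness to noise at long TE. Combination
weights follow the classical TSNR-optimal rule
$w_e \propto TE_e\, e^{-TE_e/T2^*}$, normalised to sum to one; parcels
whose fit failed (non-positive echo mean) fall back to the simple average
and are logged. Weights are time-invariant and per-parcel. TSNR is the
time-series mean over its standard deviation; zero-variance series are
flagged undefined rather than infinite. The single-echo comparison uses
the second echo (30 ms), the closest analogue of a conventional
acquisition.

## 3. TE-dependence denoising

The decomposition contract is deliberately minimal: any seeded ICA that
returns temporal sources ("mixing") and spatial coefficients
reconstructing the input. `decompose()` implements symmetric fixed-point
FastICA (logcosh contrast) after PCA whitening, with seeded restarts and
the best total-negentropy solution kept; components are ordered by
variance explained and sign-fixed so the largest spatial coefficient is
positive.

`decompose_multiecho()` estimates the unmixing on the *echo-stacked*
centred data instead of the combined series. $\Delta R2^*$ sources scale
with TE across the stacked blocks while $\Delta S0$ sources are TE-flat,
so the two classes occupy nearly orthogonal spatial subspaces in stacked
space; estimating the rotation there separates weak network sources from
strong artifacts far better than the combined series allows, while the
returned coefficients still reconstruct the combined series by least
squares. The default dimension is a Marchenko–Pastur noise-floor estimate
(`mp_rank`): thermal noise is iid across stacked rows, and eigenvalues
above the bulk edge (with a Tracy–Widom-scale margin, $1 + 3T^{-2/3}$)
count as signal. A 95%-variance PCA rule is kept as `decompose()`'s
default for generic inputs but is not used on stacked data, where noise
eigenvalues would dominate the tail.

Per component and parcel, every echo's time series is regressed on the
component time course; the per-echo amplitudes are converted to percent
(divided by the echo's mean signal) and fit by two one-parameter models —
$\Delta S0$: percent amplitude constant in TE; $\Delta R2^*$: percent
amplitude $\propto TE$. $\kappa$ is the coefficient-squared-weighted mean
of the $\Delta R2^*$ F statistic over parcels; $\rho$ the same for
$\Delta S0$. A component is BOLD iff $\kappa > \rho$ (ratio configurable);
an exact tie is conservatively non-BOLD. An optional statistical guard
(`z_guard`) can require the margin to exceed a multiple of the weighted
standard error, but its default is 0: with three echoes the per-parcel F
statistics have 2 denominator degrees of freedom and are far too
heavy-tailed for the guard to be reliable.

The three outputs mirror standard multi-echo practice: component maps,
the BOLD-only back-projected time series (quality metrics are computed on
this series, with parcel means restored), and the BOLD coefficient set
(MEFC) whose column count is the degrees of freedom carried into
connectivity.

## 4. Quality control

Framewise displacement uses the 50 mm-sphere convention
($FD_t = \sum|\Delta \text{trans}| + 50\sum|\Delta \text{rot}|$); DVARS is
the parcel-RMS frame difference divided by its own run median, so a
typical frame sits near 1 and the series is scale-free. A subject is
excluded iff some frame has FD > 0.5 mm *and* DVARS > 1 at that same frame
(a run-wise reading of the conjunction is available as a config), or
median denoised TSNR < 50, or fewer than 10 retained BOLD components, or
an externally flagged coregistration failure. Note the consequence of
median standardisation: about half of all frames have DVARS > 1, so the
conjunction — not the DVARS threshold alone — carries the motion rule.

## 5. MEFC connectivity

Connectivity is the product-moment correlation of MEFC coefficient rows
across parcels (not a time-series correlation), transformed by
$Z = \operatorname{arctanh}(R)\sqrt{df-3}$ with $df$ the subject's BOLD
component count — the variance-stabilised Fisher transform, which puts
subjects with different component counts on a common scale. $|R|$ is
clipped to $1-10^{-12}$ before the transform. The diagonal is excluded
from all downstream statistics (stored as 0 and flagged). The group matrix
is the elementwise mean of subject z matrices. Coefficient correlations
over a few dozen components are noisier than time-series correlations
over hundreds of frames; group averaging, not per-subject precision, is
what makes the block structure legible — the same trade the MEFC approach
makes at full scale.

## 6. Community detection

`modularity_q` implements
$Q = \frac{1}{l}\sum_{ij}\left(w_{ij} - \gamma \frac{k_i k_j}{l}\right)
\delta(m_i, m_j)$ with $l$ the total weight and $\gamma$ multiplying the
null term (the standard generalised form; at $\gamma = 1$ the one-module
partition scores exactly 0). `louvain` is the greedy two-phase algorithm
with a warm start: sweeps in seeded random order, ties to the lowest
module id, aggregation between phases, and seeded restarts (alternating
singleton and random coarse initialisations when no warm start is given)
with the best-Q partition returned — output Q never falls below the warm
start's Q. Warm starts matter scientifically: initialising from 7-network
labels with the limbic module separate asks whether the data *pull*
limbic parcels into the default network against their prior assignment.

Negative z edges are thresholded to zero for both algorithms: random-walk
semantics require nonnegative weights, and a shared convention keeps the
two algorithms comparable. The map equation is the two-level codelength
$L = q\,H(\text{exit}) + \sum_m (p_m + q_m) H(\text{module}_m)$ with
degree-proportional visit rates; a single-module partition reduces to the
entropy of the visit distribution, and the codelength is invariant to
rescaling all weights. `infomap_partition` minimises $L$ by seeded local
moves plus greedy module merges and never returns anything worse than the
one-module partition. On dense weighted group matrices the two-level map
equation legitimately prefers very coarse partitions (its known
field-of-view behaviour); conclusions should rest on the majority
assignment, not the module count. Disconnected graphs are computed per
component with a warning, degree-proportional rates remaining stationary.

## 7. Limbic subnetwork clustering

For limbic parcels $a, b$ with whole-brain connectivity profiles the
similarity is
$\eta^2 = 1 - \frac{\sum_p (a_p - m_p)^2 + (b_p - m_p)^2}
{\sum_p (a_p - M)^2 + (b_p - M)^2}$ with $m_p$ the pointwise mean and $M$
the grand mean — the standard profile-similarity definition in
connectivity parcellation, bounded in [0, 1]. Self-connection columns stay
in the profiles (as zeros, by the diagonal convention). Per-subject
similarity matrices are averaged into the group matrix; clustering
operates on the group matrix's rows as feature vectors. Ward's method runs
via Lance–Williams updates (`stats::hclust`, `ward.D`, squared Euclidean
distances); reported merge heights are halved so they equal the
error-sum-of-squares increase of each merge, and they are nondecreasing.
Ward is greedy: its cuts are checked against brute-force minimal-ESS
bipartitions in the tests, but exact optimality is not asserted. No
automatic cluster count is applied — `cut_dendrogram` takes an explicit
`k` and reports the merge-height gap at every candidate so the choice is
visible rather than silent.

## 8. Statistical maps

One-sample maps are parcel-wise $t = \bar{z}/(s/\sqrt{n})$ with two-sided
p from the t distribution on $n-1$ df; paired contrasts are one-sample
maps of differences. A zero-variance parcel is flagged undefined and
excluded from masks; its t is reported as 0 when the mean is also 0
(identical paired inputs give t = 0 everywhere) and NA otherwise. The
Bonferroni mask is exactly $\{p < \alpha / n_{\text{comparisons}}\}$; the
correction denominator is a parameter so a full-scale 1,032-parcel
convention can be matched regardless of the toy parcel count. The top-10%
mask keeps round-half-away-from-zero of $fraction \times n$ parcels by
absolute value, ties broken by parcel id, so the count is deterministic
(103 of 1,032 at 10%). Network profiles average z per 17-network label
and per subcortical structure; contrasts at that level are paired t tests
per label.

## 9. What the tests establish — and what they do not

The generator emulates: TE-dependent vs TE-flat fluctuation classes,
susceptibility dropout (short T2\*, low S0) in ventral parcels, hierarchic
network structure with a switchable limbic hypothesis, planted limbic
sub-clusters, motion spikes with matched signal transients, and planted QC
violations. It does **not** emulate hemodynamic response shapes, spatial
autocorrelation or surface geometry (parcels are exchangeable units),
cardiac/respiratory waveforms, scanner drifts, multi-site effects, or
individual differences in functional topography. A green suite therefore
establishes that the pipeline's logic is faithful and that each stage
recovers what was planted at realistic signal levels — not that the
scientific conclusion holds in any real dataset.

Numerical conventions collected in one place: T2\* clips [5, 150] ms;
$|R|$ clip $1-10^{-12}$; negative-edge thresholding at 0; Louvain ties to
the lowest module id; ICA seeds fix restarts, sweep orders and sign
conventions; round-half-away-from-zero for the top-fraction count;
diagonal excluded everywhere; the Fisher variance-stabilising factor
$\sqrt{df-3}$ requires $df \ge 4$.

Known limitations: the ICA stand-in is a plain FastICA, not a full
decision-tree multi-echo pipeline (no mid-κ categories, no adaptive
masks); per-subject component separation occasionally merges correlated
latents, which is why component-count QC contrasts use the flat latent
scheme; the two-level map equation's coarse preference is inherited, not
corrected; and NIfTI volume I/O is out of scope — fixtures are TSV/JSON.
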