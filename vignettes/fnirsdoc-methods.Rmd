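---
title: "Methods: resting-state fNIRS connectivity analysis for disorders of consciousness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state fNIRS connectivity analysis for disorders of consciousness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`fnirsdoc` implements a resting-state functional near-infrared spectroscopy
(rs-fNIRS) analysis chain for assessing residual consciousness in patients
with disorders of consciousness (DOC): raw dual-wavelength intensity is
converted to hemoglobin concentration changes, denoised and
quality-controlled; whole-head Pearson functional connectivity (FC) is
summarized regionally and as sparsity-thresholded binary brain networks;
group differences and a leave-one-out classification of minimally conscious
state (MCS) versus unresponsive wakefulness syndrome (UWS) close the chain.
Because clinical recordings of this population are not publicly available,
the package ships a synthetic cohort generator with analytically known
ground truth; every stage is tested against it.

# The processing model, stage by stage

## Hemodynamic conversion

The montage has 48 channels (24 sources, 16 detectors, 3 cm separation)
over six regions — left/right prefrontal, motor and occipital cortex; two
channels (20 and 43) sit on region boundaries and are counted in both of
their regions.  Light at 730 and 850 nm gives an optical-density change
per channel, `dOD(t) = -log10(I(t)/I0)`, with the baseline `I0` taken as
the temporal mean of each channel/wavelength series (the choice is a gauge:
FC is invariant to it).  The modified Beer-Lambert law then gives relative
concentration changes,

$$\Delta OD(\lambda) = \big[\varepsilon_{HbO}(\lambda)\,\Delta HbO +
  \varepsilon_{HbR}(\lambda)\,\Delta HbR\big]\, DPF(\lambda)\, L ,$$

solved per sample as a 2-by-2 linear system; `HbT = HbO + HbR` holds
exactly and is preserved by every later stage.  Extinction coefficients
for 730/850 nm and a differential pathlength factor of 6.0 are shipped as
documented defaults and are overridable; since all downstream statistics
are correlation-based, they are invariant to this linear calibration.
Analysis focuses on HbT, the proxy for regional cerebral blood volume.

## Denoising

A third-order Butterworth band-pass (0.01 to 0.1 Hz), applied
forward-backward for zero phase with odd-reflection padding, isolates the
spontaneous hemodynamic band and rejects cardiac (0.8 to 1.6 Hz),
respiratory (0.2 to 0.6 Hz) and Mayer-wave (about 0.1 Hz) oscillations.
Motion and superficial systemic contamination are then reduced by
principal-component filtering across channels (per chromophore, default
one component removed, or a target variance fraction); global components
load on it, distributed cortical covariance largely does not.  Finally the
most stable contiguous 5-minute segment is selected by minimizing the
across-channel energy of the first difference of HbT (ties break to the
earliest offset), which avoids windows containing residual motion
transients.

## Channel quality control

Before any band-pass (the cardiac band must be intact), each channel is
screened by three rules and flagged bad if it fails any: (1) its maximum
Pearson correlation with the other channels, computed on unfiltered HbT,
is 0 or less; (2) the raw-intensity SNR (temporal mean over temporal SD,
minimum across the two wavelengths) is below 2; (3) the cardiac component
is absent — the Welch-periodogram power fraction of the 850 nm intensity
in 0.8 to 1.6 Hz is below 0.05 *and* no local spectral peak stands out in
that band (peak = in-band maximum exceeding 5 times the median power above
0.5 Hz).  Pruned channels are dropped, never interpolated; region means
and networks renormalize over the survivors, and a region losing all but
one channel reports a missing value rather than zero.

## Connectivity and networks

Pearson correlation between the HbT segments of every active channel pair
gives a 48-by-48 FC matrix per subject.  Region summaries average the
within-region off-diagonal entries over pairs whose both channels survive
QC (raw r, no Fisher transform — an optional flag exists but the default
matches the classical procedure).  Group-level maps average entrywise over
the subjects where both channels are active, and suprathreshold edges
(group-mean r > 0.35) are exported as plain-text `.node`/`.edge` files.

For graph analysis each FC matrix is binarized over a sparsity grid (0.05
to 0.80, step 0.05): at sparsity `s` the `round(s * N(N-1)/2)` largest
correlations (signed r; the ranking rule is configurable) become edges, so
all subjects' networks have equal edge counts.  Rounding is half-up and
rank ties break lexicographically, making the edge set bit-reproducible.
Four global metrics are computed at every grid point:

- characteristic path length `Lp`: mean shortest-path length over ordered
  pairs.  Disconnected pairs are excluded from the mean (connected-pairs
  convention) and their count is reported; this keeps `Lp` finite at the
  low-sparsity end of the grid, where the thresholded graphs are routinely
  disconnected and the bare formula would be undefined.
- clustering coefficient `Cp`: mean over nodes of
  `E_i / (D_i (D_i - 1)/2)`, zero for degree < 2.
- global efficiency `Eg`: mean of `1/d_ij` with `1/Inf = 0`.
- local efficiency `Eloc`: mean over nodes of the global efficiency of the
  subgraph induced by each node's neighbors.

Shortest paths come from breadth-first expansion (iterated boolean matrix
products); the implementation is verified exactly against Floyd-Warshall
and exhaustive triangle/neighborhood enumeration on random graphs, and
against igraph.  Each metric's curve is summarized by its trapezoidal area
under the curve (AUC) over the grid; for the default grid a constant curve
`m` gives `0.75 m`.  The trapezoid rule (rather than step-sum) is recorded
in the output metadata.

## Group statistics and classification

Each subject yields ten features: six region means and four metric AUCs.
Groups are compared feature-wise by two-sample t-tests (pooled-variance
Student's by default, Welch selectable) with Cohen's d on the pooled SD;
constant samples follow an explicit contract (equal means: t = 0, p = 1;
unequal: infinite t, p = 0).  No multiple-comparison correction is applied
by default, matching the classical report style; a Benjamini-Hochberg
option exists and the output notes which was used.

Classification uses KNN (k = 3, Euclidean) and linear discriminant
analysis under leave-one-out cross-validation, with MCS as the positive
class.  Features are z-scored with means/SDs fit inside each training fold
only — the held-out subject never influences its own fold's scaling, which
a leakage probe in the test suite verifies.  KNN breaks distance ties by
the lower training index and (for even k) vote ties by the nearest
neighbor; LDA uses empirical priors and adds a small documented ridge only
if the pooled covariance is singular.  Because every rule is
deterministic, the averaged "20 repetitions" of the classical protocol
collapse to a single run; the repetition loop exists (with a seed list)
so stochastic variants remain supported, and with the default rules all
repeats coincide by construction.  Six predefined feature sets mirror the
classical comparison: all four graph metrics; all six region means; their
union; the two metrics that separate the groups (`Eg`, `Lp`); the one
separating region (`L_OC`); and the hybrid of those last two.

## CRS-R scoring

The Coma Recovery Scale-Revised parser reads the compact
`"total(d1d2d3d4d5d6)"` notation (auditory, visual, motor, oromotor,
communication, arousal), validates each subscale range and the digit sum,
and applies the diagnostic rule: MCS if any of auditory 3-4, visual 2-5,
motor 3-6, oromotor 3, communication 1-3; VS/UWS if all of auditory <= 2,
visual <= 1, motor <= 2, oromotor <= 2, communication 0.  The
communication subscale is stored with range 0-3 because the rule's printed
upper bound (3) exceeds the scale's nominal maximum (2); both conventions
parse.  Over all valid subscore combinations exactly one diagnosis fires
(verified by enumeration).  Applied to the bundled 18-patient example
table, the rule disagrees with the recorded diagnosis for the four
patients with visual = 2 recorded as UWS; the report surfaces this
`agreement` flag and deliberately does not "correct" either side.

# The synthetic cohort generator

## What it emulates

`generate_cohort()` draws two groups (default 8 "MCS-like", 10
"UWS-like") of 20-minute, 48-channel, 11 Hz dual-wavelength recordings.
Per subject the HbT signal is a sum of:

- a **latent cortical component** with a known cross-channel correlation
  structure (below), band-limited to 0.4 Hz — slow enough to look
  hemodynamic, broad enough that a 5-minute segment resolves the
  correlation structure;
- **physiological oscillations** with a shared per-subject phase: cardiac
  (about 1 Hz, per-channel gain jitter), respiration (0.2 to 0.6 Hz) and
  Mayer waves (about 0.1 Hz);
- a **global systemic fluctuation** (slow, common to all channels),
  emulating superficial/extracerebral contamination — this is the
  component PCA correction is meant to remove, and without it the first
  principal component would be cortical signal rather than artifact;
- per-channel **random-walk drift** and **white sensor noise**;
- optional **motion transients** (Poisson boxcar steps on random
  channels) and **planted bad channels**: `low_snr` inflates a channel's
  white noise until the intensity SNR drops below 2, `no_cardiac` omits
  its cardiac oscillation, and `anticorrelated` replaces it by the
  negative of the mean good-channel signal — each defect trips exactly
  one QC rule.

Concentrations are split into HbO/HbR (7:3 plus a small opposing
component that cancels in the sum) and pushed through the forward optical
model to strictly positive intensities, so the cohort enters the pipeline
at the same point real data would.  A fixed seed makes cohorts
bit-identical; the ground-truth object records labels, per-subject
coupling graphs, densities, planted defects and injected transients.

## The latent coupling model

The generator's scientific core is the latent correlation matrix.  All
channel pairs share a short-range background that decays exponentially
with distance along the montage chain (peak 0.6 relative to the coupling
strength, decay length 2 channels) — the ubiquitous distance-dependence
of cortical FC.  On top of it, a small set of connector "hub" channels
(default `n/8`, randomly placed) carries the coupling graph: every pair
involving a hub is coupled independently with the group's density, and
coupled pairs are lifted to a high correlation.  High-degree hubs pull
the whole montage within two network steps, so integration — global
efficiency, short path lengths — scales with the density of the hub
coupling graph.  This mirrors the connector-hub (mesocircuit) account of
impaired consciousness, in which awareness loss tracks the thinning of
long-range relay coupling.  A global correlation gain rising with density
(`0.6 + 0.4 * density`) additionally makes the integrated group's FC
uniformly stronger, as observed clinically; being a uniform off-diagonal
scale it leaves each subject's edge ranking, and hence network topology,
unchanged.  The matrix is made positive definite by flooring its
eigenvalues and renormalizing the diagonal; coupled entries are targeted
at 0.65 of the coupling strength, which keeps the hub-star geometry close
to Gram-consistent so this repair barely moves the targets.  Per-subject
density jitter (SD 0.08) models inter-subject heterogeneity and keeps
group effect sizes finite.

`latent_to_hbt()` exposes a simpler, fully closed-form mixing model used
for unit testing: `Sigma = I + c_eff A` with
`c_eff = c / max(1, -lambda_min(A))`, so an isolated coupled pair has
population correlation exactly `c`, uncoupled pairs exactly 0, and a
complete graph approaches perfect correlation as `c -> 1`.

## A design lesson recorded deliberately

Several natural-seeming latent designs — coupled cliques whose size grows
with density, modular graphs with denser between-module wiring,
small-world shortcut lifts — plant **no** usable global-efficiency
separation, or invert it.  The reason is structural: at a fixed edge
count, the group with less genuine structure fills its sparsity budget
with effectively random edges, and on a 48-node graph random edges are
the most integrating structure there is (almost any graph with a modest
random part has diameter about 2 beyond sparsity 0.2).  The only
low-budget structure that beats random fill-in is a radial hub: a few
high-degree nodes put every pair within two steps.  That is why the
generator plants integration as hub degree, not as cluster size, and why
the group contrast lives mostly at the sparse end of the grid.

## Which features of real data it does not have

The generator has no hemodynamic response function, no biophysical head
model or photon-transport forward simulation, no heart-rate variability,
no shared genetics of noise across wavelengths beyond the linear optical
model, and its "anatomy" is a one-dimensional chain rather than a scalp
geometry.  Passing tests demonstrate that the pipeline recovers planted
covariance structure, flags planted defects, and is statistically
calibrated — not that it would classify real patients at any particular
accuracy.

# Study conditions used by the verification suite

Two documented conditions are exercised:

- the **default condition** (all confounds at default amplitude, 20-min
  recordings) drives the end-to-end pipeline tests and the full-pipeline
  run of the acceptance script;
- the **confound-free condition** (all confound amplitudes zero except
  white noise 0.3 uM, 6-minute recordings, features computed as
  MBLL -> FC -> metrics without band-pass or PCA) drives the replicate
  statistics: with the 0.01-0.1 Hz band and a 5-minute segment, each
  correlation rests on roughly fifty effective samples, which compresses
  *any* planted ordering toward that of a random matrix; the clean
  condition is where the planted contrast is identifiable at replicate
  scale.  The 6-minute length was calibrated (on cohorts disjoint from
  the verification seeds) so that the planted global-efficiency effect
  sits in the d-of-about-1.2 regime: at this condition the measured
  effect is d approximately 1.2, the group-mean direction reproduces in
  over 95% of cohorts, two-sample detection lands near 63% at
  n = 8 vs 10 (the theoretical power of a t-test at that effect size),
  the path-length effect is stronger and opposite in sign, and the
  left-occipital region mean separates at d near 1.5.  Replicate counts
  (2000 null replicates for type-I calibration at the latent stage; 200
  cohorts for detection; 50 for the classifier comparison; 100 for QC
  screening) are the package's chosen verification sizes.

One asymmetry against the clinical report is deliberate: the generator's
left-occipital contrast has the MCS-like group higher, whereas the
clinical observation was the reverse; the pipeline is direction-agnostic
(two-tailed tests, standardized classifiers), so only the magnitude
matters for verification.

# Numerical choices and edge cases

- Half-up rounding of edge counts; lexicographic tie-break on equal
  correlations; earliest-offset tie-break on equal segment scores.
- `Lp` on an empty graph is missing; `Eg` of an empty graph is 0; node
  terms of `Cp`/`Eloc` are 0 below degree 2.
- Zero-variance channels make correlations undefined: flagged missing
  with a warning, then treated as inactive.
- The band-pass uses odd-reflection padding (3 cycles of the low cutoff)
  to suppress end transients at 0.01 Hz.
- PCA correction operates on HbO and HbR and recomputes HbT, preserving
  additivity exactly.
- All randomness flows from explicit integer seeds; identical
  configuration and seed give bit-identical cohorts and pipeline outputs.

# Limitations

Real patient recordings for this clinical population are not distributable
and none ship with the package, so no claim about clinical accuracy is
made or tested.  The full-noise pipeline compresses planted group
contrasts (see above), which is a faithful property of the 5-min/0.01-0.1
Hz design itself, not an implementation artifact.  Short-separation
regression and spline/wavelet motion correction are out of scope, as are
weighted networks, nodal centralities and dynamic (sliding-window)
connectivity.
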