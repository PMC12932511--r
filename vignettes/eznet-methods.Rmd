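---
title: "Network topology of the epileptogenic zone: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network topology of the epileptogenic zone: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eznet)
```

## The problem

In drug-resistant epilepsy, surgical outcome depends on delineating the
epileptogenic zone (EZ) — the tissue whose removal or disconnection is
necessary and sufficient for seizure freedom. Clinical localization combines
scalp EEG (global coverage, poor spatial resolution) with stereo-EEG (SEEG;
precise but spatially sparse depth recordings). `eznet` implements a
quantitative localization pipeline on top of both modalities: multichannel
epochs are decomposed into seven frequency bands, converted into binary
functional networks by thresholding Pearson correlations, summarized by four
nodal graph metrics, and the EZ/NEZ contrast is assessed with paired
nonparametric statistics and patient-grouped machine-learning validation.
Scalp recordings are first source-imaged (sLORETA) onto a parcellation so
that network nodes are cortical regions rather than electrodes.

The package ships a synthetic cohort generator with known EZ labels, so the
entire chain is testable without clinical recordings.

## Signal conditioning

Seven analysis bands: full band, delta (0.5–4 Hz), theta (4–8), alpha
(8–13), beta (13–30), gamma (30–80) and a high-frequency band starting at
80 Hz. The HF (and full-band) upper edge is `min(300, 0.45 * fs)` — 300 Hz
at the 2 kHz SEEG rate, 225 Hz at the 500 Hz scalp rate — so the band always
sits inside the representable range.

Filters are 4th-order Butterworth band-passes applied with zero net phase,
which matters because downstream connectivity is *zero-lag* Pearson
correlation: any phase distortion would bias it. Two numerical choices
deviate from the naive textbook implementation and are deliberate:

* **Biquad factorization.** The expanded polynomial (b, a) form of a narrow
  band-pass (delta at 2 kHz has all 8 poles within ~0.01 of `z = 1`) is
  numerically unstable in double precision; the design is kept in zero-pole
  form and applied as a cascade of second-order sections.
* **Spectral application (default).** Forward–backward filtering has the
  real, non-negative frequency response `|H(w)|^2`. The default `"fft"`
  method multiplies the epoch spectrum by that response directly — the exact
  steady-state zero-phase response, with circular boundary conditions
  instead of startup transients. For the narrow low-frequency bands the
  time-domain transient would otherwise stretch over seconds of a 10 s
  epoch and contaminate variance normalization. `method = "sos"` provides
  the conventional time-domain path; the two agree away from the epoch
  edges.

The mains notch (50 Hz, 2 Hz stop band, all harmonics below Nyquist) is
available for recorded data; simulated cohorts contain no line noise, so the
pipeline skips it by default. Artifact rejection (ICA, visual bad-channel
marking) is a clinician-dependent step outside the package's scope; the
conditioning functions are a pass-through point where such cleaning can be
inserted before network construction.

## Source imaging

Scalp potentials follow the linear forward model `phi = K J + c 1`, with
`K` the lead field and `c` an arbitrary reference constant. The package
solves the inverse problem in three steps:

1. **Forward model.** A concentric multi-shell spherical conductor (default
   three shells: brain/skull/scalp radii 0.87/0.92/1.0, conductivities
   0.33/0.0042/0.33 S/m). The dipole potential is expanded in spherical
   harmonics and the per-degree radial boundary-value problem (continuity of
   potential and radial current at each interface, zero current at the
   scalp) is solved numerically for any number of layers. This avoids
   transcription errors in memorized closed forms; the tests verify the
   expansion against the closed-form infinite-medium dipole potential and
   the homogeneous-sphere limit. A realistic BEM head model with individual
   anatomy is out of scope by design — the spherical model preserves the
   structure of the inverse problem, which is what the analysis depends on.
2. **Minimum-norm estimate.** `J = K' (K K' + alpha H)^+ H phi`, where `H`
   is the average-reference centering projector (this is what absorbs `c`;
   estimates are invariant to adding any constant to `phi`). The
   regularization default is `alpha = 1e-6 * mean(diag(K K'))`; the original
   analysis does not state its value, and at this near-noiseless setting the
   localization property below is exact while the solve stays
   well-conditioned.
3. **sLORETA standardization.** Each source's 3-vector estimate is scaled by
   the inverse of its 3×3 resolution-based variance block
   `[K'(K K' + alpha H)^+ K]_ll`. The defining property — the standardized
   power of a noiseless single dipole peaks exactly at the true source — is
   asserted in the tests over random dipoles and is the package's main
   correctness check for this stage.

Region time series are the mean over member sources of the square root of
standardized power (a magnitude; averaging signed components would cancel
across arbitrary dipole orientations). The parcellation is generic and
configurable, defaulting to 148 regions (74 per hemisphere by symmetric
construction); real atlas geometry is not reproduced, and EZ region labels
are supplied by the user or the simulator.

## Networks and nodal metrics

Connectivity is the Pearson correlation between all channel (or region)
pairs within a banded epoch. Binary undirected networks keep edges with
`|r| >= T`, default `T = 0.7`, with a sweep utility over {0.6, 0.7, 0.8}
for sensitivity analyses. Thresholding by magnitude (rather than signed
value) treats strong anticorrelations as couplings; a `signed` option
implements the alternative reading. Zero-variance channels become isolated
nodes rather than errors so node indexing stays aligned with clinical
labels.

Four nodal metrics are computed on the whole network before EZ/NEZ labels
are applied (so class sizes cannot bias them):

* node degree `nd_i = sum_j a_ij`;
* clustering coefficient `c_i = 2 e_i / (k_i (k_i - 1))`;
* local efficiency: mean inverse geodesic among the neighbours of `i`,
  measured in the subgraph induced by those neighbours, unreachable pairs
  contributing zero — the per-node quantity (the network average is a
  trivial summary of it);
* betweenness centrality by Brandes' algorithm over unordered pairs,
  unnormalized by default (within-sample EZ-vs-NEZ contrasts cancel the
  normalization constant; a flag divides by `(N-1)(N-2)/2`).

With seven bands this yields the 28-column `{band}_{metric}` feature table.
All four metrics are validated against exhaustive brute-force oracles
(Floyd–Warshall + path enumeration) and, where available, igraph.

The sub-network density analysis partitions nodes into EZ and NEZ modules
and reports internal densities `d_ez`, `d_nez` (edges / C(n,2)) and the
interaction density `d_cross` (edges / n_ez n_nez). Modules with fewer than
two nodes yield `NA`, not zero.

## Statistics

Comparisons are paired within sample: for each epoch the nodal values are
aggregated (mean by default; median by option) over EZ nodes and over NEZ
nodes, and the per-sample pairs enter a two-sided Wilcoxon signed-rank
test. Zero differences are dropped (Wilcoxon's convention); fewer than five
informative pairs yields a flagged undefined result. For up to 25
informative pairs the null distribution of the rank sum is computed exactly
by convolution over the realized ranks — identical to enumerating all `2^n`
sign assignments, and valid under ties, which thresholded network metrics
produce routinely (this is why `stats::wilcox.test`, exact only for untied
data, is a cross-check rather than the implementation). Above 25 pairs a
normal approximation with continuity and tie correction takes over.
Benjamini–Hochberg correction is applied within one modality × state family
of 28 band × metric tests (each results table is corrected together; the
ictal-vs-interictal density family is 3 densities × 7 bands).

## Classifier validation

Nodal features are validated as EZ biomarkers with five classifiers — SVM
(RBF), random forest, gradient boosting, k-NN and ridge logistic
regression — under a nested, patient-grouped protocol: outer Group 5-fold
over patient identifiers (no patient ever spans a train/test boundary),
inner grouped 3-fold grid search selecting the hyperparameters with the
highest mean inner AUC. Grids follow the study protocol where stated (SVM
C ∈ {0.1, 1, 10}; RF trees ∈ {50, 100, 200} × depth {unlimited, 10, 20};
k ∈ {3, 5, 7, 9, 11}); the boosting grid (rounds × learning rate
{0.05, 0.1}) and the LR inverse penalty C ∈ {0.1, 1, 10} (mapped to ridge
`lambda = 1/(C n)`) are documented assumptions where the protocol gives
only examples. Classes are balanced 1:1 beforehand by seeded random
undersampling of the majority class, allocated proportionally across
patients so the group structure survives.

Preprocessing is fitted strictly on training rows: `log(1+x)` (degree and
betweenness can be exactly zero) deflates the heavy right tail of the
count-like metrics, then Z-scoring with training means and SDs. The Z step
applies only to the scale-sensitive models (SVM, k-NN, LR); trees keep the
original feature space. Test-fold scores are pooled over outer folds before
computing AUC (rank statistic, ties counted half) and the threshold-0.5
confusion metrics; per-fold averaging is available by recomputing from the
per-fold audit stored in every report.

SVM scores are `plogis` of the decision value rather than Platt-scaled
probabilities: libsvm's internal Platt cross-validation draws from a C
library RNG outside R's control and would break the package's
identical-seed ⇒ identical-report guarantee. The 0.5 threshold coincides
with the SVM decision boundary, so confusion metrics are unaffected.

Significance of an observed AUC is assessed by permutation: labels are
reshuffled across the pooled table (the study protocol states global
shuffling), the full nested CV is re-run per draw, and
`p = (1 + #{null >= observed}) / (1 + n_perm)` with `n_perm = 1000` by
default — the add-one form can never return zero.

## The synthetic generator

`simulate_seeg()` emulates the statistical structure the analysis assumes,
not the biophysics of seizures:

* Each channel is a weighted mixture of band-limited latent sources (white
  noise filtered into each band, the same filters as the analysis path)
  plus independent band-limited noise (`noise_sd = 0.45` per band).
* NEZ channels share a strong community source (`c_intra_nez = 0.9`); EZ
  channels share a weaker one (`c_intra_ez = 0.55`); each community leaks
  into the other with the smallest weight (`c_cross = 0.2`). After
  thresholding this produces the isolated-EZ phenotype: a sparse EZ block,
  a dense NEZ block, and near-empty cross-module connectivity, with
  `d_cross < d_ez < d_nez` in every band.
* Per-channel log-normal coupling jitter (CV 0.3) represents
  electrode–tissue variability; it spreads pairwise correlations around
  their expected value so that edge densities respond smoothly to the
  couplings instead of saturating at 0 or 1 (wide-band sample correlations
  are otherwise nearly deterministic over a 10 s epoch).
* A per-patient log-normal gain multiplies all couplings — CV 0.4 for SEEG,
  0.16 for scalp, the inter-patient heterogeneity that motivates the log+Z
  transform. Its positive skew is why the log matters.
* The ictal state multiplies beta/gamma/HF couplings by 2.0, boosts the
  EZ-internal delta coupling by 1.8 (slow-wave resonance confined to the
  EZ), and adds a shared hypersynchrony source (weight 1.5) in
  beta/gamma/HF. The shared source is a deliberate modelling choice: a
  purely multiplicative surge rescales every latent weight equally, and
  correlation coefficients are invariant to common rescaling, so no surge
  factor alone can push cross-community correlations past the 0.7 threshold
  once the interictal EZ is sparse. Seizure-like breakthrough of the
  EZ–NEZ "fence" therefore needs a genuinely shared ictal component, which
  is also the physiologically natural reading of global hypersynchrony.
* SEEG cohorts draw channel counts from N(113, 20²) (truncated at 40) and
  EZ contact counts uniformly from 8–30 per patient. The source analysis
  fixes EZ label counts only in region space (5–31); contact-level counts
  are not reported anywhere, so the 8–30 default is a documented
  assumption.

`simulate_scalp()` places a shared high-amplitude delta/theta driver
(amplitude ratio 5:1 over background, configurable but required > 1) at the
EZ parcels, independent broadband background at NEZ sources, radial dipole
orientations, and projects through the spherical lead field with sensor
noise. After sLORETA the EZ parcels form the high-amplitude, mutually
correlated "hub" halo that the scalp-level analysis expects — an artifact
of field spread that the generator reproduces on purpose.

What the generator does *not* emulate: spike/HFO morphology, neural-mass or
epileptor dynamics, non-stationarity within epochs, artifacts, volume
conduction between SEEG contacts, or real atlas geometry. Passing tests
therefore demonstrate that the pipeline recovers the intended statistical
structure from data that contain it — not clinical performance on real
recordings, which the undeposited study data cannot support.

## Problem sizes and numerical conventions

* Study-scale checks use 20-patient SEEG cohorts at the full defaults
  (113±20 channels, 2 kHz, 10 s epochs) for the direction-recovery and
  density analyses; classifier-preprocessing comparisons use ten 8-patient
  cohorts at 60 channels / 5 s, and the type-I calibration uses 200
  cohorts of 10 patients at 24 channels / 250 Hz / 2 s — sizes chosen so
  the full suite runs comfortably on a single CPU while keeping every
  estimate's sampling error within the asserted bounds.
* Determinism: every stochastic stage derives its RNG state from the
  configured seed (per-patient sub-seeds `seed*1000 + patient`); reports are
  bit-reproducible for a fixed seed, including the tree ensembles (ranger
  and xgboost are seeded from the R stream, single-threaded).
* Ties at exactly the threshold are edges (`|r| >= T`); the binarized
  diagonal is always zero; degenerate channels produce isolated nodes with
  all four metrics zero.
* BH-adjusted values equal `p.adjust(method = "BH")` and are monotone in
  raw-p rank order; undefined (flagged) tests propagate `NA` through the
  correction without affecting the other adjusted values.

## Known limitations

* The spherical forward model and generic parcellation preserve the
  mathematical structure, not individual anatomy; localization statements
  are about grid indices, not brain coordinates.
* The EDF layer covers classic single-rate EDF with a JSON sidecar for
  labels; EDF+ annotations and mixed-rate files are not interpreted.
* Permutation tests re-run the entire nested CV per draw; at the study's
  n_perm = 1000 with slow models this is expensive — the n_perm argument
  exists precisely to scale it.
* With fewer than ~8 patients the exact signed-rank floor
  (`p = 2/2^n`) cannot clear a BH-corrected 0.05 across 28 features; cohort
  sizes below that are only useful for direction, not significance.
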