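---
title: "Comparing structural and effective iEEG networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing structural and effective iEEG networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieegnet)
library(dplyr)
```

## The problem

Intracranial EEG (iEEG) in epilepsy surgery candidates samples the brain with
subdural grids (ECoG, 10 mm contact pitch) or depth shafts (sEEG, 3.5 or 5 mm
pitch). Two measurements probe connectivity between the implanted contacts:

* **Structural**: diffusion-MRI tractography streamlines running between
  *contact areas* — patches of grey-white matter boundary assigned to each
  contact.
* **Effective**: single pulse electrical stimulation (SPES) of adjacent
  contact pairs, with cortico-cortical evoked potentials (CCEPs) detected on
  the remaining channels.

`ieegnet` turns both into binary networks over the same nodes, measures their
overlap, and asks — across patients — what predicts a node's structural
degree. This vignette documents the models, every tunable that matters, what
the synthetic-data generator does and does not emulate, and the design
decisions taken where the procedure was genuinely open.

## Contact areas and node covariates

Each included contact claims its nearest boundary voxels (Euclidean distance
to voxel centres, NIfTI affine convention, 0-based voxel indices), up to
`max_voxels = 64` at 1 mm isotropic voxels, within a `search_radius_mm = 20`
cap. Voxels claimed by several contacts — or strictly nearer to another
contact — are kept only by the globally nearest contact, ties resolved by
ascending contact index, and areas are *not* refilled afterwards, so closely
spaced contacts end up below the 64 mm³ cap. The cap reflects the size of the
cortical patch a stimulation pulse plausibly activates; the radius cap is
this package's own guard for contacts far from the boundary (a contact with
no voxel in range is flagged and carries no structural node). Per-node
covariates: the volume of the electrode contact area (VEA, voxel count ×
voxel volume, mm³) and the node proximity (median Euclidean distance to all
other included contacts, mm), which absorbs irregular spatial sampling.

## Structural network

Streamlines are counted for a contact pair when one endpoint lies in each
contact area (unordered; same-area and out-of-area streamlines are ignored).
The streamline density divides the count by the volume of the two involved
areas; the literature phrase leaves the combination ambiguous, so the
denominator is a parameter: the **sum** `VEA_i + VEA_j` (default — symmetric,
bounded, keeps the usual threshold on a per-mm³ scale), with `mean` and
`product` available. A structural connection forms when density strictly
exceeds `threshold = 0.1` ("exceeds", so a density of exactly 0.1 forms no
edge).

## Effective network

* **Epoching**: half-open sample windows `[round(-2 fs), round(+2 fs))`
  around each stimulus sample; half-open intervals and snap-to-sample event
  times make epoching bit-reproducible. Stimulated contacts are
  non-analyzable in their own trials.
* **Re-referencing**: per trial, the `max(1, round(0.10 n))` lowest-variance
  analyzable channels form the reference; their per-sample median is
  subtracted everywhere. This removes channel-common signal without letting
  large evoked responses contaminate the reference.
* **ERP**: pointwise mean over the (up to ten) epochs; the baseline median of
  the averaged trace is subtracted and the baseline SD computed on the
  corrected trace. The baseline window is −2 to −0.1 s: the 100 ms guard
  before the stimulus is this package's choice, protecting the baseline from
  artifact bleed; it is configurable.
* **Detection**: the signed extremum in the 9–100 ms post-stimulus window —
  the most negative sample for ECoG (grid CCEPs present as negative sharp
  potentials), the largest-magnitude sample of either polarity for sEEG. A
  CCEP is called when the magnitude strictly exceeds `k` × baseline SD, with
  `k = 2.6` (ECoG) and `k = 3.5` (sEEG). Published CCEP detectors add
  morphology checks beyond threshold/window/polarity; those are deliberately
  out of scope here, and the consequences are quantified below. When the
  baseline SD is exactly zero (noise-free traces) the threshold inequality
  degenerates to "any nonzero deflection"; the condition is flagged
  (`sd_zero`) rather than treated as an error, which keeps noise-free
  round-trip checks meaningful.
* **Network**: a detection on channel *c* under stimulation of pair *(a, b)*
  adds undirected edges *a–c* and *b–c*; the response cannot be attributed to
  one contact of the pair, and the symmetrization makes the effective network
  comparable to the undirected structural one (directional information is
  deliberately discarded).

### Detector calibration and the window extremum

The detector's z-statistic is calibrated per sample: under pure Gaussian
noise, a given sample of the averaged, baseline-corrected trace exceeds
`k` × (estimated baseline SD) at the Gaussian tail rate — `pnorm(-2.6)` ≈
0.47% one-sided, `2 pnorm(-3.5)` ≈ 0.047% two-sided. The whole-window
false-alarm rate of an extremum detector is necessarily larger: with `m`
effectively independent samples in the 9–100 ms window it follows the Šidák
form `1 − (1 − p)^m` (about 0.58 for ECoG at 2048 Hz). Both facts are
verified in the acceptance tests. The practical consequence: threshold-only
detection is specific only when responses dwarf the noise floor, which is
exactly the regime averaged clinical CCEPs (tens to hundreds of µV against a
few µV of averaged noise) occupy, and the regime the generator's defaults
reproduce. Morphology-aware detectors exist to buy specificity at lower SNR;
this package exposes the threshold rule the comparison pipeline actually
defines.

## Similarity statistics

Densities, the Jaccard index, its density-matched expectation
`d₁d₂/(d₁+d₂−d₁d₂)`, and the symmetric-difference log-ratio are closed-form.
Significance of the observed Jaccard index uses an explicit density-preserving
permutation null: each of `B` permutations (default 10000) places the two
networks' edge counts independently and uniformly over the unordered pairs,
and `p = (1 + #[JI_perm ≥ JI_obs]) / (B + 1)`. The mean of the permuted
indices must agree with the closed-form expectation — an oracle equivalence
the tests assert within 0.01 at B = 10000. The exact test variant used in
prior literature is not recoverable from its description; an explicit
permutation scheme with an analytic cross-check was chosen for transparency.
When `B` limits resolution the minimum attainable p-value is `1/(B+1)`;
p-values below 1e-4 print as a bound.

## Topology and the multilevel model

Degree is the adjacency row sum. Betweenness centrality is unnormalized and
counted over unordered pairs (normalization is irrelevant downstream: the
per-patient comparisons are rank correlations). Per-patient Spearman
correlations (average ranks for ties, asymptotic p-values) are corrected
across patients by Benjamini–Hochberg at q = 0.05.

The group model is a random-intercept linear mixed model fitted by REML with
`lme4`, outcome structural degree, candidate predictors effective degree,
node proximity, VEA and SOZ. Decisions where the procedure was open:

* **Standardization** (`standardize = TRUE` default): outcome and continuous
  predictors are z-scored over all pooled rows; binary SOZ stays 0/1.
  Standardized coefficients are the natural scale for comparing predictors
  of different units; a raw-scale switch is provided.
* **Degrees of freedom**: Wald t with residual df = rows − fixed effects −
  patients by default; Satterthwaite (via `lmerTest`) as an option. The df
  convention changes nothing material at ~850 rows.
* **ICC** from the intercept-only model, `σ²_inter/(σ²_inter+σ²_intra)`;
  marginal and conditional R² by the Nakagawa variance decomposition.
* **Backward elimination**: drop the largest-p predictor above α = 0.05,
  refit, repeat; the path is recorded. Models containing SOZ are fit only on
  patients whose SOZ is determined (rows with missing SOZ drop); once SOZ is
  eliminated the refits use every patient. If everything is eliminated the
  intercept-only model is returned, flagged.

## What the generator emulates — and what it does not

`sim_config()` defaults define the study conditions: ECoG grids at 10 mm
pitch or sEEG shafts at 3.5/5 mm pitch; a boundary mask thick enough that
isolated contacts reach full 64-voxel areas while neighbours compete;
structural/effective densities 0.20/0.23 with overlap 0.43, chosen so the
planted Jaccard index sits near 0.25 against an expected ~0.12; SPES at
2048 Hz, ten 1 ms pulses per pair at 0.2 Hz, 2 mA (sEEG) or 8 mA (ECoG)
recorded as metadata; evoked deflections of 200 µV at 30 ms latency as a
damped half-sine of ~20 ms width (only amplitude, latency and polarity matter
to a threshold detector, so the waveform shape is the simplest smooth pulse);
Gaussian noise of 10 µV per sample; cohorts of 13 patients × 66 nodes with
standardized fixed effects +0.13 (effective degree) and −0.13 (node
proximity), null VEA and SOZ effects, between/within variances 0.37/0.63
(ICC 0.37), and 2 of 13 patients with undetermined SOZ.

Two generator choices deserve emphasis:

* **Pair-consistent effective truth.** Because the network construction draws
  edges from *both* stimulated contacts to a responding channel, an arbitrary
  planted network is not exactly recoverable. The generator therefore
  stimulates disjoint adjacent pairs and plants the effective network as the
  lift of a quotient graph over those pairs (each quotient edge contributes
  the four contact edges between two pairs). Lifted networks are precisely
  the fixed points of the construction rule, so the noiseless round trip is
  exact; effective edge counts are consequently multiples of four, and
  densities are matched to the nearest feasible count. Clinical SPES
  protocols that stimulate every consecutive (overlapping) pair produce
  effective networks with an analogous but richer closure structure; the
  analysis pipeline handles those identically, only the exact-recovery
  guarantee is specific to disjoint pairs.
* **Cohort tables are generated at the node level**, not by running 13 full
  imaging/electrophysiology simulations: predictors are drawn as standard
  normals so the planted coefficients are already on the standardized scale.
  The generative ICC is defined conditionally on the predictors
  (`σ²_u/(σ²_u+σ²_e)` = 0.37); the intercept-only fit's ICC is slightly
  smaller (≈ 0.358 in expectation) because the fixed-effect variance folds
  into the within-patient term.

What the generator does **not** emulate: 1/f and line noise, artifacts other
than the stimulus spike, spatially correlated noise across channels,
distance-dependent connection probability, tractography's
distance/curvature-dependent error structure, or anatomically realistic
electrode trajectories. Passing tests therefore demonstrate the correctness
of the pipeline's logic and statistics under controlled conditions — not that
the thresholds are optimal for clinical recordings.

## Numerical choices and degenerate inputs

Ties in voxel assignment go to the lower contact index; epoch windows are
half-open; event times snap to the nearest sample; an empty network pair
yields Jaccard 0 with a warning; an empty symmetric difference yields NaN
with a warning and one-sided emptiness yields ±Inf; both-zero densities make
the expected Jaccard an error; the permutation test refuses empty networks
and warns below 100 permutations; singular mixed-model fits are reported, not
hidden. All randomness flows from explicit integer seeds through `withr`
(internal stages derive fixed offsets from the configuration seed), so every
simulation, permutation test and pipeline run is reproducible, and rerunning
the pipeline with the same seed writes byte-identical outputs.

## Problem sizes used in the checks

The test suite exercises desk-scale instances chosen to make the mathematics
sharp rather than the data large: 12–32 contact geometries at 512 Hz for
end-to-end round trips; all-≤8-node random graphs against an exhaustive
betweenness oracle; B = 10000 permutations for the null-mean cross-check;
10,000 pure-noise ERPs at 2048 Hz for detector calibration; and 200 cohort
replicates at the 13 × 66 scale for coefficient coverage, ICC recovery and
elimination behaviour. The full-cohort clinical quantities (median Jaccard
index and densities across real patients) require the original recordings and
upstream co-registration/tractography and are outside what the synthetic
conditions can establish.

## Example

```{r example, eval = FALSE}
cfg <- sim_config("sEEG", n_shafts = 2, contacts_per_shaft = 8, fs = 512,
                  noise_sd_uv = 0, seed = 7)
pat <- simulate_patient(cfg)
res <- run_patient_pipeline(pat$electrodes, pat$mask, pat$recording,
                            counts = pat$counts, B = 10000, seed = 1)
glance(res$similarity)
autoplot(res$sc, res$ec)           # overlap adjacency map

cohort <- simulate_cohort(sim_config(seed = 1))
fit <- backward_eliminate(cohort)
tidy(fit)
autoplot(fit)                      # coefficient forest plot
```

## Known limitations

* The extremum detector's specificity depends entirely on SNR (see the
  calibration section); morphology rules would be needed at low SNR.
* Exact effective-truth recovery presumes disjoint stimulation pairs.
* The multilevel model assumes Gaussian residuals for a degree outcome that
  is integer-valued and bounded; at ~66 nodes per patient the normal
  approximation is adequate, but small networks would warrant a count model.
* Structural and effective errors are simulated independently; in real data
  both correlate with inter-contact distance, which is exactly why node
  proximity is carried as a covariate.
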