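# ieegnet

Compare structural and effective brain networks anchored on intracranial EEG
electrode contacts.

In epilepsy surgery candidates, two very different measurements probe the same
patient-specific brain network. Diffusion-MRI tractography yields *structural*
connections: streamlines between electrode contact areas on the grey-white
matter boundary. Single pulse electrical stimulation (SPES) yields *effective*
connections: cortico-cortical evoked potentials (CCEPs) recorded on distant
contacts after stimulating adjacent contact pairs. `ieegnet` builds both
binary networks over the same electrode-contact nodes, quantifies how much
they agree, and models what drives that agreement across a patient cohort. A
synthetic-data generator with planted ground truth makes every stage
verifiable end-to-end without clinical data.

## The statistics at the core

For two binary networks `SC` and `EC` on the same `N` nodes (edge sets over
unordered contact pairs):

- **Density** `d = sum(A) / (N (N - 1))`, i.e. `2E / (N (N - 1))`.
- **Jaccard index** `JI = |SC ∩ EC| / |SC ∪ EC|`, with its density-matched
  chance level `JI_expected = d_SC d_EC / (d_SC + d_EC − d_SC d_EC)` and a
  permutation test that places each network's edge count uniformly at random.
- **Symmetric-difference ratio**
  `log10(|SC \ EC| / |EC \ SC|)` — 0 when both modalities contribute equally
  to the non-overlap, −1 when effective-only connections outnumber
  structural-only ones ten to one.
- **Topology**: per-node degree and unnormalized betweenness centrality
  `BC(v) = Σ_{s≠v≠t} σ_st(v) / σ_st`, compared between modalities per patient
  by Spearman rank correlation with Benjamini–Hochberg FDR correction.
- **Multilevel model**: pooling nodes across patients,
  `SC degree ~ EC degree + node proximity + VEA + SOZ + (1 | patient)` by
  REML, with the intraclass correlation
  `ICC = σ²_inter / (σ²_inter + σ²_intra)` from the intercept-only model,
  Nakagawa marginal/conditional R², and backward elimination of
  non-significant predictors. Node proximity (median distance to all other
  contacts) absorbs the irregular spatial sampling of iEEG; VEA is the
  contact-area volume; SOZ flags seizure-onset-zone contacts.

Pipeline stages: contact areas (≤ 64 nearest boundary voxels per contact,
contested voxels to the nearest contact) → streamline density
(count / (VEA_i + VEA_j), edge when > 0.1) → SPES epoching (−2 to +2 s),
low-variance re-referencing, ERP averaging, CCEP detection (9–100 ms window;
negative deflections > 2.6 baseline SD for ECoG, either polarity > 3.5 for
sEEG) → bi-directional effective network → similarity and models.

## Worked example

A noiseless synthetic sEEG patient, recovered end-to-end:

```r
library(ieegnet)

cfg <- sim_config("sEEG", n_shafts = 2, contacts_per_shaft = 8, fs = 512,
                  noise_sd_uv = 0, seed = 7)
pat <- simulate_patient(cfg)
pat$truth
#> <synthetic_truth> 16 nodes; SC 24 edges, EC 28 edges, shared 10, planted JI 0.238

res <- run_patient_pipeline(pat$electrodes, pat$mask, pat$recording,
                            counts = pat$counts, B = 10000, seed = 1)
res$similarity
#> <network_similarity> 16 nodes
#>   JI 0.238 (expected 0.121), p 0.0209
#>   densities: SC 0.200, EC 0.233
#>   edges: 10 shared, 14 SC-only, 18 EC-only; log10 ratio -0.109
```

The recovered Jaccard index equals the planted 0.238 exactly (edge-for-edge
recovery at zero noise), it is about twice the 0.121 expected under
density-matched chance, and the permutation test calls that excess
significant (p ≈ 0.02 at B = 10000). The log10 ratio −0.109 says the
non-overlapping part holds slightly more effective-only than structural-only
connections.

At the cohort level, a 13-patient × 66-node table with planted standardized
effects 0.13 (effective degree) and −0.13 (node proximity), null VEA/SOZ, and
generative ICC 0.37:

```r
cohort <- simulate_cohort(sim_config(seed = 1))
fit_intercept_only(cohort)$icc
#> [1] 0.3442055

backward_eliminate(cohort)
#> <ml_fit> sc_degree ~ ec_degree + proximity_mm + (1 | patient); 858 rows, 13 patients
#>   ICC 0.358; marginal R2 0.030, conditional R2 0.377
#>          term  estimate std_error statistic  df  p_value conf_low conf_high
#>   (Intercept)  2.33e-15    0.1684  1.38e-14 842 1.00e+00  -0.3305    0.3305
#>     ec_degree  1.25e-01    0.0275  4.53e+00 842 6.69e-06   0.0707    0.1786
#>  proximity_mm -1.26e-01    0.0277 -4.55e+00 842 6.09e-06  -0.1804   -0.0717
```

Backward elimination drops the null predictors (VEA, SOZ) and retains
effective degree (+0.125) and node proximity (−0.126), close to the planted
±0.13; the ICC says roughly a third of the outcome variance sits between
patients, which is what makes the random intercept necessary.

`tidy()`, `glance()` and `autoplot()` methods are available for networks,
similarity results and model fits.

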