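# orgresponse

Individual-organoid treatment-response analysis for patient-derived cancer
organoids (PDCOs), with a synthetic imaging-cohort generator so the whole
pipeline runs and is testable without any patient data.

## The problem and who this is for

Drug-response assays on 3-D organoid cultures are usually read out at the
well level (ATP luminescence, endpoint size distributions). But organoids
within one culture respond heterogeneously, and baseline sizes vary so much
that well-level readouts drown modest treatment effects. The alternative
implemented here — for imaging-core and translational-oncology analysts —
tracks every organoid individually between a pre-treatment (Day 0) and a
post-treatment (Day 4) imaging session and quantifies response per
organoid on two modalities:

* **growth**: relative change in longest diameter,
  `100 · (d_Day4 − d_Day0) / d_Day0`, from brightfield;
* **metabolism**: change in the optical redox ratio
  `ORR = I_NAD(P)H / (I_NAD(P)H + I_FAD)` computed over the organoid's
  leading edge (outer 20-pixel band) from widefield autofluorescence,
  `ΔORR = ORR_Day4 − ORR_Day0`.

Each treated arm is scored against its control with a median-based Glass's
delta,

```
mGΔ = (median_control − median_treatment) / sd_control
```

and classified sensitive / intermediate / resistant with validated
treatment-class cutoffs (chemotherapy: diameter ≥ 1.25 / ≤ 0.75, ΔORR
> 1.5 / < 0; chemoradiation: diameter ≥ 1 / ≤ 0, ΔORR > 1 / < 0). The
predictions are cross-tabulated against clinical RECIST v1.1 categories
derived from sum-of-longest-diameter (SLD) changes.

The package covers the full chain: synthetic cohort simulation and
multi-channel field rendering (`generate_cohort()`, `render_field()`),
classical segmentation with leading-edge extraction and background
normalization (`segment_organoids()`, `leading_edge_mask()`,
`background_normalize()`), morphometry and cross-day tracking
(`longest_diameter()`, `pair_organoids()`), redox quantification
(`organoid_orr()`, `delta_orr()`), arm statistics (`summarize_arm()`,
`mglass_delta()`, `compare_arms()`, `well_level_readouts()`), and
classification/concordance (`classify_response()`, `combine_modalities()`,
`recist_category()`, `concordance_table()`). `run_pipeline()` executes the
whole thing into a reproducible run directory.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Step 2
runs the imaging pipeline over a simulated LARC12 demonstration cohort
(75 organoids per arm, reduced-field geometry) and step 3 computes effect
sizes:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_segment_measure.R
Rscript analysis/03_effect_sizes.R
Rscript analysis/04_concordance.R
```

Step 3 prints (abridged):

```
  treatment_label modality median_control median_treatment sd_control
1          FOLFOX diameter        75.5353         -25.3122     60.942
2          FOLFOX      ORR         0.0452           0.0253      0.043
3         5FU+XRT diameter        75.5353          23.2409     60.942
4         5FU+XRT      ORR         0.0452           0.0387      0.043
  mglass_delta  p_value    predicted
1        1.655 4.84e-14    sensitive
2        0.463 1.40e-03 intermediate
3        0.858 1.04e-05 intermediate
4        0.153 4.21e-01 intermediate
```

Reading it: in this simulated cohort the untreated LARC12 organoids grew
(median +75.5% over four days) while FOLFOX-treated ones shrank (−25.3%);
dividing the median difference by the control SD gives a diameter mGΔ of
1.66, past the 1.25 chemotherapy cutoff, so the arm is called sensitive.
The 5FU+XRT arm still grew (+23.2%), giving mGΔ 0.86 — an intermediate
call under the chemoradiation thresholds. The ΔORR modality shows a
smaller metabolic shift (mGΔ 0.46 for FOLFOX), which remains intermediate;
combining modalities most-sensitive-wins leaves FOLFOX sensitive. Sample
medians differ from the generative ones (64.0 / −10.6 / 17.5) because each
arm here is only 75 organoids. The p-values are two-sided rank-sum tests of
arm separation.

Step 4 simulates a 20-subject clinical cohort and prints the concordance
table of predicted vs RECIST categories with per-row response rates.

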