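---
title: "Methods: individual-organoid treatment response from brightfield and optical redox imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-organoid treatment response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgresponse)
```

## The measurement problem

Patient-derived cancer organoids (PDCOs) respond heterogeneously to
treatment: organoids within one culture grow, stall or shrink at very
different rates, and cultures are plated with widely varying baseline
sizes. Well-level endpoint assays — an ATP-luminescence readout
(CellTiter-Glo style) or the distribution of Day-4 diameters — integrate
over that heterogeneity and lose sensitivity. This package implements the
alternative: track each organoid individually between a pre-treatment
(Day 0) and post-treatment (Day 4) imaging session and quantify response at
the organoid level, on two complementary modalities.

**Growth.** From brightfield images, each organoid's longest diameter is
measured on both days and summarised as

$$\text{relative change in diameter (\%)} =
  \frac{d_{\text{Day4}} - d_{\text{Day0}}}{d_{\text{Day0}}} \times 100 .$$

**Metabolism.** From widefield autofluorescence images of NAD(P)H and FAD,
each organoid's optical redox ratio is computed over its leading edge
(the outer 20-pixel band of the mask, where signal is concentrated):

$$\mathrm{ORR} = \frac{I_{\mathrm{NAD(P)H}}}{I_{\mathrm{NAD(P)H}} +
  I_{\mathrm{FAD}}},$$

with $I$ the mean background-normalized intensity, and the per-organoid
change $\Delta\mathrm{ORR} = \mathrm{ORR}_{\text{Day4}} -
\mathrm{ORR}_{\text{Day0}}$. A metabolic decrease after treatment gives a
negative $\Delta$ORR. The difference form is a deliberate design choice:
it is the unique simple definition for which "ORR decreases under
effective treatment" corresponds to a negative sign; a variant normalized
to the control arm's baseline can be emulated by shifting, which the
effect size below ignores anyway.

**Effect size.** Each treated arm is scored against the same line's
untreated control with a median-based (modified) Glass's delta,

$$\mathrm{mG}\Delta = \frac{\tilde{x}_{\text{control}} -
  \tilde{x}_{\text{treatment}}}{\sigma_{\text{control}}},$$

where $\tilde{x}$ is the arm median of either modality's per-organoid
values pooled across replicates and $\sigma_{\text{control}}$ is the
control arm's sample standard deviation (n − 1 denominator; the
convention is stated because the statistic's source leaves it implicit).
mGΔ is invariant under shifting all values by a constant and rescaling by
a positive constant, which makes it robust to measurement conventions
(units, small constant measurement offsets) — a property the tests assert
with randomized cases.

**Classification.** mGΔ is mapped to sensitive / intermediate / resistant
with treatment-class cutoffs: chemotherapy regimens (5FU, oxaliplatin,
SN38, FOLFOX, FOLFIRI) use diameter cutoffs 1.25-or-higher / 0.75-or-lower
and ΔORR cutoffs strictly-above-1.5 / strictly-below-0; chemoradiation
(XRT, 5FU+XRT) uses diameter 1-or-higher / 0-or-lower and ΔORR
strictly-above-1 / strictly-below-0. Boundary inclusivity follows the
wording of the validated cutoffs literally and is carried explicitly in
`threshold_presets()`. The source material states two variants of the
chemoradiation diameter resistant cutoff (0 in the methods, 0.5 in the
results); both are shipped as named presets (`"methods"`, the default, and
`"results"`) rather than silently adjudicating.

**Clinical concordance.** Clinical response enters as RECIST v1.1
target-lesion categories on the sum of longest diameters (SLD): CR when
the SLD disappears, PR at a ≥30% decrease, PD at a ≥20% *and* ≥5 mm
increase, SD otherwise. `concordance_table()` cross-tabulates organoid
predictions against these categories and reports the per-category
clinical response rate, counting PR or CR as response. When both
modalities are available they are combined most-sensitive-wins
(`combine_modalities()`): the ΔORR modality can upgrade an intermediate
diameter call but never downgrade a sensitive one, matching how the two
modalities complement each other; require-both or averaged-mGΔ rules were
considered and rejected because they cannot express that upgrade
behaviour.

## The synthetic imaging cohort

No patient data ship with the package. Instead, `generate_cohort()` and
`render_field()` produce two-timepoint, three-channel (BF, NAD(P)H, FAD)
fields with known per-organoid ground truth, emulating gridded glass
dishes: 3.34 mm × 3.34 mm fields, 2044 × 2048 px at 1.634 µm/px, five
fields per replicate and three replicates by default.

Organoids are placed one per grid cell; Day-4 positions add a small gel
drift (SD 5 µm). Ellipses (axis ratio 0.75–1, random orientation) are
drawn with the major axis equal to the true longest diameter; the
brightfield shows a dark rim on a bright background, and the two
fluorescence channels share a rim-concentrated radial profile whose
amplitudes are split `S·ORR` and `S·(1 − ORR)`, so the background-
subtracted ratio of mask means reproduces the true ORR for *any* mask —
which is also why the ORR measurement is insensitive to the exact leading-
edge width on phantoms. An object below sampling resolution still darkens
the pixel it sits in, so strongly responding organoids remain visible.

Generative laws and their defaults:

| Quantity | Law | Default | Why |
|---|---|---|---|
| Day-0 diameter | lognormal | median 200 µm, sdlog 0.15 | typical plated organoid scale; no size distribution is reported, so this is a documented stand-in |
| growth (%) | normal | per arm | medians from the reported arms; control SD solved from the reported effect-size identity |
| Day-0 ORR | normal, clipped to [0.01, 0.99] | 0.55 ± 0.05 | mid-range redox state |
| ΔORR | normal | per arm | reported medians where printed; stand-ins otherwise (below) |
| viability factor | constant per arm | 1 control; 0.6–0.8 treated | scales the luminescence proxy only |

The preset lines (`line_presets()`) encode the three reported worked
examples: LARC12 (control 64.0% vs FOLFOX −10.6% and 5FU+XRT 17.5%;
control SD 56.6 solved from the printed identity 74.6/1.32 and confirmed
by 46.5/0.82), LARC7 (14.5% vs −9.4%, SD 23.9/0.92) and CRC8 (70.3% vs
22.4%, SD 47.9/1.26). The LARC12 ΔORR arms use the printed medians 0.046
and 0.026 with implied SD 0.020/0.47. For LARC7 and CRC8 the ΔORR arm
medians are not printed — only the effect sizes 1.26 and 1.08 — so the
presets use a stand-in control median of 0.046 (the printed LARC12
control value) with SD 0.04, and solve the treated median from the
printed effect size. These stand-ins set the *scale* of the ΔORR arms;
the recovered effect size is insensitive to them because mGΔ is
shift/scale invariant.

Two placement caps keep masks strictly inside their grid cells so masks
can never overlap: Day-0 diameters are capped at 45% and Day-4 diameters
at 92% of the grid pitch. Under the default laws and geometry these caps
bind for well under 1% of organoids, so the realized medians and SDs
match the laws; this mattered in practice, because a tighter early cap
visibly shrank the control-arm SD and biased recovered effect sizes
upward.

What the phantoms do **not** emulate: optical physics (PSF, vignetting,
photobleaching, excitation dose), segmentation-hostile morphology
(budding, lumen collapse, debris, out-of-focus organoids), inter-replicate
batch effects, and real attrition mechanics (attrition is a simple
per-organoid Bernoulli flag, default off). Passing tests therefore
demonstrate that the *quantification chain* is correct and unbiased on
well-formed inputs, not that the classical segmenter would match a
trained network on real micrographs — the segmenter sits behind
`segment_organoids()` precisely so a learned model can be swapped in.

## Image processing choices

* **Segmentation** (`segment_organoids()`): the brightfield is inverted
  and rescaled; an Otsu level is estimated on a smoothed (σ = 1.5 px),
  2× downsampled copy — smoothing stabilises the level under noise, and
  the level only has to fall between the intensity classes, so the
  downsampling is immaterial; the mask itself is thresholded on the
  *unsmoothed* image at that level, because masking the smoothed image
  dilates every object by roughly the smoothing radius (a ~1 px
  diameter bias measured end-to-end) and erases sub-resolution remnants.
  Holes are filled, components below `min_area_um2` are dropped, and
  touching objects are split by a marker-based watershed on the distance
  transform, run per connected component on padded bounding boxes (the
  result is identical to a whole-field watershed; components are
  independent). Labels are renumbered 1..K in column-major order of first
  appearance, so labelling is deterministic. A blank-field guard returns
  zero labels unless the Otsu classes are separated by at least 6
  background-MADs.
* **`min_area_um2`** defaults to 2000 µm² (≈ a 50 µm disk), a
  conservative floor for general use. The effect-size recovery runs use
  40 µm² instead: strong responders shrink far below 2000 µm² by Day 4,
  and dropping those remnants censors exactly the strongest responses,
  biasing the treated-arm median upward. On the high-contrast phantoms the
  low floor admits no noise objects (the threshold sits ~8 noise-SDs from
  the background).
* **Background normalization** (`background_normalize()`): background =
  complement of the labels dilated by 10 px (keeping halos out), statistic
  = median (robust to residual dim objects), correction = subtraction with
  clipping at zero. Division is available behind a flag; under the shared-
  background construction of the simulator both leave every effect size
  unchanged, which is why subtraction was chosen without further
  adjudication. The median is computed on a regular 20 000-pixel
  subsample; its SE is far below one count.
* **Longest diameter** (`longest_diameter()`): maximum Feret diameter —
  the greatest pairwise distance between boundary pixel centres (computed
  exactly via the convex hull) plus one pixel for pixel extent, so a
  single pixel has diameter 1 px rather than 0. This mirrors a manual
  longest-diameter line measurement. Measured bias on noise-free phantoms
  is well under 1 px.
* **Leading edge** (`leading_edge_mask()`): pixels of a label whose
  distance transform is ≤ 20 px; an object thinner than twice the band
  yields its full mask. The 20 px width (≈ 33 µm at 1.634 µm/px) is kept
  in pixels, matching the validated convention; the "(32 mm)" annotation
  sometimes attached to that convention is treated as a typo for ≈32 µm.
* **Tracking** (`pair_organoids()`): greedy nearest-centroid matching
  within each field, acceptance radius 150 µm, ties broken by detection
  order — densities are low (grid pitch ≈ 670 µm), so optimal assignment
  would change nothing while being harder to reason about. Unpaired Day-0
  organoids are kept as records but excluded from change-based statistics;
  unmatched Day-4 detections are reported as an attribute.
* **Arm comparison** (`compare_arms()`): two-sided Mann–Whitney rank-sum
  by default (per-organoid distributions are skewed); Welch's t-test
  behind a flag. No multiple-testing correction is applied across lines or
  treatments, matching the source analysis; this is flagged rather than
  silently "improved".

## Reduced-field mode and problem sizes

Mass simulations use `reduced_field_spec()`: the same 3.34 mm physical
field sampled at 6.536 µm/px (512 × 512 px), with a 5 × 5 grid per field.
Diameters of order 100 µm and mask-mean intensity ratios are insensitive
to the 4× coarser sampling, and the geometry is a parameter throughout.
The effect-size recovery study (`recover_effect_sizes()`) runs 500
organoids per arm, averaged over five master seeds — 20 fields per arm,
rendered and measured at both days — for each of the three preset lines;
the package's acceptance checks run exactly this study. The power-ordering
study uses 200 replicates of 40 organoids per arm at truth level with
three wells per arm for the luminescence comparator.

## Determinism

One master seed drives everything: per-arm sampling streams and per-field,
per-day rendering streams are derived as fixed child seeds, so an
identical `cohort_spec()` reproduces bit-identical truth tables and
images, and `run_pipeline()` reproduces byte-identical CSVs (a config
hash and the seed are written into every run's provenance block).

## Known limitations

* The classical segmenter is tuned to high-contrast phantoms; real
  brightfield micrographs need a trained model behind the same interface.
* The ΔORR definition is the simple paired difference; if the
  control-baseline-normalized variant is required, shift invariance of
  mGΔ makes arm-level effect sizes agree, but per-organoid values differ.
* The clinical link in `simulate_clinical_outcome()` (−35% SLD per mGΔ
  unit, linear, clamped) is a synthetic calibration chosen so that a
  moderately sensitive line maps near the −31% SLD change of the worked
  example; it is a device for exercising the concordance stage, not a
  validated pharmacodynamic model.
* Attrition handling (unpaired exclusion) is implemented but the source
  analysis is silent on it; the default attrition rate is therefore 0.
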