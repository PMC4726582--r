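---
title: "Frequency-selective non-linear blending: model, phantom and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-selective non-linear blending: model, phantom and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsnlb)
```

## The problem and the model

Ischemic brain edema lowers tissue attenuation by only 1–8 HU within the
first hours of stroke, on images whose gray/white contrast is about 10 HU
and whose noise is several HU. A linear display window cannot separate
such a lesion from noise: widening the gray-level gain amplifies both
equally. The best-contrast (BC) idea exploits the fact that the two live
at different spatial frequencies — tissue contrast is smooth, CT noise is
mostly pixel-to-pixel — and applies a strong non-linear gray-level gain
*only* to the low-frequency band.

`apply_bc()` composes three operations:

1. **Band split** (`decompose_bands()`). The low band is a Gaussian
   low-pass with spatial standard deviation `sigma_mm`; the high band is
   defined as the residual, so reconstruction is exact by construction
   (the complement identity `low + high == original` is tested to
   1e-6 HU). The filter is applied in the frequency domain after mirror
   padding by 4σ, which prevents the very bright skull from ringing into
   the brain at the image border; the frequency response is the analytic
   Gaussian transfer exp(−2π²σ²f²), which the test suite verifies on pure
   sinusoids to within 2%.
2. **Non-linear transfer** (`bc_transfer()`). The published description of
   the scaling curve is schematic, so its functional form is a design
   choice of this package:
   T(x) = c + sΔ·tanh((x − c)/Δ). This curve is smooth and strictly
   increasing, fixes the center (T(c) = c), has gain exactly `slope` at
   the center (`contrast_gain()` returns the analytic derivative
   s·sech²((x−c)/Δ)), and saturates at c ± sΔ. At the defaults it maps the
   25–35 HU band onto ≈ 5–55 HU — i.e. the narrow edema band fills a
   standard brain display window. The curve is a plain function of the
   parameter object, so alternative sigmoids can be substituted without
   touching the pipeline.
3. **Merge**. The description of the re-merge step names no weights; we
   use the additive merge T(low) + `high_weight`·high with
   `high_weight = 1`, which preserves the high band (and hence noise and
   edge detail) unchanged. No output renormalization is performed: whether
   the vendor implementation rescales its dynamic range after merging is
   unknown, and renormalizing would entangle the contrast gain with image
   statistics.

### Parameters

| parameter | unit | default | meaning |
|---|---|---|---|
| `center` | HU | 30 | attenuation level being highlighted; sits between white (≈28) and gray (≈38) matter |
| `delta` | HU | 5 | half-width of the highlighted band |
| `slope` | — | 5 | contrast gain at the center |
| `sigma_mm` | mm | 2.0 | spatial scale of the band split |
| `high_weight` | — | 1.0 | gain on the high band at merge |

`center`, `delta` and `slope` are the published operating point. The
phrase "slope" is read as *gain at the center* of the transfer curve;
that is the only reading that makes the parameter dimensionless and
independent of delta. `sigma_mm` and `high_weight` parameterize the parts
of the pipeline whose exact settings were never published ("the
thresholds for the applied high- and low-pass filters"): σ = 2 mm cleanly
separates anatomic contrast (≥ 5 mm structures) from pixel noise at
typical brain-CT pixel sizes of 0.4–0.9 mm, and is specified in mm so the
behavior is invariant to the reconstruction matrix.

### Numerical choices

All computation is in double-precision HU; quantization happens only at
export (16-bit DICOM, slope 1 / intercept −1024, error ≤ 0.5 HU; NIfTI is
written as 64-bit float and round-trips bit-exactly). Display windowing
rounds half-up, so window midpoints are platform-stable. The transfer is
mathematically strictly monotone; in double precision it is flat in the
deep saturated tails (|x − c| ≳ 20Δ), so the strict-monotonicity property
is asserted over the brain attenuation range and non-strict monotonicity
over the full 12-bit CT range. Images smaller than 8×8 pixels are
rejected rather than filtered. BC is intentionally not idempotent —
re-applying it re-amplifies the already-amplified low band — but the band
complement identity holds on its output like on any image.

## The phantom: what it emulates and what it does not

The generator (`aspects_template()`, `render_phantom()`, `make_cohort()`)
stands in for the patient scans of a stroke-imaging study. It is
*stylized, not anatomical*: an elliptical brain in a skull ring with
lateral ventricles, deep-gray nuclei (caudate, lentiform), internal
capsule, insular ribbon and cortical sectors — each region a homogeneous
tissue with standard adult attenuations (CSF 8, white 28, gray 38, deep
gray 40, skull 800 HU) plus additive Gaussian noise (default sd 4 HU,
optionally spatially correlated). Geometry is parametric and exactly
mirror-symmetric about the sagittal midline, which makes ground truth and
contralateral comparison exact; that is the point of a stylized phantom,
and the reason region masks partition cleanly at any matrix size.

Lesions are injected as compact blobs covering a chosen fraction of one
region on one side, each reducing attenuation by `delta_hu` with optional
edge feathering. Cohort defaults are chosen once, on physical and
epidemiological grounds:

* **lesion contrast 2–4 HU** — the subtle range where early edema is
  near the limit of visual detection;
* **coverage 0.3–0.7** — partial territorial involvement, which puts the
  *region-mean* drop (coverage × contrast ≈ 0.6–2.8 HU) astride the
  1.5 HU reading threshold on unprocessed images;
* **1–3 unilateral lesions per positive patient** — matching the ≈ 2
  lesions per affected patient of MCA-stroke series, with region weights
  dominated by lentiform nucleus and insula;
* **prevalence 0.855** — the fraction of confirmed infarcts in the
  reference cohort the simulation mirrors.

What the phantom does *not* emulate: beam-hardening streaks next to the
cranial vault (clinically a major cause of missed cortical lesions),
partial-volume effects from slice thickness, anatomical variability,
asymmetric positioning, and hemorrhage. Passing the simulation therefore
shows that the algorithm and reading pipeline behave as designed under
idealized symmetric noise — it does not certify clinical sensitivity
magnitudes, which depend on human readers and artifact structure. For the
same reason the simulated accuracy figures are expected to reproduce the
*direction* of the published trade-off (BC raises sensitivity and lowers
specificity at a fixed reading rule), not its exact magnitudes.

One consequence of the chosen transfer curve is worth stating openly: at
the default operating point the curve saturates above ≈ 40 HU, so lesions
inside deep-gray nuclei (40 HU) receive *less* than unit gain on their
region-mean contrast, while lesions in and around the white/gray band
(insula, cortex, internal capsule) are amplified several-fold. The
patient-level benefit in the simulation is carried by the amplified
regions together with the reader rule (any flagged region marks the
patient positive).

## The automated reader

Human hypoattenuation calls are replaced by a deterministic rule: for
each region, the mean HU inside the mask is compared with the mean inside
its mirror image; a region is flagged when the difference is ≤ −1.5 HU
(`threshold_hu`, reported with every result — the source study gives no
numeric criterion, and 1.5 HU is roughly 3–4 null standard errors of a
region-mean difference at noise sd 4, keeping the false-flag rate low on
unprocessed images). ASPECTS is 10 minus the number of distinct flagged
regions; the hypoattenuated area is measured by smoothing the mirror
difference image (1.5 mm), thresholding, and summing connected
components ≥ 0.1 cm² (components below that are isolated noise pixels).
The same rule is applied to NECT and BC images — the comparison isolates
the effect of the post-processing, not of the reading rule.

## Statistics conventions

Confidence intervals for proportions are exact Clopper–Pearson (beta
quantiles); that is the only standard method consistent with the printed
30.8–89.1% interval for 7 of 11 true negatives that the package
reproduces. Fisher's exact test is two-sided by the point-probability
rule (the convention of `stats::fisher.test`, which backs the
implementation; the test suite checks it against exhaustive
hypergeometric enumeration). Percentages in accuracy tables round
half-up to whole percent, CI bounds to one decimal. Cohen's kappa and
Bland–Altman limits of agreement (mean ± 1.96 sd, t-based CI for the
mean) are computed from their defining formulas; zero denominators and
zero-variance differences are flagged or raised as errors, never silently
reported as 0. No multiple-testing correction is applied anywhere.

## Problem sizes

The simulation sizes used by the tests and the acceptance script are a
deliberate compromise between Monte-Carlo stability and a laptop-friendly
run: 200 phantoms at 256×256 (0.86 mm pixels) for the reading trade-off,
100–200 seeded repetitions at 128×128 for null-calibration and
exchangeability properties, 2000 replicates for interval coverage and
p-value calibration. At these sizes the full suite runs in well under a
minute and the acceptance script in under half a minute.

## Known limitations

* The transfer curve and band split are this package's concrete reading
  of a schematic description; a vendor implementation will differ in
  detail (curve shape, filter roll-off, possible renormalization).
* Detectability magnitudes are not transferable to real scans (see the
  phantom section); only orderings and directions are.
* The DICOM codec is deliberately minimal (single-frame, Explicit VR
  little endian, 16-bit monochrome); clinical archives with compressed
  transfer syntaxes must be converted before ingestion.
* Slices are processed independently; no 3-D filtering is attempted.
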