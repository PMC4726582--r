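# fsnlb — frequency-selective non-linear blending for brain CT

Early ischemic edema is notoriously hard to see on non-enhanced brain CT
(NECT): the attenuation drop it causes is only a few Hounsfield units (HU),
against gray/white-matter contrast of ~10 HU and image noise of similar
size. `fsnlb` implements the *best contrast* (BC) post-processing idea for
this problem — amplify subtle, spatially smooth attenuation differences
without amplifying pixel noise — together with everything needed to
evaluate it quantitatively: a seeded digital brain phantom with an
ASPECTS-style region template, an automated mirror-comparison reader, and
the diagnostic-accuracy statistics used in clinical reader studies. It is
aimed at imaging researchers who want a transparent, reproducible
implementation of frequency-selective contrast enhancement and a test bed
for reading thresholds and lesion detectability.

## The algorithm

A CT slice *I* is split into complementary bands with a Gaussian low-pass
*G<sub>σ</sub>* (spatial scale σ in mm, executed via the DFT with mirror
padding):

&nbsp;&nbsp;&nbsp;&nbsp;*L* = *G<sub>σ</sub>* ∗ *I*,&nbsp;&nbsp;
*H* = *I* − *L*

so *L* + *H* = *I* exactly. The low band — which carries the tissue
contrast — passes through a non-linear attenuation transfer centred on the
HU level *c* being highlighted:

&nbsp;&nbsp;&nbsp;&nbsp;*T*(x) = *c* + *s*·Δ·tanh((x − *c*)/Δ)

with half-width Δ (HU) and gain *s* (dimensionless): *T*(*c*) = *c*,
*T*′(*c*) = *s*, and the output saturates at *c* ± *s*Δ. The result is
re-merged with the untouched high band:

&nbsp;&nbsp;&nbsp;&nbsp;*I<sub>BC</sub>* = *T*(*L*) + *w*·*H*

At the published operating point (*c* = 30 HU, Δ = 5 HU, *s* = 5) the
25–35 HU band — where white matter, gray matter and ischemic edema live —
is spread across ≈ 5–55 HU, a five-fold local contrast gain, while white
noise (which lives almost entirely in *H*) passes through with gain
*w* = 1.

## Worked example

```r
library(fsnlb)

p <- bc_params()        # center 30 HU, delta 5 HU, slope 5
round(bc_transfer(c(25, 28, 30, 32, 35, 40), p), 1)
#> [1] 11.0 20.5 30.0 39.5 49.0 54.1
```

The 28-vs-32 HU pair — a typical edema-vs-normal white matter contrast of
4 HU — maps to 20.5 vs 39.5 HU: a 19 HU displayed difference.

A phantom with a 3 HU insular lesion (80% coverage), read by mirror
comparison before and after BC:

```r
tpl <- aspects_template("ganglionic", shape = c(256, 256))
cfg <- phantom_config(shape = c(256, 256), noise_sd = 4, seed = 7)
ph  <- render_phantom(cfg, tpl,
                      list(lesion_spec("insula", "left", delta_hu = 3,
                                       coverage = 0.8)))

r <- measure_regions(ph$slice, tpl)
subset(r, name == "insula")
#>   region   name  side  mean_hu contralateral_mean_hu difference
#> 3      2 insula  left 35.31678              38.34001   -3.02323
#> 4      2 insula right 38.34001              35.31678    3.02323

rbc <- measure_regions(apply_bc(ph$slice, p), tpl)
subset(rbc, name == "insula")
#>   region   name  side  mean_hu contralateral_mean_hu difference
#> 3      2 insula  left 45.84127              52.20662  -6.365347
#> 4      2 insula right 52.20662              45.84127   6.365347

aspects_score(detect_regions(rbc, threshold_hu = 1.5))
#> [1] 9
```

The left insula reads 3.0 HU below its mirror on the raw image and 6.4 HU
below after BC — the lesion moves well clear of the 1.5 HU reading
threshold, costing one ASPECTS point (score 9 of 10).

The statistics layer reproduces clinical accuracy tables from raw counts:

```r
diagnostic_accuracy(confusion2x2(tp = 35, fp = 0, fn = 30, tn = 11))
#> <diag_accuracy>
#>   sensitivity  54% (35/65; 95%-CI 41.0-66.3%)
#>   specificity 100% (11/11; 95%-CI 71.5-100.0%)
#>   ppv         100% (35/35; 95%-CI 90.0-100.0%)
#>   npv          27% (11/41; 95%-CI 14.2-42.9%)
#>   accuracy     61% (46/76; 95%-CI 48.6-71.6%)
```

A command-line interface (`inst/cli/fsnlb.R`) exposes the same
functionality as subcommands `apply`, `phantom`, `cohort`, `experiment`
and `stats`.

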