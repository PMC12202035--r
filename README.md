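# cedtrace

Analysis toolkit for convection-enhanced delivery (CED) trials that
co-infuse a gadolinium tracer to image drug distribution — the setting of
first-in-human CED studies in diffuse intrinsic pontine glioma (DIPG),
where a catheter infuses nanoliposomal drug plus gadoteridol directly
into the brainstem and serial T1-weighted MRI shows where the infusate
actually went.

The package implements four things a trial team needs to analyse such a
study, plus a synthetic phantom generator that makes the whole chain
testable without any patient data:

1. **Subtraction volumetry of the tracer distribution volume (Vd).**
   Pre- and post-infusion T1 volumes are rigidly co-registered, the post
   image is intensity-normalised against an uninfused reference
   structure (matching the reference-mask mean and standard deviation:
   `scale = sd_ref(pre)/sd_ref(post)`,
   `offset = mean_ref(pre) - scale * mean_ref(post)`), and the
   difference image is thresholded at `k * sigma_residual` within a
   region of interest, with speckle removal and hole filling. Voxels
   above threshold form the Vd mask; its volume in cm³ is the per-
   treatment Vd.
2. **Tumor-coverage metrics.** Per-patient union of the per-treatment Vd
   masks, coverage of the FLAIR-defined tumor volume
   (`100 * covered / tumor`), convection efficiency `Vd/Vi`, and the
   cohort summary statistics (mean ± SD) of a published-style treatment
   table.
3. **Kaplan–Meier survival endpoints** with log-transformed Greenwood
   confidence intervals (`exp(log S ± 1.96 se(log S))`), under two
   policies for a patient lost to follow-up: loss counted as an event at
   its recorded time, or censored.
4. **A dose-escalation design simulator**: an accelerated titration
   design (single-patient cohorts; escalate on grade 0–1, hold on
   tolerable grade 2, de-escalate on dose-limiting toxicity) that
   converts to a standard 3+3 on the first cycle-1 DLT or the second
   cycle-1 related grade ≥ 2 event, with RP2D rules (0/3 escalate, 1/3
   expand to six, ≥ 2/3 or > 1/6 declare the next lower level), a
   seeded Monte-Carlo harness and an exact decision-tree enumerator.

Everything tabular takes a data frame and returns a tibble, so results
chain with the pipe; fitted objects have `tidy()`/`glance()` methods and
`autoplot()` figures.

## Worked example

The package ships the six-patient, thirteen-infusion PNOC009 trial
tables as plain CSV fixtures. One call reproduces the published
endpoints:

```r
library(cedtrace)
run_pipeline(run_config(seed = 1))
#> <run_report>
#>   coverage: 6 patients, mean coverage 35.4%
#>   OS12 (lost_as_event): 67% (CI 38-100), median 13.7 months
#>   OS12 (lost_censored): 80% (CI 52-100), median 14.3 months
```

The coverage block says that across the six patients the tracer covered
on average 35.4% of the tumor volume. The survival lines show how the
lost-to-follow-up policy moves the 12-month overall survival estimate:
counting the loss as an event gives 67% (95% CI 38–100), censoring it
gives 80% (52–100) with a median OS of 14.3 months.

The per-metric cohort summary:

```r
build_coverage_table(pnoc009_infusions())
#> <coverage_summary: 6 patients, 13 treatments, Vd/Vi basis 'first_infusion'>
#> # A tibble: 6 × 5
#>   metric                    n  mean    sd sd_population
#>   <chr>                 <int> <dbl> <dbl>         <dbl>
#> 1 tumor_volume_cm3          6  28.9   8.8           8
#> 2 vd_per_infusion_cm3      13   6.2   2.1           2
#> 3 coverage_percent          6  35.4  17.7          16.2
#> 4 vd_vi_ratio               6   2.6   0.8           0.7
#> 5 outside_tumor_cm3         6   1.4   1             0.9
#> 6 infusion_duration_min    13 362.   65            62.4
```

Mean baseline tumor volume 28.9 ± 8.8 cm³, mean per-infusion Vd
6.2 ± 2.1 cm³, first-infusion Vd/Vi 2.6 ± 0.8, mean infusion duration
361.6 ± 65 min.

A synthetic end-to-end check of the imaging chain:

```r
ph <- generate_phantom(phantom_spec(), seed = 1)
roi <- binary_mask(array(TRUE, dim(ph$pre_t1$voxels)))
m  <- measure_vd(ph$pre_t1, ph$post_t1, roi, ph$reference_mask)
dice_coefficient(m$vd_mask, ph$vd_truth)   # ~0.99 at SNR 10
```

An `inst/scripts/run_pipeline.R` wrapper exposes the pipeline from the
shell (`Rscript run_pipeline.R --config run.json`).

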