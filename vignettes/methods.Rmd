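---
title: "Methods: subtraction volumetry, coverage, survival and design simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtraction volumetry, coverage, survival and design simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, estimators and design choices behind
`cedtrace`, in the spirit of a statistical-methods appendix: what is
computed, under which assumptions, which parameters matter, and where
the design was genuinely open.

## The measurement problem

Convection-enhanced delivery (CED) pushes drug through a catheter
directly into brain tissue. Because the drug itself is invisible on MRI,
a gadolinium tracer (gadoteridol) is co-infused: its T1-shortening
raises the T1-weighted signal wherever infusate spreads. The
quantity of interest is the distribution volume **Vd** — the tissue
volume showing tracer-attributable signal change — and derived metrics:
the convection efficiency **Vd/Vi** (distribution volume per millilitre
infused) and the **tumor coverage**, the percentage of the FLAIR-defined
tumor overlapped by the union of all treatments' Vd masks.

The difficulty is that the pre- and post-infusion scans differ by more
than the tracer: patient position changes and global scanner intensity
drift. The subtraction method therefore has three stages, each with an
explicit model.

## Subtraction volumetry

**Registration.** `register_rigid()` estimates the rigid transform
(rotation + translation) minimising mean squared intensity difference,
initialised by the integer-voxel shift maximising FFT cross-correlation
and refined by Nelder–Mead over six parameters. Same-session pairs are
assumed pre-aligned by default (`register = FALSE` in `measure_vd()`);
the optimiser is there for when it is needed. Deformable registration is
out of scope — brainstem anatomy between same-day scans is well
approximated as rigid.

**Intensity normalisation.** The scanner drift between scans is modelled
as a single global affine map `post = a * true + b`. Inside an
anatomical reference structure untouched by the infusion, pre and post
image identical tissue, so matching the reference-mask mean and standard
deviation identifies the drift:

```
scale  = sd_ref(pre) / sd_ref(post)
offset = mean_ref(pre) - scale * mean_ref(post)
```

Mean/SD matching is the minimal invertible model; full histogram
matching would add parameters without a validation signal. One property
of this estimator matters in practice: with additive noise of standard
deviation σ on the post scan, `sd_ref(post)` is inflated to
`sqrt(a² sd_ref² + σ²)`, so the scale estimate is biased low unless the
reference structure's *internal* contrast dominates the noise. Anatomy
normally guarantees this; the synthetic phantom makes it explicit by
giving its reference structure an internal intensity ramp and fine
texture (standard deviation ≈ 9 intensity units against the default
noise σ = 5). A nearly homogeneous reference would degrade the method —
that is a property of variance matching itself, not of this
implementation, and is the reason `normalize_post()` refuses a
zero-variance reference outright.

**Segmentation.** Voxels in the region of interest where
`post_norm − pre > k * sigma_residual` are kept, where `sigma_residual`
is the standard deviation of the normalised difference inside the
reference mask — the only stated uninfused calibration region. The
threshold multiplier defaults to `k = 3` (a 0.13% one-sided false-positive
rate per voxel under Gaussian noise). Two cleanups follow: connected
components smaller than `min_component_cm3` (default 0.05 cm³) are
dropped as noise speckle, and interior holes are filled so enclosed
hypointense (cystic/necrotic) compartments count as covered. The
threshold is floored at 10⁻⁶ of the pre-image dynamic range: with
noise-free inputs the estimated sigma collapses to floating-point dust,
and "strictly positive difference" must not segment rounding error. The
degenerate case is flagged on the returned mask.

The ROI stands in for the manual gross delineation of the infused
region; for phantoms the whole grid is a valid default because the
cleanups handle the speckle. `mask_volume_cm3()` is an exact voxel
count times the physical voxel volume; all rounding (one decimal, ties
away from zero, `round_half_up()`) happens at presentation only.

**Tumor segmentation.** The proprietary semi-automatic planning tool
used clinically is re-implemented as seeded region growing on FLAIR at a
user threshold, followed by hole filling (cystic compartments are
tumor). This reproduces the *contract* — connected hyperintense
component containing the seed, holes included — not any vendor's exact
output.

## The synthetic phantom

`generate_phantom()` builds the study's imaging conditions from known
ground truth: a deterministic pre-infusion T1 (smooth background
texture, a brighter reference structure with internal contrast), a FLAIR
with an ellipsoidal hyperintense tumor, and a post-infusion T1
constructed literally from the corruption model the pipeline assumes:

```
post = drift_scale * pre + drift_offset + delta_intensity * 1[vd_truth] + noise
```

The ground-truth Vd is an ellipsoid with an optional planar cap carved
away (`blocked_fraction`), mimicking tissue regions that blocked
infusate spread. The cap touches the ellipsoid surface (its plane
position solves the spherical-cap volume equation), so the carved
region is not an interior hole that filling would undo. Default
geometry: 64³ voxels at 1 mm, a ≈ 29 cm³ tumor and a ≈ 6.2 cm³ infusate
ellipsoid, matching the observed cohort means; unit tests use a 36³
variant for speed. Defaults `delta_intensity = 50`, `noise_sigma = 5`
set signal-to-noise at 10, with drift `(1.1, 15)` making the
normalisation step consequential.

Discretisation: masks are voxel-centre indicators, so a rasterised
ellipsoid's volume differs from the analytic `4/3 π abc` by a
surface-shell term — under 1% for a 10 mm sphere at 1 mm voxels, a few
percent once the cap plane is added. Tests assert the analytic volume at
those bounds, and segmentation accuracy is always judged against the
voxelised truth.

What the phantom does *not* emulate: convection physics (no
pore-pressure PDE — the carved ellipsoid is a geometric stand-in),
pulse-sequence effects, spatially varying bias fields, partial-volume
intensities, or concentration-dependent tracer detectability (the
trial's late low-concentration infusion visibly underestimated Vd;
nothing in the generator reproduces that). Passing phantom tests
therefore validates the computational chain under its stated corruption
model, not clinical segmentation accuracy.

The cohort generator draws survival times exponential with median
14.3 months (the observed median), loses patients to follow-up with
probability 1/6 (one of six in the cohort) at a uniform fraction of
their latent death time, censors administratively at 72 months, and
draws per-cycle, per-dose toxicity from Bernoulli probabilities.
Synthetic infusion durations are normal(361.6, 65) truncated at zero,
the observed distribution. The infusion-rate ramp schedule is left as a
configuration table: published descriptions of ramped CED protocols do
not pin down a unique schedule, and no result here depends on it.

## Coverage metrics

Per patient, the total distribution volume is the voxel-wise union of
per-treatment Vd masks (nearest-neighbour resampled onto the baseline
lattice), never the sum — repeated treatments overlap, so
`total_vd ≤ Σ vd` is enforced as an invariant. Coverage is
`100 * covered / tumor`. When only scalar volumes are available (the
published table), the per-patient totals are taken from the table rather
than recomputed; the mask-based and table-based routes share one output
schema.

Two conventions needed fixing against the published table:

* **Vd/Vi basis.** The cohort Vd/Vi statistic is computed over each
  patient's *first* infusion (one value per patient, default
  `vd_vi_basis = "first_infusion"`). This is the only basis consistent
  with the published cohort value of 2.6 ± 0.8; pooling all thirteen
  infusions gives 2.2 (both are computed in the test suite). It is also
  the defensible estimator: only the first infusion's Vd is
  attributable to a single treatment. The alternatives remain available
  as options.
* **SD convention.** Published tables mix sample (n−1) and population
  (n) standard deviations (the outside-tumor SD matches the population
  form, the tumor-volume SD the sample form), so `cohort_summary()`
  reports both; means are the quantities of record.

Published per-patient percentages do not all recompute exactly from the
rounded printed volumes (13.5/21.1 → 64.0 vs a printed 63.7): the
originals were evidently computed pre-rounding. The table route
therefore carries the printed percentage alongside the recomputed one.

## Survival endpoints

Overall survival runs from diagnosis to death; patients without a
recorded death contribute their off-study time. With one of six patients
lost to follow-up, the handling of that patient is material, so both
policies are first-class: `lost_as_event` (conservative) and
`lost_censored` (conventional). `km_fit()` delegates the product-limit
computation to `survival::survfit()` with `conf.type = "log"` — the
log-transformed Greenwood interval `exp(log S ± z se(log S))`, truncated
to [0, 1]. This CI type is the one that reproduces the published
intervals for both policies from the tabulated times; the hand-rolled
product-limit oracle in the test suite verifies estimates and intervals
to 10⁻¹² on all small inputs. Conventions: deaths precede censorings at
tied times; the median is the smallest event time with S(t) ≤ 0.5 and is
undefined (NA) when the curve never reaches 0.5; the CI collapses to the
estimate where it is degenerate (before the first event, and after S
hits zero, where the log interval is undefined). Querying the curve
beyond the last follow-up returns the last value with a truncation flag
rather than extrapolating.

## Dose-escalation design

The design is an accelerated titration phase with single-patient
cohorts and a rule-triggered conversion to a standard 3+3. A
dose-limiting toxicity (DLT) is an intolerable grade 2 or any grade ≥ 3
neurological toxicity related to the procedure or infusion, or any
related systemic grade ≥ 3 toxicity except managed
nausea/vomiting/diarrhea, within 14 days of the last infusion.
Tolerability of a grade 2 event is an input flag: it is a clinical
adjudication and cannot be computed.

Interpretation choices the published rule text leaves open, fixed here
and exercised by the replay test of the actual six-patient history:

* The cycle-1 "second grade ≥ 2 occurrence" tally counts
  *treatment-related* grade ≥ 2 events only, and one patient can
  contribute several (in the actual trial a single patient's second
  related grade 2 event triggered the conversion, while an earlier
  unrelated grade 3 in another patient did not count). Outcomes
  therefore carry an occurrence count, not just a maximum grade.
* On conversion, the triggering patient counts toward the first 3+3
  triplet, so two further patients complete it — the reading that
  matches the actual trial's enrollment arithmetic.
* Intra-patient dose modification (escalate on grade 0–1, hold on
  tolerable grade 2, de-escalate on DLT) is tracked separately from the
  cohort's enrollment level: one patient's de-escalation does not move
  the cohort, which matches later patients continuing at the higher
  level in the actual trial.
* In the accelerated phase, a grade 0–1 outcome at the top configured
  level declares that level the recommended phase 2 dose; without this
  the accelerated phase would enrol indefinitely at the top level.

`simulate_trial()` draws per-patient cycle-1 outcomes categorically
(DLT with `p_dlt[dl]`; else tolerable grade 2 with `p_grade2[dl]`; else
grade 0–1) and advances the state machine; `enumerate_trial()` walks the
same machine over every outcome branch with exact probabilities,
memoised on the decision-relevant state, giving the exact outcome
distribution that the Monte-Carlo harness is checked against (10 000
replicates, agreement within three binomial standard errors, in the
test suite).

## Problem sizes and numerical tolerances

Unit tests run on 36³ phantoms; the seeded-recovery check uses 20
phantoms at SNR 10 and asserts Dice ≥ 0.90 with mean absolute volume
error ≤ 5% — comfortably above what the chain achieves (≈ 0.99 Dice),
the margin covering the variance-matching bias discussed above.
Noise-free phantoms must be recovered *exactly* (voxel-identical masks),
including under any affine drift with scale in [0.8, 1.2] and offset in
[−30, 30]. Oracle comparisons (product-limit, two-pass mean/variance)
use 10⁻¹² tolerances; registration recovers an exact two-voxel shift to
0.1 mm and a sub-voxel shift under 2% noise to 0.5 mm.

## Known limitations

Registration is intensity-based rigid only, and its Nelder–Mead
refinement can in principle stall on low-texture images (it falls back
to the FFT initialisation when refinement does not improve the
criterion). The normalisation model is a single global affine map —
spatially varying bias is not corrected. The escalation simulator models
cycle-1 decisions; multi-cycle intra-patient trajectories are supported
in replay but not simulated stochastically. The phantom's noise is
i.i.d. Gaussian, which is optimistic relative to Rician MRI noise at low
SNR; at the SNR ≈ 10 regime simulated here the distinction is
negligible.
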