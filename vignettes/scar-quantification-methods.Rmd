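---
title: "Quantifying infarct core and peri-infarct zone on CE-CMR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying infarct core and peri-infarct zone on CE-CMR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrscar)
```

## The measurement problem

On late gadolinium enhancement (LGE) images, infarcted myocardium retains
contrast and appears bright; chronically viable myocardium appears dark
gray. The scar is not homogeneous: a densely fibrotic *core* is bordered
by a *heterogeneous (peri-infarct) zone* of admixed viable and fibrotic
tissue, which is electrophysiologically interesting because it can host
reentry circuits. `cmrscar` quantifies both zones with the
full-width-at-half-maximum (FWHM) rule and propagates them into the
segmental, territorial and cohort-level summaries used in clinical
arrhythmia research.

## The FWHM model and its assumptions

Let $\mathrm{SI}_{\max}$ be the maximal signal intensity over the
intersection of an analyst-drawn hyperenhancement region of interest with
the myocardium. Each myocardial voxel with intensity $s$ is labelled

- **core** if $s \ge 0.50\,\mathrm{SI}_{\max}$ (the "half maximum");
- **peri-infarct** if $0.35\,\mathrm{SI}_{\max} \le s < 0.50\,\mathrm{SI}_{\max}$;
- **unenhanced** otherwise.

Total scar is core plus peri. Zone sizes are reported as percentages of
the LV myocardial voxel count of the CE stack — the denominator is the
whole myocardium, not the enhanced region. Both thresholds are *relative*,
so the classification is exactly invariant under multiplication of all
intensities by any positive constant; it is **not** invariant under
additive offsets, which change intensity ratios — the scale-invariance
tests therefore exercise positive rescaling only. Assumptions worth
keeping in mind:

- The reference $\mathrm{SI}_{\max}$ is a single global maximum per study
  (a per-slice mode exists behind `perSlice = TRUE`). Under noise the
  sample maximum of $n$ voxels is biased upward by roughly
  $\sigma\sqrt{2\log n}$, which inflates both thresholds
  multiplicatively; a `topK` option averages the brightest $k$ voxels to
  damp this, but the plain maximum is the default and is what all
  shipped validation uses.
- The drawn ROI is authoritative: if it excludes the brightest voxel,
  the maximum over what it covers is used. ROI discipline matters —
  including blood pool would inflate the reference — and is testable
  with the phantom, whose blood pool is deliberately brighter than
  remote myocardium.
- Voxels are classified independently; no minimum-cluster or
  morphological cleanup is applied (none is part of the method), and
  hypo-enhanced microvascular obstruction is not reclassified into the
  core.
- Threshold boundaries are inclusive exactly as stated: $s = 0.50\,
  \mathrm{SI}_{\max}$ is core, $s = 0.35\,\mathrm{SI}_{\max}$ is peri.

## Geometry conventions

Contour coordinates are millimetres in the image plane, origin at the
centre of pixel (0, 0), x along columns, y along rows. A voxel belongs to
a region when its *centre* is inside the polygon; the myocardium is
"inside epicardium and not inside endocardium". All rasterization —
phantom truth and analysis path alike — uses this one convention, which
is what makes exact noiseless recovery a genuine identity rather than an
approximation.

The AHA 17-segment model is applied per slice: slices with myocardium are
split base-to-apex into basal/mid/apical tiers of near-equal slice counts
(ties go basal-ward); basal and mid tiers carry six 60° sectors
(segments 1–6, 7–12), the apical tier four 90° sectors (13–16, rotated
45° so sector centres are anterior/septal/inferior/lateral), and slices
flagged as having a closed cavity become the apical cap (17). The angular
origin is the ray from the LV centre to the anterior RV insertion point,
with sector index increasing with `atan2`-angle from that ray; the
chirality is fixed and documented because a mirrored assignment is a
silent error. Rotating the image together with the landmarks leaves
labels unchanged (tested). Territories default to LAD {1,2,7,8,13,14,17},
RCA {3,4,9,10,15}, LCX {5,6,11,12,16} and are configurable because
institutional variants exist; whether the apical cap enters regional
scores is controlled by supplying a custom map.

Scoring conventions: the printed integer scar-score bins ("1–25%",
"26–50%", …) are applied to continuous percentages as the unique
consistent half-open partition $(0,25], (25,50], (50,75], (75,100]$ with
$0 \mapsto 0$ — so 25.4% scores 2. Segmental scar uses *total* scar
(core + peri). Transmural extent counts observed segments scoring 3–4.
Regional scores are unweighted means of segment scores per territory.
WMSI averages wall-motion grades 0–4 over *observed* segments —
unobserved segments must be `NA`, never 0, because the index divides by
the observed count. (This 0–4 scale differs from the echocardiographic
1–5 convention; it is implemented as used in the CMR literature this
package follows.)

## Volumetrics

Disc summation: cavity volume is $\sum_i A_i\,(t + g)$ over slices with
an endocardial contour, with $A_i$ the polygon area, $t$ the slice
thickness and $g$ the inter-slice gap (default 0; the gap of a clinical
CE stack is acquisition-dependent and therefore user-supplied). Mass is
(epicardial − endocardial volume) × 1.05 g/ml. Papillary muscles are by
convention part of the cavity. LVEF is $100(EDV-ESV)/EDV$; note that a
group's mean LVEF is the mean of per-patient EFs, which is *not* the EF
of the group-mean volumes (284/222 ml give 21.8%, while a printed group
mean can be 23%). BSA uses Mosteller
$\sqrt{h_{cm} w_{kg}/3600}$ by default with DuBois as an option; the two
differ by well under 5% over physiologic adult builds.

## The synthetic phantom

Because patient scans cannot be redistributed, validation rests on a
generator of short-axis stacks with exact ground truth. Per slice, the
phantom is an annulus (endocardial/epicardial circles realized as
256-gon contours) around a bright blood pool; scar is an angular wedge
from the endocardium out to a chosen transmurality, split radially into
a core plateau and an outer rim at the intermediate border intensity.
Intensities are plateaus plus additive Gaussian noise (Rician optional);
truth masks, zone percentages and per-segment scar are computed on the
noiseless labels.

Default conditions emulate the dilated post-infarct ventricles of an ICD
cohort on a clinical LGE protocol: 10 slices of 10 mm, 1.4 mm pixels,
endo/epi radii 22/32 mm, a 90° wedge at 60% transmurality with a 30%
border rim, plateaus core 100 / border 42.5 / remote 15 / blood 70
(arbitrary units), noise SD 2. The border plateau sits mid-way inside
the 35–50% band and remote myocardium well below 35%, so the thresholds
bracket the plateaus; no published intensity statistics exist for these
tissues, so the levels are free parameters chosen once for realism, not
calibrated to any dataset. Noise SD 2 corresponds to a core-to-remote
contrast-to-noise ratio of ≈42, diagnostic quality; at much lower SNR
the maximum-bias described above degrades peri-zone recovery first,
because the inflated 35% threshold climbs past the border plateau.

What the phantom does *not* emulate: partial-volume averaging (labels
are decided at voxel centres, keeping truth exactly reproducible),
cardiac motion blur, inversion-recovery nulling artefacts, coil
inhomogeneity, and anatomically realistic scar shapes. Passing recovery
tests therefore demonstrates correctness of the *computational* chain,
not clinical accuracy on real images.

`phantomCohort()` draws per-phantom parameters uniformly from per-group
ranges; with identical ranges it yields null cohorts for calibration
experiments, with disjoint ranges known effect sizes for power checks.
Group sizes 66/29 mirror a typical primary/secondary-prevention split.

## Statistical layer

Continuous variables: Student's t (classical equal-variance form;
Welch behind a flag) or Mann–Whitney U, auto-selected by Shapiro–Wilk
normality (both groups p > 0.05 → t). Categorical: Pearson chi-square
(no Yates correction by default) or Fisher's exact test, auto-selected
by the expected-cell-below-5 rule; both rules are this package's
documented conventions, since published reports list the tests without
itemizing the mapping. The two-sided Fisher p is the sum of
probabilities of all tables (at fixed margins) no more probable than
the observed one — stated explicitly because two-sided conventions
differ. At margins like 12 events among 95 patients split 66/29, the
expected-cell rule always selects Fisher, whose discreteness makes the
realized type-I rate conservative (below nominal); the calibration
experiments therefore assert the nominal rate for the continuous test
and a 0.065 upper bound for the categorical arm.

## Numerical choices and degenerate inputs

- Point-in-polygon is ray-crossing (`mgcv::in.out`); circle contours are
  realized as polygons whose edges are tangent to the target circle, so
  voxel-centre containment matches the analytic disc to a sliver below
  3 µm at clinical radii.
- Polygon simplicity is checked by exact segment-pair crossing tests;
  self-intersecting contours are geometry errors, as are endocardial
  contours not contained in epicardial ones (coincident contours are
  allowed and mean zero wall).
- Degenerate statistics fail loudly: constant identical samples under t,
  empty myocardium, zero table margins, ROI disjoint from myocardium,
  zero observed segments for WMSI.
- Readers never default silently: a stack without spacing or thickness
  metadata is a metadata error. NIfTI stores pixdim in single precision;
  voxel values round-trip exactly.

## Problem sizes used in shipped experiments

The validation suite and `scripts/acceptance.R` use reduced phantoms
chosen to make the experiments quick to re-run while keeping every
mechanism engaged: recovery experiments use 6-slice, 64×64 stacks
(5 noiseless phantoms; 100 noisy replicates), scale invariance 50
random 3-slice phantoms, calibration 200 null cohorts of 95
two-slice 24×24 phantoms each, and the Fisher/Mann–Whitney enumeration
oracles 500/8 random instances. These sizes are stated here as the
package's own experimental design.

## Known limitations

- Wall-motion grades are expert inputs; no cine analysis is performed.
- The maximum-based FWHM reference is noise-biased (see above); the
  robust `topK` variant is available but off by default to match the
  method as practised.
- Survival/interaction modelling of events over follow-up is out of
  scope; the package stops at the contingency comparison.
- The phantom's apex never closes (annular slices only), so segment 17
  appears only via the `cavityClosed` flag, and phantom-based regional
  scores treat the cap as unobserved.
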