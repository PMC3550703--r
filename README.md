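# cmrscar

Infarct tissue characterization on contrast-enhanced cardiovascular
magnetic resonance (CE-CMR).

## What it does, and for whom

After a myocardial infarction, gadolinium accumulates in scar, which
appears hyperenhanced on T1-weighted late-enhancement images against the
dark gray of viable myocardium. Clinical researchers studying arrhythmic
risk — for instance comparing ICD (implantable cardioverter-defibrillator)
recipients implanted for primary versus secondary prevention — need
reproducible, quantitative descriptions of that scar. `cmrscar` implements
the full analysis chain from segmented short-axis stacks to the
group-comparison tables such studies report:

- **FWHM scar zones.** With `SI_max` the maximal signal intensity in the
  analyst-drawn hyperenhancement region, each myocardial voxel is
  labelled *infarct core* when `SI >= 0.50 * SI_max`, *peri-infarct
  (heterogeneous) zone* when `0.35 * SI_max <= SI < 0.50 * SI_max`, and
  unenhanced otherwise. Core, peri and total (core + peri) scar are
  reported as a percentage of the LV myocardial voxel count.
- **AHA 17-segment model.** Six basal, six mid-cavity and four apical
  60/90-degree sectors plus the apical cap, numbered from the anterior RV
  insertion point; segments map onto the LAD / RCA / LCX coronary
  territories. Per-segment scar percentage is binned into the scar score
  (0; 1 = 1–25%; 2 = 26–50%; 3 = 51–75%; 4 = 76–100% of segmental area),
  *transmural extent* counts segments scored 3–4, regional scores average
  the segment scores per territory, and the wall motion score index
  (WMSI) averages expert wall-motion grades (0 normal … 4 dyskinesia)
  over observed segments.
- **LV volumetrics.** Disc summation over endo/epicardial contour
  polygons: EDV, ESV, LVEF = 100·(EDV−ESV)/EDV, wall mass (density
  1.05 g/ml), and body-surface-area indexed variants (Mosteller BSA by
  default).
- **Cohort statistics.** Student t / Mann–Whitney U for continuous
  variables and chi-square / Fisher exact for 2×2 tables, with documented
  auto-selection rules and table-style group summaries with strata.
- **Synthetic phantoms.** `generatePhantom()` builds short-axis stacks
  with an annular myocardium, a scar wedge (core plateau + intermediate
  border rim), blood pool and Gaussian noise — with exact voxel-level
  ground truth, so the whole pipeline is validated end to end.

## Worked example

```r
library(cmrscar)

ph <- generatePhantom(phantomSpec(nSlices = 6, gridSize = 64,
                                  pixelSpacingMm = 2, seed = 7))
res <- characterizeScar(ph$stack, truthContours(ph$truth))
round(res$fractions, 2)
#>  core  peri total
#>   7.4   3.5  10.9
round(truePercentages(ph$truth), 2)
#>  core  peri total
#>   7.4   3.5  10.9

lm <- landmarks(truthContours(ph$truth))
seg <- assignSegments(truthMask(ph$truth), lm$lvCenter, lm$rvInsertion,
                      pixelSpacing(ph$stack))
scores <- scarScore(segmentScarPct(res$scarMap, seg))
transmuralExtent(scores)
#> [1] 2
regionalScores(scores)
#> LAD RCA LCX
#> 0.0 0.4 2.0

compareCategorical(eventTable(3, 66, 9, 29))$p_value
#> [1] 0.000921332
```

The recovered zone fractions equal the phantom's ground truth (7.4%
core, 3.5% peri) because the intensity plateaus sit on either side of
the 35%/50% thresholds; two segments are more than half scarred
(transmural extent 2), the wedge lies mainly in LCX territory, and the 2×2
event comparison (3 of 66 vs 9 of 29) is significant by Fisher's exact
test.

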