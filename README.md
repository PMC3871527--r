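# dcepk — DCE-MRI transvascular parameters with nested-model selection and test–retest statistics

`dcepk` implements a complete dynamic contrast-enhanced (DCE) MRI analysis
workflow for paired test–retest small-animal glioma studies, together with
a synthetic cohort generator that makes every stage verifiable against
known ground truth. It targets researchers who quantify acute
vascular-normalization effects of anti-angiogenic drugs with imaging
biomarkers.

Per voxel, tissue contrast-agent concentration is described by three
nested kinetic models driven by the plasma curve Cp(t):

* Model 1 — intact vasculature: `Ct = vp·Cp`
* Model 2 — Patlak influx, no backflux: `Ct = vp·Cp + Ktrans·∫Cp`
* Model 3 — extended Tofts with backflux: `Ct = vp·Cp + Ktrans·∫Cp(u)·exp(−kep(t−u))du`, with `ve = Ktrans/kep`

The pipeline estimates pre-contrast T1 from a Look-Locker
inversion-recovery series (three-parameter magnitude fit with the
`T1 = T1*·(B/A − 1)` correction), removes T2\* effects by dual-echo
extrapolation, inverts the spoiled gradient-echo signal equation for
concentration, fits the nested models by separable least squares, and
assigns each voxel a model order by sequential F-tests (order 3 requires
both steps significant at α = 0.05). Cohort-level statistics on the
Model-3 region reproduce the test–retest design: paired t-tests per
treatment time, one-way ANOVA, and a planned contrast of pooled early
(2 & 4 h) versus late (12 & 24 h) treatment groups tested against the
ANOVA pooled error. An ADC map from the two-b-value diffusion pair is
included for tumor localization context.

## Worked example

The `analysis/` scripts run the workflow end to end and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R    # simulate the 31-animal cohort
Rscript analysis/02_fit_parameter_maps.R # maps for one example animal
Rscript analysis/03_test_retest_stats.R  # full cohort statistics
```

The simulated design is five treatment-time cohorts (2, 4, 8, 12, 24 h;
n = 7, 6, 6, 6, 6) imaged twice 24 h apart at SNR 30, with each animal's
true (vp, Ktrans, ve) shift drawn from its group's Gaussian. The third
script prints, for one seeded cohort:

```
Planned contrast (2&4 h pooled vs 12&24 h pooled), ANOVA pooled error:
  ktrans estimate +0.00516 (SE 0.00184), t(26) = +2.80, p = 0.0095
  ve     estimate +0.00431 (SE 0.00822), t(26) = +0.52, p = 0.6045
  vp     estimate +0.00054 (SE 0.00172), t(26) = +0.32, p = 0.7537
```

i.e. for this cohort draw the early groups' Ktrans rose and the late
groups' fell, the contrast estimate `mean(pooled 2&4) − mean(pooled
12&24)` is +0.0052 min⁻¹, and only Ktrans reaches significance — vp and
ve shifts of this size are hard to detect at n = 25. The same run writes
`cohort_table.csv` (per-animal ROI summaries and differences),
pooled-difference tables in absolute and percent modes, a boxplot-ready
percent-difference table, and a JSON stats report, all stamped with the
configuration hash and seed; rerunning with the same configuration is
byte-identical.

The same computations are available programmatically:

```r
library(dcepk)
res <- run_cohort(design = cohort_design(), spec = acq_spec(),
                  snr = 30, seed = 1234)
res$pooled$absolute               # pooled group differences
res$stats$ktrans$anova_contrast   # ANOVA + planned contrast
```

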