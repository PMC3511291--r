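# lungrecruit

Model-based analysis of step-wise PEEP recruitment manoeuvres in
mechanically ventilated subjects, for researchers in respiratory
mechanics and model-based ventilation monitoring.

Acutely injured (ARDS) lungs contain collapsed alveoli that reopen only
above a unit-specific threshold opening pressure (TOP) and collapse again
below a threshold closing pressure (TCP). Treating the lung as a large
population of such units with normally distributed thresholds gives the
minimal recruitment model

    V(P) = 1/2 * (1 + erf((P - mean) / (sqrt(2) * SD))) * TLC

where `V(P)` is the recruited volume at airway pressure `P` (cmH2O),
`mean` is the pressure of the maximum recruitment rate, `SD` the spread
of the threshold distribution (lung heterogeneity), and `TLC` the
recruitable capacity. Fitting this curve to the inflation and deflation
limbs of per-PEEP pressure-volume (PV) curves yields patient-specific
(mean TOP, SD) and (mean TCP, SD) estimates; tracking (mean TOP, SD) on
a four-panel disease-state-grouping (DSG) plane follows a subject from
health into injury and back.

The package implements the full chain:

- `sample_unit_population()` / `simulate_rm()` / `simulate_scenario()` —
  a hysteretic multi-unit lung simulator that generates volume-controlled
  manoeuvre waveforms (PEEP 5→20 cmH2O in 5-cmH2O steps, Vt = 12 ml/kg)
  with known ground truth, including the trapped end-expiratory volume
  after each PEEP step, measurement noise and optional auto-PEEP;
- `segment_breaths()`, `select_representative_breath()`,
  `estimate_trapped_volume()`, `build_pv_curves()` — waveform processing
  from raw pressure/flow traces to stacked per-PEEP PV curves;
- `fit_limb()` / `fit_manoeuvre()` — bounded Levenberg-Marquardt
  estimation of (mean, SD, TLC) per limb and PEEP with a
  mean-absolute-percentage fitting error (MAPE);
- `summarize_fits()`, `wilcoxon_rank_sum()`,
  `compute_static_compliance()`, `assign_dsg_panel()`, `track_dsg()` —
  median/IQR summary tables, an exact rank-sum test, and DSG placement
  and trajectory labelling.

Bundled under `inst/extdata/` are per-subject reference estimates from a
piglet PEEP-titration study (nine healthy animals, three re-studied after
oleic-acid lung injury) used by the summary stage, and the two seeded
scenario configurations the analysis scripts simulate.

## Worked example

The numbered scripts under `analysis/` run the whole workflow and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # scenario waveforms + ground truth
Rscript analysis/02_process.R    # breaths, trapped volumes, PV curves
Rscript analysis/03_fit.R        # per-PEEP, per-limb model fits
Rscript analysis/04_report.R     # summary tables, rank-sum tests, DSG
```

which prints, among other lines:

```
healthy: 48 breaths at 5/10/15/20 cmH2O; trapped volumes (0->5, 5->10, 10->15, 15->20) = 130.4, 94.7, 153.8, 247.9 ml
healthy: fitted mean TOP across PEEP 5/10/15/20 -> 49, 47.8, 39.9, 17.5 cmH2O (max MAPE 3.24%)
ards: fitted mean TOP across PEEP 5/10/15/20 -> 61.5, 60.2, 51.2, 25.2 cmH2O (max MAPE 3.82%)
healthy mean TOP at PEEP 5: 42.4 [38.2-44.6] cmH2O
injured-state average TOP at PEEP 5: 55.2 cmH2O
subject 6: healthy (panel B) -> ards (panel C): worsening
```

Reading the numbers: each PEEP increment traps additional end-expiratory
volume (the recruited lung does not fully empty), the fitted mean TOP
falls as PEEP recruits the lung and rises ~12 cmH2O from the healthy to
the injured scenario at every PEEP, fitting errors stay in the few-percent
range, and the summary stage reproduces the reference median [IQR] cells
from the bundled per-subject values. On the DSG plane the injured subjects
leave the healthy low-TOP/low-SD panel B.

A minimal in-R session:

```r
library(lungrecruit)
sc  <- healthy_scenario()
rec <- simulate_scenario(sc, seed = 1)
br  <- segment_breaths(rec)
cv  <- build_pv_curves(rec, br, resistance = 0.02)
fit_manoeuvre(cv, tlc_max = "auto")[, c("peep_cmH2O", "limb", "mean_cmH2O",
                                        "sd_cmH2O", "mape_pct")]
```

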