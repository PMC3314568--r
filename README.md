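# luxchar

Quantitative characterization of a LuxR/HSL-inducible promoter device across
DNA copy-number contexts, from raw microplate kinetics to the promoter's
transfer function with respect to its actual intracellular inducer.

## The problem

Synthetic-biology devices are routinely characterized on multicopy plasmids,
but their output does not scale linearly with gene dosage: transcription and
translation saturate at high copy number. For an HSL-inducible device
(constitutive *luxR* cassette plus a *luxI*-promoter-driven RFP reporter) the
copy number of the LuxR cassette varies together with the reporter's, so
induction curves measured against the HSL concentration are not comparable
across copy-number conditions — the same dose yields different amounts of the
actual activator, the HSL–LuxR complex. `luxchar` implements the full
analysis pipeline for this problem, for experimentalists characterizing
promoter devices in plate readers and for modelers studying gene-dosage
nonlinearity:

1. **Kinetics** — background-subtracted OD600 and fluorescence time series,
   automated exponential-phase detection on ln(OD600), doubling time
   ln(2)/m, and the per-cell reporter synthesis rate
   S_cell = (dF/dt)/OD600 averaged over exponential growth (from 50 min
   after induction), normalized to detector gain 50 through a calibration
   curve.
2. **Relative Promoter Units** — RPU_x = S_cell,x / S_cell,ref against the
   J23101 reference device in the same condition, indirect copy-number
   estimation n ≈ S_cell(condition)/S_cell(single copy) from constitutive
   devices, and t-based 95% CIs over clones.
3. **Dose response** — nonlinear least-squares Hill fits
   Y = Vmax·I^q/(Km^q + I^q) with asymptotic per-parameter CVs.
4. **Model-based axis transform** — steady-state model
   X̄ = n·α_tet/γ_X, Ā = X̄/(1 + (K_H/H)^{n_H}),
   S_cell = n·α_lux/(1 + (K_A/Ā)^{n_A}), used to re-express induction
   curves as RPU vs the activated complex A and to estimate K_A, n_A and
   α_lux = Vmax·S_cell,ref/n per condition, plus the K_A-vs-copy-number
   trend and its robustness to 2-fold α_tet perturbation.
5. **Synthetic data** — a plate-reader generator (growth curves, gain
   response, background wells, measurement noise, clone variability) with a
   ground-truth manifest, so every estimator is testable by parameter
   recovery.

## Worked example

Simulate the full characterization experiment (two constitutive devices and
the inducible device, four copy-number conditions, 13 HSL doses, 3 clones,
default noise) and run the whole pipeline:

```r
library(luxchar)
res <- runCharacterization(seed = 1)
res$estimatesTable
```

```
 condition  vmax        kA     nA alpha_lux       n
        SC 8.350 0.0005174 0.7441     5.958   1.000
        LC 9.191 0.0008841 0.4364     5.966   3.749
        MC 4.743 0.0029300 0.5035     3.589  46.790
        HC 2.857 0.0315700 0.5036     2.160 116.500
```

Vmax is the full-induction activity in RPU; it drops from ~8.5 at single
copy to ~2.9 at high copy — the dose-limited saturation the device shows.
K_A rises monotonically with the estimated copy number n (rank correlation
1), i.e. the promoter appears to need more activated complex per copy as
dosage grows, while α_lux (the per-copy maximum synthesis rate, computed as
Vmax·S_cell,ref/n) falls. The run also summarizes the lacIQ control
promoter, whose relative activity is copy-number-stable:

```r
round(res$lacIQ$perCondition, 3)   #  SC 0.732  LC 0.878  MC 0.649  HC 0.650
round(res$lacIQ$grandMean, 3)      #  0.727
round(res$copyNumbers$mean, 2)     #  HC 116.50  LC 3.75  MC 46.79  SC 1.00
```

(Values vary with the seed; the generating truths are the published
characterization values in `referenceScell()`, `referenceDoublingTimes()`
and `referenceHillEstimates()`.)

## Acceptance script

`scripts/acceptance.R` recomputes the pipeline's desk-scale identities from
the published input tables through the installed package: the per-copy
maximum synthesis rate α_lux at single and high copy (via the unrounded mean
copy-number estimate) and the model's predicted full-induction RPU at single
copy. Run from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
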