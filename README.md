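# cnspbpk

Regional brain physiologically based pharmacokinetic (PBPK) modelling for
rat and human.

Most CNS pharmacokinetic models treat the brain as one or two lumped
compartments, which cannot say anything about *where* in the brain a drug
goes. `cnspbpk` implements a whole-body PBPK model whose CNS is resolved
into five compartments — intracranial blood, rest-of-brain, hippocampus,
frontal cortex and cerebrospinal fluid — so that regional extracellular
fluid (ECF) concentration-time profiles, the biophase sampled by brain
microdialysis, can be predicted from in vitro inputs. It is aimed at DMPK
and neuropharmacology scientists who want forward (non-fitted) predictions
of regional brain exposure, in rats or extrapolated to humans.

## The model in brief

* **Whole body**: 15 compartments (arterial/venous blood, lung, 12
  well-stirred perfusion-limited tissues with portal-vein topology).
  Tissue balance: `V_t dC_t/dt = Q_t (C_art − C_t·Rb/Kp_t)`.
* **Hepatic clearance** by the well-stirred liver model
  `CL_H = fu_p·CLint·Q_L / (Q_L + fu_p·CLint/Rb)`, with in vitro intrinsic
  clearance scaled through microsomal recovery (45 mg/g liver) or
  hepatocellularity (130e6 cells/g); **renal clearance** by GFR correction.
* **BBB permeability**: `PS = Papp × weight × surface area × CF`
  (150 cm²/g rat, 157 cm²/g human; regional weights for the regional
  compartments; CF swappable for a transporter REF; efflux ratio applied
  to the brain-to-blood direction).
* **CNS block**: unbound-gated BBB exchange per region, hub-and-spoke
  diffusion (HC↔ROB, FC↔ROB), ECF bulk flow to CSF (0.2 µL/min/g), CSF
  production/absorption at equal rates; regional amounts distribute in ECF
  volumes.
* **Summaries**: Cmax/tmax/AUC (trapezoid), `Kp_brain`,
  `Kp_uu,brain = fu_brain·AUC_brain / (fu_p·AUC_plasma)`, fold error
  `max(obs/pred, pred/obs)`, afe/rmse, 2-/5-fold bands.
* **Uncertainty**: Monte Carlo on the three regional ECF volumes
  (log-normal, 30% CV, median-preserving, ≥1000 joint draws), 5th/95th
  percentile bands and mean ± SD summaries.
* **Sensitivity**: 25×25 log-spaced sweeps of a region's BBB PS against its
  inter-regional PS over 0.01–100 mL/min, with 10-fold lower/higher
  rest-of-brain PS scenarios.

System parameters (tissue volumes/flows, CNS geometry) ship as validated
YAML fixtures. Compound profiles for the 11 bundled compounds are
**literature-informed synthetic reconstructions** (each field carries a
provenance string) and are meant to be edited; see the methods vignette
(`vignettes/regional-brain-pbpk.Rmd`) for what that implies.

## Worked example

Rat phenytoin, 50 mg/kg intraperitoneal, regional CNS model:

```r
library(cnspbpk)

spec <- model_spec(load_physiology("rat"), load_compound("phenytoin"),
                   cns = "regional", geometry = load_cns_geometry("rat"))
spec$clearances
#> <clearance_set: CL_H 0.5255, CL_R 0, CLint 4.5 mL/min>

res <- simulate_pbpk(spec, load_regimen("phenytoin_rat_ip"), duration = 480)
pk_summary(res, c("plasma", "rob", "hc", "fc", "csf"), units = "umol/L")
#>   compartment      cmax  tmax auc_0_last
#> 1      plasma 179.55359   6.3  45812.497
#> 2         rob  26.31945  10.4   7139.683
#> 3          hc  26.28353  10.5   7138.600
#> 4          fc  26.40167  10.1   7141.298
#> 5         csf  14.08501 184.9   5689.758

kpuu_brain(res$times, res$conc[, "hc"], res$conc[, "plasma"],
           spec$compound$fu_brain, spec$compound$fu_plasma)
#> [1] 0.9738882
```

Reading this: plasma peaks at 179.6 µmol/L 6.3 min after the IP dose (fast
absorption, ka = 0.25/min); the three brain regions equilibrate within
~10 min to about `fu_p/fu_brain` = 0.16 of plasma (the ECF sees only
unbound drug); CSF lags behind (tmax 185 min) because it fills through the
slow production and bulk flows. The AUC-ratio `Kp_uu` of 0.97 is what any
symmetric passive parameterization converges to (≈ the blood:plasma
ratio).

Higher-level drivers run whole workflows:

```r
run_case("phenytoin_rat")          # scale -> simulate -> Monte Carlo -> NCA
run_step1_panel()                  # 10-compound Kp_uu validation panel
ps_sweep(spec, load_regimen("phenytoin_rat_ip"), 480, sweep_spec("hc"))
```

A thin CLI wraps the same functions:

```sh
Rscript scripts/cnspbpk report --compound carbamazepine \
    --regimen carbamazepine_rat --duration 300 --out-dir out/
Rscript scripts/cnspbpk mc --n 1000 --cv 0.3 --seed 7 --out-dir out/
```

Every CLI run writes a JSON manifest (inputs, seed, version, outputs) for
bit-for-bit replay.

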