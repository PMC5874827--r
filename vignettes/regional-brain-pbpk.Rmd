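---
title: "Regional brain PBPK modelling with cnspbpk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional brain PBPK modelling with cnspbpk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cnspbpk` simulates whole-body drug disposition in rat and human with a
mechanistic central-nervous-system sub-model that resolves the hippocampus
(HC) and frontal cortex (FC) as separate compartments alongside the
rest-of-brain (ROB), intracranial blood (BB) and cerebrospinal fluid (CSF).
Its purpose is forward prediction of regional brain
extracellular-fluid (ECF) concentration-time profiles — the biophase sampled
by microdialysis — from in vitro and physiological inputs, without fitting
to the observed brain data.

# The model

## Whole-body backbone

Fifteen compartments: arterial and venous blood, lung, and twelve
well-stirred perfusion-limited tissues (adipose, bone, brain, gut, heart,
kidney, liver, muscle, pancreas, skin, spleen; the stomach is merged into
gut because no separate parameter row is available). For a non-eliminating
tissue $t$,

$$V_t \frac{dC_t}{dt} = Q_t\left(C_{art} - \frac{C_t\,R_b}{K_{p,t}}\right),$$

with $Q_t$ the tissue blood flow (mL/min), $V_t$ its volume (mL), $K_{p,t}$
the tissue:plasma partition coefficient and $R_b$ the blood:plasma ratio.
Gut, spleen and pancreas drain through the portal vein into the liver; the
liver additionally clears drug at the hepatic blood clearance $CL_H$ applied
to its emergent blood concentration, and the kidney clears at $CL_R$. The
lung bridges venous to arterial blood at cardiac output.

Cardiac output is computed as the sum of venous returns under the portal
topology rather than taken from the lung row of the perfusion table; the
human table is self-consistent to 0.2% under this rule, the rat table to
about 10%, and using the computed value makes the flow balance at the lung
exact — a property the test suite asserts. The hepatic artery carries
$Q_{liver} - Q_{gut} - Q_{spleen} - Q_{pancreas}$.

## IVIVE of clearance

In vitro intrinsic clearance is scaled to the whole liver with the standard
recovery factors (45 mg microsomal protein/g liver or 130e6 hepatocytes/g
liver, liver mass = 40 g/kg body weight in rat) and converted to organ
clearance with the well-stirred liver model

$$CL_H = \frac{fu_p \; CL_{int,\,in\,vivo} \; Q_L}
  {Q_L + fu_p\,CL_{int,\,in\,vivo}/R_b},$$

with the single $/R_b$ divisor kept exactly in this form (it is the form the
rest of the arithmetic is validated against, and it makes $CL_H$ saturate at
$Q_L R_b$). In vivo systemic clearances bypass this route: a blood clearance
is used directly as $CL_H$, a plasma clearance is divided by $R_b$ first.
Renal clearance follows a glomerular-filtration-rate correction: a
cross-species value scales by the GFR ratio, a fraction-of-filtration rule
returns $f \cdot fu_p \cdot GFR$, and compounds whose renal route is
excluded (phenytoin) return zero. GFR itself is not part of the transcribed
parameter tables, so the fixtures carry standard physiological defaults
(rat 1.31, human 125 mL/min), flagged as such in their provenance strings.

## Permeability scaling

In vitro apparent permeability scales to a permeability-surface-area
product

$$PS = P_{app} \times W \times SA \times CF,$$

with $W$ the brain weight (1.8 g rat, 1500 g human; for regional
compartments the regional tissue weight at unit density), $SA$ the
microvascular endothelial surface area (150 cm²/g rat, 157 cm²/g human) and
$CF$ an in vitro-in vivo correction factor, 1 by default. For transporter
substrates a relative expression factor (REF) occupies the same
multiplicative slot. A single reported $P_{app}$ makes the PS
bidirectional; efflux substrates multiply the brain-to-blood PS by the
efflux ratio. Fixtures may declare $P_{app}$ in the common
$10^{-6}$ cm/s convention; the loader converts to cm/min.

## The five-compartment CNS block

Intracranial blood receives arterial inflow $Q_{brain} C_{art}$ and returns
$Q_{brain} C_{BB}$ to the venous pool. Every exchange is gated by the
unbound concentration on its source side (only unbound drug crosses
barriers):

* BBB exchange per region $r$:
  $PS_{in,r}\,fu_p\,C_{BB} - PS_{out,r}\,fu_{brain}\,C_r$;
* inter-regional diffusion in a hub-and-spoke topology — HC and FC each
  exchange with ROB through $PS_{HC\_BT}$ and $PS_{FC\_BT}$ (no direct
  HC-FC path), matching the parameter pairs swept in the sensitivity
  analysis;
* bulk flow $Q_{bulk,r}\,fu_{brain}\,C_r$ carries drug from each region's
  ECF into CSF (0.2 µL/min/g of region in rat);
* CSF is produced from intracranial blood at a fixed rate and absorbed to
  venous blood at the same rate; by default the produced fluid carries
  unbound drug ($Q_{prod}\,fu_p\,C_{BB}$), controlled by the
  `csf_production_carries_drug` flag, and the sink removes
  $Q_{sink}\,fu_{CSF}\,C_{CSF}$.

Regional amounts distribute into the **ECF volumes** (ROB 0.243, HC 0.019,
FC 0.038 mL in rat), reflecting the microdialysis biophase; parent tissue
volumes enter only through the PS weight scaling. The printed ECF values
take precedence over the 0.188 interstitial-fraction product where the two
disagree (FC: 0.038 vs 0.044 mL). Arterial blood feeds the intracranial
blood compartment, following the whole-body convention. The ECF-CSF
interface is realized as bulk-flow coupling only ("no rate-limiting
diffusion barrier" is read as the absence of an additional resistance
term, matching the tabulated flow set).

The inter-regional diffusion clearances are scaled like the regional BBB
terms (regional weight times surface area times $P_{app}$), a choice made
once in the absence of tabulated values; the sensitivity sweep treats them
as free axes anyway.

A Step-1 variant replaces the CNS block by a single permeability-limited
whole-brain compartment (volume = brain weight at unit density) behind the
same intracranial blood compartment; it is used for the ten-compound
Kp_uu validation panel.

## Dosing, units, integration

IV bolus doses initialize the venous amount; infusions apply a constant
venous input with an integrator restart at the end of the infusion; IP
doses fill a depot absorbed first-order (rate `ka`, fraction `f_abs`) into
the portal stream, the splanchnic route being the dominant fate of IP drug.
Internal state is amounts in mg with volumes in mL and time in minutes;
reported series convert to mg/L and, through the molecular weight, to
µmol/L or ng/mL as needed. Integration uses a stiff adaptive solver
(`lsoda`) at relative tolerance 1e-8 and absolute tolerance 1e-10 mg with a
compiled right-hand side; an R transcription of the same equations is
exported (`pbpk_rhs`) and the test suite verifies the two integrate
identically. Output is sampled on a regular grid (0.1 min by default) so
that reported tmax is not grid-limited; internal breakpoints are not
output samples. The system is linear by construction (no saturable terms),
which the suite asserts as exact dose-proportionality.

# Pharmacokinetic summaries

`nca()` reports Cmax and tmax from the dense grid and AUC(0-last) by linear
trapezoid (AUC(0-inf) by log-linear tail extrapolation is available but
never used for validation). `kpuu_brain()` implements

$$K_{p,uu,brain} = \frac{fu_{brain}\,AUC_{brain}}{fu_p\,AUC_{plasma}},$$

over the simulated window. Fold error is the symmetric
$\max(obs/pred, pred/obs)$; `afe` is the geometric-mean fold deviation
$10^{\mathrm{mean}(\log_{10}(pred/obs))}$ and `rmse` the root-mean-square
error on the units of the compared data (the conventional definitions; the
source analysis cites the values without formulas). The 2-fold and 5-fold
acceptance bands are boundary-inclusive.

Plasma is reported as venous blood concentration divided by $R_b$. A
consequence worth knowing: for symmetric passive transfer the AUC-based
Kp_uu converges to $R_b$ (=1 for an $R_b$ of 1), and for an IV bolus it
carries a deficit of $CL/CO$ (dose enters venous blood, the brain sees
arterial blood), which is why the structural Kp_uu test uses a
low-extraction probe compound.

# Uncertainty and sensitivity analyses

`run_mc()` propagates uncertainty in the three regional ECF volumes:
each iteration draws ROB, HC and FC volumes jointly and independently from
log-normal distributions with a 30% CV and median equal to the nominal
volume ($sd_{\log} = \sqrt{\ln(1+cv^2)}$); 1000 iterations (3000
compartment-perturbations) per compound is the default budget. Keeping the
median (not the mean) at the nominal value keeps the deterministic run the
central trajectory; a mean-preserving mode is available behind
`lognormal_mean_mode`. Parent tissue volumes, and with them the scaled PS
values, stay fixed — only the ECF distribution volumes vary. Failed
iterations are redrawn and counted; more than 1% aborts the analysis. The
5th/50th/95th percentile bands are computed pointwise, and Cmax/tmax/AUC
are summarized as mean ± SD over iterations; the per-case SD on predicted
Cmax is interpreted as exactly this Monte Carlo sample SD.

`ps_sweep()` reproduces the two-parameter sensitivity analysis: for HC (or
FC) it overrides the region's bidirectional BBB PS and its inter-regional
PS on a log-spaced 25×25 grid spanning 0.01-100 mL/min (values applied
directly on the mL/min axis, after scaling) and records the regional Cmax;
scenarios scale the ROB BBB PS by 0.1 or 10. A degenerate 1×1 grid
evaluates the nominal PS pair and reproduces the unswept simulation
exactly.

One structural finding is documented here because it contradicts an
intuitive expectation: with ECF-sized regional volumes the ROB compartment
(0.243 mL in rat) equilibrates with intracranial blood within minutes, so a
ten-fold higher ROB BBB PS does **not** act as a persistent competing sink
that lowers HC/FC Cmax; after a bolus it briefly captures the arterial
transient and re-releases it, slightly raising the other regions' exposure.
A sustained sink ordering would require brain-tissue-scale distribution
volumes ($V/fu$ large), which the microdialysis-biophase convention
deliberately does not use. The test suite characterizes this buffer
behaviour.

# Compound fixtures are synthetic reconstructions

The physiological tables (volumes, flows, CNS geometry) are transcribed
from the published system parameters and validated against them in the test
suite. The compound profiles are **not** transcriptions: the original
compound appendix is not available to this implementation, so the eleven
bundled profiles (ten-compound passive panel plus morphine; phenytoin and
carbamazepine belong to both the panel and the case studies) carry
literature-informed synthetic values — chosen once, before any comparison
against the published predictions, and flagged `synthetic` in each field's
provenance string. Under this parameterization the structural conclusions
(mass balance, linearity, limits, Monte Carlo calibration) are exact, but
the published numerical endpoints are generally not reproduced:

* plasma Cmax scales inversely with the apparent distribution volume of the
  Kp set (~1.5 L/kg here for phenytoin);
* regional ECF Cmax is governed by $fu_p/fu_{brain}$ relative to plasma
  under the ECF-biophase convention;
* the AUC-ratio Kp_uu of any symmetric passive parameterization converges
  to $R_b \approx 1$, far above the published regional values (0.12/0.057),
  which therefore require asymmetric or much slower regional exchange than
  any single $P_{app}$ consistent with the published sensitivity hull;
* a 10-min IV infusion always peaks in plasma at 10 min, so the published
  39-min carbamazepine tmax implies an absorption-rate-limited regimen
  whose constants are not printed. Both printed carbamazepine regimens
  (2.5 mg/kg, and the 10 mg/10 min infusion that duplicates the human
  morphine regimen) ship as fixtures, with 2.5 mg/kg used for the rat case.

The acceptance suite nevertheless asserts the published endpoints at their
stated tolerances, so those checks fail visibly rather than silently; they
become meaningful the moment a user replaces the synthetic profiles with
measured ones (every field is an editable YAML entry).

What the passing tests do show about real data is therefore structural:
conservation, linearity, correct IVIVE arithmetic, correct distribution of
the Monte Carlo perturbations, and the correct qualitative topology of the
CNS block (verified against an independently constructed matrix-exponential
solution to 1e-6). What they cannot show is quantitative predictivity for
any particular compound, which rests entirely on the quality of the
compound inputs.

# Numerical and design choices

* Tolerances: rtol 1e-8, atol 1e-10 mg; mass balance holds to ~1e-13 in
  practice and is asserted at 1e-8.
* Negative amounts below integrator noise (1e-6 of the dose triggers an
  error; smaller excursions are clipped to zero).
* The rat body weight is fixed at 0.25 kg and human at 70 kg (dose
  resolution for mg/kg regimens); both are config fields.
* IP absorption for the phenytoin case uses ka = 0.25/min, f_abs = 1 —
  a rapid-absorption representation chosen once for a small lipophilic
  acid given IP; it is a regimen field, not a compound property.
* Problem sizes: case simulations run 480 min (rat phenytoin), 300 min
  (rat carbamazepine) and 360 min (human morphine) at 0.1-min output for
  deterministic endpoints and 1-min output inside the Monte Carlo and
  sweep loops; the panel runs 3000 min at 1-min output so that AUC(0-last)
  approximates AUC(0-inf) for the slowest compound.
* `csf_production_carries_drug = TRUE` by default (production filters
  unbound plasma water); the flag exists because drug-free production is
  an equally defensible reading.
* Monte Carlo seeds are explicit and recorded; identical seeds reproduce
  bands bit-for-bit.

# Known limitations

No saturable binding, metabolism or transport; no brain intracellular
sub-compartment; no spinal/regional CSF segments; no multiple-dose
regimens; no parameter estimation (CF/REF are inputs, never fitted). The
published "better/worse" brain-tissue classification is handled only as two
observed series compared against the ROB compartment. Regional differences
in brain tissue binding are not modelled — one fu_brain applies to all
regions.
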