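# Morphine (human case compound). Literature-informed synthetic
# reconstruction. Treated as passive here (efflux_ratio 1) per the case
# analysis convention; systemic clearance supplied as in vivo values.
name: morphine
mw: {value: 285.34, units: g/mol}
fu_plasma: {value: 0.65, units: fraction, provenance: "synthetic; ~35% bound in human plasma"}
fu_brain:  {value: 0.90, units: fraction, provenance: "synthetic; ECF biophase"}
fu_csf:    {value: 1.0,  units: fraction, provenance: "synthetic"}
rb: {value: 1.02, units: ratio}
clearance:
  kind: blood_cl
  value: {value: 900.0, units: mL/min, provenance: "synthetic; human hepatic blood clearance"}
renal:
  kind: observed_clr
  value: {value: 130.0, units: mL/min, provenance: "synthetic; human renal clearance"}
papp_ab: {value: 0.6, units: 1e-6 cm/s, provenance: "synthetic; low passive monolayer permeability"}
papp_ba: null
efflux_ratio: {value: 1.0, units: ratio}
cf: {value: 1.0, units: ratio}
kp_tissues:
  adipose: 0.8
  bone: 0.8
  gut: 2.5
  heart: 1.5
  kidney: 3.0
  liver: 3.5
  lung: 2.5
  muscle: 1.5
  pancreas: 1.5
  skin: 1.5
  spleen: 1.8
observed_kpuu: {value: 0.29, units: ratio, provenance: "synthetic; net efflux reported in vivo"}
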