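# Midazolam (Step-1 panel). Synthetic reconstruction; CYP3A substrate.
name: midazolam
mw: {value: 325.77, units: g/mol}
fu_plasma: {value: 0.06, units: fraction, provenance: "synthetic"}
fu_brain:  {value: 0.50, units: fraction, provenance: "synthetic; ECF biophase"}
fu_csf:    {value: 0.85, units: fraction, provenance: "synthetic"}
rb: {value: 0.73, units: ratio}
clearance:
  kind: clint_microsomes
  value: {value: 250.0, units: uL/min/mg, provenance: "synthetic; high-extraction"}
renal:
  kind: none
papp_ab: {value: 35.0, units: 1e-6 cm/s, provenance: "synthetic"}
papp_ba: null
efflux_ratio: {value: 1.0, units: ratio}
cf: {value: 1.0, units: ratio}
kp_tissues:
  adipose: 4.5
  bone: 1.2
  gut: 2.5
  heart: 2.0
  kidney: 2.8
  liver: 4.0
  lung: 2.5
  muscle: 1.6
  pancreas: 2.0
  skin: 2.2
  spleen: 2.0
observed_kpuu: {value: 0.56, units: ratio, provenance: "synthetic"}
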