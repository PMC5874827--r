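# Zolpidem (Step-1 panel). Synthetic reconstruction.
name: zolpidem
mw: {value: 307.39, units: g/mol}
fu_plasma: {value: 0.17, units: fraction, provenance: "synthetic"}
fu_brain:  {value: 0.70, units: fraction, provenance: "synthetic; ECF biophase"}
fu_csf:    {value: 0.90, units: fraction, provenance: "synthetic"}
rb: {value: 0.76, units: ratio}
clearance:
  kind: clint_microsomes
  value: {value: 45.0, units: uL/min/mg, provenance: "synthetic"}
renal:
  kind: none
papp_ab: {value: 28.0, units: 1e-6 cm/s, provenance: "synthetic"}
papp_ba: null
efflux_ratio: {value: 1.0, units: ratio}
cf: {value: 1.0, units: ratio}
kp_tissues:
  adipose: 1.5
  bone: 0.8
  gut: 1.5
  heart: 1.2
  kidney: 1.8
  liver: 2.5
  lung: 1.5
  muscle: 1.0
  pancreas: 1.3
  skin: 1.3
  spleen: 1.2
observed_kpuu: {value: 0.85, units: ratio, provenance: "synthetic"}
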