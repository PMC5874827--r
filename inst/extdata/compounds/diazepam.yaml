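# Diazepam (Step-1 panel). Synthetic reconstruction; lipophilic, highly
# plasma-bound, rapid passive BBB equilibration.
name: diazepam
mw: {value: 284.74, units: g/mol}
fu_plasma: {value: 0.14, units: fraction, provenance: "synthetic"}
fu_brain:  {value: 0.55, units: fraction, provenance: "synthetic; ECF biophase"}
fu_csf:    {value: 0.85, units: fraction, provenance: "synthetic"}
rb: {value: 1.04, units: ratio}
clearance:
  kind: clint_microsomes
  value: {value: 60.0, units: uL/min/mg, provenance: "synthetic"}
renal:
  kind: none
papp_ab: {value: 40.0, units: 1e-6 cm/s, provenance: "synthetic"}
papp_ba: null
efflux_ratio: {value: 1.0, units: ratio}
cf: {value: 1.0, units: ratio}
kp_tissues:
  adipose: 5.0
  bone: 1.2
  gut: 2.5
  heart: 2.0
  kidney: 2.5
  liver: 3.5
  lung: 2.0
  muscle: 1.5
  pancreas: 2.0
  skin: 2.0
  spleen: 1.8
observed_kpuu: {value: 0.86, units: ratio, provenance: "synthetic"}
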