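# Buspirone (Step-1 panel). Synthetic reconstruction; high-clearance base.
name: buspirone
mw: {value: 385.50, units: g/mol}
fu_plasma: {value: 0.05, units: fraction, provenance: "synthetic"}
fu_brain:  {value: 0.60, units: fraction, provenance: "synthetic; ECF biophase"}
fu_csf:    {value: 0.90, units: fraction, provenance: "synthetic"}
rb: {value: 0.85, units: ratio}
clearance:
  kind: clint_microsomes
  value: {value: 180.0, units: uL/min/mg, provenance: "synthetic; high-extraction"}
renal:
  kind: none
papp_ab: {value: 25.0, units: 1e-6 cm/s, provenance: "synthetic"}
papp_ba: null
efflux_ratio: {value: 1.0, units: ratio}
cf: {value: 1.0, units: ratio}
kp_tissues:
  adipose: 4.0
  bone: 1.5
  gut: 3.0
  heart: 2.5
  kidney: 4.0
  liver: 5.0
  lung: 4.0
  muscle: 2.0
  pancreas: 2.5
  skin: 2.5
  spleen: 2.5
observed_kpuu: {value: 0.19, units: ratio, provenance: "synthetic"}
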