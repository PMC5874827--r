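# Thiopental (Step-1 panel). Synthetic reconstruction; lipophilic barbiturate.
name: thiopental
mw: {value: 242.34, units: g/mol}
fu_plasma: {value: 0.18, units: fraction, provenance: "synthetic"}
fu_brain:  {value: 0.60, units: fraction, provenance: "synthetic; ECF biophase"}
fu_csf:    {value: 0.90, units: fraction, provenance: "synthetic"}
rb: {value: 0.88, units: ratio}
clearance:
  kind: clint_microsomes
  value: {value: 12.0, units: uL/min/mg, provenance: "synthetic"}
renal:
  kind: none
papp_ab: {value: 25.0, units: 1e-6 cm/s, provenance: "synthetic"}
papp_ba: null
efflux_ratio: {value: 1.0, units: ratio}
cf: {value: 1.0, units: ratio}
kp_tissues:
  adipose: 6.0
  bone: 1.0
  gut: 1.8
  heart: 1.5
  kidney: 1.8
  liver: 2.5
  lung: 1.6
  muscle: 1.2
  pancreas: 1.5
  skin: 1.6
  spleen: 1.4
observed_kpuu: {value: 0.70, units: ratio, provenance: "synthetic"}
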