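# Carbamazepine (rat case compound). Literature-informed synthetic
# reconstruction; ECF-biophase convention for fu_brain/fu_csf.
name: carbamazepine
mw: {value: 236.27, units: g/mol}
fu_plasma: {value: 0.25, units: fraction, provenance: "synthetic"}
fu_brain:  {value: 0.80, units: fraction, provenance: "synthetic; ECF biophase"}
fu_csf:    {value: 0.90, units: fraction, provenance: "synthetic"}
rb: {value: 1.07, units: ratio}
clearance:
  kind: clint_microsomes
  value: {value: 28.0, units: uL/min/mg, provenance: "synthetic; rat liver microsomes"}
renal:
  kind: none
papp_ab: {value: 30.0, units: 1e-6 cm/s, provenance: "synthetic"}
papp_ba: null
efflux_ratio: {value: 1.0, units: ratio}
cf: {value: 1.0, units: ratio}
kp_tissues:
  adipose: 2.5
  bone: 1.0
  gut: 2.0
  heart: 1.5
  kidney: 2.2
  liver: 3.0
  lung: 1.8
  muscle: 1.4
  pancreas: 1.8
  skin: 2.0
  spleen: 1.5
observed_kpuu: {value: 1.0, units: ratio, provenance: "synthetic"}
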