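# Benzylpenicillin (Step-1 panel). Synthetic reconstruction; hydrophilic acid,
# renally cleared, very low passive permeability.
name: benzylpenicillin
mw: {value: 334.39, units: g/mol}
fu_plasma: {value: 0.40, units: fraction, provenance: "synthetic"}
fu_brain:  {value: 0.95, units: fraction, provenance: "synthetic; ECF biophase"}
fu_csf:    {value: 1.0,  units: fraction, provenance: "synthetic"}
rb: {value: 0.86, units: ratio}
clearance:
  kind: clint_microsomes
  value: {value: 0.5, units: uL/min/mg, provenance: "synthetic; minimal hepatic metabolism"}
renal:
  kind: gfr_fraction
  value: {value: 3.0, units: ratio, provenance: "synthetic; active tubular secretion multiple of filtration"}
papp_ab: {value: 0.2, units: 1e-6 cm/s, provenance: "synthetic"}
papp_ba: null
efflux_ratio: {value: 1.0, units: ratio}
cf: {value: 1.0, units: ratio}
kp_tissues:
  adipose: 0.1
  bone: 0.3
  gut: 0.6
  heart: 0.5
  kidney: 1.5
  liver: 0.8
  lung: 0.5
  muscle: 0.4
  pancreas: 0.5
  skin: 0.4
  spleen: 0.5
observed_kpuu: {value: 0.02, units: ratio, provenance: "synthetic; strong net CNS efflux reported"}
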