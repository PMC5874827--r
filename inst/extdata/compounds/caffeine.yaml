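# Caffeine (Step-1 panel). Synthetic reconstruction; low binding, freely
# permeable, near-unity brain partitioning.
name: caffeine
mw: {value: 194.19, units: g/mol}
fu_plasma: {value: 0.70, units: fraction, provenance: "synthetic"}
fu_brain:  {value: 0.95, units: fraction, provenance: "synthetic; ECF biophase"}
fu_csf:    {value: 1.0,  units: fraction, provenance: "synthetic"}
rb: {value: 1.04, units: ratio}
clearance:
  kind: clint_microsomes
  value: {value: 3.0, units: uL/min/mg, provenance: "synthetic"}
renal:
  kind: gfr_fraction
  value: {value: 0.1, units: ratio, provenance: "synthetic; extensive reabsorption"}
papp_ab: {value: 30.0, units: 1e-6 cm/s, provenance: "synthetic"}
papp_ba: null
efflux_ratio: {value: 1.0, units: ratio}
cf: {value: 1.0, units: ratio}
kp_tissues:
  adipose: 0.3
  bone: 0.6
  gut: 0.9
  heart: 0.9
  kidney: 0.9
  liver: 1.0
  lung: 0.9
  muscle: 0.8
  pancreas: 0.9
  skin: 0.8
  spleen: 0.9
observed_kpuu: {value: 0.81, units: ratio, provenance: "synthetic"}
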