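# Sertraline (Step-1 panel). Synthetic reconstruction; very lipophilic base,
# extensive tissue and brain binding.
name: sertraline
mw: {value: 306.23, units: g/mol}
fu_plasma: {value: 0.02, units: fraction, provenance: "synthetic"}
fu_brain:  {value: 0.30, units: fraction, provenance: "synthetic; ECF biophase"}
fu_csf:    {value: 0.70, units: fraction, provenance: "synthetic"}
rb: {value: 1.20, units: ratio}
clearance:
  kind: clint_microsomes
  value: {value: 140.0, units: uL/min/mg, provenance: "synthetic"}
renal:
  kind: none
papp_ab: {value: 20.0, units: 1e-6 cm/s, provenance: "synthetic"}
papp_ba: null
efflux_ratio: {value: 1.0, units: ratio}
cf: {value: 1.0, units: ratio}
kp_tissues:
  adipose: 12.0
  bone: 2.0
  gut: 6.0
  heart: 5.0
  kidney: 8.0
  liver: 10.0
  lung: 12.0
  muscle: 3.0
  pancreas: 5.0
  skin: 5.0
  spleen: 6.0
observed_kpuu: {value: 0.11, units: ratio, provenance: "synthetic"}
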