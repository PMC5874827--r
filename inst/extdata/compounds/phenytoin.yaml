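# Phenytoin (rat case compound). All values are literature-informed synthetic
# reconstructions; fu_brain/fu_csf follow the ECF-biophase convention (weakly
# bound interstitial fluid), not brain-homogenate fractions.
name: phenytoin
mw: {value: 252.27, units: g/mol}
fu_plasma: {value: 0.12, units: fraction, provenance: "synthetic; rat plasma protein binding ~88%"}
fu_brain:  {value: 0.75, units: fraction, provenance: "synthetic; ECF biophase"}
fu_csf:    {value: 0.90, units: fraction, provenance: "synthetic"}
rb: {value: 0.98, units: ratio}
clearance:
  kind: clint_microsomes
  value: {value: 10.0, units: uL/min/mg, provenance: "synthetic; rat liver microsomes"}
renal:
  kind: none   # liver assumed the only clearance site for phenytoin
papp_ab: {value: 12.0, units: 1e-6 cm/s, provenance: "synthetic; in vitro monolayer"}
papp_ba: null
efflux_ratio: {value: 1.0, units: ratio}
cf: {value: 1.0, units: ratio}
kp_tissues:
  adipose: 3.0
  bone: 1.0
  gut: 2.0
  heart: 1.5
  kidney: 2.0
  liver: 3.5
  lung: 1.7
  muscle: 1.3
  pancreas: 1.8
  skin: 2.0
  spleen: 1.5
observed_kpuu: {value: 0.46, units: ratio, provenance: "synthetic; rat microdialysis literature"}
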