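# Rat phenytoin case regimen: 50 mg/kg intraperitoneal.
# ka chosen to represent rapid rat IP absorption (absorption half-time ~3 min,
# consistent with the reported early plasma peak); not a source-printed value.
route: ip
amount: {value: 50.0, units: mg/kg}
ka: {value: 0.25, units: 1/min, provenance: "synthetic; rapid IP absorption"}
f_abs: {value: 1.0, units: fraction}
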