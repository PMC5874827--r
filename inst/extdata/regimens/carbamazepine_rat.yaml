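# Rat carbamazepine case regimen: 2.5 mg/kg over a 10-min IV infusion.
# Used for the rat-case comparisons.
route: iv_infusion
amount: {value: 2.5, units: mg/kg}
infusion_duration: {value: 10.0, units: min}
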