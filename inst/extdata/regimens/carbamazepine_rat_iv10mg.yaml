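# Alternative printed carbamazepine regimen: 10 mg IV infusion over 10 min.
# Ships alongside the 2.5 mg/kg regimen; appears to duplicate the human
# morphine infusion and is not used for the rat-case comparisons.
route: iv_infusion
amount: {value: 10.0, units: mg}
infusion_duration: {value: 10.0, units: min}
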