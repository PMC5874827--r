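# Human regional CNS geometry.
species: human
v_bb:      {value: 75.0,   units: mL}
v_rob:     {value: 1211.0, units: mL}
v_rob_ecf: {value: 267.0,  units: mL}
v_hc:      {value: 5.68,   units: mL}
v_hc_ecf:  {value: 1.07,   units: mL}
v_fc:      {value: 283.0,  units: mL}
v_fc_ecf:  {value: 53.2,   units: mL}
v_csf:     {value: 160.0,  units: mL}
q_bulk_rob: {value: 0.285,   units: mL/min}
q_bulk_hc:  {value: 0.00114, units: mL/min}
q_bulk_fc:  {value: 0.0566,  units: mL/min}
q_csf_production: {value: 0.35, units: mL/min}
q_csf_sink:       {value: 0.35, units: mL/min}
q_brain_blood:    {value: 750.0, units: mL/min}
ecf_fraction: {value: 0.188, units: fraction}
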