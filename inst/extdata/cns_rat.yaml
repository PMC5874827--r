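# Rat regional CNS geometry.
# ECF volumes use the printed table values (the frontal-cortex ECF row keeps
# the printed 0.038 mL even though 0.233 * 0.188 rounds differently).
species: rat
v_bb:      {value: 0.025, units: mL}
v_rob:     {value: 1.222, units: mL}
v_rob_ecf: {value: 0.243, units: mL}
v_hc:      {value: 0.093, units: mL}
v_hc_ecf:  {value: 0.019, units: mL}
v_fc:      {value: 0.233, units: mL}
v_fc_ecf:  {value: 0.038, units: mL}
v_csf:     {value: 0.25,  units: mL}
q_bulk_rob: {value: 0.00024, units: mL/min}
q_bulk_hc:  {value: 0.00002, units: mL/min}
q_bulk_fc:  {value: 0.00005, units: mL/min}
q_csf_production: {value: 0.0037, units: mL/min}
q_csf_sink:       {value: 0.0037, units: mL/min}
q_brain_blood:    {value: 1.12,   units: mL/min}
ecf_fraction: {value: 0.188, units: fraction}
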