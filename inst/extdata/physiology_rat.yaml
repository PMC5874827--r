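# Rat whole-body physiology (0.25 kg reference animal).
# Tissue volumes/perfusions from the published rat parameter set; stomach is
# merged into gut (no separate printed row). GFR is a standard physiological
# default, not taken from the source tables.
species: rat
body_weight: {value: 0.25, units: kg}
brain_weight: {value: 1.8, units: g}
bbb_surface_area: {value: 150.0, units: cm^2/g}
liver_weight_per_kg: {value: 40.0, units: g/kg}
microsomal_protein: {value: 45.0, units: mg/g}
hepatocellularity: {value: 1.3e+8, units: cells/g}
gfr: {value: 1.31, units: mL/min, provenance: "standard physiological default (not a source-table value)"}
arterial_volume: {value: 6.8, units: mL}
venous_volume: {value: 13.6, units: mL}
tissues:
  adipose:  {volume: {value: 19.03, units: mL}, perfusion: {value: 4.72, units: mL/min}}
  bone:     {volume: {value: 10.37, units: mL}, perfusion: {value: 8.08, units: mL/min}}
  brain:    {volume: {value: 1.43,  units: mL}, perfusion: {value: 1.12, units: mL/min}}
  gut:      {volume: {value: 6.75,  units: mL}, perfusion: {value: 12.0, units: mL/min}}
  heart:    {volume: {value: 0.825, units: mL}, perfusion: {value: 3.2,  units: mL/min}}
  kidney:   {volume: {value: 1.825, units: mL}, perfusion: {value: 11.6, units: mL/min}}
  liver:    {volume: {value: 10.3,  units: mL}, perfusion: {value: 20.0, units: mL/min}}
  lung:     {volume: {value: 1.25,  units: mL}, perfusion: {value: 80.0, units: mL/min}}
  muscle:   {volume: {value: 101.0, units: mL}, perfusion: {value: 18.96, units: mL/min}}
  pancreas: {volume: {value: 1.3,   units: mL}, perfusion: {value: 1.0,  units: mL/min}}
  skin:     {volume: {value: 47.5,  units: mL}, perfusion: {value: 4.08, units: mL/min}}
  spleen:   {volume: {value: 0.5,   units: mL}, perfusion: {value: 0.88, units: mL/min}}
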