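# Human whole-body physiology (70 kg reference adult).
# GFR and liver scalars are standard physiological defaults, not source-table
# values; microsomal protein / hepatocellularity kept at the rat scale-up
# convention in the absence of printed human values.
species: human
body_weight: {value: 70.0, units: kg}
brain_weight: {value: 1500.0, units: g}
bbb_surface_area: {value: 157.0, units: cm^2/g}
liver_weight_per_kg: {value: 25.8, units: g/kg, provenance: "1807.5 g liver / 70 kg"}
microsomal_protein: {value: 45.0, units: mg/g}
hepatocellularity: {value: 1.3e+8, units: cells/g}
gfr: {value: 125.0, units: mL/min, provenance: "standard physiological default (not a source-table value)"}
arterial_volume: {value: 1927.5, units: mL}
venous_volume: {value: 3855.0, units: mL}
tissues:
  adipose:  {volume: {value: 10725.0, units: mL}, perfusion: {value: 277.5,  units: mL/min}}
  bone:     {volume: {value: 9300.0,  units: mL}, perfusion: {value: 270.0,  units: mL/min}}
  brain:    {volume: {value: 1552.5,  units: mL}, perfusion: {value: 750.0,  units: mL/min}}
  gut:      {volume: {value: 1770.0,  units: mL}, perfusion: {value: 975.0,  units: mL/min}}
  heart:    {volume: {value: 285.0,   units: mL}, perfusion: {value: 160.5,  units: mL/min}}
  kidney:   {volume: {value: 330.0,   units: mL}, perfusion: {value: 1177.5, units: mL/min}}
  liver:    {volume: {value: 1807.5,  units: mL}, perfusion: {value: 1575.0, units: mL/min}}
  lung:     {volume: {value: 1252.5,  units: mL}, perfusion: {value: 5325.0, units: mL/min}}
  muscle:   {volume: {value: 32175.0, units: mL}, perfusion: {value: 802.5,  units: mL/min}}
  pancreas: {volume: {value: 90.0,    units: mL}, perfusion: {value: 142.5,  units: mL/min}}
  skin:     {volume: {value: 8325.0,  units: mL}, perfusion: {value: 322.5,  units: mL/min}}
  spleen:   {volume: {value: 202.5,   units: mL}, perfusion: {value: 82.5,   units: mL/min}}
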