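body_weight: 73.0
hematocrit: 0.45
layout: whole_body
compartments:
- name: arterial_plasma
  volume: 1.2
  flow: .na.real
  organ: arterial_blood
  fraction: 1.0
- name: venous_plasma
  volume: 2.2
  flow: .na.real
  organ: venous_blood
  fraction: 0.55
- name: venous_cells
  volume: 1.8
  flow: .na.real
  organ: venous_blood
  fraction: 0.45
- name: gut_lumen
  volume: 1.0
  flow: .na.real
  organ: gut
  fraction: 0.476
- name: gut_wall
  volume: 1.1
  flow: 0.9
  organ: gut
  fraction: 0.524
- name: liver_vascular
  volume: 0.45
  flow: 0.35
  organ: liver
  fraction: 0.25
- name: liver_interstitial
  volume: 0.5
  flow: .na.real
  organ: liver
  fraction: 0.278
- name: liver_intracellular
  volume: 0.85
  flow: .na.real
  organ: liver
  fraction: 0.472
- name: kidney
  volume: 0.31
  flow: 0.66
  organ: kidney
  fraction: 1.0
- name: periphery
  volume: 35.0
  flow: 1.2
  organ: periphery
  fraction: 1.0
enzyme_expression:
  CYP3A4:
    liver_intracellular: 1.0
    gut_wall: 0.1
  CYP2C9:
    liver_intracellular: 1.0
  CYP2J2:
    liver_intracellular: 1.0
  CYP1A2:
    liver_intracellular: 1.0
  UGT2B7:
    liver_intracellular: 1.0
    gut_wall: 0.05
  UGT1A6:
    liver_intracellular: 1.0
  ADH:
    liver_intracellular: 1.0
  esterase:
    liver_intracellular: 1.0
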