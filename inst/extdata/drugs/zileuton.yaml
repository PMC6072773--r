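name: zileuton
abbreviation: ZLT
therapeutic_dose_mg: 600.0
molecular_weight: 236.29
fraction_unbound: 0.07
targets:
- enzyme: 5-LOX
  ki: 0.021
partition_coefficients:
  periphery: 0.9757
  liver_intracellular: 2.0
  venous_cells: 1.0
absorption:
  ka: 0.01035
  lag: 10.0
  formulation: dissolved
processes:
- kind: metabolism
  site: liver_intracellular
  enzyme: UGT1A6
  kcat: 127.31682
  km: 30.0
  product: zileuton-GLU
- kind: metabolism
  site: liver_intracellular
  enzyme: CYP3A4
  kcat: 8.487788
  km: 30.0
  product: zileuton-SO
- kind: metabolism
  site: liver_intracellular
  enzyme: CYP1A2
  kcat: 12.731682
  km: 30.0
  product: OH-zileuton
- kind: clearance_hepatic
  site: liver_intracellular
  rate: 0.0005
metabolites:
- name: zileuton-GLU
  molecular_weight: 412.37
  fraction_unbound: 0.2
  processes:
  - kind: clearance_renal
    site: kidney
    rate: 0.03
- name: zileuton-SO
  molecular_weight: 252.29
  fraction_unbound: 0.15
  processes:
  - kind: clearance_renal
    site: kidney
    rate: 0.02
- name: OH-zileuton
  molecular_weight: 252.29
  fraction_unbound: 0.15
  processes:
  - kind: clearance_renal
    site: kidney
    rate: 0.02
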