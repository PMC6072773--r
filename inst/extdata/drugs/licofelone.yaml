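name: licofelone
abbreviation: LCF
therapeutic_dose_mg: 200.0
molecular_weight: 379.88
fraction_unbound: 0.01
targets:
- enzyme: COX-2
  ki: 0.032
- enzyme: 5-LOX
  ki: 0.056
partition_coefficients:
  periphery: 1.0812
  liver_intracellular: 3.0
  venous_cells: 3.0
absorption:
  ka: 0.01125
  lag: 12.0
  formulation: dissolved
processes:
- kind: metabolism
  site: liver_intracellular
  enzyme: CYP2J2
  kcat: 48.35466
  km: 10.0
  product: OH-licofelone
- kind: metabolism
  site: liver_intracellular
  enzyme: UGT2B7
  kcat: 80.5911
  km: 10.0
  product: licofelone-AGLU
- kind: transport_efflux
  site: gut_wall
  to: gut_lumen
  enzyme: P-gp
  rate: 0.002
- kind: clearance_hepatic
  site: liver_intracellular
  rate: 0.0002
metabolites:
- name: OH-licofelone
  molecular_weight: 395.88
  fraction_unbound: 0.05
  processes:
  - kind: clearance_renal
    site: kidney
    rate: 0.02
- name: licofelone-AGLU
  molecular_weight: 556.01
  fraction_unbound: 0.1
  processes:
  - kind: clearance_biliary
    site: liver_intracellular
    rate: 0.03
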