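name: diclofenac
abbreviation: DFN
therapeutic_dose_mg: 50.0
molecular_weight: 296.15
fraction_unbound: 0.005
targets:
- enzyme: COX-2
  ki: 0.018
partition_coefficients:
  periphery: 0.129
  liver_intracellular: 4.0
  venous_cells: 1.5
absorption:
  ka: 0.09653
  lag: 8.0
  formulation: dissolved
processes:
- kind: metabolism
  site: liver_intracellular
  enzyme: CYP2C9
  kcat: 284.44976
  km: 10.0
  product: 4'-OH-diclofenac
- kind: metabolism
  site: liver_intracellular
  enzyme: CYP3A4
  kcat: 106.66866
  km: 10.0
  product: 5-OH-diclofenac
- kind: metabolism
  site: liver_intracellular
  enzyme: CYP2C9
  kcat: 71.11244
  km: 10.0
  product: 3'-OH-diclofenac
- kind: metabolism
  site: liver_intracellular
  enzyme: UGT2B7
  kcat: 213.33732
  km: 10.0
  product: diclofenac-AGLU
- kind: clearance_renal
  site: kidney
  rate: 0.002
metabolites:
- name: 4'-OH-diclofenac
  molecular_weight: 312.15
  fraction_unbound: 0.05
  processes:
  - kind: clearance_renal
    site: kidney
    rate: 0.02
- name: 5-OH-diclofenac
  molecular_weight: 312.15
  fraction_unbound: 0.05
  processes:
  - kind: clearance_renal
    site: kidney
    rate: 0.02
- name: 3'-OH-diclofenac
  molecular_weight: 312.15
  fraction_unbound: 0.05
  processes:
  - kind: clearance_renal
    site: kidney
    rate: 0.02
- name: diclofenac-AGLU
  molecular_weight: 472.29
  fraction_unbound: 0.1
  processes:
  - kind: clearance_biliary
    site: liver_intracellular
    rate: 0.03
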