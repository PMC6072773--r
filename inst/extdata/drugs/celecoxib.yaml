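name: celecoxib
abbreviation: CEL
therapeutic_dose_mg: 100.0
molecular_weight: 381.37
fraction_unbound: 0.03
targets:
- enzyme: COX-2
  ki: 0.017
partition_coefficients:
  periphery: 2.8344
  liver_intracellular: 3.0
  venous_cells: 5.0
absorption:
  ka: 0.00597
  lag: 15.0
  formulation: dissolved
processes:
- kind: metabolism
  site: liver_intracellular
  enzyme: CYP2C9
  kcat: 65.57227
  km: 10.0
  product: OH-celecoxib
- kind: clearance_renal
  site: kidney
  rate: 0.0005
metabolites:
- name: OH-celecoxib
  molecular_weight: 397.37
  fraction_unbound: 0.05
  processes:
  - kind: metabolism
    site: liver_intracellular
    enzyme: ADH
    kcat: 0.5
    km: 10.0
    product: COOH-celecoxib
  - kind: clearance_renal
    site: kidney
    rate: 0.005
  metabolites:
  - name: COOH-celecoxib
    molecular_weight: 411.35
    fraction_unbound: 0.1
    processes:
    - kind: clearance_renal
      site: kidney
      rate: 0.02
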