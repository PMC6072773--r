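name: rifampicin
abbreviation: RIF
therapeutic_dose_mg: 600.0
molecular_weight: 822.94
fraction_unbound: 0.2
targets:
- enzyme: PXR
  ki: 1.18
partition_coefficients:
  periphery: 0.6151
  liver_intracellular: 5.0
  venous_cells: 1.0
absorption:
  ka: 0.01507
  lag: 15.0
  formulation: dissolved
processes:
- kind: metabolism
  site: liver_intracellular
  enzyme: esterase
  kcat: 4.81925
  km: 30.0
  product: desacetyl-rifampicin
- kind: transport_influx
  site: liver_interstitial
  to: liver_intracellular
  enzyme: OATP1B1
  rate: 0.05
- kind: clearance_biliary
  site: liver_intracellular
  rate: 0.0144578
- kind: clearance_renal
  site: kidney
  rate: 0.01
metabolites:
- name: desacetyl-rifampicin
  molecular_weight: 780.9
  fraction_unbound: 0.25
  processes:
  - kind: clearance_biliary
    site: liver_intracellular
    rate: 0.02
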