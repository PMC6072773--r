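id: 6
label: CEL + ZLT
result: drug_efficacy
drugs:
  - {drug: celecoxib, dose_mg: 100, route: oral}
  - {drug: zileuton, dose_mg: 600, route: oral}
horizon_h: 6
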