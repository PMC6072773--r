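id: 3
label: RIF + CEL
result: ddi_drug_efficacy
drugs:
  - {drug: celecoxib, dose_mg: 100, route: oral}
pretreatment: {drug: rifampicin, dose_mg: 600, days: 7, interval_min: 1440}
horizon_h: 6
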