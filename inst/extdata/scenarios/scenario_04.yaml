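id: 4
label: RIF + DFN
result: ddi_drug_efficacy
drugs:
  - {drug: diclofenac, dose_mg: 50, route: oral}
pretreatment: {drug: rifampicin, dose_mg: 600, days: 7, interval_min: 1440}
horizon_h: 6
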