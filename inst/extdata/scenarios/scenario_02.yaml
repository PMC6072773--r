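id: 2
label: DFN
result: drug_efficacy
drugs:
  - {drug: diclofenac, dose_mg: 50, route: oral}
horizon_h: 6
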