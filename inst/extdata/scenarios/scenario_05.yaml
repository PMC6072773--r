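id: 5
label: LCF
result: drug_efficacy
drugs:
  - {drug: licofelone, dose_mg: 200, route: oral}
horizon_h: 6
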