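id: 8
label: DFN correlation
result: pge2_pain_correlation
# correlation study doses: 25, 50 and 100 mg; the packaged run uses 50 mg
drugs:
  - {drug: diclofenac, dose_mg: 50, route: oral}
horizon_h: 6
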