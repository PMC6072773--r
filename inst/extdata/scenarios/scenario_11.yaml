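id: 11
label: RIF + CEL (clinical DDI study)
result: ddi_pk_validation
drugs:
  - {drug: celecoxib, dose_mg: 200, route: oral}
pretreatment: {drug: rifampicin, dose_mg: 600, days: 5, interval_min: 1440}
horizon_h: 6
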