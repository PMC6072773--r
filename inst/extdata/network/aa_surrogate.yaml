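provenance: packaged_surrogate
version: 1.0
species:
- name: PL
  initial: 100.0
  boundary: yes
- name: AA
  initial: 0.9714415
  boundary: no
- name: PGE2
  initial: 1.6676427
  boundary: no
- name: LTB4
  initial: 1.4000234
  boundary: no
- name: wLTB4
  initial: 1.8729412
  boundary: no
reactions:
- name: aa_release
  substrate: PL
  product: AA
  enzyme: PLA2
  vmax: 10.0
  km: 400.0
- name: aa_reacylation
  substrate: AA
  product: PL
  enzyme: LPCAT
  vmax: 60.0
  km: 30.0
- name: cox2_pge2
  substrate: AA
  product: PGE2
  enzyme: COX-2
  vmax: 6.0
  km: 50.0
- name: lox5_ltb4
  substrate: AA
  product: LTB4
  enzyme: 5-LOX
  vmax: 5.0
  km: 50.0
- name: ltb4_omega
  substrate: LTB4
  product: wLTB4
  enzyme: CYP4F3
  vmax: 4.0
  km: 60.0
- name: pge2_deg
  substrate: PGE2
  product: ~
  enzyme: 15-PGDH
  vmax: 5.6
  km: 80.0
- name: wltb4_deg
  substrate: wLTB4
  product: ~
  enzyme: wLTB4-deg
  vmax: 3.5
  km: 70.0
feedback:
- regulator: PGE2
  target: lox5_ltb4
  sign: -1.0
  strength: 0.3
  k_half: 10.0
- regulator: LTB4
  target: aa_release
  sign: 1.0
  strength: 0.2
  k_half: 5.0
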