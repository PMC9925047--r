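states:
- label: C1
  class: closed
  f: 0.0
  conducting: no
- label: C2
  class: closed
  f: 1.0
  conducting: no
- label: O3
  class: open
  f: 1.0
  conducting: yes
transitions:
- from: C1
  to: C2
  k0: 0.000139
  z: -0.9
- from: C2
  to: C1
  k0: 9.866e-05
  z: 0.2
- from: C2
  to: O3
  k0: 0.001177
  z: -0.55
- from: O3
  to: C2
  k0: 0.002371
  z: 0.45
allow_irreversible: no
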