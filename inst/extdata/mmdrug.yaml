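name: mmdrug
MW: 420.0
logP: 3.5
fu: 0.4
k_lip: 50.0
interfaces:
  a:
  - rbc
  - pls
  - cell
  b:
  - pls
  - int
  - int
  K:
  - 0.8
  - 1.0
  - 5.0
  P:
  - 30.0
  - 20.0
  - 10.0
metabolism:
  mode: michaelis_menten
  V_max: 60.0
  K_m: 15.0
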