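name: lindrug
MW: 326.0
logP: 2.5
fu: 0.6
k_lip: 30.0
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
  - 3.0
  P:
  - 30.0
  - 20.0
  - 10.0
metabolism:
  mode: linear
  k_met: 1.5
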