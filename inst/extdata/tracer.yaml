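name: tracer
MW: 557.0
logP: 3.0
fu: 0.9
k_lip: 40.0
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
  - 4.0
  P:
  - 30.0
  - 20.0
  - 10.0
metabolism:
  mode: none
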