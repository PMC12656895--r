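# Small-conductance calcium-activated potassium channel (SK).
# Purely calcium-gated: Hill activation on submembrane free calcium.
# ec50 in mM (0.5 uM), Hill coefficient 2 (effective shell coupling).
name: sk
erev: -90
p_act: 1
p_inact: 0
is_ca: false
act:
  type: sk
  ec50: 5.0e-4
  hill_n: 2
  tau_ms: 8
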