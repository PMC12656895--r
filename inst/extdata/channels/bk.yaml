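# Large-conductance calcium- and voltage-activated potassium channel (BK).
# Boltzmann activation whose half-activation voltage shifts leftward with
# log10 of submembrane calcium (shift_per_decade mV per tenfold calcium).
name: bk
erev: -90
p_act: 1
p_inact: 0
is_ca: false
act:
  type: bk
  vh0: 0
  shift_per_decade: 40
  caref: 1.0e-3
  k: 10
  tau_ms: 1
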