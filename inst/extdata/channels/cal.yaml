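# L-type (high-voltage-activated) calcium channel, m^2 kinetics.
# Ohmic approximation with fixed calcium reversal potential.
name: cal
erev: 120
p_act: 2
p_inact: 0
is_ca: true
act:
  type: v
  vh: -20
  k: 6
  tau: {type: const, tmin: 1.5}
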