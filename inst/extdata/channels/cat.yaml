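# T-type (low-voltage-activated) calcium channel, m^2 h kinetics.
name: cat
erev: 120
p_act: 2
p_inact: 1
is_ca: true
act:
  type: v
  vh: -48
  k: 5
  tau: {type: const, tmin: 2}
inact:
  type: v
  vh: -80
  k: -5
  tau: {type: const, tmin: 20}
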