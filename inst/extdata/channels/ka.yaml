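# A-type (fast transient) potassium channel, a b kinetics.
name: ka
erev: -90
p_act: 1
p_inact: 1
is_ca: false
act:
  type: v
  vh: -35
  k: 14
  tau: {type: const, tmin: 1}
inact:
  type: v
  vh: -78
  k: -6
  tau: {type: const, tmin: 30}
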