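# M-type (muscarinic-sensitive) slow potassium channel.
name: km
erev: -90
p_act: 1
p_inact: 0
is_ca: false
act:
  type: v
  vh: -28
  k: 7
  tau: {type: const, tmin: 40}
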