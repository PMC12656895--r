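# Delayed-rectifier potassium channel, n^4 kinetics with a slow
# inactivation gate: sustained depolarized firing envelopes erode the
# delayed rectifier over hundreds of milliseconds, as Kv2-family
# channels do. At resting and ordinary interspike potentials the gate
# stays near 1 and the channel behaves as a plain n^4 rectifier.
name: kdr
erev: -90
p_act: 4
p_inact: 1
is_ca: false
act:
  type: v
  vh: -25
  k: 12
  tau: {type: bell, tmin: 0.5, tamp: 4, vt: -30, k1: 15, k2: 15}
inact:
  type: v
  vh: -40
  k: -7
  tau: {type: const, tmin: 300}
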