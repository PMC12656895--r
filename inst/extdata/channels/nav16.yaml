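# Fast voltage-gated sodium channel (Nav1.6-type), m^3 h s kinetics:
# fast Boltzmann activation/inactivation plus a slow inactivation gate
# (s, tau ~250 ms) that engages only above ~-50 mV. The slow gate is
# what produces use-dependent depolarization block during sustained
# strong depolarization while leaving slow subthreshold approaches
# (ramps) unaffected. Units: mV, ms, S/cm^2.
name: nav16
erev: 60
p_act: 3
p_inact: 1
p_inact2: 1
is_ca: false
act:
  type: v
  vh: -29
  k: 7
  tau: {type: bell, tmin: 0.04, tamp: 0.15, vt: -35, k1: 12, k2: 12}
inact:
  type: v
  vh: -52
  k: -6
  tau: {type: bell, tmin: 1, tamp: 20, vt: -45, k1: 20, k2: 8}
inact2:
  type: v
  vh: -45
  k: -6
  tau: {type: const, tmin: 250}
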