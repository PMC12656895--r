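# Reduced problem sizes for simulation-heavy tests: a shorter myelinated
# axon (21 nodes) and coarser dendrite keep every electrical feature of
# the full cell (propagation, gigaohm impedance, DB/NDB regimes) at
# about a quarter of the per-step cost.
fast_config <- function(...) {
  vpglu_config(
    morphology = list(
      dendrite = list(L = 1371, diam = 0.3, nseg = 21),
      axon = list(n_nodes = 21, n_internodes = 20)
    ),
    ...
  )
}

# Passive variants: active conductances zero; optionally silence the
# nodal mechanism so the whole cell is a linear cable.
passive_theta <- function(leak = 1e-4) {
  conductance_vector(c(rep(0, 8), leak))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
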