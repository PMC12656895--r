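# Independent analytic oracle: steady-state input resistance of the
# sealed-end finite-cable chain, via cascaded two-port admittances.
# Derived from the closed-form uniform-cable solution
#   G_in = G_inf * (G_L + G_inf tanh(L/lambda)) /
#                  (G_inf + G_L tanh(L/lambda)),
# applied section by section from the sealed distal axon tip back to the
# soma, with the dendrite (sealed) and somatic membrane in parallel.
analytic_input_resistance <- function(theta_leak, config) {
  pas <- config$passive
  ra <- pas$ra
  g_inf <- function(d_um, g) {
    d <- d_um * 1e-4
    (pi / 2) * d^1.5 * sqrt(g / ra)
  }
  lambda_cm <- function(d_um, g) sqrt((d_um * 1e-4) / (4 * g * ra))
  through <- function(G_L, L_um, d_um, g) {
    Gi <- g_inf(d_um, g)
    t <- tanh((L_um * 1e-4) / lambda_cm(d_um, g))
    Gi * (G_L + Gi * t) / (Gi + G_L * t)
  }
  m <- config$morphology
  G <- 0 # sealed distal end
  secs <- list()
  for (i in seq_len(m$axon$n_nodes)) {
    secs[[length(secs) + 1]] <- list(L = m$axon$node$L,
                                     d = m$axon$node$diam,
                                     g = config$hh$gl)
    if (i <= m$axon$n_internodes)
      secs[[length(secs) + 1]] <- list(L = m$axon$internode$L,
                                       d = m$axon$internode$diam,
                                       g = pas$g_internode)
  }
  for (s in rev(secs)) G <- through(G, s$L, s$d, s$g)
  G <- through(G, m$hillock$L, m$hillock$diam, theta_leak)
  G_dend <- through(0, m$dendrite$L, m$dendrite$diam, theta_leak)
  d_cm <- m$soma$diam * 1e-4
  L_cm <- m$soma$L * 1e-4
  G_soma <- theta_leak * pi * d_cm * L_cm
  1e-6 / (G + G_dend + G_soma) # MOhm
}
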