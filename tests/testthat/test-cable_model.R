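test_that("default morphology reproduces the reference dimensions", {
  m <- build_morphology()
  s <- m$sections
  expect_equal(s[s$name == "soma", c("L", "diam")],
               data.frame(L = 10, diam = 10, row.names = 1L))
  expect_equal(unname(unlist(s[s$name == "hillock", c("L", "diam")])),
               c(30, 1))
  expect_equal(unname(unlist(s[s$name == "dendrite", c("L", "diam")])),
               c(1371, 0.3))
  expect_equal(m$axon_node_count, 100)
  expect_equal(m$axon_internode_count, 99)
  axon <- s[s$kind %in% c("node", "internode"), ]
  expect_equal(nrow(axon), 199)
  # node-first alternation
  expect_equal(axon$kind[1], "node")
  expect_equal(axon$kind[199], "node")
  expect_true(all(axon$kind[seq(1, 199, by = 2)] == "node"))
  expect_true(all(axon$kind[seq(2, 198, by = 2)] == "internode"))
})

test_that("degenerate morphology configurations are rejected", {
  cfg <- vpglu_config()$morphology
  bad <- cfg
  bad$axon$n_nodes <- 0
  bad$axon$n_internodes <- -1
  expect_error(build_morphology(bad), "node")
  bad2 <- cfg
  bad2$soma$diam <- -1
  expect_error(build_morphology(bad2), "non-positive")
  bad3 <- cfg
  bad3$dendrite$nseg <- 0
  expect_error(build_morphology(bad3), "n_segments")
})

test_that("conductance vectors are validated", {
  expect_error(conductance_vector(rep(-1, 9)), ">= 0")
  expect_error(conductance_vector(1:5), "length 9")
  th <- conductance_vector(c(leak = 1e-4, nav16 = 0.1, kdr = 0.1,
                             ka = 0, sk = 0, bk = 0, km = 0,
                             cal = 0, cat = 0))
  expect_equal(names(th), conductance_names()) # canonical reordering
  expect_equal(unname(unclass(th)[["leak"]]), 1e-4)
})

test_that("all-passive input resistance matches the analytic finite-cable solution", {
  # silence the nodal mechanism so the whole chain is a linear cable
  cfg <- vpglu_config(hh = list(gna = 0, gk = 0))
  for (leak in c(5e-5, 1e-4, 3e-4)) {
    cell <- discretize(build_morphology(cfg$morphology),
                       passive_theta(leak), cfg)
    rin <- input_resistance(cell, cfg$settings, cfg)
    expect_rel_equal(rin, analytic_input_resistance(leak, cfg), 0.01)
  }
})

test_that("a -5 pA step on the all-passive cell reproduces the analytic value", {
  cfg <- vpglu_config(hh = list(gna = 0, gk = 0))
  cell <- discretize(build_morphology(cfg$morphology),
                     passive_theta(1e-4), cfg)
  tr <- simulate_cell(cell, protocol_step(-5, 500), cfg$settings)
  v <- tr$v_mV[tr$time_ms >= attr(tr, "t_equil")]
  baseline <- v[1]
  dt <- attr(tr, "dt")
  n_off <- round(500 / dt) + 1
  dv <- mean(v[(n_off - round(50 / dt)):n_off]) - baseline
  rin <- dv / (-5e-3)
  expect_rel_equal(rin, analytic_input_resistance(1e-4, cfg), 0.01)
})

test_that("an isolated single compartment obeys Ohm's law", {
  # minimal hand-built cell: one passive compartment, no axon/hillock
  area <- 3.1416e-6 # cm^2
  gl_dens <- 1e-4   # S/cm^2
  cell <- structure(list(
    ncomp = 1L, cm_nF = 1 * area * 1e3, area_cm2 = area,
    g_ax_uS = numeric(0), gl_uS = gl_dens * area * 1e6, el_mV = -60,
    hillock_idx = integer(0), node_idx = integer(0), inj_idx = 0L,
    theta = unclass(reference_theta())[1:8],
    channels = unname(vpglu_config()$channels), hh = vpglu_config()$hh,
    ca = vpglu_config()$calcium,
    pv = list(ptot_mM = 0, kon = 40, koff = 4e-4)
  ), class = "vpglu_cell")
  tr <- simulate_cell(cell, protocol_step(-5, 500),
                      simulation_settings(t_equil = 200))
  v_end <- tr$v_mV[length(tr$v_mV)]
  rin_expected <- 1e-6 / (gl_dens * area) # MOhm
  expect_rel_equal((v_end - (-60)) / (-5e-3), rin_expected, 0.01)
})

test_that("mesh refinement leaves the passive input resistance unchanged", {
  cfg1 <- vpglu_config(hh = list(gna = 0, gk = 0))
  m <- cfg1$morphology
  m$soma$nseg <- 2 * m$soma$nseg
  m$hillock$nseg <- 2 * m$hillock$nseg
  m$dendrite$nseg <- 2 * m$dendrite$nseg + 1
  m$axon$node$nseg <- 2
  m$axon$internode$nseg <- 2
  cfg2 <- vpglu_config(hh = list(gna = 0, gk = 0), morphology = m)
  r1 <- input_resistance(discretize(build_morphology(cfg1$morphology),
                                    passive_theta(), cfg1),
                         cfg1$settings, cfg1)
  r2 <- input_resistance(discretize(build_morphology(cfg2$morphology),
                                    passive_theta(), cfg2),
                         cfg2$settings, cfg2)
  expect_lt(abs(r2 - r1) / r1, 0.005)
})

test_that("with no stimulus the membrane settles monotonically toward rest", {
  cfg <- fast_config(hh = list(gna = 0, gk = 0))
  cell <- discretize(build_morphology(cfg$morphology), passive_theta(),
                     cfg)
  dvdt <- rest_convergence(cell, t_total = 200, cfg$settings)
  expect_true(all(is.finite(dvdt)))
  expect_true(all(diff(dvdt) <= 1e-9))
  expect_lt(dvdt[length(dvdt)], 1e-6)
})

test_that("an unstimulated active cell stays at its equilibrium", {
  cfg <- fast_config()
  cell <- discretize(build_morphology(cfg$morphology), reference_theta(),
                     cfg)
  tr <- simulate_cell(cell, protocol_hold(500), cfg$settings)
  expect_false(attr(tr, "diverged"))
  expect_length(detect_spikes(tr), 0)
  post <- tr$v_mV[tr$time_ms >= attr(tr, "t_equil")]
  expect_lt(abs(post[length(post)] - post[1]), 1)
})

test_that("somatic spikes propagate to the distal node of Ranvier", {
  cfg <- vpglu_config()
  cell <- discretize(build_morphology(cfg$morphology), reference_theta(),
                     cfg)
  res <- vpglu:::run_protocols(cell, list(protocol_step(100, 500)),
                               cfg$settings,
                               record_idx = c(cell$hillock_idx[1],
                                              vpglu:::distal_node_index(cell)))
  v_hill <- res$traces[[1]][1, ]
  v_dist <- res$traces[[1]][2, ]
  dt <- cfg$settings$dt
  t_hill <- which(v_hill > 0)[1] * dt
  t_dist <- which(v_dist > 0)[1] * dt
  expect_false(is.na(t_hill))
  expect_false(is.na(t_dist))
  expect_gt(t_dist, t_hill)        # conduction, not reflection
  expect_lt(t_dist - t_hill, 25)   # arrives within 25 ms
})

test_that("voltage traces have the contracted length and metadata", {
  cfg <- fast_config()
  cell <- discretize(build_morphology(cfg$morphology), passive_theta(),
                     cfg)
  set <- cfg$settings
  tr <- simulate_cell(cell, protocol_step(-5, 250), set)
  expect_s3_class(tr, "voltage_trace")
  expect_equal(nrow(tr), round((set$t_equil + 250) / set$dt) + 1)
  expect_true(all(is.finite(tr$v_mV)))
  expect_equal(attr(tr, "dt"), 0.025)
  expect_equal(sort(unique(tr$i_pA)), c(-5, 0))
})
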