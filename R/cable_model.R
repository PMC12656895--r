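#' Build the ball-and-stick morphology
#'
#' Constructs the five-region morphology of the VP glutamatergic neuron
#' model: a somatic cylinder, an axon hillock, a single equivalent
#' dendritic cable, and a myelinated axon of alternating nodes of Ranvier
#' and internodal segments (node first). Defaults reproduce the reference
#' dimensions: soma 10 x 10 um, hillock 30 x 1 um, dendrite 1371 x 0.3 um,
#' and an axon of 100 nodes and 99 internodes.
#'
#' @param config morphology configuration (the `morphology` element of
#'   [vpglu_config()]); `NULL` for the defaults.
#' @return object of class `vpglu_morphology`: a `sections` data frame
#'   (name, kind, length um, diameter um, n_segments) plus node/internode
#'   counts.
#' @export
build_morphology <- function(config = NULL) {
  if (is.null(config)) config <- vpglu_config()$morphology
  m <- config
  nn <- m$axon$n_nodes
  ni <- m$axon$n_internodes
  if (!is.numeric(nn) || nn < 1)
    stop("axon must have at least one node of Ranvier")
  if (!is.numeric(ni) || ni < 0 || ni != nn - 1)
    stop("axon must alternate node-first: n_internodes = n_nodes - 1")
  check_sec <- function(s, nm) {
    if (s$L <= 0 || s$diam <= 0)
      stop("non-positive dimension in section '", nm, "'")
    if (s$nseg < 1) stop("n_segments must be >= 1 in section '", nm, "'")
  }
  check_sec(m$soma, "soma")
  check_sec(m$hillock, "hillock")
  check_sec(m$dendrite, "dendrite")
  check_sec(m$axon$node, "node")
  check_sec(m$axon$internode, "internode")

  base <- data.frame(
    name = c("soma", "hillock", "dendrite"),
    kind = c("soma", "hillock", "dendrite"),
    L = c(m$soma$L, m$hillock$L, m$dendrite$L),
    diam = c(m$soma$diam, m$hillock$diam, m$dendrite$diam),
    nseg = c(m$soma$nseg, m$hillock$nseg, m$dendrite$nseg),
    stringsAsFactors = FALSE
  )
  axon_kind <- rep(c("node", "internode"), length.out = nn + ni)
  axon_num <- c(rbind(seq_len(nn), c(seq_len(ni), NA)))[seq_len(nn + ni)]
  axon <- data.frame(
    name = paste0(axon_kind, "_", axon_num),
    kind = axon_kind,
    L = ifelse(axon_kind == "node", m$axon$node$L, m$axon$internode$L),
    diam = ifelse(axon_kind == "node", m$axon$node$diam,
                  m$axon$internode$diam),
    nseg = ifelse(axon_kind == "node", m$axon$node$nseg,
                  m$axon$internode$nseg),
    stringsAsFactors = FALSE
  )
  structure(list(sections = rbind(base, axon),
                 axon_node_count = nn,
                 axon_internode_count = ni),
            class = "vpglu_morphology")
}

#' @export
print.vpglu_morphology <- function(x, ...) {
  s <- x$sections
  cat("VP_Glu ball-and-stick morphology\n")
  for (nm in c("soma", "hillock", "dendrite")) {
    r <- s[s$name == nm, ]
    cat(sprintf("  %-9s L = %6.1f um, diam = %4.2f um, nseg = %d\n",
                nm, r$L, r$diam, r$nseg))
  }
  cat(sprintf("  axon      %d nodes + %d internodes (node first)\n",
              x$axon_node_count, x$axon_internode_count))
  invisible(x)
}

#' The nine-parameter conductance vector
#'
#' The free parameters explored by the calibration: maximal conductances
#' (S/cm^2) of the eight active hillock channels (Nav1.6,
#' delayed-rectifier K, A-type K, SK, BK, M-type K, L-type Ca, T-type Ca)
#' plus the passive leak conductance applied uniformly to soma, dendrite
#' and hillock.
#'
#' @param values numeric vector of length 9, in the order of
#'   [conductance_names()], or named in any order.
#' @return named numeric vector of class `conductance_vector`
#' @export
conductance_vector <- function(values) {
  nm <- conductance_names()
  if (!is.numeric(values) || length(values) != 9)
    stop("conductance vector must be numeric of length 9")
  if (!is.null(names(values))) {
    if (!setequal(names(values), nm)) stop("bad conductance names")
    values <- values[nm]
  } else {
    names(values) <- nm
  }
  if (any(!is.finite(values)) || any(values < 0))
    stop("conductances must be finite and >= 0")
  structure(values, class = "conductance_vector")
}

#' Discretize the morphology into a simulable cell
#'
#' Turns a morphology plus passive constants and a conductance vector into
#' the compartmental cell consumed by the integrator. Compartments are
#' ordered as an unbranched chain: dendrite (distal to proximal), soma,
#' hillock, then the axon (node first). Each section contributes `nseg`
#' equal cylindrical compartments; membrane areas come from cylinder
#' geometry and axial coupling conductances from the axial resistivity.
#' The eight active channels are placed on the hillock compartments only;
#' nodes of Ranvier carry squid-type kinetics; soma, dendrite and
#' internodes are passive. The ninth entry of `theta` sets the leak
#' conductance of soma, dendrite and hillock uniformly.
#'
#' @param morph a `vpglu_morphology`
#' @param theta a [conductance_vector()] (or length-9 numeric)
#' @param config full configuration ([vpglu_config()]); supplies passive
#'   constants, channel tables, calcium and buffer kinetics
#' @param pv_mM total parvalbumin concentration in the hillock calcium
#'   shell, mM (0 = no buffer)
#' @return object of class `vpglu_cell`
#' @export
discretize <- function(morph = build_morphology(), theta,
                       config = vpglu_config(), pv_mM = 0) {
  theta <- conductance_vector(unclass(theta))
  pas <- config$passive
  stopifnot(pas$cm > 0, pas$ra > 0, pv_mM >= 0)

  s <- morph$sections
  # chain order: dendrite (distal->proximal), soma, hillock, axon
  dend <- s[s$kind == "dendrite", ]
  soma <- s[s$kind == "soma", ]
  hill <- s[s$kind == "hillock", ]
  axon <- s[s$kind %in% c("node", "internode"), ]

  seg_rows <- function(sec, reverse = FALSE) {
    idx <- seq_len(nrow(sec))
    out <- do.call(rbind, lapply(idx, function(i) {
      n <- sec$nseg[i]
      data.frame(section = sec$name[i], kind = sec$kind[i],
                 L = rep(sec$L[i] / n, n), diam = sec$diam[i],
                 stringsAsFactors = FALSE)
    }))
    if (reverse) out[rev(seq_len(nrow(out))), ] else out
  }
  comp <- rbind(seg_rows(dend, reverse = TRUE), seg_rows(soma),
                seg_rows(hill), seg_rows(axon))
  rownames(comp) <- NULL
  ncomp <- nrow(comp)

  L_cm <- comp$L * 1e-4
  d_cm <- comp$diam * 1e-4
  area <- pi * d_cm * L_cm                       # cm^2
  cm_dens <- ifelse(comp$kind == "internode", pas$cm_internode, pas$cm)
  cm_nF <- cm_dens * area * 1e3                  # uF/cm^2 * cm^2 -> nF
  r_half <- pas$ra * (L_cm / 2) / (pi * (d_cm / 2)^2)  # Ohm
  g_ax <- 1e6 / (r_half[-ncomp] + r_half[-1])    # uS between i, i+1

  gl_dens <- numeric(ncomp)
  gl_dens[comp$kind %in% c("soma", "dendrite", "hillock")] <- theta[["leak"]]
  gl_dens[comp$kind == "internode"] <- pas$g_internode
  # nodes: leak lives in the squid-type mechanism
  gl_uS <- gl_dens * area * 1e6
  el <- rep(pas$e_leak, ncomp)

  hill_idx <- which(comp$kind == "hillock") - 1L
  node_idx <- which(comp$kind == "node") - 1L
  soma_idx <- which(comp$kind == "soma")[1] - 1L

  structure(list(
    ncomp = ncomp,
    comp = comp,
    cm_nF = cm_nF,
    area_cm2 = area,
    g_ax_uS = g_ax,
    gl_uS = gl_uS,
    el_mV = el,
    hillock_idx = as.integer(hill_idx),
    node_idx = as.integer(node_idx),
    inj_idx = as.integer(soma_idx),
    theta = unclass(theta)[CHANNEL_ORDER],
    theta_full = unclass(theta),
    channels = unname(config$channels),
    hh = config$hh,
    ca = config$calcium,
    pv = list(ptot_mM = pv_mM, kon = config$pv_kinetics$kon,
              koff = config$pv_kinetics$koff),
    morphology = morph
  ), class = "vpglu_cell")
}

#' @export
print.vpglu_cell <- function(x, ...) {
  cat("VP_Glu compartmental cell:", x$ncomp, "compartments\n")
  cat("  hillock compartments:", length(x$hillock_idx),
      "| nodes of Ranvier:", length(x$node_idx), "\n")
  cat("  active conductances (S/cm^2):\n")
  print(signif(x$theta, 4))
  cat("  leak:", signif(x$theta_full[["leak"]], 4), "S/cm^2",
      "| PV:", x$pv$ptot_mM, "mM\n")
  invisible(x)
}

# Index (0-based) of the most distal node of Ranvier, for propagation
# checks.
distal_node_index <- function(cell) {
  cell$node_idx[length(cell$node_idx)]
}

#' Reference conductance sets
#'
#' Hand-validated exemplar parameter sets, one per firing phenotype,
#' used as the default base guess of the calibration's initialization
#' (the search for a phenotype starts its restart noise schedule at the
#' exemplar of that phenotype) and as the reference models of the
#' integrator's convergence checks. The NDB exemplar is a
#' non-depolarization-block regime with gigaohm-range input resistance,
#' ~30 pA rheobase and a monotone F-I curve on the 0-130 pA grid; the
#' DB exemplar is a low-sodium, low-potassium regime whose F-I curve
#' rises to a peak near 70 pA and then declines into depolarization
#' block.
#'
#' @param phenotype `"NDB"` or `"DB"`
#' @return a [conductance_vector()]
#' @export
reference_theta <- function(phenotype = c("NDB", "DB")) {
  phenotype <- match.arg(phenotype)
  if (phenotype == "NDB") {
    conductance_vector(c(nav16 = 0.6, kdr = 0.12, ka = 0.02, sk = 0.002,
                         bk = 0.01, km = 0.001, cal = 3e-4, cat = 3e-4,
                         leak = 8e-5))
  } else {
    conductance_vector(c(nav16 = 0.16, kdr = 0.002, ka = 0.005,
                         sk = 5e-4, bk = 0.002, km = 5e-4, cal = 3e-4,
                         cat = 1e-3, leak = 3.2e-5))
  }
}
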