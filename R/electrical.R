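#' Boltzmann steady-state activation
#'
#' Steady state of a voltage-gated channel gate,
#' `1 / (1 + exp(-(V - Vh) / k))`.  Activation gates use positive slope
#' `k`, inactivation gates negative `k`.
#'
#' @param V membrane potential (mV).
#' @param Vh half-activation voltage (mV).
#' @param k slope (mV), nonzero.
#' @return open fraction in `[0, 1]`.
#' @export
boltzmann_inf <- function(V, Vh, k) {
  if (any(k == 0)) stop("Boltzmann slope k must be nonzero")
  1 / (1 + exp(-(V - Vh) / k))
}

#' Channel description
#'
#' Hodgkin-Huxley / Boltzmann channel with activation exponent `x`,
#' inactivation exponent `y` and an inactivation coefficient `a` that
#' scales inactivation depth: the effective inactivation variable is
#' `a * h + (1 - a)`, which reduces to plain Hodgkin-Huxley kinetics at
#' `a = 1` and shallows (a < 1) or deepens (a > 1) the inactivation
#' otherwise.
#'
#' Time constants are either fixed (ms) or tabulated as a two-column
#' `data.frame(v, tau)` interpolated piecewise-linearly (clamped at the
#' ends).  Calcium-gated channels (`kind = "calcium"`) replace the voltage
#' Boltzmann of the activation gate with a Hill function of the local
#' shell calcium (`ca_kd`, `ca_hill`).
#'
#' @param name channel name.
#' @param gbar maximal conductance density (S/cm^2).
#' @param erev reversal potential (mV).
#' @param x,y activation/inactivation exponents (non-negative integers).
#' @param a inactivation coefficient (default 1).
#' @param m_vh,m_k activation Boltzmann parameters (mV).
#' @param m_tau fixed value (ms) or lookup `data.frame(v, tau)`.
#' @param h_vh,h_k,h_tau inactivation gate parameters (needed when `y > 0`).
#' @param kind `"voltage"` (default) or `"calcium"`.
#' @param ca_kd,ca_hill Hill parameters for calcium gating (mM, -).
#' @return object of class `"channel_spec"`.
#' @export
channel_spec <- function(name, gbar, erev, x = 1, y = 0, a = 1,
                         m_vh = NA, m_k = NA, m_tau = 1,
                         h_vh = NA, h_k = NA, h_tau = 1,
                         kind = c("voltage", "calcium"),
                         ca_kd = 5e-4, ca_hill = 4) {
  kind <- match.arg(kind)
  stopifnot(gbar >= 0, x >= 0, y >= 0, x == round(x), y == round(y))
  check_tau <- function(tau, lab) {
    if (is.data.frame(tau)) {
      stopifnot(ncol(tau) >= 2)
      if (any(tau[[2]] <= 0)) stop(lab, ": tabulated tau must be positive everywhere")
    } else if (!(is.numeric(tau) && tau > 0)) {
      stop(lab, ": fixed tau must be a positive number (ms)")
    }
    tau
  }
  if (kind == "voltage") {
    if (is.na(m_vh) || is.na(m_k)) stop("voltage-gated channel needs m_vh, m_k")
    if (m_k == 0) stop("Boltzmann slope k must be nonzero")
  }
  if (y > 0) {
    if (is.na(h_vh) || is.na(h_k)) stop("inactivating channel needs h_vh, h_k")
    if (h_k == 0) stop("Boltzmann slope k must be nonzero")
  }
  structure(list(name = name, gbar = gbar, erev = erev, x = as.integer(x),
                 y = as.integer(y), a = a,
                 m_vh = m_vh, m_k = m_k, m_tau = check_tau(m_tau, "m_tau"),
                 h_vh = h_vh, h_k = h_k,
                 h_tau = if (y > 0) check_tau(h_tau, "h_tau") else 1,
                 kind = kind, ca_kd = ca_kd, ca_hill = ca_hill),
            class = "channel_spec")
}

#' Instantaneous channel current density
#'
#' `I = gbar * m^x * h_eff^y * (V - E_rev)` with
#' `h_eff = a * h + (1 - a)`; the plain Hodgkin-Huxley current is the
#' special case `a = 1`.
#'
#' @param spec a [channel_spec()].
#' @param gates list with elements `m` and `h` in `[0, 1]`.
#' @param V membrane potential (mV).
#' @return current density (mA/cm^2; positive = outward).
#' @export
channel_current <- function(spec, gates, V) {
  stopifnot(inherits(spec, "channel_spec"))
  m <- gates$m
  stopifnot(all(m >= 0 & m <= 1))
  g <- spec$gbar * m^spec$x
  if (spec$y > 0) {
    h <- gates$h
    stopifnot(all(h >= 0 & h <= 1))
    heff <- spec$a * h + (1 - spec$a)
    g <- g * heff^spec$y
  }
  g * (V - spec$erev) * 1e-3  # S/cm^2 * mV -> mA/cm^2
}

tau_at <- function(tau, V) {
  if (is.data.frame(tau)) {
    stats::approx(tau[[1]], tau[[2]], xout = V, rule = 2)$y
  } else {
    rep(tau, length(V))
  }
}

#' Relax channel gates toward their steady state
#'
#' First-order gate kinetics integrated exactly over `dt` for frozen
#' voltage: `m <- m_inf + (m - m_inf) * exp(-dt / tau(V))`.
#'
#' @param spec a [channel_spec()].
#' @param gates list with `m` and (if `y > 0`) `h`.
#' @param V membrane potential (mV).
#' @param dt time step (ms), positive.
#' @return updated gates list.
#' @export
step_gates <- function(spec, gates, V, dt) {
  stopifnot(inherits(spec, "channel_spec"), dt > 0)
  m_tau <- tau_at(spec$m_tau, V)
  if (any(m_tau <= 0)) stop("tau lookup returned a non-positive value")
  m_inf <- boltzmann_inf(V, spec$m_vh, spec$m_k)
  gates$m <- pmin(1, pmax(0, m_inf + (gates$m - m_inf) * exp(-dt / m_tau)))
  if (spec$y > 0) {
    h_tau <- tau_at(spec$h_tau, V)
    if (any(h_tau <= 0)) stop("tau lookup returned a non-positive value")
    h_inf <- boltzmann_inf(V, spec$h_vh, spec$h_k)
    gates$h <- pmin(1, pmax(0, h_inf + (gates$h - h_inf) * exp(-dt / h_tau)))
  }
  gates
}

#' Thin-shell calcium state
#'
#' Submembrane calcium compartment of one electrical section: influx from
#' calcium-carrying currents, Michaelis-Menten extrusion pump, and
#' diffusive relaxation toward the equilibrium concentration.
#'
#' @param ca initial concentration (mM).
#' @param depth shell depth (um, default 0.1).
#' @param ca_inf equilibrium concentration (mM, default 5e-5).
#' @param tau_r diffusive relaxation time constant (ms, default 43).
#' @param pump_vmax pump turnover (mM/ms, default 1e-5).
#' @param pump_km pump Michaelis constant (mM, default 1e-3).
#' @param faraday Faraday constant (C/mmol, default 96.489).
#' @return list of class `"calcium_shell"`.
#' @export
calcium_shell <- function(ca = 5e-5, depth = 0.1, ca_inf = 5e-5, tau_r = 43,
                          pump_vmax = 1e-5, pump_km = 1e-3,
                          faraday = 96.489) {
  stopifnot(ca >= 0, depth > 0, tau_r > 0, pump_vmax >= 0, pump_km > 0)
  structure(list(ca = ca, depth = depth, ca_inf = ca_inf, tau_r = tau_r,
                 pump_vmax = pump_vmax, pump_km = pump_km, faraday = faraday),
            class = "calcium_shell")
}

#' Advance a calcium shell
#'
#' Integrates
#' `d[Ca]/dt = -I_Ca / (2 F depth) - Vmax [Ca] / ([Ca] + Km) - ([Ca] - [Ca]_inf) / tau_r`
#' over `dt` (inner Euler substeps).  An inward calcium current (negative
#' by the membrane-current sign convention) raises the concentration.  A
#' negative result is clamped to zero with a warning.
#'
#' @param shell a [calcium_shell()].
#' @param I_Ca total calcium current (nA; negative = inward).
#' @param area membrane area of the section (cm^2).
#' @param dt time step (ms).
#' @return updated shell.
#' @export
shell_calcium_step <- function(shell, I_Ca, area, dt) {
  stopifnot(inherits(shell, "calcium_shell"), dt > 0, area > 0)
  density <- I_Ca * 1e-6 / area            # nA -> mA, per cm^2
  influx <- -10 * density / (2 * shell$faraday * shell$depth)  # mM/ms
  n_sub <- max(1L, ceiling(dt / 0.005))
  h <- dt / n_sub
  ca <- shell$ca
  clamped <- FALSE
  for (i in seq_len(n_sub)) {
    d_ca <- influx - shell$pump_vmax * ca / (ca + shell$pump_km) -
      (ca - shell$ca_inf) / shell$tau_r
    ca <- ca + h * d_ca
    if (ca < 0) { ca <- 0; clamped <- TRUE }
  }
  if (clamped) warning("shell calcium fell below zero and was clamped")
  shell$ca <- ca
  shell
}

#' Synapse state
#'
#' Double-exponential conductance synapse.  Each delivered event adds a
#' conductance transient normalized so that its peak equals
#' `weight * gpeak`.
#'
#' @param kind `"AMPA"` or `"NMDA"`.
#' @param tau_r,tau_d rise and decay time constants (ms), `tau_d > tau_r > 0`.
#' @param gpeak peak conductance of a unit-weight event (nS).
#' @param erev reversal potential (mV, default 0).
#' @param weight dimensionless multiplier (default 1).
#' @param events delivered event times (ms).
#' @return list of class `"synapse_state"`.
#' @export
synapse_state <- function(kind = c("AMPA", "NMDA"), tau_r, tau_d, gpeak,
                          erev = 0, weight = 1, events = numeric(0)) {
  kind <- match.arg(kind)
  if (!(tau_d > tau_r && tau_r > 0)) stop("need tau_d > tau_r > 0")
  if (weight < 0) stop("weight must be non-negative")
  structure(list(kind = kind, tau_r = tau_r, tau_d = tau_d, gpeak = gpeak,
                 erev = erev, weight = weight, events = events),
            class = "synapse_state")
}

#' Time of the double-exponential conductance peak after an event
#' @param tau_r,tau_d rise and decay time constants (ms).
#' @return peak latency (ms): `tau_r tau_d / (tau_d - tau_r) * log(tau_d / tau_r)`.
#' @export
synapse_peak_time <- function(tau_r, tau_d) {
  tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
}

#' Synaptic conductance at a given time
#'
#' Sum over delivered events of
#' `weight * gpeak * norm * (exp(-(t - t0)/tau_d) - exp(-(t - t0)/tau_r))`
#' for `t > t0`, with `norm` chosen so each event's peak equals
#' `weight * gpeak`.
#'
#' @param syn a [synapse_state()].
#' @param t evaluation time (ms), `t >= 0`.
#' @return conductance (nS).
#' @export
synapse_conductance <- function(syn, t) {
  stopifnot(inherits(syn, "synapse_state"), all(t >= 0))
  if (length(syn$events) == 0) return(rep(0, length(t)))
  tp <- synapse_peak_time(syn$tau_r, syn$tau_d)
  norm <- 1 / (exp(-tp / syn$tau_d) - exp(-tp / syn$tau_r))
  vapply(t, function(tt) {
    dt <- tt - syn$events
    dt <- dt[dt > 0]
    if (length(dt) == 0) return(0)
    syn$weight * syn$gpeak * norm *
      sum(exp(-dt / syn$tau_d) - exp(-dt / syn$tau_r))
  }, numeric(1))
}

# --- default channel set ------------------------------------------------------

#' Default channel library of the spiny-neuron model
#'
#' Fourteen conductances in the families used by medium spiny neuron
#' models: fast and persistent sodium; inward-rectifier, slow and fast
#' A-type, 4-AP-resistant persistent, and small/large-conductance
#' calcium-activated potassium; and N-, Q-, R-, T-type plus two L-type
#' (high- and low-threshold) calcium channels.  Gating parameters and
#' densities are package defaults in the ranges reported for this cell
#' type; all are configurable, and the slow/fast A-type potassium, N-type
#' and high-threshold L-type channels carry a partial-inactivation
#' coefficient `a < 1`.
#'
#' @return named list of [channel_spec()]s.
#' @export
default_channel_set <- function() {
  ek <- -90; ena <- 50; eca <- 130
  naf_taum <- data.frame(v = c(-100, -60, -40, -20, 0, 40),
                         tau = c(0.08, 0.12, 0.25, 0.18, 0.10, 0.08))
  naf_tauh <- data.frame(v = c(-100, -70, -50, -30, 0, 40),
                         tau = c(0.5, 1.5, 4.0, 1.5, 0.8, 0.5))
  kir_taum <- data.frame(v = c(-120, -90, -60, -30),
                         tau = c(0.4, 0.6, 1.0, 1.6))
  list(
    NaF = channel_spec("NaF", gbar = 1.5, erev = ena, x = 3, y = 1,
                       m_vh = -23.9, m_k = 11.8, m_tau = naf_taum,
                       h_vh = -62.9, h_k = -10.7, h_tau = naf_tauh),
    NaP = channel_spec("NaP", gbar = 4e-5, erev = ena, x = 1, y = 1,
                       m_vh = -52.6, m_k = 4.6, m_tau = 3,
                       h_vh = -48.8, h_k = -10, h_tau = 2000),
    KAf = channel_spec("KAf", gbar = 0.225, erev = ek, x = 2, y = 1, a = 0.88,
                       m_vh = -10.0, m_k = 17.7, m_tau = 1,
                       h_vh = -75.6, h_k = -10, h_tau = 25),
    KAs = channel_spec("KAs", gbar = 0.0104, erev = ek, x = 2, y = 1, a = 0.996,
                       m_vh = -27.0, m_k = 16, m_tau = 10,
                       h_vh = -33.5, h_k = -21.5, h_tau = 1000),
    KIR = channel_spec("KIR", gbar = 1.4e-4, erev = ek, x = 1, y = 0,
                       m_vh = -82, m_k = -13, m_tau = kir_taum),
    KRP = channel_spec("KRP", gbar = 1e-3, erev = ek, x = 1, y = 1,
                       m_vh = -13.5, m_k = 11.8, m_tau = 50,
                       h_vh = -54.7, h_k = -18.6, h_tau = 3000),
    SKKCa = channel_spec("SKKCa", gbar = 2e-3, erev = ek, x = 1, y = 0,
                         kind = "calcium", ca_kd = 5.7e-4, ca_hill = 4,
                         m_tau = 4),
    BKKCa = channel_spec("BKKCa", gbar = 1e-3, erev = ek, x = 1, y = 0,
                         kind = "calcium", ca_kd = 1e-2, ca_hill = 2,
                         m_tau = 1),
    CaL12 = channel_spec("CaL12", gbar = 4.2e-5, erev = eca, x = 1, y = 1,
                         a = 0.17,
                         m_vh = -8.9, m_k = 6.7, m_tau = 1,
                         h_vh = -13.4, h_k = -11.9, h_tau = 44.3),
    CaL13 = channel_spec("CaL13", gbar = 4.2e-5, erev = eca, x = 1, y = 0,
                         m_vh = -33.0, m_k = 6.7, m_tau = 1),
    CaN = channel_spec("CaN", gbar = 3e-5, erev = eca, x = 2, y = 1, a = 0.21,
                       m_vh = -8.7, m_k = 7.4, m_tau = 0.5,
                       h_vh = -74.8, h_k = -6.5, h_tau = 70),
    CaQ = channel_spec("CaQ", gbar = 2e-5, erev = eca, x = 2, y = 0,
                       m_vh = -9.0, m_k = 6.6, m_tau = 0.377),
    CaR = channel_spec("CaR", gbar = 2.6e-5, erev = eca, x = 3, y = 1,
                       m_vh = -10.3, m_k = 6.6, m_tau = 1.7,
                       h_vh = -33.3, h_k = -17, h_tau = 65),
    CaT = channel_spec("CaT", gbar = 4e-6, erev = eca, x = 3, y = 1,
                       m_vh = -51.7, m_k = 6.5, m_tau = 2,
                       h_vh = -80, h_k = -6.7, h_tau = 20)
  )
}

#' Default channel placement by compartment type
#'
#' Spine placement rules: the PSD carries the two L-type calcium channels
#' (high- and low-threshold); the head carries the Q-, R- and N-type
#' calcium channels and the small-conductance calcium-activated potassium
#' channel; the inward rectifier sits in both head and neck.  Soma and
#' dendrites carry the full somatodendritic set.
#'
#' @return named list: compartment type -> character vector of channel
#'   names.
#' @export
default_channel_placement <- function() {
  dend <- c("NaF", "NaP", "KAf", "KAs", "KIR", "KRP", "SKKCa",
            "CaL12", "CaL13", "CaR", "CaQ", "CaT")
  list(
    soma = c("NaF", "NaP", "KAf", "KAs", "KIR", "KRP", "BKKCa", "SKKCa",
             "CaL12", "CaL13", "CaN", "CaQ", "CaR"),
    proximal = dend, medial = dend, distal = dend,
    psd = c("CaL12", "CaL13"),
    head = c("CaQ", "CaR", "CaN", "SKKCa", "KIR"),
    neck = c("KIR")
  )
}

# per-type maximal-conductance overrides (S/cm^2); soma keeps the fast
# sodium density, dendrites are much sparser
default_gbar_overrides <- function() {
  list(
    proximal = c(NaF = 0.0195, KAf = 0.021),
    medial = c(NaF = 0.0195, KAf = 0.021),
    distal = c(NaF = 0.0195, KAf = 0.021)
  )
}

#' Reduced spiny-neuron morphology
#'
#' Soma plus `n_dendrites` primary dendrites, each a proximal, a medial
#' and two distal sections (`tree = "reduced"`, the desk-scale default) or
#' the full symmetric arborization of four primaries each dividing into
#' two medial branches that divide into two distal branches
#' (`tree = "full"`, 28 dendritic sections).
#'
#' @param n_dendrites number of primary dendrites (1-4) for the reduced
#'   tree.
#' @param tree `"reduced"` or `"full"`.
#' @param ra axial resistivity (Ohm cm).
#' @param cm specific capacitance (uF/cm^2).
#' @param gl leak conductance density (S/cm^2).
#' @param el leak reversal (mV).
#' @return data frame with one row per section.
#' @export
msn_morphology <- function(n_dendrites = 1, tree = c("reduced", "full"),
                           ra = 100, cm = 1, gl = 1.15e-4, el = -75) {
  tree <- match.arg(tree)
  stopifnot(n_dendrites >= 1, n_dendrites <= 4)
  rows <- list(list(id = "soma", type = "soma", parent = NA_character_,
                    diameter_um = 16, length_um = 16))
  add <- function(id, type, parent, d, L) {
    rows[[length(rows) + 1L]] <<- list(id = id, type = type, parent = parent,
                                       diameter_um = d, length_um = L)
  }
  nd <- if (tree == "full") 4 else n_dendrites
  for (i in seq_len(nd)) {
    prox <- sprintf("dend%d", i)
    add(prox, "proximal", "soma", 2.25, 20)
    n_med <- if (tree == "full") 2 else 1
    for (j in seq_len(n_med)) {
      med <- sprintf("dend%d_%d", i, j)
      add(med, "medial", prox, 1.10, 24)
      for (k in 1:2) {
        add(sprintf("dend%d_%d_%d", i, j, k), "distal", med, 0.72, 190)
      }
    }
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  df$ra_ohm_cm <- ra
  df$cm_uF_cm2 <- cm
  df$gl_S_cm2 <- gl
  df$el_mV <- el
  df
}

# --- model construction -------------------------------------------------------

# lateral membrane area of a cable section, cm^2 (um^2 * 1e-8)
section_area_cm2 <- function(d_um, L_um, caps = FALSE) {
  cylinder_area(d_um, L_um, caps = caps) * 1e-8
}

# axial conductance from a section (at its proximal end) to its parent, uS
axial_conductance_uS <- function(d_um, L_um, ra_ohm_cm) {
  # R_axial = Ra * L / (pi r^2); lengths in cm
  r_cm <- d_um / 2 * 1e-4
  L_cm <- L_um * 1e-4
  if (L_cm <= 0) return(1e3)  # zero-length stub: effectively fused
  g_S <- (pi * r_cm^2) / (ra_ohm_cm * L_cm)
  g_S * 1e6
}

#' Build the compartmental electrical model
#'
#' Assembles the fast simulator: soma and dendritic sections from a
#' morphology table, plus one three-section spine (neck, head, PSD) per
#' row of `spines`, with channels placed per compartment type, a thin
#' calcium shell in every compartment, and co-localized AMPA/NMDA
#' double-exponential synapses in each spine's PSD.
#'
#' @param morphology data frame from [msn_morphology()] (or the same
#'   columns).
#' @param spines data frame with columns `id` and `segment` (the dendrite
#'   section each spine attaches to); may be empty.
#' @param channels named list of [channel_spec()]s.
#' @param placement list: compartment type -> channel names.
#' @param gbar_overrides list: compartment type -> named gbar vector
#'   (S/cm^2).
#' @param geometry a [spine_geometry()].
#' @param passive drop all channels (passive cable; for verification).
#' @param v_init initial membrane potential (mV).
#' @param dt_elec internal integration step (ms, default 0.025).
#' @param ampa,nmda lists with `tau_r`, `tau_d` (ms), `gpeak` (nS), `erev`
#'   (mV), `ca_frac` (effective fraction of the synaptic current deposited
#'   as free calcium in the shell; an order of magnitude below the ionic
#'   calcium fraction because the shell has no explicit endogenous buffer,
#'   so buffering is folded into this factor).
#' @param shell named list of [calcium_shell()] arguments applied to every
#'   compartment.
#' @return an environment of class `"electrical_model"`.
#' @export
build_electrical_model <- function(morphology = msn_morphology(),
                                   spines = data.frame(id = character(0),
                                                       segment = character(0)),
                                   channels = default_channel_set(),
                                   placement = default_channel_placement(),
                                   gbar_overrides = default_gbar_overrides(),
                                   geometry = spine_geometry(),
                                   passive = FALSE,
                                   v_init = -80,
                                   dt_elec = 0.025,
                                   ampa = list(tau_r = 0.5, tau_d = 3,
                                               gpeak = 0.5, erev = 0,
                                               ca_frac = 3e-4),
                                   nmda = list(tau_r = 2, tau_d = 100,
                                               gpeak = 0.3, erev = 0,
                                               ca_frac = 3e-3),
                                   shell = list(depth = 0.1, ca_inf = 5e-5,
                                                tau_r = 43, pump_vmax = 1e-5,
                                                pump_km = 1e-3,
                                                faraday = 96.489)) {
  stopifnot(is.data.frame(morphology), is.data.frame(spines))
  comp <- morphology[, c("id", "type", "parent", "diameter_um", "length_um",
                         "ra_ohm_cm", "cm_uF_cm2", "gl_S_cm2", "el_mV")]
  comp$caps <- FALSE

  # append spine sections: dendrite -> neck -> head -> psd
  if (nrow(spines) > 0) {
    for (r in seq_len(nrow(spines))) {
      id <- as.character(spines$id[r])
      seg <- as.character(spines$segment[r])
      if (!seg %in% comp$id) stop(sprintf("spine '%s': unknown segment '%s'", id, seg))
      base <- comp[comp$id == seg, ][1, ]
      sp <- function(part, parent, dims) {
        data.frame(id = paste0(id, "_", part), type = part, parent = parent,
                   diameter_um = dims$diameter, length_um = dims$length,
                   ra_ohm_cm = base$ra_ohm_cm, cm_uF_cm2 = base$cm_uF_cm2,
                   gl_S_cm2 = base$gl_S_cm2, el_mV = base$el_mV, caps = TRUE,
                   stringsAsFactors = FALSE)
      }
      comp <- rbind(comp,
                    sp("neck", seg, geometry$neck),
                    sp("head", paste0(id, "_neck"), geometry$head),
                    sp("psd", paste0(id, "_head"), geometry$psd))
    }
  }

  # parents must precede children for the tree solve
  ord <- integer(0)
  remaining <- seq_len(nrow(comp))
  placed <- character(0)
  while (length(remaining) > 0) {
    ready <- remaining[is.na(comp$parent[remaining]) |
                         comp$parent[remaining] %in% placed]
    if (length(ready) == 0) stop("morphology is not a tree (cycle or missing parent)")
    ord <- c(ord, ready)
    placed <- c(placed, comp$id[ready])
    remaining <- setdiff(remaining, ready)
  }
  comp <- comp[ord, ]
  rownames(comp) <- NULL
  idx <- stats::setNames(seq_len(nrow(comp)) - 1L, comp$id)  # 0-based

  area <- mapply(section_area_cm2, comp$diameter_um, comp$length_um, comp$caps)
  gax <- mapply(axial_conductance_uS, comp$diameter_um, comp$length_um,
                comp$ra_ohm_cm)

  # flatten channel instances
  ch <- list(comp = integer(0), gbar = numeric(0), erev = numeric(0),
             x = integer(0), y = integer(0), a = numeric(0),
             is_ca = integer(0), kind = integer(0),
             m_vh = numeric(0), m_k = numeric(0), m_tau_fix = numeric(0),
             m_tab = integer(0), h_vh = numeric(0), h_k = numeric(0),
             h_tau_fix = numeric(0), h_tab = integer(0),
             ca_kd = numeric(0), ca_hill = numeric(0),
             name = character(0))
  tau_tables <- list()
  tab_index <- function(tau) {
    if (!is.data.frame(tau)) return(-1L)
    tau_tables[[length(tau_tables) + 1L]] <<-
      as.matrix(tau[, 1:2, drop = FALSE])
    length(tau_tables) - 1L  # 0-based
  }
  if (!passive) {
    for (i in seq_len(nrow(comp))) {
      type <- comp$type[i]
      for (nm in placement[[type]] %||% character(0)) {
        spec <- channels[[nm]]
        if (is.null(spec)) stop(sprintf("placement names unknown channel '%s'", nm))
        gbar <- spec$gbar
        ov <- gbar_overrides[[type]]
        if (!is.null(ov) && nm %in% names(ov)) gbar <- ov[[nm]]
        ch$comp <- c(ch$comp, idx[[comp$id[i]]])
        ch$gbar <- c(ch$gbar, gbar * area[i] * 1e6)  # S -> uS
        ch$erev <- c(ch$erev, spec$erev)
        ch$x <- c(ch$x, spec$x); ch$y <- c(ch$y, spec$y); ch$a <- c(ch$a, spec$a)
        ch$is_ca <- c(ch$is_ca, as.integer(startsWith(nm, "Ca")))
        ch$kind <- c(ch$kind, as.integer(spec$kind == "calcium"))
        ch$m_vh <- c(ch$m_vh, spec$m_vh %||% 0)
        ch$m_k <- c(ch$m_k, spec$m_k %||% 1)
        ch$m_tau_fix <- c(ch$m_tau_fix,
                          if (is.data.frame(spec$m_tau)) 1 else spec$m_tau)
        ch$m_tab <- c(ch$m_tab, tab_index(spec$m_tau))
        ch$h_vh <- c(ch$h_vh, if (spec$y > 0) spec$h_vh else 0)
        ch$h_k <- c(ch$h_k, if (spec$y > 0) spec$h_k else 1)
        ch$h_tau_fix <- c(ch$h_tau_fix,
                          if (spec$y > 0 && !is.data.frame(spec$h_tau)) spec$h_tau else 1)
        ch$h_tab <- c(ch$h_tab, if (spec$y > 0) tab_index(spec$h_tau) else -1L)
        ch$ca_kd <- c(ch$ca_kd, spec$ca_kd)
        ch$ca_hill <- c(ch$ca_hill, spec$ca_hill)
        ch$name <- c(ch$name, nm)
      }
    }
  }

  # initial gates at steady state for v_init (calcium-gated: at resting Ca)
  ca0 <- shell$ca_inf
  gate_m <- numeric(length(ch$comp))
  gate_h <- numeric(length(ch$comp))
  for (c in seq_along(ch$comp)) {
    gate_m[c] <- if (ch$kind[c] == 1) {
      ca0^ch$ca_hill[c] / (ca0^ch$ca_hill[c] + ch$ca_kd[c]^ch$ca_hill[c])
    } else {
      boltzmann_inf(v_init, ch$m_vh[c], ch$m_k[c])
    }
    gate_h[c] <- if (ch$y[c] > 0) boltzmann_inf(v_init, ch$h_vh[c], ch$h_k[c]) else 1
  }

  # synapses: AMPA + NMDA per spine PSD
  syn <- list(comp = integer(0), e = numeric(0), taur = numeric(0),
              taud = numeric(0), gpeak = numeric(0), cafrac = numeric(0),
              weight = numeric(0), spine = character(0), kind = character(0))
  if (nrow(spines) > 0) {
    for (r in seq_len(nrow(spines))) {
      id <- as.character(spines$id[r])
      psd <- idx[[paste0(id, "_psd")]]
      for (k in c("AMPA", "NMDA")) {
        par <- if (k == "AMPA") ampa else nmda
        syn$comp <- c(syn$comp, psd)
        syn$e <- c(syn$e, par$erev)
        syn$taur <- c(syn$taur, par$tau_r)
        syn$taud <- c(syn$taud, par$tau_d)
        syn$gpeak <- c(syn$gpeak, par$gpeak * 1e-3)  # nS -> uS
        syn$cafrac <- c(syn$cafrac, par$ca_frac)
        syn$weight <- c(syn$weight, 1)
        syn$spine <- c(syn$spine, id)
        syn$kind <- c(syn$kind, k)
      }
    }
  }

  pack <- list(
    parent = vapply(comp$parent,
                    function(p) if (is.na(p)) -1L else idx[[p]], integer(1)),
    gax_uS = as.numeric(gax),
    cm_nF = comp$cm_uF_cm2 * area * 1e3,
    gl_uS = comp$gl_S_cm2 * area * 1e6,
    el_mV = comp$el_mV,
    v_mV = rep(v_init, nrow(comp)),
    iinj_nA = rep(0, nrow(comp)),
    area_cm2 = as.numeric(area),
    ca_mM = rep(ca0, nrow(comp)),
    ca_inf_mM = rep(shell$ca_inf, nrow(comp)),
    ca_tau_ms = rep(shell$tau_r, nrow(comp)),
    ca_pump_vmax = rep(shell$pump_vmax, nrow(comp)),
    ca_pump_km = rep(shell$pump_km, nrow(comp)),
    ca_depth_um = rep(shell$depth, nrow(comp)),
    # a PSD is an internal section of its head: its calcium current feeds
    # the head's shell
    ca_route = vapply(seq_len(nrow(comp)), function(i) {
      if (comp$type[i] == "psd") idx[[comp$parent[i]]] else idx[[comp$id[i]]]
    }, integer(1)),
    faraday = shell$faraday,
    ch_comp = ch$comp, ch_gbar_uS = ch$gbar, ch_erev = ch$erev,
    ch_x = ch$x, ch_y = ch$y, ch_a = ch$a, ch_is_ca = ch$is_ca,
    ch_kind = ch$kind,
    m_vh = ch$m_vh, m_k = ch$m_k, m_tau_fix = ch$m_tau_fix, m_tab = ch$m_tab,
    h_vh = ch$h_vh, h_k = ch$h_k, h_tau_fix = ch$h_tau_fix, h_tab = ch$h_tab,
    ca_kd_mM = ch$ca_kd, ca_hill = ch$ca_hill,
    gate_m = gate_m, gate_h = gate_h,
    tau_tables = tau_tables,
    syn_comp = syn$comp, syn_e = syn$e, syn_taur = syn$taur,
    syn_taud = syn$taud, syn_gpeak_uS = syn$gpeak, syn_ca_frac = syn$cafrac,
    syn_weight = syn$weight, syn_A = rep(0, length(syn$comp)),
    syn_B = rep(0, length(syn$comp))
  )

  m <- new.env(parent = emptyenv())
  m$pack <- pack
  m$comp_table <- comp
  m$idx <- idx
  m$channel_names <- ch$name
  m$syn_meta <- data.frame(spine = syn$spine, kind = syn$kind,
                           stringsAsFactors = FALSE)
  m$spine_ids <- as.character(spines$id)
  m$time <- 0
  m$dt <- dt_elec
  m$pending <- data.frame(time = numeric(0), syn = integer(0))
  m$trace_chunks <- list()
  m$n_ca_clamped <- 0L
  class(m) <- "electrical_model"
  m
}

#' @export
print.electrical_model <- function(x, ...) {
  cat(sprintf("<electrical_model> %d compartments (%d spines), %d channel instances, %d synapses\n",
              nrow(x$comp_table), length(x$spine_ids),
              length(x$pack$ch_comp), length(x$pack$syn_comp)))
  cat(sprintf("  t = %g ms, dt = %g ms, V(soma) = %.2f mV\n",
              x$time, x$dt, x$pack$v_mV[1]))
  invisible(x)
}

# recording layout: V + Ca of every spine head, and soma V
recording_spec <- function(model) {
  comp <- integer(0); kind <- integer(0); name <- character(0)
  comp <- c(comp, 0L); kind <- c(kind, 0L)   # root section
  name <- c(name, "V_soma")
  for (id in model$spine_ids) {
    hc <- model$idx[[paste0(id, "_head")]]
    comp <- c(comp, hc, hc)
    kind <- c(kind, 0L, 1L)
    name <- c(name, paste0("V_head_", id), paste0("Ca_", id))
  }
  list(comp = comp, kind = kind, name = name)
}

#' Advance the electrical model to an absolute time
#'
#' Runs the compiled integrator from the model's current time to
#' `to_time` with the internal step `dt_elec`, consuming pending synaptic
#' events and appending recorded traces (1 ms cadence by default).
#'
#' @param model an [build_electrical_model()] environment.
#' @param to_time target time (ms).
#' @param record_dt trace recording cadence (ms); 0 disables recording.
#' @return the model, invisibly.
#' @export
step_electrical <- function(model, to_time, record_dt = 1) {
  stopifnot(inherits(model, "electrical_model"))
  if (to_time < model$time - 1e-9) stop("step_electrical cannot move backwards")
  if (to_time <= model$time + 1e-12) return(invisible(model))
  due <- model$pending$time <= to_time + 1e-9
  ev <- model$pending[due, , drop = FALSE]
  ord <- order(ev$time)
  rec <- recording_spec(model)
  out <- .elec_advance(model$pack, model$time, to_time, model$dt,
                       ev$time[ord], as.integer(ev$syn[ord]),
                       record_dt, as.integer(rec$comp), as.integer(rec$kind))
  for (f in c("v_mV", "ca_mM", "gate_m", "gate_h", "syn_A", "syn_B")) {
    model$pack[[f]] <- out[[f]]
  }
  model$n_ca_clamped <- model$n_ca_clamped + out$n_ca_clamped
  model$pending <- model$pending[!due, , drop = FALSE]
  if (record_dt > 0 && nrow(out$trace) > 0) {
    colnames(out$trace) <- c("time_ms", rec$name)
    model$trace_chunks[[length(model$trace_chunks) + 1L]] <- out$trace
  }
  model$time <- to_time
  invisible(model)
}

#' Collected traces of an electrical model
#' @param model an [build_electrical_model()] environment.
#' @return data frame (`time_ms`, `V_soma`, and per spine `V_head_<id>`,
#'   `Ca_<id>`).
#' @export
electrical_traces <- function(model) {
  stopifnot(inherits(model, "electrical_model"))
  if (length(model$trace_chunks) == 0) {
    rec <- recording_spec(model)
    return(stats::setNames(
      as.data.frame(matrix(numeric(0), ncol = length(rec$name) + 1)),
      c("time_ms", rec$name)))
  }
  as.data.frame(do.call(rbind, model$trace_chunks))
}

#' Wrap an electrical model as a simulator handle
#'
#' The fast simulator of the co-simulation.  Readable variables:
#' `V_soma`, and per spine `V_head_<id>`, `Ca_<id>` (mM), `weight_<id>`.
#' Writable: `weight_<id>` (AMPA synaptic weight) and `iinj_<comp>`
#' (constant injected current, nA).  Delivered events add a conductance
#' transient to the target spine's AMPA and/or NMDA synapse at the
#' model's current time.
#'
#' @param model an [build_electrical_model()] environment.
#' @param record_dt trace cadence (ms, default 1).
#' @return a [sim_handle()].
#' @export
electrical_handle <- function(model, record_dt = 1) {
  stopifnot(inherits(model, "electrical_model"))
  sim_handle(
    time = model$time,
    step = function(h, to_time) {
      step_electrical(h$model, to_time, record_dt = h$record_dt)
    },
    get = function(h, name) {
      m <- h$model
      if (name == "V_soma") return(m$pack$v_mV[1L])  # root section
      if (startsWith(name, "V_head_")) {
        id <- sub("^V_head_", "", name)
        return(m$pack$v_mV[m$idx[[paste0(id, "_head")]] + 1L])
      }
      if (startsWith(name, "Ca_")) {
        id <- sub("^Ca_", "", name)
        return(m$pack$ca_mM[m$idx[[paste0(id, "_head")]] + 1L])
      }
      if (startsWith(name, "weight_")) {
        id <- sub("^weight_", "", name)
        s <- which(m$syn_meta$spine == id & m$syn_meta$kind == "AMPA")
        if (length(s) == 0) stop(sprintf("no AMPA synapse for spine '%s'", id))
        return(m$pack$syn_weight[s[1]])
      }
      stop(sprintf("electrical handle has no variable '%s'", name))
    },
    set = function(h, name, value) {
      m <- h$model
      if (startsWith(name, "weight_")) {
        id <- sub("^weight_", "", name)
        s <- which(m$syn_meta$spine == id & m$syn_meta$kind == "AMPA")
        if (length(s) == 0) stop(sprintf("no AMPA synapse for spine '%s'", id))
        if (value < 0) stop("synaptic weight must be non-negative")
        m$pack$syn_weight[s] <- value
        return(invisible(NULL))
      }
      if (startsWith(name, "iinj_")) {
        id <- sub("^iinj_", "", name)
        if (!id %in% names(m$idx)) stop(sprintf("unknown compartment '%s'", id))
        m$pack$iinj_nA[m$idx[[id]] + 1L] <- value
        return(invisible(NULL))
      }
      stop(sprintf("electrical handle variable '%s' is not writable", name))
    },
    deliver = function(h, event) {
      m <- h$model
      id <- as.character(event$target_id)
      kinds <- if (event$synapse_kind == "both") c("AMPA", "NMDA") else event$synapse_kind
      s <- which(m$syn_meta$spine == id & m$syn_meta$kind %in% kinds)
      if (length(s) == 0) {
        stop(sprintf("event targets unknown spine '%s'", id))
      }
      m$pending <- rbind(m$pending,
                         data.frame(time = rep(m$time, length(s)),
                                    syn = s - 1L))  # 0-based for C++
    },
    label = "electrical",
    state = list(model = model, record_dt = record_dt)
  )
}

#' Audit spine channel placement
#'
#' Verifies the construction rules: PSD carries the high- and
#' low-threshold L-type calcium channels; the head carries Q-, R-, N-type
#' and the small-conductance calcium-activated potassium channel; the
#' inward rectifier is present in head and neck.
#'
#' @param model an [build_electrical_model()] environment.
#' @return `TRUE` if all rules hold, otherwise a character vector of
#'   violations.
#' @export
audit_channel_placement <- function(model) {
  stopifnot(inherits(model, "electrical_model"))
  required <- list(psd = c("CaL12", "CaL13"),
                   head = c("CaQ", "CaR", "CaN", "SKKCa", "KIR"),
                   neck = c("KIR"))
  bad <- character(0)
  for (type in names(required)) {
    comps <- which(model$comp_table$type == type) - 1L
    for (ci in comps) {
      present <- model$channel_names[model$pack$ch_comp == ci]
      missing <- setdiff(required[[type]], present)
      if (length(missing) > 0) {
        bad <- c(bad, sprintf("%s '%s' lacks %s",
                              type, model$comp_table$id[ci + 1L],
                              paste(missing, collapse = ", ")))
      }
    }
  }
  if (length(bad) == 0) TRUE else bad
}
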