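#' Michaelis-Menten rate
#'
#' @param kcat catalytic constant (1/s).
#' @param Km Michaelis constant (M), positive.
#' @param E enzyme concentration (M).
#' @param S substrate concentration (M).
#' @return rate in M/s: `kcat * E * S / (S + Km)`.
#' @export
mm_rate <- function(kcat, Km, E, S) {
  if (!(Km > 0)) stop("Km must be positive")
  kcat * E * S / (S + Km)
}

#' Default kinetic parameters of the spine signaling network
#'
#' All values in M and s.  The table grouping mirrors the configuration
#' layout: `table6` holds the allosteric calmodulin machinery (a shared
#' diffusion-limited on-rate, per-step dissociation rates for the tense and
#' relaxed conformations, and the conformational equilibrium), `table7` the
#' remaining reaction constants, `table8` the initial concentrations
#' ([default_initial_concentrations()]).
#'
#' The conformational transition rates are derived from the allosteric
#' constant `L0` (tense/relaxed ratio of empty calmodulin) and the per-step
#' dissociation ratios, so the binding/transition cycle satisfies detailed
#' balance by construction: `L_i = L0 * prod(koff_r/koff_t)[1..i]`,
#' `k_RT_i = k_conf * sqrt(L_i)`, `k_TR_i = k_conf / sqrt(L_i)`.
#'
#' @return nested named list.
#' @export
default_biochem_params <- function() {
  p <- list(
    table6 = list(
      kon = 1e8,                             # Ca on-rate, both conformations
      koff_t = c(2500, 2800, 3200, 3600),    # tense (low-affinity) off-rates
      koff_r = c(40, 50, 60, 80),            # relaxed (high-affinity) off-rates
      L0 = 2e4,                              # [T0]/[R0] allosteric constant
      k_conf = 1e3                           # conformational rate scale
    ),
    table7 = list(
      pump_vmax = 2e-5, pump_km = 1e-6,      # Ca extrusion (Michaelis-Menten)
      ca_leak = 1.82e-6,                     # constant Ca leak (M/s)
      can_kon = 4.6e7, can_koff = 0.01,      # CaM(R3) + calcineurin
      camkii_kon = 2.1e6, camkii_koff = 2.2, # CaM(R4) + CaMKII
      autophos_kcat = 0.5,                   # Thr286 autophosphorylation
      pka_kon = 5.6e6, pka_koff = 10.8, pka_kcat = 2.7,     # PKA -> D32 Thr34
      can_d32p_kon = 5e6, can_d32p_koff = 20, can_d32p_kcat = 2,
      d32p_pp1_kon = 1e6, d32p_pp1_koff = 0.3,              # PP1 inhibition
      pp1_ck_kon = 1e6, pp1_ck_koff = 0.5, pp1_ck_kcat = 0.5,
      camkii_ampar_kcat = 0.01, camkii_ampar_km = 4e-8,     # Ser831 phosphorylation
      pp1_ampar_kcat = 0.005, pp1_ampar_km = 2e-6           # Ser831 dephosphorylation
    )
  )
  p
}

#' @rdname default_biochem_params
#' @export
default_initial_concentrations <- function() {
  c(Ca = 1e-7, CaM = 1e-5, CaMKII = 2e-5, CaN = 1e-6,
    PKA = 1e-7, PP1 = 2e-6, DARPP32 = 4e-5, AMPAR = 4.5e-7)
}

# species name vector; order fixed, used by the stoichiometry matrix
biochem_species_names <- function() {
  c("Ca",
    paste0("CaMT", 0:4), paste0("CaMR", 0:4),
    "CaN", "CaN_CaM", "CaN_CaM_D32P",
    "CaMKII", "CaMKII_CaM", "CaMKII_CaM_P", "PP1_CaMKII_P",
    "PKA", "PKA_D32", "D32", "D32P", "D32P_PP1",
    "PP1", "AMPAR", "AMPAR_P")
}

# one reaction record; stoich vectors are named (species = coefficient)
biochem_reaction <- function(name, kind, reactants, products, pars, group) {
  list(name = name, kind = kind, reactants = reactants, products = products,
       pars = pars, group = group)
}

#' Build the spine plasticity reaction network
#'
#' Assembles the deterministic kinetic model of the spine signaling
#' network: two-conformation (tense/relaxed) allosteric calmodulin with
#' four sequential calcium-binding steps per conformation; relaxed
#' calmodulin binding calcineurin (three-calcium conformation, the
#' low-calcium sensor) and CaMKII (fully loaded, the high-calcium sensor);
#' CaMKII Thr286
#' autophosphorylation on the bound complex; PKA phosphorylation of
#' DARPP-32 Thr34; calcineurin dephosphorylation of phospho-DARPP-32;
#' phospho-DARPP-32 binding and inhibiting PP1; PP1 dephosphorylation of
#' phospho-CaMKII; phosphorylation of AMPA receptors at Ser831 by the
#' CaMKII-calmodulin complex and dephosphorylation by free PP1 (both
#' Michaelis-Menten); a Michaelis-Menten calcium pump, a constant calcium
#' leak, and a zeroth-order calcium influx process driven by the electrical
#' model through the coupling layer.
#'
#' @param params nested parameter list, see [default_biochem_params()].
#' @param concentrations named initial totals (M), see
#'   [default_initial_concentrations()].
#' @param cam_switching conformational-transition wiring: `"all_levels"`
#'   (default; tense/relaxed exchange at every calcium occupancy) or
#'   `"endpoints"` (concerted limit, exchange only for empty and fully
#'   loaded calmodulin).
#' @param rtol,atol solver tolerances for [step_biochemical()].
#' @return object of class `"reaction_network"`.
#' @export
build_network <- function(params = default_biochem_params(),
                          concentrations = default_initial_concentrations(),
                          cam_switching = c("all_levels", "endpoints"),
                          rtol = 1e-8, atol = 1e-14) {
  cam_switching <- match.arg(cam_switching)
  t6 <- params$table6
  t7 <- params$table7
  need6 <- c("kon", "koff_t", "koff_r", "L0", "k_conf")
  need7 <- c("pump_vmax", "pump_km", "ca_leak", "can_kon", "can_koff",
             "camkii_kon", "camkii_koff", "autophos_kcat",
             "pka_kon", "pka_koff", "pka_kcat",
             "can_d32p_kon", "can_d32p_koff", "can_d32p_kcat",
             "d32p_pp1_kon", "d32p_pp1_koff",
             "pp1_ck_kon", "pp1_ck_koff", "pp1_ck_kcat",
             "camkii_ampar_kcat", "camkii_ampar_km",
             "pp1_ampar_kcat", "pp1_ampar_km")
  missing6 <- setdiff(need6, names(t6))
  missing7 <- setdiff(need7, names(t7))
  if (length(missing6) || length(missing7)) {
    stop("missing parameter key(s): ",
         paste(c(paste0("table6.", missing6), paste0("table7.", missing7)),
               collapse = ", "))
  }
  need8 <- c("Ca", "CaM", "CaMKII", "CaN", "PKA", "PP1", "DARPP32", "AMPAR")
  missing8 <- setdiff(need8, names(concentrations))
  if (length(missing8)) {
    stop("missing initial concentration(s): ",
         paste(paste0("table8.", missing8), collapse = ", "))
  }

  rx <- list()
  add <- function(...) rx[[length(rx) + 1L]] <<- biochem_reaction(...)

  # -- allosteric calmodulin: sequential Ca binding in each conformation
  for (i in 0:3) {
    add(sprintf("CaMT%d_bind", i), "mass_action_bi",
        c(stats::setNames(1, sprintf("CaMT%d", i)), Ca = 1),
        stats::setNames(1, sprintf("CaMT%d", i + 1)),
        list(k = t6$kon), "calmodulin")
    add(sprintf("CaMT%d_release", i + 1), "mass_action_uni",
        stats::setNames(1, sprintf("CaMT%d", i + 1)),
        c(stats::setNames(1, sprintf("CaMT%d", i)), Ca = 1),
        list(k = t6$koff_t[i + 1]), "calmodulin")
    add(sprintf("CaMR%d_bind", i), "mass_action_bi",
        c(stats::setNames(1, sprintf("CaMR%d", i)), Ca = 1),
        stats::setNames(1, sprintf("CaMR%d", i + 1)),
        list(k = t6$kon), "calmodulin")
    add(sprintf("CaMR%d_release", i + 1), "mass_action_uni",
        stats::setNames(1, sprintf("CaMR%d", i + 1)),
        c(stats::setNames(1, sprintf("CaMR%d", i)), Ca = 1),
        list(k = t6$koff_r[i + 1]), "calmodulin")
  }
  # conformational transitions; detailed balance via L_i
  L <- t6$L0 * cumprod(c(1, t6$koff_r / t6$koff_t))
  levels_used <- if (cam_switching == "all_levels") 0:4 else c(0L, 4L)
  for (i in levels_used) {
    add(sprintf("CaMT%d_to_R", i), "mass_action_uni",
        stats::setNames(1, sprintf("CaMT%d", i)),
        stats::setNames(1, sprintf("CaMR%d", i)),
        list(k = t6$k_conf / sqrt(L[i + 1])), "calmodulin")
    add(sprintf("CaMR%d_to_T", i), "mass_action_uni",
        stats::setNames(1, sprintf("CaMR%d", i)),
        stats::setNames(1, sprintf("CaMT%d", i)),
        list(k = t6$k_conf * sqrt(L[i + 1])), "calmodulin")
  }

  # -- relaxed calmodulin binds its two targets: calcineurin takes the
  # partially loaded conformation (the low-calcium sensor), CaMKII requires
  # full loading (the high-calcium sensor)
  add("CaN_bind_CaM", "mass_action_bi", c(CaMR3 = 1, CaN = 1), c(CaN_CaM = 1),
      list(k = t7$can_kon), "calcineurin")
  add("CaN_release_CaM", "mass_action_uni", c(CaN_CaM = 1), c(CaMR3 = 1, CaN = 1),
      list(k = t7$can_koff), "calcineurin")
  add("CaMKII_bind_CaM", "mass_action_bi", c(CaMR4 = 1, CaMKII = 1),
      c(CaMKII_CaM = 1), list(k = t7$camkii_kon), "camkii")
  add("CaMKII_release_CaM", "mass_action_uni", c(CaMKII_CaM = 1),
      c(CaMR4 = 1, CaMKII = 1), list(k = t7$camkii_koff), "camkii")

  # -- CaMKII autophosphorylation (first order on the bound complex)
  add("CaMKII_autophos", "mass_action_uni", c(CaMKII_CaM = 1),
      c(CaMKII_CaM_P = 1), list(k = t7$autophos_kcat), "camkii")

  # -- PP1 dephosphorylates phospho-CaMKII (enzyme-substrate scheme)
  add("PP1_CaMKIIP_bind", "mass_action_bi", c(PP1 = 1, CaMKII_CaM_P = 1),
      c(PP1_CaMKII_P = 1), list(k = t7$pp1_ck_kon), "pp1")
  add("PP1_CaMKIIP_release", "mass_action_uni", c(PP1_CaMKII_P = 1),
      c(PP1 = 1, CaMKII_CaM_P = 1), list(k = t7$pp1_ck_koff), "pp1")
  add("PP1_CaMKIIP_cat", "mass_action_uni", c(PP1_CaMKII_P = 1),
      c(PP1 = 1, CaMKII_CaM = 1), list(k = t7$pp1_ck_kcat), "pp1")

  # -- PKA phosphorylates DARPP-32 on Thr34
  add("PKA_D32_bind", "mass_action_bi", c(PKA = 1, D32 = 1), c(PKA_D32 = 1),
      list(k = t7$pka_kon), "darpp32")
  add("PKA_D32_release", "mass_action_uni", c(PKA_D32 = 1), c(PKA = 1, D32 = 1),
      list(k = t7$pka_koff), "darpp32")
  add("PKA_D32_cat", "mass_action_uni", c(PKA_D32 = 1), c(PKA = 1, D32P = 1),
      list(k = t7$pka_kcat), "darpp32")

  # -- calcineurin dephosphorylates phospho-DARPP-32
  add("CaN_D32P_bind", "mass_action_bi", c(CaN_CaM = 1, D32P = 1),
      c(CaN_CaM_D32P = 1), list(k = t7$can_d32p_kon), "calcineurin")
  add("CaN_D32P_release", "mass_action_uni", c(CaN_CaM_D32P = 1),
      c(CaN_CaM = 1, D32P = 1), list(k = t7$can_d32p_koff), "calcineurin")
  add("CaN_D32P_cat", "mass_action_uni", c(CaN_CaM_D32P = 1),
      c(CaN_CaM = 1, D32 = 1), list(k = t7$can_d32p_kcat), "calcineurin")

  # -- phospho-DARPP-32 binds and inhibits PP1
  add("D32P_PP1_bind", "mass_action_bi", c(D32P = 1, PP1 = 1), c(D32P_PP1 = 1),
      list(k = t7$d32p_pp1_kon), "pp1")
  add("D32P_PP1_release", "mass_action_uni", c(D32P_PP1 = 1), c(D32P = 1, PP1 = 1),
      list(k = t7$d32p_pp1_koff), "pp1")

  # -- AMPA receptor phospho-cycle (Michaelis-Menten fluxes)
  add("AMPAR_phos", "michaelis_menten", c(AMPAR = 1), c(AMPAR_P = 1),
      list(kcat = t7$camkii_ampar_kcat, Km = t7$camkii_ampar_km,
           enzyme = c("CaMKII_CaM", "CaMKII_CaM_P")), "ampar")
  add("AMPAR_dephos", "michaelis_menten", c(AMPAR_P = 1), c(AMPAR = 1),
      list(kcat = t7$pp1_ampar_kcat, Km = t7$pp1_ampar_km,
           enzyme = "PP1"), "ampar")

  # -- calcium housekeeping and the coupling influx
  add("Ca_pump", "michaelis_menten", c(Ca = 1), numeric(0),
      list(kcat = 1, Km = t7$pump_km, enzyme = NULL, vmax = t7$pump_vmax),
      "calcium")
  add("Ca_leak", "constant_flux", numeric(0), c(Ca = 1),
      list(k = t7$ca_leak), "calcium")
  add("Ca_influx", "constant_flux", numeric(0), c(Ca = 1),
      list(k = 0), "coupling")

  species <- biochem_species_names()
  y0 <- stats::setNames(rep(0, length(species)), species)
  y0["Ca"] <- concentrations[["Ca"]]
  y0["CaMT0"] <- concentrations[["CaM"]]
  y0["CaN"] <- concentrations[["CaN"]]
  y0["CaMKII"] <- concentrations[["CaMKII"]]
  y0["PKA"] <- concentrations[["PKA"]]
  y0["D32"] <- concentrations[["DARPP32"]]
  y0["PP1"] <- concentrations[["PP1"]]
  y0["AMPAR"] <- concentrations[["AMPAR"]]

  # stoichiometry matrix (species x reactions)
  S <- matrix(0, nrow = length(species), ncol = length(rx),
              dimnames = list(species, vapply(rx, `[[`, "", "name")))
  for (j in seq_along(rx)) {
    for (nm in names(rx[[j]]$reactants)) {
      S[nm, j] <- S[nm, j] - rx[[j]]$reactants[[nm]]
    }
    for (nm in names(rx[[j]]$products)) {
      S[nm, j] <- S[nm, j] + rx[[j]]$products[[nm]]
    }
  }

  state <- list(
    species = y0,
    reactions = rx,
    stoich = S,
    params = params,
    concentrations = concentrations,
    cam_switching = cam_switching,
    time_s = 0,
    rtol = rtol, atol = atol,
    k_flux = 0,
    ampar_p_eq = NA_real_,
    equilibrated = FALSE
  )
  class(state) <- "reaction_network"
  state
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d reactions @ t = %g s\n",
              length(x$species), length(x$reactions), x$time_s))
  cat(sprintf("  calmodulin switching: %s; influx k = %g M/s\n",
              x$cam_switching, x$k_flux))
  tot <- moiety_totals(x)
  cat("  moiety totals (M): ",
      paste(sprintf("%s=%.3g", names(tot), tot), collapse = ", "), "\n")
  if (x$equilibrated) {
    cat(sprintf("  equilibrium AMPAR-P: %.4g M\n", x$ampar_p_eq))
  }
  invisible(x)
}

#' Conserved-moiety totals of the network state
#'
#' @param state a [build_network()] state.
#' @return named numeric: total calmodulin, CaMKII, DARPP-32, PP1 and AMPA
#'   receptor across all bound and modified forms.
#' @export
moiety_totals <- function(state) {
  y <- state$species
  c(
    calmodulin = sum(y[c(paste0("CaMT", 0:4), paste0("CaMR", 0:4),
                         "CaN_CaM", "CaN_CaM_D32P",
                         "CaMKII_CaM", "CaMKII_CaM_P", "PP1_CaMKII_P")]),
    camkii = sum(y[c("CaMKII", "CaMKII_CaM", "CaMKII_CaM_P", "PP1_CaMKII_P")]),
    darpp32 = sum(y[c("D32", "D32P", "PKA_D32", "CaN_CaM_D32P", "D32P_PP1")]),
    pp1 = sum(y[c("PP1", "D32P_PP1", "PP1_CaMKII_P")]),
    ampar = sum(y[c("AMPAR", "AMPAR_P")])
  )
}

#' Reaction table of a network (for audits and export)
#'
#' @param state a [build_network()] state.
#' @return data frame with one row per reaction: name, kind, group,
#'   reactants, products, parameters.
#' @export
reaction_table <- function(state) {
  fmt <- function(v) paste(sprintf("%g %s", unname(v), names(v)), collapse = " + ")
  do.call(rbind, lapply(state$reactions, function(r) {
    data.frame(name = r$name, kind = r$kind, group = r$group,
               reactants = fmt(r$reactants), products = fmt(r$products),
               pars = paste(sprintf("%s=%g", names(Filter(is.numeric, r$pars)),
                                    unlist(Filter(is.numeric, r$pars))),
                            collapse = "; "),
               stringsAsFactors = FALSE)
  }))
}

# free plus calmodulin-bound calcium (M); calcineurin complexes carry the
# single calcium of the partially loaded conformation, CaMKII complexes the
# four of the fully loaded one
total_calcium <- function(y) {
  occup <- sum((1:4) * (y[paste0("CaMT", 1:4)] + y[paste0("CaMR", 1:4)]))
  complexes <- 3 * sum(y[c("CaN_CaM", "CaN_CaM_D32P")]) +
    4 * sum(y[c("CaMKII_CaM", "CaMKII_CaM_P", "PP1_CaMKII_P")])
  unname(y[["Ca"]] + occup + complexes)
}

# reaction rates (M/s) at species vector y; negative concentrations are
# treated as zero so transient solver undershoots cannot feed back
biochem_rates <- function(y, reactions, k_flux) {
  yp <- pmax(y, 0)
  vapply(reactions, function(r) {
    switch(r$kind,
      mass_action_uni = r$pars$k * yp[[names(r$reactants)[1]]],
      mass_action_bi = {
        nm <- names(r$reactants)
        if (length(nm) == 1) r$pars$k * yp[[nm]]^2
        else r$pars$k * yp[[nm[1]]] * yp[[nm[2]]]
      },
      michaelis_menten = {
        s <- yp[[names(r$reactants)[1]]]
        E <- if (is.null(r$pars$enzyme)) 1 else sum(yp[r$pars$enzyme])
        vmax <- if (!is.null(r$pars$vmax)) r$pars$vmax else r$pars$kcat * E
        vmax * s / (s + r$pars$Km)
      },
      constant_flux = {
        k <- if (r$name == "Ca_influx") k_flux else r$pars$k
        # free-calcium floor: a negative influx fades out smoothly as Ca
        # approaches 0 (a hard switch would stall the stiff solver)
        if (k < 0) k * yp[["Ca"]] / (yp[["Ca"]] + 1e-9) else k
      },
      stop("unknown reaction kind: ", r$kind))
  }, numeric(1))
}

biochem_derivative <- function(t, y, state) {
  v <- biochem_rates(y, state$reactions, state$k_flux)
  list(as.numeric(state$stoich %*% v))
}

#' Set the zeroth-order calcium influx constant
#'
#' The coupling layer drives biochemical calcium with a constant-flux
#' process whose rate is the discrete derivative of the electrical shell
#' calcium (see [flux_constant()]).  Negative values are allowed and
#' represent net decline; free calcium is floored at zero.
#'
#' @param state a [build_network()] state.
#' @param k_flux flux constant (M/s).
#' @return the updated state.
#' @export
set_calcium_influx <- function(state, k_flux) {
  stopifnot(inherits(state, "reaction_network"), is.finite(k_flux))
  state$k_flux <- k_flux
  state
}

#' Advance the biochemical network to an absolute time
#'
#' Stiff-capable adaptive integration (lsoda) of the reaction network from
#' the state's current time to `to_time_s`.
#'
#' @param state a [build_network()] state.
#' @param to_time_s target time (s), not earlier than the current time.
#' @return the updated state.
#' @export
step_biochemical <- function(state, to_time_s) {
  stopifnot(inherits(state, "reaction_network"))
  if (to_time_s < state$time_s - 1e-12) {
    stop("step_biochemical cannot move backwards in time")
  }
  if (to_time_s <= state$time_s + 1e-12) return(state)
  t_now <- state$time_s
  y_now <- state$species
  # lsoda may stop short of the target when a step budget is exhausted in a
  # stiff stretch; resume from where it got to rather than mislabel the state
  for (attempt in 1:25) {
    out <- try(suppressWarnings(deSolve::lsoda(
      y = y_now,
      times = c(t_now, to_time_s),
      func = biochem_derivative,
      parms = state,
      rtol = state$rtol, atol = state$atol,
      maxsteps = 200000
    )), silent = TRUE)
    if (inherits(out, "try-error") || nrow(out) < 2) {
      snap <- paste(sprintf("%s=%.4g", names(y_now), y_now), collapse = ", ")
      stop("biochemical solver failure at t = ", t_now, " s; species: ", snap)
    }
    t_reached <- out[nrow(out), 1]
    y_now <- stats::setNames(as.numeric(out[nrow(out), -1]), names(y_now))
    y_now[y_now < 0 & y_now > -1e-12] <- 0   # trim solver round-off
    if (t_reached >= to_time_s - 1e-9) {
      state$species <- y_now
      state$time_s <- to_time_s
      return(state)
    }
    if (t_reached <= t_now) {
      stop("biochemical solver stalled at t = ", t_now, " s")
    }
    t_now <- t_reached
  }
  stop("biochemical solver could not reach t = ", to_time_s,
       " s (stopped at ", t_now, " s)")
}

#' Relax the network to its resting fixed point
#'
#' Integrates with zero calcium influx until the maximum relative
#' derivative falls below `tol` or the horizon is reached, then records the
#' equilibrium phosphorylated-receptor concentration used to normalize the
#' synaptic weight.
#'
#' @param state a [build_network()] state with `k_flux = 0`.
#' @param horizon maximum integration time (s, default 1e6; the slowest
#'   basal mode, turnover of the nearly exhausted free DARPP-32 pool, has a
#'   timescale of about 1e5 s and is integrated out honestly -- the solver
#'   crosses the quiet approach in a handful of large steps).
#' @param tol convergence threshold on `max |dy| / max(|y|, 1e-9)` in 1/s
#'   (default 1e-8).
#' @return the updated state; `state$equilibrated` reports convergence and
#'   `state$ampar_p_eq` the stored reference.  Non-convergence leaves the
#'   state usable but flagged, with a warning.
#' @export
equilibrate <- function(state, horizon = 1e6, tol = 1e-8) {
  stopifnot(inherits(state, "reaction_network"))
  if (state$k_flux != 0) stop("equilibrate requires zero calcium influx")
  rel_deriv <- function(s) {
    dy <- abs(biochem_derivative(s$time_s, s$species, s)[[1]])
    max(dy / pmax(abs(s$species), 1e-9))
  }
  if (rel_deriv(state) < tol) {
    state$equilibrated <- TRUE
    if (is.na(state$ampar_p_eq)) state$ampar_p_eq <- state$species[["AMPAR_P"]]
    return(state)
  }
  t0 <- state$time_s
  chunk <- 50
  while (state$time_s - t0 < horizon) {
    state <- step_biochemical(state,
                              min(state$time_s + chunk, t0 + horizon))
    chunk <- min(chunk * 2, 1e5)
    if (rel_deriv(state) < tol) break
  }
  conv <- rel_deriv(state) < tol
  if (!conv) {
    warning(sprintf("equilibrate: not converged within %g s (max rel. derivative %.3g)",
                    horizon, rel_deriv(state)))
  }
  state$equilibrated <- conv
  state$ampar_p_eq <- state$species[["AMPAR_P"]]
  state
}

#' Wrap a reaction network as a simulator handle
#'
#' Exposes the slow (biochemical) simulator through the kernel's
#' step/get/set contract.  Handle time is in ms (the kernel's clock); the
#' network integrates in seconds internally, and this boundary owns the
#' conversion.  Readable variables: `AMPAR_P` (M), `AMPAR_P_count`
#' (molecules over the configured volume), `Ca` (M, free), `Ca_total`
#' (free plus calmodulin-bound calcium; the quantity that mirrors the
#' electrical calcium waveform), `active_CaMKII`, `active_PP1`,
#' `D32P_fraction` (fractions of their moiety totals), `k_flux` (M/s) and
#' any species name.  Writable: `k_flux`.
#'
#' @param state a [build_network()] state, normally after [equilibrate()].
#' @param volume_fl volume for count conversion (fL, default the reference
#'   spine-head volume).
#' @param time current kernel time (ms).
#' @return a [sim_handle()].
#' @export
biochemical_handle <- function(state, volume_fl = 1.0843, time = 0) {
  stopifnot(inherits(state, "reaction_network"))
  state$time_s <- time * 1e-3   # rebase the network clock to the kernel's
  totals0 <- moiety_totals(state)
  record_row <- function(h, t_ms) {
    y <- h$network$species
    h$trace_rows[[length(h$trace_rows) + 1L]] <- c(
      time_ms = t_ms,
      Ca = y[["Ca"]],
      Ca_total = total_calcium(y),
      AMPAR_P = y[["AMPAR_P"]],
      weight = if (is.na(h$network$ampar_p_eq) || h$network$ampar_p_eq <= 0)
        NA_real_ else y[["AMPAR_P"]] / h$network$ampar_p_eq,
      active_CaMKII = sum(y[c("CaMKII_CaM", "CaMKII_CaM_P", "PP1_CaMKII_P")]) /
        totals0[["camkii"]],
      active_PP1 = y[["PP1"]] / totals0[["pp1"]],
      D32P_fraction = sum(y[c("D32P", "D32P_PP1", "CaN_CaM_D32P")]) /
        totals0[["darpp32"]],
      k_flux = h$network$k_flux)
  }
  sim_handle(
    time = time,
    step = function(h, to_time) {
      if (!is.null(h$record_dt) && h$record_dt > 0) {
        t <- h$time
        repeat {
          t2 <- min(t + h$record_dt, to_time)
          h$network <- step_biochemical(h$network, t2 * 1e-3)
          record_row(h, t2)
          t <- t2
          if (t >= to_time - 1e-9) break
        }
      } else {
        h$network <- step_biochemical(h$network, to_time * 1e-3)
      }
    },
    get = function(h, name) {
      y <- h$network$species
      switch(name,
        AMPAR_P = y[["AMPAR_P"]],
        AMPAR_P_count = conc_to_count(y[["AMPAR_P"]], h$volume_fl),
        Ca = y[["Ca"]],
        Ca_total = total_calcium(y),
        k_flux = h$network$k_flux,
        ampar_p_eq = h$network$ampar_p_eq,
        active_CaMKII = sum(y[c("CaMKII_CaM", "CaMKII_CaM_P", "PP1_CaMKII_P")]) /
          totals0[["camkii"]],
        active_PP1 = y[["PP1"]] / totals0[["pp1"]],
        D32P_fraction = sum(y[c("D32P", "D32P_PP1", "CaN_CaM_D32P")]) /
          totals0[["darpp32"]],
        {
          if (!name %in% names(y)) {
            stop(sprintf("biochemical handle has no variable '%s'", name))
          }
          y[[name]]
        })
    },
    set = function(h, name, value) {
      if (name != "k_flux") {
        stop(sprintf("biochemical handle variable '%s' is read-only", name))
      }
      h$network <- set_calcium_influx(h$network, value)
    },
    deliver = NULL,
    label = "biochemical",
    state = list(network = state, volume_fl = volume_fl,
                 record_dt = 0, trace_rows = list())
  )
}

#' Read and write kinetic parameter configurations
#'
#' YAML layout mirrors the table-keyed parameter structure:
#' `table6:` (calmodulin machinery), `table7:` (reaction constants),
#' `table8:` (initial concentrations).
#'
#' @param params nested list as from [default_biochem_params()].
#' @param concentrations named numeric as from
#'   [default_initial_concentrations()].
#' @param path file path.
#' @return `read_biochem_config` returns `list(params, concentrations)`;
#'   `write_biochem_config` returns `path` invisibly.
#' @export
write_biochem_config <- function(params, concentrations, path) {
  yaml::write_yaml(list(table6 = params$table6, table7 = params$table7,
                        table8 = as.list(concentrations)), path)
  invisible(path)
}

#' @rdname write_biochem_config
#' @export
read_biochem_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  t6 <- cfg$table6
  t6$koff_t <- as.numeric(unlist(t6$koff_t))
  t6$koff_r <- as.numeric(unlist(t6$koff_r))
  list(params = list(table6 = t6, table7 = cfg$table7),
       concentrations = unlist(cfg$table8))
}
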