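#' Variable-exchange specification
#'
#' Describes what the synchronization cycle exchanges between the two
#' simulators.  Each mapping names a source variable, a destination variable
#' and the phase it belongs to: phase 1 mappings are read from the slow
#' simulator and written into the fast one before the fast simulator
#' advances; phase 3 mappings flow from fast to slow after it.  An optional
#' `transform` function receives the raw value and the destination's current
#' value and returns the value to write (identity by default).
#'
#' Three hooks support stateful couplings: `on_window_start(fast, slow)`
#' runs when a forced-synchronization window opens (the hybrid coupling
#' seeds its calcium memory there); `on_window_end(fast, slow)` runs when
#' the window closes (the hybrid coupling zeroes the influx constant there,
#' because a discrete derivative estimated inside the window must not keep
#' extrapolating while the simulators run free); and
#' `before_deliver(fast, slow, event)` runs just before an event is
#' injected into the fast simulator (the hybrid coupling refreshes the
#' synaptic weight there, so the stimulus is delivered with the up-to-date
#' weight).
#'
#' @param mappings list of [coupling_map()]s.
#' @param on_window_start optional function(fast, slow).
#' @param on_window_end optional function(fast, slow).
#' @param before_deliver optional function(fast, slow, event).
#' @return list of class `"coupling_spec"`.
#' @seealso [hybrid_coupling()], [gain_coupling()]
#' @export
coupling_spec <- function(mappings = list(), on_window_start = NULL,
                          on_window_end = NULL, before_deliver = NULL) {
  structure(list(mappings = mappings,
                 on_window_start = on_window_start,
                 on_window_end = on_window_end,
                 before_deliver = before_deliver),
            class = "coupling_spec")
}

#' @rdname coupling_spec
#' @param phase 1 (slow to fast) or 3 (fast to slow).
#' @param var_from source variable name.
#' @param var_to destination variable name.
#' @param transform optional function(raw, current) returning the value to
#'   write.
#' @export
coupling_map <- function(phase, var_from, var_to, transform = NULL) {
  stopifnot(phase %in% c(1L, 3L))
  list(phase = as.integer(phase), var_from = var_from, var_to = var_to,
       transform = transform)
}

#' @rdname coupling_spec
#' @export
coupling_none <- function() coupling_spec(list())

#' Symmetric additive coupling between two scalar simulators
#'
#' Test coupling for the toy simulators: on each cycle the destination's
#' variable is incremented by `gain` times the source's value, in both
#' directions (`x_fast <- x_fast + g x_slow` in phase 1, and conversely in
#' phase 3).  With `gain = 0` the simulators are fully decoupled and each
#' follows its own closed form.
#'
#' @param gain dimensionless coupling gain.
#' @param var variable name on both sides (default `"x"`).
#' @return a [coupling_spec()].
#' @export
gain_coupling <- function(gain, var = "x") {
  if (gain == 0) return(coupling_none())
  add <- function(raw, current) current + gain * raw
  coupling_spec(list(
    coupling_map(1L, var, var, add),
    coupling_map(3L, var, var, add)
  ))
}

# --- unit bridges -------------------------------------------------------------

#' Avogadro constant (1/mol)
#' @keywords internal
.avogadro <- 6.02214076e23

#' Calcium flux constant from two electrical calcium samples
#'
#' The biochemical model receives electrical calcium as a zeroth-order flux
#' rather than by overwriting its free-calcium pool (which would be
#' instantly buffered by calmodulin and lose the waveform).  The flux
#' constant is the discrete derivative of the electrical shell concentration
#' over the exchange interval, converted from mM/ms to M/s.  The sign is
#' preserved: a declining electrical calcium drives a declining biochemical
#' calcium.
#'
#' @param ca_t1 shell calcium at the start of the interval (mM).
#' @param ca_t2 shell calcium at the end of the interval (mM).
#' @param delta interval length (ms), positive.
#' @return flux constant in M/s.  (mM/ms and M/s are numerically equal, so
#'   the conversion factor is 1; it is kept explicit for auditability.)
#' @examples
#' flux_constant(0.0, 0.001, 1)  # rise of 1 uM over 1 ms -> 1e-3 M/s
#' @export
flux_constant <- function(ca_t1, ca_t2, delta) {
  if (!(delta > 0)) stop("delta must be positive")
  mM_per_ms <- (ca_t2 - ca_t1) / delta
  mM_per_ms * 1e-3 / 1e-3   # mM -> M and 1/ms -> 1/s
}

#' Synaptic weight from phosphorylated AMPA receptor abundance
#'
#' The weight of the AMPA synapse is the phosphorylated-receptor count at
#' the current time normalized by its equilibrium value, so the resting
#' weight is 1, potentiation gives weights above 1 and depression below 1.
#' The weight multiplies the AMPA peak conductance at the next delivered
#' stimulus.
#'
#' @param ampar_p_t current phosphorylated AMPA receptor count (or
#'   concentration; only the ratio matters).
#' @param ampar_p_eq equilibrium reference, strictly positive.
#' @return dimensionless weight.
#' @export
compute_weight <- function(ampar_p_t, ampar_p_eq) {
  if (!(ampar_p_eq > 0)) stop("equilibrium AMPAR-P reference must be positive")
  ampar_p_t / ampar_p_eq
}

#' Convert a concentration to a molecule count
#'
#' @param conc concentration (M).
#' @param volume compartment volume (fL).
#' @return expected molecule count (real-valued; rounding, if wanted, is a
#'   reporting decision).
#' @examples
#' conc_to_count(1e-6, 1.084)  # ~653 molecules of a 1 uM species in a spine head
#' @export
conc_to_count <- function(conc, volume) {
  if (!(volume > 0)) stop("volume must be positive")
  conc * .avogadro * volume * 1e-15
}

#' @rdname conc_to_count
#' @param count molecule count.
#' @export
count_to_conc <- function(count, volume) {
  if (!(volume > 0)) stop("volume must be positive")
  count / (.avogadro * volume * 1e-15)
}

# --- the hybrid electrical <-> biochemical coupling ---------------------------

#' Coupling between the electrical and biochemical spine models
#'
#' Builds the [coupling_spec()] that ties the two simulators together, one
#' mapping pair per stimulated spine:
#'
#' * phase 1 (slow to fast): phosphorylated AMPA receptor concentration is
#'   read from the biochemical instance, converted to a count over the
#'   spine-head volume, normalized by its equilibrium count
#'   ([compute_weight()]), and written to the electrical synapse weight.
#' * phase 3 (fast to slow): the electrical shell calcium is read, its
#'   discrete derivative over the elapsed exchange interval is converted to
#'   a zeroth-order flux constant ([flux_constant()]) and written to the
#'   biochemical calcium-influx process.
#'
#' Variable names follow the handle conventions of the two simulators:
#' `weight_<id>` and `Ca_<id>` on the electrical side, `<id>:AMPAR_P` and
#' `<id>:k_flux` on the biochemical side (see [composite_handle()]).
#'
#' @param spine_ids character vector of stimulated spine identifiers.
#' @param volume_fl spine-head volume (fL) used for count conversion.
#' @param ampar_p_eq named numeric: equilibrium phosphorylated-receptor
#'   concentration (M) per spine id, recorded by [equilibrate()].
#' @param endpoint_sampling if `TRUE` (default) the calcium derivative uses
#'   the interval endpoints; this is the fixed-cadence scheme, the only mode
#'   the kernel currently exercises.
#' @return a [coupling_spec()].
#' @export
hybrid_coupling <- function(spine_ids, volume_fl, ampar_p_eq,
                            endpoint_sampling = TRUE) {
  spine_ids <- as.character(spine_ids)
  stopifnot(all(spine_ids %in% names(ampar_p_eq)))
  rt <- new.env(parent = emptyenv())    # cycle timing, filled by the kernel
  rt$delta <- NA_real_
  mem <- new.env(parent = emptyenv())   # previous calcium sample per spine
  mem$ca_prev <- stats::setNames(rep(NA_real_, length(spine_ids)), spine_ids)

  weight_map <- function(id) {
    eq_count <- conc_to_count(ampar_p_eq[[id]], volume_fl)
    coupling_map(1L, paste0(id, ":AMPAR_P"), paste0("weight_", id),
                 transform = function(raw, current) {
                   compute_weight(conc_to_count(raw, volume_fl), eq_count)
                 })
  }
  flux_map <- function(id) {
    force(id)
    coupling_map(3L, paste0("Ca_", id), paste0(id, ":k_flux"),
                 transform = function(raw, current) {
                   prev <- mem$ca_prev[[id]]
                   mem$ca_prev[[id]] <- raw
                   if (is.na(prev) || !isTRUE(rt$delta > 0)) return(0)
                   flux_constant(prev, raw, rt$delta)
                 })
  }

  spec <- coupling_spec(
    mappings = c(lapply(spine_ids, weight_map), lapply(spine_ids, flux_map)),
    on_window_start = function(fast, slow) {
      for (id in spine_ids) {
        mem$ca_prev[[id]] <- handle_get(fast, paste0("Ca_", id))
      }
    },
    on_window_end = function(fast, slow) {
      for (id in spine_ids) {
        handle_set(slow, paste0(id, ":k_flux"), 0)
      }
    },
    before_deliver = function(fast, slow, event) {
      id <- as.character(event$target_id)
      if (!id %in% spine_ids) return(invisible(NULL))
      eq_count <- conc_to_count(ampar_p_eq[[id]], volume_fl)
      w <- compute_weight(
        conc_to_count(handle_get(slow, paste0(id, ":AMPAR_P")), volume_fl),
        eq_count)
      handle_set(fast, paste0("weight_", id), w)
      invisible(NULL)
    }
  )
  spec$runtime <- rt
  spec
}

#' Apply the phase-1 and phase-3 transforms of a coupling once
#'
#' Convenience wrapper running one four-phase cycle of length `delta` under
#' `spec`; identical to [synchronize_cycle()] but named for the coupling
#' view of the operation.
#'
#' @param fast,slow [sim_handle()]s at equal times.
#' @param spec a [coupling_spec()].
#' @param delta cycle length (ms).
#' @return common end time, invisibly.
#' @export
exchange_pair <- function(fast, slow, spec, delta) {
  synchronize_cycle(fast, slow, delta, exchange = spec)
}
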