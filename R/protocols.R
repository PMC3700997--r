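#' Stimulation train
#'
#' Regular train of synaptic events: `n_inputs` events starting at `start`
#' with spacing `1000 / frequency` ms.  The reported duration follows the
#' convention `n_inputs / frequency` seconds (an 8 Hz train of 50 inputs
#' lasts 6.25 s).
#'
#' @param frequency stimulation frequency (Hz), positive.
#' @param n_inputs number of stimuli, at least 1.
#' @param start time of the first stimulus (ms).
#' @param targets spine ids receiving the train.
#' @param synapse_kind `"both"` (default), `"AMPA"` or `"NMDA"`.
#' @return object of class `"stim_train"` with fields `times` (ms) and
#'   `duration_s`.
#' @examples
#' build_train(8, 50)$duration_s    # 6.25
#' diff(build_train(8, 3)$times)    # 125 125
#' @export
build_train <- function(frequency, n_inputs, start = 0, targets = "s1",
                        synapse_kind = "both") {
  if (!(frequency > 0)) stop("frequency must be positive")
  if (!(n_inputs >= 1)) stop("n_inputs must be at least 1")
  times <- start + (seq_len(n_inputs) - 1) * (1000 / frequency)
  structure(list(frequency = frequency, n_inputs = as.integer(n_inputs),
                 start = start, targets = as.character(targets),
                 synapse_kind = synapse_kind,
                 times = times, duration_s = n_inputs / frequency),
            class = "stim_train")
}

#' @export
print.stim_train <- function(x, ...) {
  cat(sprintf("<stim_train> %g Hz x %d inputs from %g ms (%.4g s) -> %s\n",
              x$frequency, x$n_inputs, x$start, x$duration_s,
              paste(x$targets, collapse = ",")))
  invisible(x)
}

# flatten trains into a sorted event list
trains_to_events <- function(trains) {
  evs <- list()
  for (tr in trains) {
    for (t in tr$times) {
      for (tg in tr$targets) {
        evs[[length(evs) + 1L]] <- sync_event(t, tg, tr$synapse_kind)
      }
    }
  }
  evs[order(vapply(evs, function(e) e$time, numeric(1)))]
}

#' Experiment configuration
#'
#' Everything needed to rerun a co-simulation experiment: morphology and
#' spine placement, stimulation trains, synchronization schedule, solver
#' settings, and which spines get a biochemical instance (only stimulated
#' spines do; the others remain purely electrical).
#'
#' @param trains list of [build_train()]s.
#' @param t_stop end of simulation (ms).
#' @param spines data frame (`id`, `segment`); defaults to one spine on
#'   the distal dendrite of a single-branch reduced tree.
#' @param stimulated ids receiving biochemical instances; defaults to all
#'   train targets.
#' @param n_dendrites,tree passed to [msn_morphology()].
#' @param delta_exchange,window_length synchronization parameters (ms).
#' @param strategy `"event"` (default), `"fixed"` or `"on-demand"`.
#' @param dt_sync fixed-step synchronization interval (ms; `"fixed"` only).
#' @param biochem_enabled create and couple the biochemical instances
#'   (`FALSE` freezes all synaptic weights at 1).
#' @param biochem_params,biochem_concentrations see [build_network()].
#' @param record_dt_elec,record_dt_biochem trace cadences (ms).
#' @param dt_elec electrical integration step (ms).
#' @param v_init initial potential (mV).
#' @param seed integer recorded in the archive (the deterministic pipeline
#'   does not consume randomness; the seed still names the run).
#' @return list of class `"experiment_config"`.
#' @export
experiment_config <- function(trains,
                              t_stop,
                              spines = data.frame(id = "s1",
                                                  segment = "dend1_1_1"),
                              stimulated = NULL,
                              n_dendrites = 1, tree = "reduced",
                              delta_exchange = 1, window_length = 10,
                              strategy = c("event", "fixed", "on-demand"),
                              dt_sync = 10,
                              biochem_enabled = TRUE,
                              biochem_params = default_biochem_params(),
                              biochem_concentrations = default_initial_concentrations(),
                              record_dt_elec = 1, record_dt_biochem = 10,
                              dt_elec = 0.025, v_init = -80,
                              seed = 1L) {
  strategy <- match.arg(strategy)
  if (is.null(stimulated)) {
    stimulated <- unique(unlist(lapply(trains, `[[`, "targets")))
  }
  stopifnot(all(stimulated %in% spines$id))
  structure(list(trains = trains, t_stop = t_stop, spines = spines,
                 stimulated = as.character(stimulated),
                 n_dendrites = n_dendrites, tree = tree,
                 delta_exchange = delta_exchange,
                 window_length = window_length,
                 strategy = strategy, dt_sync = dt_sync,
                 biochem_enabled = biochem_enabled,
                 biochem_params = biochem_params,
                 biochem_concentrations = biochem_concentrations,
                 record_dt_elec = record_dt_elec,
                 record_dt_biochem = record_dt_biochem,
                 dt_elec = dt_elec, v_init = v_init, seed = seed),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %d train(s), t_stop %g ms, %s sync, biochemistry %s\n",
              length(x$trains), x$t_stop, x$strategy,
              if (x$biochem_enabled) "on" else "off"))
  for (tr in x$trains) print(tr)
  invisible(x)
}

#' Head-cylinder volume of a spine geometry (fL)
#' @param geom a [spine_geometry()].
#' @export
spine_head_volume_fl <- function(geom = spine_geometry()) {
  pi * (geom$head$diameter / 2)^2 * geom$head$length  # um^3 == fL
}

#' Run a co-simulation experiment
#'
#' Builds the electrical model (all spines instantiated electrically), one
#' equilibrated biochemical network per *stimulated* spine, merges the
#' stimulation trains into a single event queue and runs the selected
#' synchronization strategy.  Returns an archive holding all recorded
#' traces, the synchronization log and a config snapshot sufficient to
#' rerun the experiment.
#'
#' @param cfg an [experiment_config()].
#' @param quiet suppress progress messages.
#' @return object of class `"spine_experiment"`.
#' @export
run_experiment <- function(cfg, quiet = TRUE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  events <- trains_to_events(cfg$trains)
  validate_events(events, cfg$t_stop)

  say("building electrical model (%d spines)", nrow(cfg$spines))
  emod <- build_electrical_model(
    morphology = msn_morphology(n_dendrites = cfg$n_dendrites, tree = cfg$tree),
    spines = cfg$spines, v_init = cfg$v_init, dt_elec = cfg$dt_elec)
  fast <- electrical_handle(emod, record_dt = cfg$record_dt_elec)
  volume_fl <- spine_head_volume_fl()

  if (cfg$biochem_enabled) {
    say("equilibrating biochemical network")
    base_net <- equilibrate(build_network(cfg$biochem_params,
                                          cfg$biochem_concentrations))
    subs <- list()
    eq <- numeric(0)
    for (id in cfg$stimulated) {
      subs[[id]] <- biochemical_handle(base_net, volume_fl = volume_fl,
                                       time = 0)
      subs[[id]]$record_dt <- cfg$record_dt_biochem
      eq[[id]] <- base_net$ampar_p_eq
    }
    slow <- composite_handle(subs)
    exchange <- hybrid_coupling(cfg$stimulated, volume_fl, eq)
  } else {
    slow <- make_toy_simulator("constant", list(c = 0))
    slow$label <- "biochemistry-disabled"
    exchange <- coupling_none()
    eq <- stats::setNames(rep(NA_real_, length(cfg$stimulated)), cfg$stimulated)
  }

  schedule <- sync_schedule(cfg$t_stop, cfg$delta_exchange, cfg$window_length)
  say("running %s-driven co-simulation to %g ms (%d events)",
      cfg$strategy, cfg$t_stop, length(events))
  synclog <- switch(cfg$strategy,
    event = run_event_driven(fast, slow, events, schedule, exchange),
    fixed = run_fixed_step(fast, slow, events, cfg$dt_sync, cfg$t_stop, exchange),
    `on-demand` = stop("on-demand strategy needs an event-emitting fast model; ",
                       "use the event strategy for a-priori trains"))

  biochem_traces <- list()
  final_networks <- list()
  if (cfg$biochem_enabled) {
    for (id in cfg$stimulated) {
      biochem_traces[[id]] <- biochem_trace_of(slow, id)
      final_networks[[id]] <- slow$subs[[id]]$network
    }
  }

  structure(list(
    config = cfg,
    traces_elec = electrical_traces(emod),
    traces_biochem = biochem_traces,
    ampar_p_eq = eq,
    synclog = synclog,
    volume_fl = volume_fl,
    initial_network = if (cfg$biochem_enabled) base_net else NULL,
    final_networks = final_networks,
    electrical_model = emod
  ), class = "spine_experiment")
}

# assemble the recorded biochemical trace of one composite sub-handle
biochem_trace_of <- function(slow, id) {
  sub <- slow$subs[[id]]
  if (is.null(sub$trace_rows) || length(sub$trace_rows) == 0) {
    return(data.frame(time_ms = numeric(0), Ca = numeric(0),
                      AMPAR_P = numeric(0), weight = numeric(0),
                      active_CaMKII = numeric(0), active_PP1 = numeric(0),
                      D32P_fraction = numeric(0), k_flux = numeric(0)))
  }
  df <- as.data.frame(do.call(rbind, sub$trace_rows))
  df
}

#' @export
print.spine_experiment <- function(x, ...) {
  cat("<spine_experiment>\n")
  print(x$config)
  print(x$synclog)
  cat(sprintf("  electrical trace: %d rows; biochemical instances: %d\n",
              nrow(x$traces_elec), length(x$traces_biochem)))
  invisible(x)
}

#' Write an experiment archive to a directory
#'
#' Plain-text hierarchical layout: `traces/electrical.csv`,
#' `traces/<spine>_biochemical.csv`, `synclog/` (see [write_sync_log()]),
#' `config.yaml` and `index.json`.
#'
#' @param archive a [run_experiment()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_archive <- function(archive, dir) {
  stopifnot(inherits(archive, "spine_experiment"))
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(archive$traces_elec,
                   file.path(dir, "traces", "electrical.csv"), row.names = FALSE)
  for (id in names(archive$traces_biochem)) {
    utils::write.csv(archive$traces_biochem[[id]],
                     file.path(dir, "traces", paste0(id, "_biochemical.csv")),
                     row.names = FALSE)
  }
  write_sync_log(archive$synclog, file.path(dir, "synclog"))
  cfg <- archive$config
  cfg_list <- cfg[setdiff(names(cfg), c("biochem_params",
                                        "biochem_concentrations", "trains",
                                        "spines"))]
  cfg_list$trains <- lapply(cfg$trains, function(tr) {
    tr[c("frequency", "n_inputs", "start", "targets", "synapse_kind")]
  })
  cfg_list$spines <- as.list(cfg$spines)
  cfg_list$biochem_params <- cfg$biochem_params
  cfg_list$biochem_concentrations <- as.list(cfg$biochem_concentrations)
  yaml::write_yaml(cfg_list, file.path(dir, "config.yaml"))
  idx <- list(kind = "spine_experiment",
              ampar_p_eq = as.list(archive$ampar_p_eq),
              volume_fl = archive$volume_fl,
              spines = names(archive$traces_biochem))
  writeLines(yaml::as.yaml(idx), file.path(dir, "index.yaml"))
  invisible(dir)
}

#' Rebuild an experiment configuration from an archive directory
#'
#' Reads `config.yaml` back into an [experiment_config()]; together with
#' [run_experiment()] this makes every archive self-reproducing.
#'
#' @param dir archive directory written by [write_archive()].
#' @return an [experiment_config()].
#' @export
read_archive_config <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  trains <- lapply(cfg$trains, function(tr) {
    build_train(tr$frequency, tr$n_inputs, tr$start,
                unlist(tr$targets), tr$synapse_kind)
  })
  bp <- cfg$biochem_params
  bp$table6$koff_t <- as.numeric(unlist(bp$table6$koff_t))
  bp$table6$koff_r <- as.numeric(unlist(bp$table6$koff_r))
  experiment_config(
    trains = trains, t_stop = cfg$t_stop,
    spines = as.data.frame(cfg$spines, stringsAsFactors = FALSE),
    stimulated = unlist(cfg$stimulated),
    n_dendrites = cfg$n_dendrites, tree = cfg$tree,
    delta_exchange = cfg$delta_exchange, window_length = cfg$window_length,
    strategy = cfg$strategy, dt_sync = cfg$dt_sync,
    biochem_enabled = cfg$biochem_enabled,
    biochem_params = bp,
    biochem_concentrations = unlist(cfg$biochem_concentrations),
    record_dt_elec = cfg$record_dt_elec,
    record_dt_biochem = cfg$record_dt_biochem,
    dt_elec = cfg$dt_elec, v_init = cfg$v_init, seed = cfg$seed)
}

#' Summarize the plasticity outcome of an experiment
#'
#' Per stimulated spine and train: peak head depolarization during the
#' train, peak phosphorylated-receptor level and its time, and the
#' second-minus-first train peak-voltage difference (the biochemical
#' fingerprint: positive when the weight increase carried over from the
#' first train amplifies the response to the second, zero when the
#' biochemistry is disabled).
#'
#' @param archive a [run_experiment()] result.
#' @param window_ms how far past the last stimulus of a train its response
#'   window extends (default 200 ms).
#' @return data frame, one row per spine.
#' @export
summarize_plasticity <- function(archive, window_ms = 200) {
  stopifnot(inherits(archive, "spine_experiment"))
  tr_el <- archive$traces_elec
  trains <- archive$config$trains
  out <- list()
  for (id in archive$config$stimulated) {
    vcol <- paste0("V_head_", id)
    if (!vcol %in% names(tr_el) || nrow(tr_el) == 0) next
    peaks <- rep(NA_real_, length(trains))
    for (k in seq_along(trains)) {
      tr <- trains[[k]]
      if (!id %in% tr$targets) next
      lo <- tr$start
      hi <- max(tr$times) + window_ms
      seg <- tr_el[tr_el$time_ms >= lo & tr_el$time_ms <= hi, vcol]
      if (length(seg) > 0) peaks[k] <- max(seg)
    }
    bio <- archive$traces_biochem[[id]]
    if (!is.null(bio) && nrow(bio) > 0) {
      ipk <- which.max(bio$AMPAR_P)
      pk_ampar <- bio$AMPAR_P[ipk]
      t_pk <- bio$time_ms[ipk]
      pk_camkii <- max(bio$active_CaMKII)
      pk_pp1 <- max(bio$active_PP1)
    } else {
      pk_ampar <- NA_real_; t_pk <- NA_real_
      pk_camkii <- NA_real_; pk_pp1 <- NA_real_
    }
    out[[id]] <- data.frame(
      spine = id,
      peak_v_train1 = peaks[1],
      peak_v_train2 = if (length(peaks) >= 2) peaks[2] else NA_real_,
      delta_peak_v = if (length(peaks) >= 2) peaks[2] - peaks[1] else NA_real_,
      peak_ampar_p = pk_ampar,
      t_peak_ampar_p_ms = t_pk,
      peak_active_camkii = pk_camkii,
      peak_active_pp1 = pk_pp1,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(spine = character(0), peak_v_train1 = numeric(0),
                      peak_v_train2 = numeric(0), delta_peak_v = numeric(0),
                      peak_ampar_p = numeric(0),
                      t_peak_ampar_p_ms = numeric(0),
                      peak_active_camkii = numeric(0),
                      peak_active_pp1 = numeric(0)))
  }
  ans <- do.call(rbind, out)
  rownames(ans) <- NULL
  ans
}

#' Compare synchronization strategies on one event set
#'
#' Runs the same events under the event-driven strategy and fixed-step
#' baselines at each `dt_sync`, using inert toy simulators (the missed /
#' delivered bookkeeping depends only on event times and the grid, never
#' on model content).  Wall-clock times are reported for information only.
#' An optional sparseness sweep splits a fixed event total across
#' different numbers of spines and reports the exchange-cycle count for
#' each (constant for the event-driven strategy).
#'
#' @param events list of [sync_event()]s (or a list of [build_train()]s).
#' @param t_stop end of simulation (ms).
#' @param strategies subset of `c("event", "fixed")`.
#' @param dt_values fixed-step intervals to try (ms).
#' @param schedule a [sync_schedule()] for the event strategy.
#' @param sparseness optional integer vector: numbers of spines across
#'   which to split the events (events per spine scale down so the total
#'   stays fixed).
#' @param make_handles function() returning `list(fast, slow)`; defaults
#'   to inert toys.  Swapping in other simulators must not change the
#'   missed-event accounting.
#' @return data frame of class `"sync_benchmark"`.
#' @export
benchmark_sync <- function(events, t_stop,
                           strategies = c("event", "fixed"),
                           dt_values = c(10, 100),
                           schedule = sync_schedule(t_stop),
                           sparseness = NULL,
                           make_handles = NULL) {
  if (length(events) > 0 && inherits(events[[1]], "stim_train")) {
    events <- trains_to_events(events)
  }
  strategies <- match.arg(strategies, several.ok = TRUE)
  if (is.null(make_handles)) {
    make_handles <- function() list(
      fast = make_toy_simulator("constant", list(c = 0)),
      slow = make_toy_simulator("constant", list(c = 0)))
  }
  rows <- list()
  run_one <- function(strategy, dt, evs, label) {
    hs <- make_handles()
    wall <- system.time(
      log <- if (strategy == "event") {
        run_event_driven(hs$fast, hs$slow, evs, schedule)
      } else {
        run_fixed_step(hs$fast, hs$slow, evs, dt, t_stop)
      }
    )[["elapsed"]]
    s <- summary(log)
    rows[[length(rows) + 1L]] <<- data.frame(
      case = label, strategy = strategy,
      dt_sync = if (strategy == "fixed") dt else NA_real_,
      events_total = s$events_total, delivered = s$events_delivered,
      missed = s$events_missed, pct_missed = s$pct_missed,
      exchange_cycles = s$exchange_cycles, wall_s = wall,
      stringsAsFactors = FALSE)
  }
  for (strategy in strategies) {
    if (strategy == "event") {
      run_one("event", NA, events, "all")
    } else {
      for (dt in dt_values) run_one("fixed", dt, events, "all")
    }
  }
  if (!is.null(sparseness)) {
    times <- vapply(events, function(e) e$time, numeric(1))
    for (ns in sparseness) {
      evs <- lapply(seq_along(times), function(i) {
        sync_event(times[i], target_id = sprintf("s%d", ((i - 1) %% ns) + 1))
      })
      run_one("event", NA, evs, sprintf("sparseness_%d", ns))
    }
  }
  ans <- do.call(rbind, rows)
  class(ans) <- c("sync_benchmark", "data.frame")
  ans
}
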