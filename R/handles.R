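#' Simulator handle contract
#'
#' A *simulator handle* is the minimal interface the synchronization kernel
#' requires from any simulator it coordinates: a current time, a `step`
#' method that advances internal state to an absolute target time, and
#' `get`/`set` methods for named scalar variables.  Handles are mutable
#' (environment-backed) so that the kernel, the coupling layer and the user
#' all observe the same state.
#'
#' Contract invariants: `step` never moves time backwards; a `get`
#' immediately after a `set` returns the written value; stepping to the
#' current time is a no-op.
#'
#' @param time initial simulated time (ms).
#' @param step function(handle, to_time) advancing internal state.
#' @param get function(handle, name) returning a named scalar.
#' @param set function(handle, name, value) writing a named scalar.
#' @param deliver optional function(handle, event) applying a stimulation
#'   event (see [sync_event()]); simulators that cannot receive events may
#'   omit it.
#' @param emitted optional function(handle) returning events generated during
#'   the most recent `step` (used by the on-demand strategy).
#' @param label short description used in printing.
#' @param state optional list copied into the handle environment.
#' @return an environment of class `"sim_handle"`.
#' @seealso [make_toy_simulator()], [run_event_driven()]
#' @export
sim_handle <- function(time = 0, step, get, set, deliver = NULL,
                       emitted = NULL, label = "simulator", state = list()) {
  stopifnot(is.function(step), is.function(get), is.function(set))
  h <- new.env(parent = emptyenv())
  h$time <- as.numeric(time)
  h$.step <- step
  h$.get <- get
  h$.set <- set
  h$.deliver <- deliver
  h$.emitted <- emitted
  h$label <- label
  for (nm in names(state)) assign(nm, state[[nm]], envir = h)
  class(h) <- "sim_handle"
  h
}

#' @export
print.sim_handle <- function(x, ...) {
  cat(sprintf("<sim_handle> %s @ t = %g ms\n", x$label, x$time))
  invisible(x)
}

#' Query a handle's current simulated time (ms)
#' @param h a [sim_handle()].
#' @export
handle_time <- function(h) h$time

#' Advance a simulator handle to an absolute time
#'
#' @param h a [sim_handle()].
#' @param to_time target time (ms); must not be earlier than the handle's
#'   current time.  Stepping to the current time is a no-op.
#' @return the handle, invisibly.
#' @export
handle_step <- function(h, to_time) {
  if (to_time < h$time - 1e-9) {
    stop(sprintf("handle '%s': cannot step backwards from %g to %g ms",
                 h$label, h$time, to_time))
  }
  if (to_time > h$time + 1e-12) {
    h$.step(h, to_time)
    h$time <- to_time
  }
  invisible(h)
}

#' Read a named scalar variable from a handle
#' @param h a [sim_handle()].
#' @param name variable name.
#' @export
handle_get <- function(h, name) h$.get(h, name)

#' Write a named scalar variable into a handle
#' @param h a [sim_handle()].
#' @param name variable name.
#' @param value new value.
#' @return the handle, invisibly.
#' @export
handle_set <- function(h, name, value) {
  h$.set(h, name, value)
  invisible(h)
}

#' Deliver a stimulation event to a handle
#' @param h a [sim_handle()].
#' @param event a [sync_event()].
#' @return the handle, invisibly.
#' @export
handle_deliver <- function(h, event) {
  if (is.null(h$.deliver)) {
    stop(sprintf("handle '%s' does not accept events", h$label))
  }
  h$.deliver(h, event)
  invisible(h)
}

#' Events emitted by a handle during its most recent step
#'
#' Simulators participating in on-demand synchronization report events they
#' generated while stepping; others return an empty list.
#' @param h a [sim_handle()].
#' @return list of [sync_event()]s (possibly empty).
#' @export
handle_emitted <- function(h) {
  if (is.null(h$.emitted)) return(list())
  h$.emitted(h)
}

#' Does a handle declare an event source?
#' @param h a [sim_handle()].
#' @keywords internal
handle_emits <- function(h) !is.null(h$.emitted)

#' Toy simulators with closed-form dynamics
#'
#' Small simulators whose exact trajectories are known analytically; they
#' serve as oracles when testing the synchronization strategies.
#'
#' * `exponential_decay`: dx/dt = -lambda * x, so x(t) = x0 * exp(-lambda t).
#' * `constant`: x(t) = c.
#' * `ramp`: x(t) = x0 + slope * t.
#'
#' All expose the variable `"x"` via get/set.  A delivered event adds
#' `impulse` to `x` (default 0, i.e. events are accepted but inert).  For
#' on-demand experiments, `emit_at` programs the simulator to report events
#' at fixed times: an event is reported at the end of the first step whose
#' interval contains its time.
#'
#' @param kind one of `"exponential_decay"`, `"constant"`, `"ramp"`.
#' @param params named list: `lambda` (1/ms) and `x0` for decay; `c` for
#'   constant; `slope` (1/ms) and optional `x0` for ramp; optional `impulse`
#'   and `emit_at` (ms) for all kinds.
#' @param time initial time (ms).
#' @return a [sim_handle()].
#' @examples
#' h <- make_toy_simulator("exponential_decay", list(lambda = 1e-3, x0 = 1))
#' handle_step(h, 1000)
#' handle_get(h, "x")  # exp(-1)
#' @export
make_toy_simulator <- function(kind = c("exponential_decay", "constant", "ramp"),
                               params = list(), time = 0) {
  kind <- match.arg(kind)
  impulse <- params$impulse %||% 0
  emit_at <- sort(as.numeric(params$emit_at %||% numeric(0)))

  step <- switch(kind,
    exponential_decay = function(h, to_time) {
      h$x <- h$x * exp(-h$lambda * (to_time - h$time))
      toy_collect_emissions(h, to_time)
    },
    constant = function(h, to_time) toy_collect_emissions(h, to_time),
    ramp = function(h, to_time) {
      h$x <- h$x + h$slope * (to_time - h$time)
      toy_collect_emissions(h, to_time)
    })

  state <- switch(kind,
    exponential_decay = {
      if (is.null(params$lambda)) stop("exponential_decay requires 'lambda'")
      list(lambda = params$lambda, x = params$x0 %||% 1)
    },
    constant = {
      if (is.null(params$c)) stop("constant requires 'c'")
      list(x = params$c)
    },
    ramp = {
      if (is.null(params$slope)) stop("ramp requires 'slope'")
      list(slope = params$slope, x = params$x0 %||% 0)
    })
  state$impulse <- impulse
  state$emit_at <- emit_at
  state$pending_emissions <- list()

  sim_handle(
    time = time,
    step = step,
    get = function(h, name) {
      if (!name %in% c("x")) stop(sprintf("toy simulator has no variable '%s'", name))
      h$x
    },
    set = function(h, name, value) {
      if (!name %in% c("x")) stop(sprintf("toy simulator has no variable '%s'", name))
      h$x <- value
    },
    deliver = function(h, event) {
      h$x <- h$x + h$impulse
    },
    emitted = if (length(emit_at) > 0) {
      function(h) {
        ev <- h$pending_emissions
        h$pending_emissions <- list()
        ev
      }
    },
    label = paste0("toy:", kind),
    state = state
  )
}

# record programmed emissions falling in (h$time, to_time]
toy_collect_emissions <- function(h, to_time) {
  if (length(h$emit_at) == 0) return(invisible(NULL))
  hit <- h$emit_at > h$time + 1e-12 & h$emit_at <= to_time + 1e-12
  if (any(hit)) {
    h$pending_emissions <- c(h$pending_emissions,
                             lapply(h$emit_at[hit], sync_event))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundle several simulator handles behind one handle
#'
#' Experiments instantiate one biochemical network per stimulated spine but
#' the kernel coordinates a single slow simulator; this wrapper steps all
#' sub-handles together and namespaces their variables as `"<id>:<var>"`.
#'
#' @param handles named list of [sim_handle()]s, all at the same time.
#' @return a [sim_handle()].
#' @export
composite_handle <- function(handles) {
  stopifnot(length(handles) > 0, !is.null(names(handles)),
            all(nzchar(names(handles))))
  t0 <- handles[[1]]$time
  for (h in handles) {
    if (abs(h$time - t0) > 1e-9) stop("sub-handles must start at the same time")
  }
  split_var <- function(name) {
    i <- regexpr(":", name, fixed = TRUE)
    if (i < 0) stop(sprintf("composite variable '%s' must be '<id>:<var>'", name))
    list(id = substr(name, 1, i - 1), var = substr(name, i + 1, nchar(name)))
  }
  sim_handle(
    time = t0,
    step = function(h, to_time) {
      for (sub in h$subs) handle_step(sub, to_time)
    },
    get = function(h, name) {
      p <- split_var(name)
      if (!p$id %in% names(h$subs)) stop(sprintf("no sub-handle '%s'", p$id))
      handle_get(h$subs[[p$id]], p$var)
    },
    set = function(h, name, value) {
      p <- split_var(name)
      if (!p$id %in% names(h$subs)) stop(sprintf("no sub-handle '%s'", p$id))
      handle_set(h$subs[[p$id]], p$var, value)
    },
    label = sprintf("composite(%s)", paste(names(handles), collapse = ",")),
    state = list(subs = handles)
  )
}
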