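# Event-driven protocol encoding and piecewise ODE integration.
#
# Medium exchanges are instantaneous state resets (the chip protocol
# replaces the full compartment volume), so the continuous dosing rate G_d
# of the RHS stays 0 in all shipped protocols and the solver is restarted
# at every event.

#' Create a protocol event
#'
#' @param time event time, hours since the simulated co-culture start
#'   (t = 0 is the day-1 GTT exchange).
#' @param kind `"MEDIUM_EXCHANGE"` (replace all medium in both
#'   compartments) or `"INSULIN_SPIKE"` (add insulin without touching
#'   glucose).
#' @param glucose_conc dosed glucose concentration (mmol/L, exchanges).
#' @param insulin_conc dosed insulin concentration (mIU/L).
#' @param applies_offsets `"none"`, `"d1"` or `"d13"`: which measured
#'   exchange-error offsets from [mps_parameters()] apply to this event.
#' @return One-row data frame describing the event.
#' @export
protocol_event <- function(time, kind = c("MEDIUM_EXCHANGE", "INSULIN_SPIKE"),
                           glucose_conc = 0, insulin_conc = 0,
                           applies_offsets = c("none", "d1", "d13")) {
  kind <- match.arg(kind)
  applies_offsets <- match.arg(applies_offsets)
  if (time < 0 || glucose_conc < 0 || insulin_conc < 0)
    stop("event time and concentrations must be nonnegative")
  data.frame(time = time, kind = kind, glucose_conc = glucose_conc,
             insulin_conc = insulin_conc, applies_offsets = applies_offsets,
             stringsAsFactors = FALSE)
}

#' Assemble a chip protocol
#'
#' @param events data frame of [protocol_event()] rows, strictly
#'   time-ordered.
#' @param sampling data frame with columns `time` (h), `window` (GTT
#'   window label or `NA`), `take` (`"post"` to sample just after a
#'   coinciding event, `"pre"` just before; irrelevant away from events).
#' @param duration total simulated time (h).
#' @param label condition tag, e.g. `"high-HCT-hyperglycemic"`.
#' @param initial_glucose glucose load (mmol/L) used for
#'   [initial_state()] when no exchange event sits at t = 0.
#' @return An object of class `mps_protocol`.
#' @seealso [gtt_protocol()] for the built-in 15-day factory.
#' @export
mps_protocol <- function(events, sampling, duration, label = "",
                         initial_glucose = 5.5) {
  stopifnot(is.data.frame(events), is.data.frame(sampling))
  if (nrow(events) && (is.unsorted(events$time, strictly = TRUE)))
    stop("events must be strictly time-ordered")
  if (any(sampling$time < 0) || any(sampling$time > duration))
    stop("sampling times must lie within [0, duration]")
  if (!"take" %in% names(sampling)) sampling$take <- "post"
  if (!"window" %in% names(sampling)) sampling$window <- NA_character_
  structure(list(events = events, sampling = sampling,
                 duration = duration, label = label,
                 initial_glucose = initial_glucose),
            class = "mps_protocol")
}

#' Built-in 15-day GTT protocol factory
#'
#' Reproduces the chip study design on the model clock (t = 0 is the day-1
#' GTT exchange; the 24 h adaptation before it is outside the simulated
#' window): full medium exchanges every `cadence` hours, glucose tolerance
#' test (GTT) windows starting on the given co-culture days with an 11 mM
#' load and samples at 0, 8, 24 and 48 h, day-1 and day-13 offset
#' parameters applied at the corresponding GTT exchanges, and an optional
#' insulin dose added with the fresh medium of the final GTT exchange.
#'
#' A trailing 48-h sample that coincides with the next scheduled exchange
#' is marked `take = "pre"` (it is drawn before the medium is replaced);
#' the 0-h sample of each window is `take = "post"` (drawn from freshly
#' exchanged medium).
#'
#' @param maintenance_glucose glucose of non-GTT exchanges (mmol/L):
#'   11 for hyperglycemic, 5.5 for normoglycemic arms.
#' @param gtt_glucose GTT load (mmol/L, default 11).
#' @param gtt_days co-culture days on which GTT windows start.
#' @param duration_days nominal co-culture length in days (day 1 to
#'   `duration_days`); the simulated window is `(duration_days - 1) * 24`
#'   hours.
#' @param cadence hours between medium exchanges (default 48).
#' @param sample_offsets sampling times within each GTT window (h).
#' @param spike_insulin insulin concentration (mIU/L) added with the fresh
#'   medium at the final GTT exchange (0 = no spike). Use [nM_to_mIU()]
#'   for doses given in nM.
#' @param label condition tag.
#' @return An `mps_protocol` object.
#' @examples
#' p <- gtt_protocol(maintenance_glucose = 11, gtt_days = c(1, 7, 13),
#'                   spike_insulin = nM_to_mIU(24))
#' p$events
#' @export
gtt_protocol <- function(maintenance_glucose = 11, gtt_glucose = 11,
                         gtt_days = c(1, 7, 13), duration_days = 15,
                         cadence = 48, sample_offsets = c(0, 8, 24, 48),
                         spike_insulin = 0, label = "") {
  duration <- (duration_days - 1) * 24
  gtt_starts <- (gtt_days - 1) * 24
  if (any(gtt_starts > duration - max(sample_offsets)))
    stop("a GTT window extends beyond the protocol duration")
  exchange_times <- seq(0, by = cadence,
                        length.out = ceiling(duration / cadence))
  exchange_times <- sort(unique(c(exchange_times, gtt_starts)))
  last_gtt <- max(gtt_starts)
  events <- do.call(rbind, lapply(exchange_times, function(tt) {
    is_gtt <- tt %in% gtt_starts
    protocol_event(
      time = tt, kind = "MEDIUM_EXCHANGE",
      glucose_conc = if (is_gtt) gtt_glucose else maintenance_glucose,
      insulin_conc = if (is_gtt && tt == last_gtt) spike_insulin else 0,
      applies_offsets = if (is_gtt && tt == 0) "d1"
                        else if (is_gtt && tt == last_gtt && tt > 0) "d13"
                        else "none")
  }))
  sampling <- do.call(rbind, lapply(seq_along(gtt_starts), function(i) {
    t0 <- gtt_starts[i]
    data.frame(time = t0 + sample_offsets,
               window = sprintf("d%d", gtt_days[i]),
               take = ifelse(sample_offsets == 0, "post", "pre"),
               stringsAsFactors = FALSE)
  }))
  mps_protocol(events = events, sampling = sampling, duration = duration,
               label = label, initial_glucose = maintenance_glucose)
}

#' Apply a discrete protocol event to a model state
#'
#' `MEDIUM_EXCHANGE` resets the glucose and insulin amounts of both
#' compartments to `(dosed concentration + applicable offset) * V_m`;
#' `INSULIN_SPIKE` adds `insulin_conc * V_m` to the insulin amounts
#' without touching glucose. Slow states (`G_int`, `G_slow_pancreas`,
#' `V_beta_islets`, `t_state`) are never modified by events.
#'
#' @param state named model state vector.
#' @param event one-row event data frame, see [protocol_event()].
#' @param params an [mps_parameters()] object (for volumes and offsets).
#' @param compartments for `INSULIN_SPIKE`: `"both"` (default) or
#'   `"liver"` (sensitivity analysis).
#' @return The post-event state vector.
#' @export
apply_event <- function(state, event, params, compartments = c("both", "liver")) {
  compartments <- match.arg(compartments)
  g <- params$geometry; o <- params$offsets
  kind <- as.character(event$kind)
  if (kind == "MEDIUM_EXCHANGE") {
    off <- switch(as.character(event$applies_offsets),
                  none = c(G = 0, I = 0),
                  d1 = c(G = o$dG_d1, I = o$dI_d1),
                  d13 = c(G = o$dG_d13, I = o$dI_d13),
                  stop("unknown applies_offsets value"))
    gc <- event$glucose_conc + off[["G"]]
    ic <- event$insulin_conc + off[["I"]]
    state[["NG_m_liver"]] <- gc * g$V_m_liver
    state[["NG_m_pancreas"]] <- gc * g$V_m_pancreas
    state[["NI_m_liver"]] <- ic * g$V_m_liver
    state[["NI_m_pancreas"]] <- ic * g$V_m_pancreas
  } else if (kind == "INSULIN_SPIKE") {
    state[["NI_m_liver"]] <- state[["NI_m_liver"]] +
      event$insulin_conc * g$V_m_liver
    if (compartments == "both")
      state[["NI_m_pancreas"]] <- state[["NI_m_pancreas"]] +
        event$insulin_conc * g$V_m_pancreas
  } else stop(sprintf("unknown event kind '%s'", kind))
  state
}

#' Solver configuration
#'
#' @param method deSolve integration method (default `"lsoda"`,
#'   stiff-capable with automatic switching).
#' @param rtol,atol relative / absolute tolerances.
#' @param engine `"compiled"` (C right-hand side, default) or `"R"`
#'   (the reference [ode_rhs()]); both give identical trajectories to
#'   solver tolerance.
#' @param dt_record spacing (h) of additional trajectory output points
#'   between events.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(method = "lsoda", rtol = 1e-8, atol = 1e-10,
                          engine = c("compiled", "R"), dt_record = 4) {
  engine <- match.arg(engine)
  structure(list(method = method, rtol = rtol, atol = atol,
                 engine = engine, dt_record = dt_record),
            class = "solver_config")
}

.integrate_segment <- function(y, times, params, G_d, solver) {
  if (length(times) < 2 || times[length(times)] - times[1] < 1e-12) {
    out <- matrix(rep(y, each = length(times)), nrow = length(times),
                  dimnames = list(NULL, names(y)))
    return(cbind(time = times, out))
  }
  if (solver$engine == "compiled") {
    out <- deSolve::lsoda(y = y, times = times, func = "mps_derivs",
                          parms = .parm_vector(params, G_d),
                          dllname = "glucotwin", initfunc = "mps_init",
                          rtol = solver$rtol, atol = solver$atol)
  } else {
    rhs <- function(t, y, parms) {
      list(ode_rhs(setNames(y, .STATE_NAMES), params, G_d))
    }
    out <- deSolve::lsoda(y = y, times = times, func = rhs, parms = NULL,
                          rtol = solver$rtol, atol = solver$atol)
  }
  out <- unclass(out)
  colnames(out)[1] <- "time"
  if (anyNA(out))
    stop(sprintf(
      "solver failure in segment [%g, %g] h (state: %s)",
      times[1], times[length(times)],
      paste(sprintf("%s=%.3g", names(y), y), collapse = ", ")))
  out
}

#' Simulate a chip protocol
#'
#' Integrates the model segment-by-segment between discrete events with a
#' stiff-capable adaptive solver, restarting at every event, and evaluates
#' the pooled glucose/insulin observables at the protocol's sampling
#' times. Deterministic given parameters and solver configuration.
#'
#' @param params an [mps_parameters()] object.
#' @param protocol an [mps_protocol()] object.
#' @param solver a [solver_config()] object.
#' @param G_d continuous glucose dosing rate (mmol/h), normally 0.
#' @param init optional starting state (see [model_state()]) overriding
#'   the default initial conditions; an exchange event at t = 0 still
#'   takes precedence for the medium amounts.
#' @return An object of class `mps_sim`: list with `samples` (data frame
#'   `time`, `window`, `take`, `glucose`, `insulin`), `trajectory` (data
#'   frame of all states plus pooled observables on a denser grid), and
#'   `events` (the applied event log).
#' @export
simulate_protocol <- function(params, protocol, solver = solver_config(),
                              G_d = 0, init = NULL) {
  stopifnot(inherits(protocol, "mps_protocol"))
  validate_parameters(params)
  ev <- protocol$events
  smp <- protocol$sampling

  has_t0_exchange <- nrow(ev) > 0 && ev$time[1] == 0 &&
    ev$kind[1] == "MEDIUM_EXCHANGE"
  if (has_t0_exchange) {
    y <- init %||% model_state(V_beta_islets = params$slow$V_beta_0)
    y <- apply_event(y, ev[1, ], params)
    ev <- ev[-1, , drop = FALSE]
  } else {
    y <- init %||% initial_state(params, protocol$initial_glucose)
  }

  bounds <- sort(unique(c(0, ev$time, protocol$duration)))
  traj <- list(); samples <- list()
  for (k in seq_len(length(bounds) - 1)) {
    ta <- bounds[k]; tb <- bounds[k + 1]
    interior <- smp$time[smp$time > ta & smp$time < tb]
    grid <- seq(ta, tb, by = solver$dt_record)
    times <- sort(unique(c(ta, interior, grid, tb)))
    out <- .integrate_segment(y, times, params, G_d, solver)
    traj[[k]] <- out

    event_at_tb <- any(ev$time == tb)
    want <- (smp$time > ta & smp$time < tb) |
      (smp$time == ta & smp$take == "post") |
      (smp$time == tb &
         (smp$take == "pre" | (tb == protocol$duration & !event_at_tb)))
    if (any(want)) {
      rows <- smp[want, , drop = FALSE]
      idx <- match(rows$time, out[, "time"])
      po <- pooled_observables(out[idx, , drop = FALSE], params$geometry)
      samples[[length(samples) + 1]] <-
        data.frame(time = rows$time, window = rows$window,
                   take = rows$take, glucose = po[, "G"],
                   insulin = po[, "I"], stringsAsFactors = FALSE)
    }

    y <- setNames(out[nrow(out), .STATE_NAMES], .STATE_NAMES)
    ev_here <- ev[ev$time == tb, , drop = FALSE]
    for (j in seq_len(nrow(ev_here)))
      y <- apply_event(y, ev_here[j, ], params)
    # post-event samples at tb belong to the next segment's start; the
    # final boundary has no further segment, so emit them here
    if (tb == protocol$duration) {
      want_post <- smp$time == tb & smp$take == "post" & nrow(ev_here) > 0
      if (any(want_post)) {
        rows <- smp[want_post, , drop = FALSE]
        po <- pooled_observables(y, params$geometry)
        samples[[length(samples) + 1]] <-
          data.frame(time = rows$time, window = rows$window,
                     take = rows$take, glucose = po[["G"]],
                     insulin = po[["I"]], stringsAsFactors = FALSE)
      }
    }
  }

  trajectory <- as.data.frame(do.call(rbind, traj))
  trajectory <- trajectory[!duplicated(trajectory$time), ]
  po <- pooled_observables(as.matrix(trajectory[, .STATE_NAMES]),
                           params$geometry)
  trajectory$glucose <- po[, "G"]; trajectory$insulin <- po[, "I"]
  samples <- if (length(samples)) do.call(rbind, samples) else
    data.frame(time = numeric(), window = character(), take = character(),
               glucose = numeric(), insulin = numeric())
  samples <- samples[order(samples$time), ]
  rownames(samples) <- NULL
  structure(list(samples = samples, trajectory = trajectory,
                 events = protocol$events, label = protocol$label,
                 hypothesis = params$hypothesis),
            class = "mps_sim")
}

#' @export
print.mps_sim <- function(x, ...) {
  cat(sprintf("<mps_sim> %s, hypothesis %s: %d samples, %d trajectory points\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$hypothesis, nrow(x$samples), nrow(x$trajectory)))
  invisible(x)
}

#' Export a simulation to tidy tabular form
#'
#' @param x an `mps_sim` object.
#' @param what `"samples"` (pooled observables at sampling times) or
#'   `"trajectory"` (one row per time and state variable).
#' @return A tidy data frame.
#' @export
as_tidy_table <- function(x, what = c("samples", "trajectory")) {
  what <- match.arg(what)
  if (what == "samples") {
    s <- x$samples
    rbind(data.frame(time = s$time, window = s$window, variable = "glucose",
                     value = s$glucose, stringsAsFactors = FALSE),
          data.frame(time = s$time, window = s$window, variable = "insulin",
                     value = s$insulin, stringsAsFactors = FALSE))
  } else {
    tr <- x$trajectory
    vars <- setdiff(names(tr), "time")
    do.call(rbind, lapply(vars, function(v)
      data.frame(time = tr$time, window = NA_character_, variable = v,
                 value = tr[[v]], stringsAsFactors = FALSE)))
  }
}
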