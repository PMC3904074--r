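# Declarative simulation object graph -----------------------------------
#
# A Simulation is an inert description: cells (morphology + channel
# distribution + passive properties), stimuli, synapses, gap junctions and
# recording requests.  Nothing numerical happens until run() hands the
# graph to the solver.  Simulations and cells are environments so the
# builder-style API (add_cell, apply_channel, record, ...) can accumulate
# state with reference semantics; independent Simulation objects share
# nothing.

#' Create a simulation
#'
#' @param name simulation name.
#' @param duration total simulated time (quantity or string, e.g.
#'   `"200 ms"`).
#' @param dt integration step (default `"0.025 ms"`).
#' @param seed integer seed stored with the simulation (the shipped
#'   mechanisms are deterministic; the seed is recorded for provenance and
#'   for user-supplied stochastic components).
#' @return an environment of class `simulation`.
#' @export
simulation <- function(name = "sim", duration = "200 ms", dt = "0.025 ms",
                       seed = 0L) {
  if (is.numeric(duration)) duration <- qty(duration, "ms")
  if (is.numeric(dt)) dt <- qty(dt, "ms")
  dur <- qty_in(.cn_check_dim(as_qty(duration), "ms", "duration"), "ms")
  step <- qty_in(.cn_check_dim(as_qty(dt), "ms", "dt"), "ms")
  if (dur <= 0) cn_abort("duration must be positive", "cablenet_domain_error")
  if (step <= 0) cn_abort("dt must be positive", "cablenet_domain_error")
  sim <- new.env(parent = emptyenv())
  sim$name <- name
  sim$duration <- dur
  sim$dt <- step
  sim$seed <- as.integer(seed)
  sim$cells <- list()
  sim$stimuli <- list()
  sim$synapses <- list()
  sim$gap_junctions <- list()
  sim$recordings <- list()
  class(sim) <- "simulation"
  sim
}

#' @export
print.simulation <- function(x, ...) {
  cat(sprintf(
    "<simulation '%s': %g ms @ dt %g ms; %d cells, %d stimuli, %d synapses, %d gap junctions, %d recordings>\n",
    x$name, x$duration, x$dt, length(x$cells), length(x$stimuli),
    length(x$synapses), length(x$gap_junctions), length(x$recordings)))
  invisible(x)
}

#' Add a cell to a simulation
#'
#' @param sim a `simulation`.
#' @param name unique cell name.
#' @param morphology a `morphology`.
#' @param capacitance specific membrane capacitance (default
#'   `"1.0 uF/cm2"`).
#' @param axial_resistivity cytoplasmic resistivity (default
#'   `"100 Ohm*cm"`).
#' @param initial_voltage optional explicit initial membrane voltage; when
#'   `NULL` the solver starts each segment at its conductance-weighted
#'   reversal potential (gates held at their steady state for -65 mV).
#' @return the cell (an environment of class `cell`).
#' @export
add_cell <- function(sim, name, morphology,
                     capacitance = "1.0 uF/cm2",
                     axial_resistivity = "100 Ohm*cm",
                     initial_voltage = NULL) {
  if (!inherits(sim, "simulation")) cn_abort("sim must be a simulation", "cablenet_domain_error")
  if (name %in% names(sim$cells)) {
    cn_abort(sprintf("cell name '%s' already in use", name), "cablenet_domain_error")
  }
  cm <- qty_in(.cn_check_dim(as_qty(capacitance), "uF/cm2", "capacitance"), "uF/cm2")
  ra <- qty_in(.cn_check_dim(as_qty(axial_resistivity), "Ohm*cm", "axial_resistivity"), "Ohm*cm")
  if (cm <= 0) cn_abort("capacitance must be positive", "cablenet_domain_error")
  if (ra <= 0) cn_abort("axial resistivity must be positive", "cablenet_domain_error")
  cell <- new.env(parent = emptyenv())
  cell$name <- name
  cell$morphology <- morphology
  cell$capacitance <- cm
  cell$axial_resistivity <- ra
  cell$initial_voltage <- if (is.null(initial_voltage)) NULL else
    qty_in(.cn_check_dim(as_qty(initial_voltage), "mV", "initial_voltage"), "mV")
  cell$applications <- list()
  class(cell) <- "cell"
  sim$cells[[name]] <- cell
  invisible(cell)
}

#' Apply a channel to a cell via a (channel, applicator, targeter) triplet
#'
#' May be called repeatedly for the same channel with different targeters;
#' priorities decide which triplet claims each section (see
#' [resolve_distribution()]).
#' @param cell a `cell`.
#' @param channel a `channel`.
#' @param applicator an [applicator()] (default: channel defaults).
#' @param targeter a targeter (default: [target_everywhere()]).
#' @export
apply_channel <- function(cell, channel, applicator = apply_uniform(),
                          targeter = target_everywhere()) {
  app <- channel_application(channel, applicator, targeter)
  cell$applications[[length(cell$applications) + 1L]] <- app
  invisible(cell)
}

#' Reference a point on a cell
#'
#' @param cell a `cell` or a cell name.
#' @param section section id (default `"soma"`).
#' @param fraction_along fraction along the section in `[0, 1]`.
#' @export
loc <- function(cell, section = "soma", fraction_along = 0.5) {
  nm <- if (inherits(cell, "cell")) cell$name else as.character(cell)
  structure(list(cell = nm, location = morph_location(section, fraction_along)),
            class = "cell_location")
}

.cn_resolve_cell <- function(sim, l) {
  cell <- sim$cells[[l$cell]]
  if (is.null(cell)) {
    cn_abort(sprintf("location references unknown cell '%s'", l$cell),
             "cablenet_reference_error")
  }
  if (!(l$location$section %in% names(cell$morphology$sections))) {
    cn_abort(sprintf("cell '%s' has no section '%s'", l$cell, l$location$section),
             "cablenet_reference_error")
  }
  cell
}

# Stimuli -----------------------------------------------------------------

#' Create a current clamp
#'
#' Protocols: `"step"` (constant `amplitude` inside the window),
#' `"ramp"` (`amplitude0` to `amplitude1` linearly over the window) and
#' `"sine"` (`amplitude * sin(2 pi freq (t - delay) + phase)` inside the
#' window). The default protocol is a step.
#'
#' @param sim a `simulation`.
#' @param location a [loc()].
#' @param protocol `"step"`, `"ramp"` or `"sine"`.
#' @param amplitude current amplitude (step/sine), e.g. `"100 pA"`.
#' @param amplitude0,amplitude1 ramp start/end currents.
#' @param delay onset time (default `"0 ms"`).
#' @param duration window length; default: until the end of the
#'   simulation.
#' @param freq sine frequency (required for `"sine"`), e.g. `"10 Hz"`.
#' @param phase sine phase in radians at `t = delay` (default 0).
#' @param name stimulus name (auto-generated when omitted).
#' @return the stimulus object (also registered with the simulation).
#' @export
create_currentclamp <- function(sim, location, protocol = c("step", "ramp", "sine"),
                                amplitude = NULL, amplitude0 = NULL,
                                amplitude1 = NULL, delay = "0 ms",
                                duration = NULL, freq = NULL, phase = 0,
                                name = NULL) {
  protocol <- match.arg(protocol)
  .cn_resolve_cell(sim, location)
  d0 <- qty_in(.cn_check_dim(as_qty(delay), "ms", "delay"), "ms")
  if (d0 < 0) cn_abort("delay must be >= 0", "cablenet_domain_error")
  dur <- if (is.null(duration)) sim$duration - d0 else
    qty_in(.cn_check_dim(as_qty(duration), "ms", "duration"), "ms")
  if (dur < 0) cn_abort("duration must be >= 0", "cablenet_domain_error")
  need <- function(x, what) {
    if (is.null(x)) {
      cn_abort(sprintf("current-clamp protocol '%s' requires parameter '%s'",
                       protocol, what), "cablenet_spec_error")
    }
    x
  }
  params <- switch(protocol,
    step = list(amp = qty_in(.cn_check_dim(as_qty(need(amplitude, "amplitude")), "pA", "amplitude"), "pA")),
    ramp = list(
      amp0 = qty_in(.cn_check_dim(as_qty(need(amplitude0, "amplitude0")), "pA", "amplitude0"), "pA"),
      amp1 = qty_in(.cn_check_dim(as_qty(need(amplitude1, "amplitude1")), "pA", "amplitude1"), "pA")),
    sine = list(
      amp = qty_in(.cn_check_dim(as_qty(need(amplitude, "amplitude")), "pA", "amplitude"), "pA"),
      freq = qty_in(.cn_check_dim(as_qty(need(freq, "freq")), "Hz", "freq"), "Hz"),
      phase = if (is.quantity(phase)) qty_in(phase, "rad") else as.numeric(phase)))
  if (is.null(name)) name <- sprintf("cclamp%d", length(sim$stimuli) + 1L)
  stim <- structure(list(kind = "current", protocol = protocol, name = name,
                         location = location, delay = d0, duration = dur,
                         params = params),
                    class = "stimulus")
  sim$stimuli[[length(sim$stimuli) + 1L]] <- stim
  invisible(stim)
}

#' Create a step voltage clamp
#'
#' Implemented in the solver as a large series conductance
#' (`1 / r_series`) between the command potential and the clamped
#' segment.
#' @param sim a `simulation`.
#' @param location a [loc()].
#' @param level command potential, e.g. `"-60 mV"`.
#' @param delay,duration clamp window (defaults: whole simulation).
#' @param r_series series resistance (default `"1 MOhm"`).
#' @param name stimulus name.
#' @export
create_voltageclamp <- function(sim, location, level, delay = "0 ms",
                                duration = NULL, r_series = "1 MOhm",
                                name = NULL) {
  .cn_resolve_cell(sim, location)
  d0 <- qty_in(.cn_check_dim(as_qty(delay), "ms", "delay"), "ms")
  dur <- if (is.null(duration)) sim$duration - d0 else
    qty_in(.cn_check_dim(as_qty(duration), "ms", "duration"), "ms")
  lvl <- qty_in(.cn_check_dim(as_qty(level), "mV", "level"), "mV")
  rs <- qty_in(.cn_check_dim(as_qty(r_series), "MOhm", "r_series"), "MOhm")
  if (rs <= 0) cn_abort("r_series must be positive", "cablenet_domain_error")
  if (is.null(name)) name <- sprintf("vclamp%d", length(sim$stimuli) + 1L)
  stim <- structure(list(kind = "voltage", protocol = "vstep", name = name,
                         location = location, delay = d0, duration = dur,
                         params = list(level = lvl, g_series_uS = 1 / rs)),
                    class = "stimulus")
  sim$stimuli[[length(sim$stimuli) + 1L]] <- stim
  invisible(stim)
}

#' Injected current of a current clamp at given times
#'
#' Closed-form evaluation (also what the solver uses), vectorised over
#' `t`.
#' @param stim a current-clamp stimulus.
#' @param t times in ms (numeric or quantity).
#' @return current(s) in pA (bare numeric).
#' @export
stimulus_current <- function(stim, t) {
  if (stim$kind != "current") cn_abort("not a current clamp", "cablenet_domain_error")
  t <- if (is.quantity(t)) qty_in(t, "ms") else t
  inside <- t >= stim$delay & t < stim$delay + stim$duration
  p <- stim$params
  i <- switch(stim$protocol,
    step = rep(p$amp, length(t)),
    ramp = p$amp0 + (p$amp1 - p$amp0) * (t - stim$delay) / stim$duration,
    sine = p$amp * sin(2 * pi * p$freq * (t - stim$delay) * 1e-3 + p$phase))
  i * inside
}

# Synapses and gap junctions ----------------------------------------------

#' Trigger a synapse from an explicit list of presynaptic spike times
#' @param times spike times in ms (within the simulation duration).
#' @export
trigger_times <- function(times) {
  structure(list(kind = "times", times = sort(as.numeric(
    if (is.quantity(times)) qty_in(times, "ms") else times))),
    class = "syn_trigger")
}

#' Trigger a synapse from a presynaptic threshold crossing
#' @param location presynaptic [loc()].
#' @param threshold detection threshold (default `"0 mV"`, upward
#'   crossing with hysteresis: no retrigger until the voltage falls below
#'   threshold again).
#' @export
trigger_presyn <- function(location, threshold = "0 mV") {
  structure(list(kind = "presyn", location = location,
                 threshold = qty_in(.cn_check_dim(as_qty(threshold), "mV", "threshold"), "mV")),
            class = "syn_trigger")
}

#' Instantiate a postsynaptic receptor between cells
#'
#' @param sim a `simulation`.
#' @param template a [psr_template()].
#' @param post postsynaptic [loc()].
#' @param trigger a [trigger_times()] or [trigger_presyn()].
#' @param delay transmission delay; defaults to the template's delay.
#'   Event delivery is folded to the next integration-step boundary;
#'   events falling after the simulation end are dropped.
#' @export
add_synapse <- function(sim, template, post, trigger, delay = NULL) {
  if (!inherits(template, "psr_template")) cn_abort("template must be a psr_template", "cablenet_domain_error")
  if (!inherits(trigger, "syn_trigger")) cn_abort("trigger required", "cablenet_domain_error")
  .cn_resolve_cell(sim, post)
  if (trigger$kind == "presyn") .cn_resolve_cell(sim, trigger$location)
  if (trigger$kind == "times" && length(trigger$times) &&
      (min(trigger$times) < 0 || max(trigger$times) > sim$duration)) {
    cn_abort("explicit spike times must lie within [0, duration]", "cablenet_domain_error")
  }
  dl <- if (is.null(delay)) template$delay else
    qty_in(.cn_check_dim(as_qty(delay), "ms", "delay"), "ms")
  if (dl < 0) cn_abort("delay must be >= 0", "cablenet_domain_error")
  syn <- structure(list(template = template, post = post, trigger = trigger,
                        delay = dl,
                        name = sprintf("syn%d", length(sim$synapses) + 1L)),
                   class = "synapse")
  sim$synapses[[length(sim$synapses) + 1L]] <- syn
  invisible(syn)
}

#' Couple two cells with a gap junction
#' @param sim a `simulation`.
#' @param conductance junctional conductance, e.g. `"1 nS"` (>= 0).
#' @param loc1,loc2 the two coupled [loc()]s (must be distinct points).
#' @export
add_gap_junction <- function(sim, conductance, loc1, loc2) {
  g <- qty_in(.cn_check_dim(as_qty(conductance), "nS", "conductance"), "nS")
  if (g < 0) cn_abort("gap-junction conductance must be >= 0", "cablenet_domain_error")
  .cn_resolve_cell(sim, loc1)
  .cn_resolve_cell(sim, loc2)
  if (identical(loc1, loc2)) {
    cn_abort("gap-junction endpoints must be distinct", "cablenet_domain_error")
  }
  gj <- structure(list(g_nS = g, loc1 = loc1, loc2 = loc2,
                       name = sprintf("gj%d", length(sim$gap_junctions) + 1L)),
                  class = "gap_junction")
  sim$gap_junctions[[length(sim$gap_junctions) + 1L]] <- gj
  invisible(gj)
}

# Recording ----------------------------------------------------------------

#' Request a recording
#'
#' One Trace (or EventSet for `"Events"`) per request is returned by
#' [run()], carrying automatic tags (modality, cell name, `loc:<section>`,
#' channel/synapse context) plus `user_tags`.
#'
#' @param sim a `simulation`.
#' @param what one of `"Voltage"`, `"CurrentDensity"`,
#'   `"ConductanceDensity"` (of a channel at a location), `"Current"` (of
#'   a stimulus, or of a synapse), `"Conductance"` (of a synapse),
#'   `"Events"` (spike detector at a location).
#' @param location a [loc()] (required for Voltage/CurrentDensity/
#'   ConductanceDensity/Events).
#' @param channel channel name (for CurrentDensity/ConductanceDensity).
#' @param stimulus a stimulus object or name (for `"Current"`).
#' @param synapse a synapse object or name (for synaptic
#'   Conductance/Current).
#' @param threshold spike threshold for `"Events"` (default `"0 mV"`).
#' @param user_tags extra tags attached to the result.
#' @param name trace name (auto-generated when omitted).
#' @export
record <- function(sim, what = c("Voltage", "CurrentDensity", "ConductanceDensity",
                                 "Current", "Conductance", "Events"),
                   location = NULL, channel = NULL, stimulus = NULL,
                   synapse = NULL, threshold = "0 mV",
                   user_tags = character(), name = NULL) {
  what <- match.arg(what)
  rec <- list(what = what, user_tags = as.character(user_tags))
  if (what %in% c("Voltage", "CurrentDensity", "ConductanceDensity", "Events")) {
    if (is.null(location)) cn_abort(sprintf("recording '%s' needs a location", what), "cablenet_reference_error")
    cell <- .cn_resolve_cell(sim, location)
    rec$location <- location
    if (what %in% c("CurrentDensity", "ConductanceDensity")) {
      if (is.null(channel)) cn_abort(sprintf("recording '%s' needs a channel name", what), "cablenet_reference_error")
      chl_names <- vapply(cell$applications, function(a) a$channel$name, "")
      if (!(channel %in% chl_names)) {
        cn_abort(sprintf("channel '%s' is not applied to cell '%s'", channel, cell$name),
                 "cablenet_reference_error")
      }
      rec$channel <- channel
    }
    if (what == "Events") {
      rec$threshold <- qty_in(.cn_check_dim(as_qty(threshold), "mV", "threshold"), "mV")
    }
  } else if (what == "Current" && !is.null(stimulus)) {
    nm <- if (inherits(stimulus, "stimulus")) stimulus$name else as.character(stimulus)
    stims <- vapply(sim$stimuli, `[[`, "", "name")
    if (!(nm %in% stims)) cn_abort(sprintf("unknown stimulus '%s'", nm), "cablenet_reference_error")
    rec$stimulus <- nm
  } else if (what %in% c("Conductance", "Current")) {
    if (is.null(synapse)) cn_abort(sprintf("recording '%s' needs a stimulus or synapse", what), "cablenet_reference_error")
    nm <- if (inherits(synapse, "synapse")) synapse$name else as.character(synapse)
    syns <- vapply(sim$synapses, `[[`, "", "name")
    if (!(nm %in% syns)) cn_abort(sprintf("unknown synapse '%s'", nm), "cablenet_reference_error")
    rec$synapse <- nm
  }
  if (is.null(name)) {
    name <- sprintf("rec%02d_%s", length(sim$recordings) + 1L, what)
  }
  rec$name <- name
  sim$recordings[[length(sim$recordings) + 1L]] <- rec
  invisible(rec)
}

# Component libraries -------------------------------------------------------

#' Create an empty component library
#'
#' A registry mapping `(model_src, component_type, kind)` to builder
#' functions. `library_instantiate()` forwards additional keyword
#' arguments to the builder, so registered components are parameterisable
#' at the call site (e.g. `include_sodium = FALSE` to model TTX).
#' @export
component_library <- function() {
  lib <- new.env(parent = emptyenv())
  lib$registry <- list()
  class(lib) <- "component_library"
  lib
}

.cn_lib_key <- function(model_src, component_type, kind) {
  paste(model_src, component_type, kind, sep = "\r")
}

#' Register a builder function with a component library
#' @param lib a [component_library()].
#' @param model_src source label (e.g. a study or database id).
#' @param component_type component name within the source.
#' @param builder function returning the component; extra arguments given
#'   to [library_instantiate()] are forwarded to it.
#' @param kind one of `"cell"`, `"channel"`, `"morphology"`, `"psr"`.
#' @export
library_register <- function(lib, model_src, component_type, builder,
                             kind = c("cell", "channel", "morphology", "psr")) {
  kind <- match.arg(kind)
  if (!is.function(builder)) cn_abort("builder must be a function", "cablenet_domain_error")
  key <- .cn_lib_key(model_src, component_type, kind)
  if (!is.null(lib$registry[[key]])) {
    cn_abort(sprintf("component (%s, %s, %s) already registered",
                     model_src, component_type, kind), "cablenet_domain_error")
  }
  lib$registry[[key]] <- list(model_src = model_src, component_type = component_type,
                              kind = kind, builder = builder)
  invisible(lib)
}

#' Instantiate a registered component
#' @param lib a [component_library()].
#' @param model_src,component_type,kind registry key.
#' @param ... forwarded to the builder function.
#' @export
library_instantiate <- function(lib, model_src, component_type,
                                kind = c("cell", "channel", "morphology", "psr"),
                                ...) {
  kind <- match.arg(kind)
  key <- .cn_lib_key(model_src, component_type, kind)
  entry <- lib$registry[[key]]
  if (is.null(entry)) {
    known <- vapply(lib$registry, function(e) {
      sprintf("(%s, %s, %s)", e$model_src, e$component_type, e$kind)
    }, "")
    cn_abort(sprintf("no %s component registered for (%s, %s); known: %s",
                     kind, model_src, component_type,
                     if (length(known)) paste(known, collapse = " ") else "<none>"),
             "cablenet_lookup_error")
  }
  entry$builder(...)
}

#' Tabulate registered components
#' @param lib a [component_library()].
#' @return data.frame with one row per registration.
#' @export
library_summary_table <- function(lib) {
  if (!length(lib$registry)) {
    return(data.frame(model_src = character(), component_type = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(unname(lib$registry), function(e) {
    data.frame(model_src = e$model_src, component_type = e$component_type,
               kind = e$kind, stringsAsFactors = FALSE)
  }))
}

#' The default component library shipped with the package
#'
#' Pre-registers the classic squid giant-axon channels (`hh_na`, `hh_k`,
#' `hh_lk`) and a single-compartment HH cell builder (`hh_soma`, with an
#' `include_sodium` switch emulating TTX application and an `area`
#' argument, default 1000 um2).
#' @export
default_component_library <- function() {
  lib <- component_library()
  library_register(lib, "squid_classic", "hh_na", hh_na_channel, kind = "channel")
  library_register(lib, "squid_classic", "hh_k", hh_k_channel, kind = "channel")
  library_register(lib, "squid_classic", "hh_lk", hh_leak_channel, kind = "channel")
  library_register(lib, "squid_classic", "hh_soma",
                   function(sim, name, area = "1000 um2",
                            include_sodium = TRUE, ...) {
                     cell <- add_cell(sim, name, build_soma_from_area(area), ...)
                     if (include_sodium) apply_channel(cell, hh_na_channel())
                     apply_channel(cell, hh_k_channel())
                     apply_channel(cell, hh_leak_channel())
                     cell
                   }, kind = "cell")
  lib
}
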