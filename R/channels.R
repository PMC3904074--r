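# Membrane mechanisms ----------------------------------------------------
#
# Three mechanism kinds share one parameter interface
# (get_variables / get_defaults):
#   * leak                 : g (density) and erev
#   * alpha_beta_gated     : gbar, erev plus voltage-gated particles whose
#                            opening/closing rates follow the classic
#                            five-parameter form
#                              rate(V) = (A + B V) / (C + exp((V + D) / E))
#                            with A in ms^-1, B in ms^-1 mV^-1, D, E in mV
#                            and C dimensionless
#   * double_exp_psr       : postsynaptic receptor with a peak-normalised
#                            difference of exponentials
# Current sign convention: positive current is outward.

#' Evaluate a five-parameter rate equation
#'
#' `rate(V) = (A + B*V) / (C + exp((V + D)/E))`, vectorised over `V` (mV),
#' returning a rate in ms^-1.  When `C == -1` the denominator vanishes at
#' `V = -D` together with the numerator of any consistently parameterised
#' gate; that removable singularity is evaluated by its analytic limit
#' `B * E` rather than by numerical nudging.
#'
#' @param params numeric 5-vector `(A, B, C, D, E)`; `E` must be nonzero.
#' @param V membrane voltage(s) in mV.
#' @return rate(s) in ms^-1.
#' @export
eval_rate <- function(params, V) {
  if (length(params) != 5L) cn_abort("rate params must be (A,B,C,D,E)", "cablenet_domain_error")
  A <- params[[1]]; B <- params[[2]]; C <- params[[3]]; D <- params[[4]]; E <- params[[5]]
  if (E == 0) cn_abort("rate parameter E must be nonzero", "cablenet_domain_error")
  den <- C + exp((V + D) / E)
  r <- (A + B * V) / den
  sing <- den == 0
  if (any(sing)) {
    num <- A + B * V[sing]
    if (any(abs(num) > 1e-9)) {
      cn_abort("rate equation has a non-removable division by zero", "cablenet_numeric_error")
    }
    r[sing] <- B * E
  }
  if (any(!is.finite(r))) {
    cn_abort("rate equation evaluated non-finite", "cablenet_numeric_error")
  }
  r
}

#' Define a gating particle
#'
#' @param name particle name (e.g. `"m"`).
#' @param exponent positive-integer power the particle enters the
#'   conductance with (e.g. 3 for m^3).
#' @param alpha,beta 5-vectors `(A, B, C, D, E)` for the opening and
#'   closing rates (see [eval_rate()]).
#' @export
gate_spec <- function(name, exponent, alpha, beta) {
  if (exponent < 1 || exponent != round(exponent)) {
    cn_abort("gate exponent must be a positive integer", "cablenet_domain_error")
  }
  structure(list(name = name, exponent = as.integer(exponent),
                 alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "gate_spec")
}

#' Steady state and time constant of a gate
#'
#' `inf = alpha / (alpha + beta)`, `tau = 1 / (alpha + beta)` (ms),
#' vectorised over `V`.
#' @param gate a [gate_spec()].
#' @param V voltage(s) in mV.
#' @return list with numeric `inf` and `tau`.
#' @export
gate_steady_state_and_tau <- function(gate, V) {
  a <- eval_rate(gate$alpha, V)
  b <- eval_rate(gate$beta, V)
  s <- a + b
  if (any(s <= 0)) {
    cn_abort("alpha + beta must be positive for inf/tau", "cablenet_numeric_error")
  }
  list(inf = a / s, tau = 1 / s)
}

.cn_channel <- function(name, kind, variables, defaults, gates = list()) {
  structure(list(name = name, kind = kind, variables = variables,
                 defaults = defaults, gates = gates),
            class = "channel")
}

#' Leak (passive) channel
#'
#' @param name channel name.
#' @param gbar specific conductance, quantity or string (e.g. `"0.3 mS/cm2"`).
#' @param erev reversal potential (e.g. `"-51 mV"`).
#' @export
leak_channel <- function(name = "leak", gbar = "0.3 mS/cm2", erev = "-51 mV") {
  g <- .cn_check_dim(as_qty(gbar), "mS/cm2", sprintf("%s gbar", name))
  e <- .cn_check_dim(as_qty(erev), "mV", sprintf("%s erev", name))
  .cn_channel(name, "leak", c("gbar", "erev"), list(gbar = g, erev = e))
}

#' Voltage-gated channel with alpha/beta kinetics
#'
#' Conductance density `gbar * prod_i gate_i^exp_i`; current density
#' `gbar * prod gates * (V - erev)` (positive outward).
#'
#' @param name channel name.
#' @param gbar maximal specific conductance.
#' @param erev reversal potential.
#' @param gates list of [gate_spec()] objects.
#' @export
gated_channel <- function(name, gbar, erev, gates) {
  g <- .cn_check_dim(as_qty(gbar), "mS/cm2", sprintf("%s gbar", name))
  e <- .cn_check_dim(as_qty(erev), "mV", sprintf("%s erev", name))
  if (!length(gates)) cn_abort("gated channel needs at least one gate", "cablenet_domain_error")
  for (gt in gates) {
    if (!inherits(gt, "gate_spec")) cn_abort("gates must be gate_spec objects", "cablenet_domain_error")
  }
  names(gates) <- vapply(gates, `[[`, "", "name")
  .cn_channel(name, "alpha_beta_gated", c("gbar", "erev"),
              list(gbar = g, erev = e), gates)
}

#' @export
get_variables <- function(chl) UseMethod("get_variables")
#' @export
get_variables.channel <- function(chl) chl$variables

#' @export
get_defaults <- function(chl) UseMethod("get_defaults")
#' @export
get_defaults.channel <- function(chl) chl$defaults

#' Ionic current density carried by a channel
#'
#' @param chl a `channel`.
#' @param state named numeric vector of gate values in `[0, 1]` (one per
#'   gate; ignored for leak channels).
#' @param V membrane voltage in mV.
#' @param params optional parameter overrides (named list of quantities);
#'   defaults to `get_defaults(chl)`.
#' @return current density as a quantity in mA/cm2, positive outward.
#' @export
channel_current_density <- function(chl, state = numeric(), V, params = NULL) {
  p <- get_defaults(chl)
  if (!is.null(params)) p[names(params)] <- lapply(params, as_qty)
  g <- qty_in(p$gbar, "S/cm2")
  e <- qty_in(p$erev, "mV")
  open <- 1
  if (chl$kind == "alpha_beta_gated") {
    for (gt in chl$gates) {
      x <- state[[gt$name]]
      if (is.null(x) || is.na(x) || x < 0 || x > 1) {
        cn_abort(sprintf("gate '%s' state must lie in [0, 1]", gt$name),
                 "cablenet_state_error")
      }
      open <- open * x^gt$exponent
    }
  }
  v <- if (is.quantity(V)) qty_in(V, "mV") else V
  qty(g * open * (v - e), "mA/cm2")   # S/cm2 * mV = mA/cm2
}

# Double-exponential postsynaptic receptor --------------------------------

#' Double-exponential postsynaptic receptor template
#'
#' Conductance waveform after an event at t = 0:
#' `g(t) = gbar * N * (exp(-t/tau_decay) - exp(-t/tau_rise))` with the
#' normalisation `N` chosen so the peak equals `gbar` exactly. The peak
#' occurs at `t_p = tau_d tau_r / (tau_d - tau_r) * log(tau_d / tau_r)`.
#' Overlapping events sum linearly.
#'
#' @param tau_rise,tau_decay rise/decay time constants (ms);
#'   `0 < tau_rise < tau_decay`.
#' @param gbar peak conductance (nS).
#' @param erev reversal potential (mV).
#' @param delay transmission delay applied to each triggering event (ms).
#' @param name template name (used in trace tags).
#' @export
psr_template <- function(tau_rise, tau_decay, gbar, erev, delay = "0 ms",
                         name = "psr") {
  tr <- qty_in(.cn_check_dim(as_qty(tau_rise), "ms", "tau_rise"), "ms")
  td <- qty_in(.cn_check_dim(as_qty(tau_decay), "ms", "tau_decay"), "ms")
  gb <- qty_in(.cn_check_dim(as_qty(gbar), "nS", "gbar"), "nS")
  ev <- qty_in(.cn_check_dim(as_qty(erev), "mV", "erev"), "mV")
  dl <- qty_in(.cn_check_dim(as_qty(delay), "ms", "delay"), "ms")
  if (!(tr > 0 && tr < td)) {
    cn_abort("require 0 < tau_rise < tau_decay", "cablenet_spec_error")
  }
  if (gb < 0) cn_abort("gbar must be >= 0", "cablenet_spec_error")
  if (dl < 0) cn_abort("delay must be >= 0", "cablenet_spec_error")
  tp <- td * tr / (td - tr) * log(td / tr)
  N <- 1 / (exp(-tp / td) - exp(-tp / tr))
  structure(list(name = name, tau_rise = tr, tau_decay = td, gbar = gb,
                 erev = ev, delay = dl, t_peak = tp, norm = N,
                 variables = c("tau_rise", "tau_decay", "gbar", "erev", "delay"),
                 kind = "double_exp_psr"),
            class = c("psr_template"))
}

#' @export
get_variables.psr_template <- function(chl) chl$variables
#' @export
get_defaults.psr_template <- function(chl) {
  list(tau_rise = qty(chl$tau_rise, "ms"), tau_decay = qty(chl$tau_decay, "ms"),
       gbar = qty(chl$gbar, "nS"), erev = qty(chl$erev, "mV"),
       delay = qty(chl$delay, "ms"))
}

#' PSR conductance waveform
#'
#' @param p a [psr_template()].
#' @param t time(s) since the (delayed) event, ms; values < 0 contribute 0.
#' @return conductance in nS (bare numeric, peak = gbar).
#' @export
psr_conductance <- function(p, t) {
  t <- if (is.quantity(t)) qty_in(t, "ms") else t
  g <- p$gbar * p$norm * (exp(-t / p$tau_decay) - exp(-t / p$tau_rise))
  g[t < 0] <- 0
  g
}

# Shipped channel library fixtures ----------------------------------------
# Classic squid giant-axon kinetics in the modern voltage convention
# (rest near -65 mV).  Rates in ms^-1 via the (A,B,C,D,E) form; e.g.
# alpha_m(V) = 0.1 (V + 40) / (1 - exp(-(V + 40)/10))
#            = (-4 - 0.1 V) / (-1 + exp((V + 40)/(-10))).

#' Classic squid sodium channel (m^3 h, 120 mS/cm2, ENa +50 mV)
#' @param gbar,erev optional overrides of the classic defaults.
#' @export
hh_na_channel <- function(gbar = "120 mS/cm2", erev = "50 mV") {
  gated_channel("hh_na", gbar, erev, list(
    gate_spec("m", 3,
              alpha = c(-4.0, -0.1, -1, 40, -10),
              beta  = c(4.0, 0, 0, 65, 18)),
    gate_spec("h", 1,
              alpha = c(0.07, 0, 0, 65, 20),
              beta  = c(1.0, 0, 1, 35, -10))
  ))
}

#' Classic squid delayed-rectifier potassium channel (n^4, 36 mS/cm2, EK -77 mV)
#' @param gbar,erev optional overrides of the classic defaults.
#' @export
hh_k_channel <- function(gbar = "36 mS/cm2", erev = "-77 mV") {
  gated_channel("hh_k", gbar, erev, list(
    gate_spec("n", 4,
              alpha = c(-0.55, -0.01, -1, 55, -10),
              beta  = c(0.125, 0, 0, 65, 80))
  ))
}

#' Classic squid leak channel (0.3 mS/cm2, -54.3 mV)
#' @param gbar,erev optional overrides of the classic defaults.
#' @export
hh_leak_channel <- function(gbar = "0.3 mS/cm2", erev = "-54.3 mV") {
  leak_channel("hh_leak", gbar, erev)
}

# JSON serialisation -----------------------------------------------------

#' Serialise a channel definition to a JSON string
#' @param chl a `channel` or `psr_template`.
#' @export
channel_to_json <- function(chl) {
  fmt_q <- function(q) {
    u <- .cn_param_unit(q)
    sprintf("%.17g %s", qty_in(q, u), u)
  }
  doc <- list(name = chl$name, kind = chl$kind)
  if (inherits(chl, "psr_template")) {
    doc$parameters <- lapply(get_defaults(chl), fmt_q)
  } else {
    doc$parameters <- lapply(chl$defaults, fmt_q)
    if (length(chl$gates)) {
      doc$gates <- lapply(unname(chl$gates), function(g) {
        list(name = g$name, exponent = g$exponent, alpha = g$alpha, beta = g$beta)
      })
    }
  }
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17))
}

#' Rebuild a channel from its JSON serialisation
#' @param json string produced by [channel_to_json()].
#' @export
channel_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  pars <- doc$parameters
  switch(doc$kind,
    leak = leak_channel(doc$name, pars$gbar, pars$erev),
    alpha_beta_gated = {
      gates <- lapply(doc$gates, function(g) {
        gate_spec(g$name, g$exponent, unlist(g$alpha), unlist(g$beta))
      })
      gated_channel(doc$name, pars$gbar, pars$erev, gates)
    },
    double_exp_psr = psr_template(pars$tau_rise, pars$tau_decay, pars$gbar,
                                  pars$erev, pars$delay, name = doc$name),
    cn_abort(sprintf("unknown channel kind '%s'", doc$kind), "cablenet_parse_error"))
}
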