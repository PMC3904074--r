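# JSON simulation documents ----------------------------------------------
#
# The full object graph serialises to a JSON document so simulations can
# be stored, diffed and run from files (CLI `run`).  Quantities are
# serialised as "<magnitude> <unit>" strings; morphologies as explicit
# section lists.

.cn_json_qty <- function(x, unit) sprintf("%.17g %s", x, unit)

.cn_morph_to_list <- function(m) {
  list(name = m$name, sections = lapply(unname(m$sections), function(s) {
    list(id = s$id, proximal = s$proximal, distal = s$distal,
         r_prox = s$r_prox, r_dist = s$r_dist,
         parent = if (is.na(s$parent)) NULL else s$parent,
         region = s$region)
  }))
}

.cn_morph_from_list <- function(d) {
  morphology(lapply(d$sections, function(s) {
    section(s$id, unlist(s$proximal), unlist(s$distal), s$r_prox, s$r_dist,
            parent = if (is.null(s$parent)) NA else s$parent,
            region = s$region)
  }), name = d$name)
}

.cn_chl_to_list <- function(chl) {
  jsonlite::fromJSON(channel_to_json(chl), simplifyVector = FALSE)
}

.cn_chl_from_list <- function(d) {
  channel_from_json(jsonlite::toJSON(d, auto_unbox = TRUE, digits = I(17)))
}

.cn_loc_to_list <- function(l) {
  list(cell = l$cell, section = l$location$section,
       fraction_along = l$location$fraction_along)
}

.cn_loc_from_list <- function(d) loc(d$cell, d$section, d$fraction_along)

#' Serialise a simulation object graph to a JSON document
#' @param sim a `simulation`.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @export
sim_to_json <- function(sim, path = NULL) {
  doc <- list(
    format = "cablenet-simulation-v1",
    name = sim$name,
    duration_ms = sim$duration, dt_ms = sim$dt, seed = sim$seed,
    cells = lapply(unname(sim$cells), function(cl) {
      list(name = cl$name,
           morphology = .cn_morph_to_list(cl$morphology),
           capacitance = .cn_json_qty(cl$capacitance, "uF/cm2"),
           axial_resistivity = .cn_json_qty(cl$axial_resistivity, "Ohm*cm"),
           initial_voltage = if (is.null(cl$initial_voltage)) NULL else
             .cn_json_qty(cl$initial_voltage, "mV"),
           applications = lapply(cl$applications, function(app) {
             list(channel = .cn_chl_to_list(app$channel),
                  applicator = list(
                    overrides = lapply(app$applicator$overrides, function(q) {
                      u <- .cn_param_unit(q)
                      sprintf("%.17g %s", qty_in(q, u), u)
                    }),
                    multipliers = app$applicator$multipliers),
                  targeter = unclass(app$targeter))
           }))
    }),
    stimuli = lapply(sim$stimuli, function(st) {
      list(kind = st$kind, protocol = st$protocol, name = st$name,
           location = .cn_loc_to_list(st$location),
           delay_ms = st$delay, duration_ms = st$duration, params = st$params)
    }),
    synapses = lapply(sim$synapses, function(sy) {
      list(name = sy$name, template = .cn_chl_to_list(sy$template),
           post = .cn_loc_to_list(sy$post), delay_ms = sy$delay,
           trigger = if (sy$trigger$kind == "times")
             list(kind = "times", times_ms = sy$trigger$times)
           else list(kind = "presyn",
                     location = .cn_loc_to_list(sy$trigger$location),
                     threshold_mV = sy$trigger$threshold))
    }),
    gap_junctions = lapply(sim$gap_junctions, function(gj) {
      list(name = gj$name, conductance_nS = gj$g_nS,
           loc1 = .cn_loc_to_list(gj$loc1), loc2 = .cn_loc_to_list(gj$loc2))
    }),
    recordings = lapply(sim$recordings, function(rc) {
      out <- list(what = rc$what, name = rc$name,
                  user_tags = as.list(rc$user_tags))
      if (!is.null(rc$location)) out$location <- .cn_loc_to_list(rc$location)
      if (!is.null(rc$channel)) out$channel <- rc$channel
      if (!is.null(rc$stimulus)) out$stimulus <- rc$stimulus
      if (!is.null(rc$synapse)) out$synapse <- rc$synapse
      if (!is.null(rc$threshold)) out$threshold_mV <- rc$threshold
      out
    }))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Rebuild a simulation from its JSON document
#' @param json a JSON string or path to a file written by [sim_to_json()].
#' @export
sim_from_json <- function(json) {
  if (length(json) == 1L && !grepl("^\\s*\\{", json) && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(doc$format, "cablenet-simulation-v1")) {
    cn_abort("not a cablenet simulation document", "cablenet_parse_error")
  }
  sim <- simulation(doc$name, qty(doc$duration_ms, "ms"), qty(doc$dt_ms, "ms"),
                    seed = doc$seed)
  for (cd in doc$cells) {
    cl <- add_cell(sim, cd$name, .cn_morph_from_list(cd$morphology),
                   capacitance = cd$capacitance,
                   axial_resistivity = cd$axial_resistivity,
                   initial_voltage = cd$initial_voltage)
    for (ad in cd$applications) {
      td <- ad$targeter
      targ <- switch(td$kind,
                     everywhere = target_everywhere(td$priority),
                     region = target_region(td$region, td$priority),
                     section = target_section(td$section, td$priority))
      appl <- applicator(overrides = ad$applicator$overrides,
                         multipliers = lapply(ad$applicator$multipliers, as.numeric))
      apply_channel(cl, .cn_chl_from_list(ad$channel), appl, targ)
    }
  }
  for (sd in doc$stimuli) {
    l <- .cn_loc_from_list(sd$location)
    if (sd$kind == "current") {
      args <- list(sim = sim, location = l, protocol = sd$protocol,
                   delay = qty(sd$delay_ms, "ms"),
                   duration = qty(sd$duration_ms, "ms"), name = sd$name)
      p <- sd$params
      if (!is.null(p$amp)) args$amplitude <- qty(p$amp, "pA")
      if (!is.null(p$amp0)) args$amplitude0 <- qty(p$amp0, "pA")
      if (!is.null(p$amp1)) args$amplitude1 <- qty(p$amp1, "pA")
      if (!is.null(p$freq)) args$freq <- qty(p$freq, "Hz")
      if (!is.null(p$phase)) args$phase <- p$phase
      do.call(create_currentclamp, args)
    } else {
      create_voltageclamp(sim, l, level = qty(sd$params$level, "mV"),
                          delay = qty(sd$delay_ms, "ms"),
                          duration = qty(sd$duration_ms, "ms"),
                          r_series = qty(1 / sd$params$g_series_uS, "MOhm"),
                          name = sd$name)
    }
  }
  for (sd in doc$synapses) {
    trg <- if (sd$trigger$kind == "times") {
      trigger_times(unlist(sd$trigger$times_ms))
    } else {
      trigger_presyn(.cn_loc_from_list(sd$trigger$location),
                     qty(sd$trigger$threshold_mV, "mV"))
    }
    add_synapse(sim, .cn_chl_from_list(sd$template),
                .cn_loc_from_list(sd$post), trg, delay = qty(sd$delay_ms, "ms"))
  }
  for (gd in doc$gap_junctions) {
    add_gap_junction(sim, qty(gd$conductance_nS, "nS"),
                     .cn_loc_from_list(gd$loc1), .cn_loc_from_list(gd$loc2))
  }
  for (rd in doc$recordings) {
    args <- list(sim = sim, what = rd$what, user_tags = unlist(rd$user_tags),
                 name = rd$name)
    if (!is.null(rd$location)) args$location <- .cn_loc_from_list(rd$location)
    if (!is.null(rd$channel)) args$channel <- rd$channel
    if (!is.null(rd$stimulus)) args$stimulus <- rd$stimulus
    if (!is.null(rd$synapse)) args$synapse <- rd$synapse
    if (!is.null(rd$threshold_mV)) args$threshold <- qty(rd$threshold_mV, "mV")
    do.call(record, args)
  }
  sim
}
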