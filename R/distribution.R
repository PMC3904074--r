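# Channel distribution rules --------------------------------------------
#
# Channel densities over a morphology are declared as triplets
# (Channel, Applicator, Targeter).  A Targeter selects sections
# (everywhere / by region / by section id) and carries a priority; an
# Applicator modifies the channel's default parameters (overrides, then
# multipliers).  For each (section, channel) pair the single matching
# triplet with the highest priority wins; two matches at equal priority
# are a hard error rather than silent shadowing.

#' Target every section
#' @param priority integer priority (default 1, the least specific).
#' @export
target_everywhere <- function(priority = 1L) {
  structure(list(kind = "everywhere", priority = as.integer(priority)),
            class = "targeter")
}

#' Target all sections in a named region
#' @param region region label.
#' @param priority integer priority (default 2).
#' @export
target_region <- function(region, priority = 2L) {
  structure(list(kind = "region", region = region,
                 priority = as.integer(priority)),
            class = "targeter")
}

#' Target a single section by id
#' @param section section id.
#' @param priority integer priority (default 3, the most specific).
#' @export
target_section <- function(section, priority = 3L) {
  structure(list(kind = "section", section = as.character(section),
                 priority = as.integer(priority)),
            class = "targeter")
}

.cn_targeter_desc <- function(t) {
  switch(t$kind,
         everywhere = "everywhere",
         region = sprintf("region '%s'", t$region),
         section = sprintf("section '%s'", t$section))
}

.cn_targeter_matches <- function(t, sec) {
  switch(t$kind,
         everywhere = TRUE,
         region = sec$region == t$region,
         section = sec$id == t$section)
}

#' Parameter modifications applied by a distribution triplet
#'
#' Starting from the channel defaults, `overrides` replace values and
#' `multipliers` then scale them. A parameter may not appear in both.
#'
#' @param overrides named list of quantities (or strings).
#' @param multipliers named list of bare numerics.
#' @export
applicator <- function(overrides = list(), multipliers = list()) {
  both <- intersect(names(overrides), names(multipliers))
  if (length(both)) {
    cn_abort(sprintf("parameter '%s' appears in both overrides and multipliers",
                     both[1]), "cablenet_domain_error")
  }
  structure(list(overrides = lapply(overrides, as_qty),
                 multipliers = multipliers),
            class = "applicator")
}

#' Uniform application of channel defaults
#' @param ... passed to [applicator()].
#' @export
apply_uniform <- function(...) applicator(...)

#' Bind a channel, an applicator and a targeter into one distribution rule
#' @param channel a `channel` object.
#' @param applicator an [applicator()]; default applies channel defaults.
#' @param targeter a targeter; default [target_everywhere()].
#' @export
channel_application <- function(channel, applicator = apply_uniform(),
                                targeter = target_everywhere()) {
  vars <- get_variables(channel)
  bad <- setdiff(c(names(applicator$overrides), names(applicator$multipliers)), vars)
  if (length(bad)) {
    cn_abort(sprintf("parameter '%s' is not a variable of channel '%s' (has: %s)",
                     bad[1], channel$name, paste(vars, collapse = ", ")),
             "cablenet_key_error")
  }
  if (!inherits(targeter, "targeter")) cn_abort("targeter required", "cablenet_domain_error")
  structure(list(channel = channel, applicator = applicator, targeter = targeter),
            class = "channel_application")
}

#' Resolve distribution triplets over a morphology
#'
#' For every section and channel, the single highest-priority matching
#' triplet determines the parameters: channel defaults, then overrides,
#' then multipliers. Sections matched by no triplet carry no instance of
#' that channel. Two matching triplets with equal priority raise an
#' ambiguity error; referencing a region absent from the morphology raises
#' a key error.
#'
#' @param applications list of [channel_application()] objects.
#' @param m a `morphology`.
#' @return nested list: `result[[section_id]][[channel_name]]` is a list
#'   with `channel` and `params` (named list of quantities).
#' @export
resolve_distribution <- function(applications, m) {
  regions <- morph_regions(m)
  for (app in applications) {
    t <- app$targeter
    if (t$kind == "region" && !(t$region %in% regions)) {
      cn_abort(sprintf("targeter references unknown region '%s' (have: %s)",
                       t$region, paste(regions, collapse = ", ")),
               "cablenet_key_error")
    }
    if (t$kind == "section" && !(t$section %in% names(m$sections))) {
      cn_abort(sprintf("targeter references unknown section '%s'", t$section),
               "cablenet_key_error")
    }
  }
  out <- list()
  chl_names <- unique(vapply(applications, function(a) a$channel$name, ""))
  for (sec in m$sections) {
    sec_out <- list()
    for (cname in chl_names) {
      apps <- Filter(function(a) a$channel$name == cname &&
                       .cn_targeter_matches(a$targeter, sec), applications)
      if (!length(apps)) next
      prios <- vapply(apps, function(a) a$targeter$priority, 0L)
      top <- which(prios == max(prios))
      if (length(top) > 1L) {
        descs <- vapply(apps[top], function(a) .cn_targeter_desc(a$targeter), "")
        cn_abort(sprintf(
          "ambiguous distribution for channel '%s' on section '%s': triplets [%s] share priority %d",
          cname, sec$id, paste(descs, collapse = "; "), max(prios)),
          "cablenet_ambiguity_error")
      }
      app <- apps[[top]]
      params <- get_defaults(app$channel)
      ov <- app$applicator$overrides
      for (nm in names(ov)) {
        params[[nm]] <- qty_convert(ov[[nm]], .cn_param_unit(params[[nm]]))
      }
      for (nm in names(app$applicator$multipliers)) {
        params[[nm]] <- params[[nm]] * qty(app$applicator$multipliers[[nm]])
        params[[nm]]$unit <- .cn_param_unit(get_defaults(app$channel)[[nm]])
      }
      sec_out[[cname]] <- list(channel = app$channel, params = params)
    }
    out[[sec$id]] <- sec_out
  }
  out
}

.cn_param_unit <- function(q) {
  if (is.null(q$unit) || is.na(q$unit)) "1" else q$unit
}

#' Tabulate a resolved distribution
#'
#' @param resolved output of [resolve_distribution()].
#' @param m the morphology it was resolved over.
#' @return data.frame with columns section, region, channel, parameter,
#'   value, unit (used by the summary generator).
#' @export
distribution_table <- function(resolved, m) {
  rows <- list()
  for (sid in names(resolved)) {
    for (cname in names(resolved[[sid]])) {
      params <- resolved[[sid]][[cname]]$params
      for (pn in names(params)) {
        q <- params[[pn]]
        u <- .cn_param_unit(q)
        rows[[length(rows) + 1L]] <- data.frame(
          section = sid, region = m$sections[[sid]]$region,
          channel = cname, parameter = pn,
          value = qty_in(q, u), unit = u,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(section = character(), region = character(),
                      channel = character(), parameter = character(),
                      value = numeric(), unit = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
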