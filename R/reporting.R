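# Plotting and model summaries -------------------------------------------
#
# TagViewer renders a single figure of stacked axes sharing one time base;
# which traces land on which axis is decided by tag-selection queries held
# in PlotSpec objects.  Summaries render a simulation's object graph
# (cells, channels, distributions, stimuli, synapses) to a standalone
# HTML or Markdown document with embedded SVG figures.

#' Define one axis of a TagViewer figure
#'
#' @param selector tag query text (e.g. `"ALL{Voltage}"`).
#' @param ylabel axis label; defaults to the selector text.
#' @param yunit unit to convert matched traces to; defaults to the unit of
#'   the first matched trace.
#' @param yrange optional `c(lo, hi)` display range.
#' @export
plot_spec <- function(selector, ylabel = NULL, yunit = NULL, yrange = NULL) {
  parse_query(selector)
  if (!is.null(yunit)) .cn_parse_unit(yunit)
  structure(list(selector = selector,
                 ylabel = if (is.null(ylabel)) selector else ylabel,
                 yunit = yunit, yrange = yrange),
            class = "plot_spec")
}

#' The default axis list used when no PlotSpecs are supplied
#'
#' One axis per standard modality, in a fixed order: Voltage, Current,
#' CurrentDensity, Conductance, ConductanceDensity, Events.  The
#' selectors are mutually exclusive because every trace carries exactly
#' one modality tag.
#' @export
default_plot_specs <- function() {
  list(plot_spec("ALL{Voltage}", "voltage", "mV"),
       plot_spec("ALL{Current}", "current", "pA"),
       plot_spec("ALL{CurrentDensity}", "current density", "mA/cm2"),
       plot_spec("ALL{Conductance}", "conductance", "nS"),
       plot_spec("ALL{ConductanceDensity}", "conductance density", "mS/cm2"),
       plot_spec("ALL{Event}", "events"))
}

# Per-axis plotted data: the pure function of (results, specs) that the
# figure is drawn from; exposed so documents can be compared by data
# rather than by pixels.
#' Data underlying a TagViewer figure
#' @param results a `simulation_results`.
#' @param plot_specs list of [plot_spec()]; default [default_plot_specs()].
#' @return list of axes, each with the spec, matched series (converted to
#'   the axis unit) and the axis unit; axes matching nothing are dropped.
#' @export
tagviewer_data <- function(results, plot_specs = NULL) {
  if (is.null(plot_specs)) plot_specs <- default_plot_specs()
  axes <- list()
  for (ps in plot_specs) {
    matched <- filter_traces(results, ps$selector)
    if (!length(matched)) next
    yunit <- ps$yunit
    series <- list()
    for (tr in matched) {
      if (inherits(tr, "cn_eventset")) {
        series[[length(series) + 1L]] <-
          list(kind = "events", name = tr$name, times = tr$times)
        next
      }
      if (is.null(yunit)) yunit <- tr$unit
      vals <- tryCatch(qty_in(qty(tr$values, tr$unit), yunit),
                       cablenet_dim_error = function(e) {
        cn_abort(sprintf(
          "axis '%s' (unit '%s') cannot display trace '%s' (unit '%s')",
          ps$selector, yunit, tr$name, tr$unit), "cablenet_dim_error")
      })
      series[[length(series) + 1L]] <-
        list(kind = "trace", name = tr$name, times = tr$times, values = vals)
    }
    axes[[length(axes) + 1L]] <- list(spec = ps, unit = yunit, series = series)
  }
  axes
}

#' Render stacked axes of tag-selected traces to an SVG file
#'
#' @param results a `simulation_results`.
#' @param plot_specs list of [plot_spec()]; when omitted the default
#'   modality axes are used and axes that match no trace are dropped.
#' @param out_path output SVG path.
#' @param width,height figure size in inches.
#' @return `out_path`, invisibly; the plotted data is attached as
#'   attribute `"data"`.
#' @export
tagviewer_render <- function(results, plot_specs = NULL, out_path,
                             width = 7, height = NULL) {
  axes <- tagviewer_data(results, plot_specs)
  if (!length(axes)) {
    all_tags <- sort(unique(unlist(lapply(results$traces, `[[`, "tags"))))
    cn_abort(sprintf("no trace matches any plot spec; available tags: %s",
                     paste(all_tags, collapse = ", ")), "cablenet_plot_error")
  }
  if (is.null(height)) height <- 1.8 * length(axes) + 0.6
  grDevices::svg(out_path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  old <- graphics::par(mfrow = c(length(axes), 1),
                       mar = c(2.5, 4.2, 0.6, 0.6), mgp = c(2.1, 0.6, 0))
  on.exit(graphics::par(old), add = TRUE)
  for (ax in axes) {
    traces <- Filter(function(s) s$kind == "trace", ax$series)
    evs <- Filter(function(s) s$kind == "events", ax$series)
    if (length(traces)) {
      xlim <- range(unlist(lapply(traces, `[[`, "times")))
      ylim <- if (!is.null(ax$spec$yrange)) ax$spec$yrange else
        range(unlist(lapply(traces, `[[`, "values")))
      if (diff(ylim) == 0) ylim <- ylim + c(-1, 1)
      graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "time [ms]",
                     ylab = sprintf("%s [%s]", ax$spec$ylabel, ax$unit))
      for (i in seq_along(traces)) {
        graphics::lines(traces[[i]]$times, traces[[i]]$values, col = i, lwd = 1.2)
      }
      if (length(traces) > 1L) {
        graphics::legend("topright", legend = vapply(traces, `[[`, "", "name"),
                         col = seq_along(traces), lwd = 1.2, bty = "n", cex = 0.7)
      }
    }
    if (length(evs)) {
      if (!length(traces)) {
        xlim <- range(c(0, unlist(lapply(evs, `[[`, "times")), 1))
        graphics::plot(NA, xlim = xlim, ylim = c(0.5, length(evs) + 0.5),
                       xlab = "time [ms]", ylab = ax$spec$ylabel, yaxt = "n")
      }
      for (i in seq_along(evs)) {
        yy <- if (length(traces)) graphics::par("usr")[4] else i
        graphics::points(evs[[i]]$times, rep(yy, length(evs[[i]]$times)),
                         pch = 3, col = i)
      }
    }
  }
  out <- out_path
  attr(out, "data") <- axes
  invisible(out)
}

# Morphology projection ----------------------------------------------------

#' Render an XY orthographic projection of a morphology to SVG
#'
#' Line width is proportional to local diameter.
#' @param m a `morphology`.
#' @param out_path output SVG path.
#' @export
morphology_projection <- function(m, out_path) {
  grDevices::svg(out_path, width = 4, height = 4)
  on.exit(grDevices::dev.off(), add = TRUE)
  xs <- unlist(lapply(m$sections, function(s) c(s$proximal[1], s$distal[1])))
  ys <- unlist(lapply(m$sections, function(s) c(s$proximal[2], s$distal[2])))
  rmax <- max(vapply(m$sections, function(s) max(s$r_prox, s$r_dist), 0))
  graphics::plot(NA, xlim = range(xs) + c(-rmax, rmax),
                 ylim = range(ys) + c(-rmax, rmax), asp = 1,
                 xlab = "x [um]", ylab = "y [um]", main = m$name)
  regions <- morph_regions(m)
  for (s in m$sections) {
    col <- match(s$region, regions)
    graphics::segments(s$proximal[1], s$proximal[2], s$distal[1], s$distal[2],
                       lwd = pmax(0.5, (s$r_prox + s$r_dist)), col = col)
  }
  if (length(regions) > 1L) {
    graphics::legend("topright", legend = regions, col = seq_along(regions),
                     lwd = 2, bty = "n", cex = 0.7)
  }
  invisible(out_path)
}

#' Rate, steady-state and time-constant curves of a gated channel (SVG)
#' @param chl a gated `channel`.
#' @param out_path output SVG path.
#' @param v_range voltage range in mV (default -100..60).
#' @export
channel_kinetics_figure <- function(chl, out_path, v_range = c(-100, 60)) {
  if (chl$kind != "alpha_beta_gated") {
    cn_abort("kinetics figure requires a gated channel", "cablenet_domain_error")
  }
  V <- seq(v_range[1], v_range[2], by = 0.5)
  grDevices::svg(out_path, width = 7, height = 2.6)
  on.exit(grDevices::dev.off(), add = TRUE)
  old <- graphics::par(mfrow = c(1, 3), mar = c(3.5, 3.5, 1.5, 0.5),
                       mgp = c(2, 0.6, 0))
  on.exit(graphics::par(old), add = TRUE)
  ng <- length(chl$gates)
  a <- lapply(chl$gates, function(g) eval_rate(g$alpha, V))
  b <- lapply(chl$gates, function(g) eval_rate(g$beta, V))
  gl <- names(chl$gates)
  graphics::matplot(V, do.call(cbind, c(a, b)), type = "l",
                    col = rep(seq_len(ng), 2), lty = rep(1:2, each = ng),
                    xlab = "V [mV]", ylab = "rate [ms^-1]", main = chl$name)
  graphics::legend("topleft", bty = "n", cex = 0.7,
                   legend = c(paste0("alpha_", gl), paste0("beta_", gl)),
                   col = rep(seq_len(ng), 2), lty = rep(1:2, each = ng))
  inf <- mapply(function(x, y) x / (x + y), a, b, SIMPLIFY = FALSE)
  tau <- mapply(function(x, y) 1 / (x + y), a, b, SIMPLIFY = FALSE)
  graphics::matplot(V, do.call(cbind, inf), type = "l", lty = 1,
                    col = seq_len(ng), xlab = "V [mV]", ylab = "steady state",
                    main = "inf(V)")
  graphics::matplot(V, do.call(cbind, tau), type = "l", lty = 1,
                    col = seq_len(ng), xlab = "V [mV]", ylab = "tau [ms]",
                    main = "tau(V)")
  invisible(out_path)
}

# Summary documents ---------------------------------------------------------

.cn_md_table <- function(df) {
  if (!nrow(df)) return(sprintf("| %s |\n(empty)\n", paste(names(df), collapse = " | ")))
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  fmt_cell <- function(x) if (is.numeric(x)) sprintf("%.6g", x) else as.character(x)
  rows <- apply(df, 1, function(r) paste0("| ", paste(vapply(r, fmt_cell, ""), collapse = " | "), " |"))
  paste(c(hdr, sep, rows), collapse = "\n")
}

.cn_md_to_html <- function(md_lines, title) {
  body <- character()
  in_table <- FALSE
  flush_row <- function(line, tag) {
    cells <- strsplit(gsub("^\\s*\\||\\|\\s*$", "", line), "\\|")[[1]]
    paste0("<tr>", paste0("<", tag, ">", trimws(cells), "</", tag, ">",
                          collapse = ""), "</tr>")
  }
  lines <- strsplit(paste(md_lines, collapse = "\n"), "\n")[[1]]
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^\\|", ln)) {
      if (!in_table) { body <- c(body, "<table>"); in_table <- TRUE }
      if (grepl("^\\|[-| ]+\\|$", ln)) { i <- i + 1L; next }
      tag <- if (i + 1L <= length(lines) && grepl("^\\|[-| ]+\\|$", lines[i + 1L])) "th" else "td"
      body <- c(body, flush_row(ln, tag))
      i <- i + 1L
      next
    }
    if (in_table) { body <- c(body, "</table>"); in_table <- FALSE }
    if (grepl("^### ", ln)) body <- c(body, sprintf("<h3>%s</h3>", sub("^### ", "", ln)))
    else if (grepl("^## ", ln)) body <- c(body, sprintf("<h2>%s</h2>", sub("^## ", "", ln)))
    else if (grepl("^# ", ln)) body <- c(body, sprintf("<h1>%s</h1>", sub("^# ", "", ln)))
    else if (grepl("^!\\[", ln)) {
      src <- sub("^!\\[[^]]*\\]\\(([^)]*)\\)$", "\\1", ln)
      body <- c(body, sprintf("<img src=\"%s\" alt=\"figure\"/>", src))
    } else if (nzchar(trimws(ln))) body <- c(body, sprintf("<p>%s</p>", ln))
    i <- i + 1L
  }
  if (in_table) body <- c(body, "</table>")
  c("<!DOCTYPE html>", "<html><head>",
    sprintf("<title>%s</title>", title),
    "<style>body{font-family:sans-serif;max-width:60em;margin:2em auto;}",
    "table{border-collapse:collapse;} td,th{border:1px solid #999;padding:2px 8px;}</style>",
    "</head><body>", body, "</body></html>")
}

#' Generate a human-readable summary document of a simulation
#'
#' The document contains per-cell tables (sections, total area,
#' capacitance, axial resistivity), a 2D morphology projection per cell,
#' per-channel parameter tables with rate/steady-state/time-constant
#' curves for gated channels, the resolved channel-distribution table,
#' stimulus/synapse/gap-junction tables and, when results are supplied,
#' the default TagViewer figure.
#'
#' @param sim a `simulation`.
#' @param results optional `simulation_results` of this simulation.
#' @param out_path output document path (figures are written next to it).
#' @param format `"html"` (standalone, default) or `"md"`.
#' @return `out_path`, invisibly.
#' @export
summarize_simulation <- function(sim, results = NULL, out_path,
                                 format = c("html", "md")) {
  format <- match.arg(format)
  dir <- dirname(out_path)
  stem <- sub("\\.(html|md)$", "", basename(out_path))
  figs <- character()
  md <- c(sprintf("# Simulation summary: %s", sim$name),
          sprintf("duration %g ms, dt %g ms, %d cells, %d stimuli, %d synapses, %d gap junctions, %d recordings",
                  sim$duration, sim$dt, length(sim$cells), length(sim$stimuli),
                  length(sim$synapses), length(sim$gap_junctions),
                  length(sim$recordings)))

  md <- c(md, "", "## Cells")
  cell_df <- do.call(rbind, lapply(sim$cells, function(cl) {
    data.frame(name = cl$name,
               sections = length(cl$morphology$sections),
               area_um2 = qty_in(surface_area(cl$morphology), "um2"),
               capacitance_uF_cm2 = cl$capacitance,
               Ra_Ohm_cm = cl$axial_resistivity,
               channels = length(cl$applications),
               stringsAsFactors = FALSE)
  }))
  if (is.null(cell_df)) cell_df <- data.frame(name = character())
  md <- c(md, .cn_md_table(cell_df))
  for (cl in sim$cells) {
    fig <- file.path(dir, sprintf("%s_morph_%s.svg", stem, cl$name))
    morphology_projection(cl$morphology, fig)
    figs <- c(figs, fig)
    md <- c(md, sprintf("![morphology of %s](%s)", cl$name, basename(fig)))
  }

  md <- c(md, "", "## Channels")
  seen <- character()
  for (cl in sim$cells) {
    for (app in cl$applications) {
      chl <- app$channel
      if (chl$name %in% seen) next
      seen <- c(seen, chl$name)
      md <- c(md, sprintf("### %s (%s)", chl$name, chl$kind))
      defs <- get_defaults(chl)
      pdf_ <- data.frame(parameter = names(defs),
                         default = vapply(defs, function(q) base::format(q), ""),
                         stringsAsFactors = FALSE)
      md <- c(md, .cn_md_table(pdf_))
      if (chl$kind == "alpha_beta_gated") {
        fig <- file.path(dir, sprintf("%s_chl_%s.svg", stem, chl$name))
        channel_kinetics_figure(chl, fig)
        figs <- c(figs, fig)
        md <- c(md, sprintf("![kinetics of %s](%s)", chl$name, basename(fig)))
      }
    }
  }

  md <- c(md, "", "## Channel distribution")
  dist_df <- do.call(rbind, lapply(sim$cells, function(cl) {
    tb <- distribution_table(resolve_distribution(cl$applications, cl$morphology),
                             cl$morphology)
    if (nrow(tb)) cbind(cell = cl$name, tb) else NULL
  }))
  if (is.null(dist_df)) dist_df <- data.frame(cell = character())
  md <- c(md, .cn_md_table(dist_df))

  md <- c(md, "", "## Stimuli")
  stim_df <- do.call(rbind, lapply(sim$stimuli, function(st) {
    data.frame(name = st$name, kind = st$kind, protocol = st$protocol,
               cell = st$location$cell,
               section = st$location$location$section,
               delay_ms = st$delay, duration_ms = st$duration,
               parameters = paste(sprintf("%s=%g", names(st$params),
                                          unlist(st$params)), collapse = ", "),
               stringsAsFactors = FALSE)
  }))
  if (is.null(stim_df)) stim_df <- data.frame(name = character())
  md <- c(md, .cn_md_table(stim_df))

  md <- c(md, "", "## Synapses")
  syn_df <- do.call(rbind, lapply(sim$synapses, function(sy) {
    data.frame(name = sy$name, template = sy$template$name,
               post = sy$post$cell,
               trigger = if (sy$trigger$kind == "times")
                 sprintf("times [%s] ms", paste(sy$trigger$times, collapse = ","))
               else sprintf("spike in %s (theta %g mV)",
                            sy$trigger$location$cell, sy$trigger$threshold),
               tau_rise_ms = sy$template$tau_rise,
               tau_decay_ms = sy$template$tau_decay,
               gbar_nS = sy$template$gbar, erev_mV = sy$template$erev,
               delay_ms = sy$delay, stringsAsFactors = FALSE)
  }))
  if (is.null(syn_df)) syn_df <- data.frame(name = character())
  md <- c(md, .cn_md_table(syn_df))

  md <- c(md, "", "## Gap junctions")
  gj_df <- do.call(rbind, lapply(sim$gap_junctions, function(gj) {
    data.frame(name = gj$name, g_nS = gj$g_nS,
               end1 = sprintf("%s:%s", gj$loc1$cell, gj$loc1$location$section),
               end2 = sprintf("%s:%s", gj$loc2$cell, gj$loc2$location$section),
               stringsAsFactors = FALSE)
  }))
  if (is.null(gj_df)) gj_df <- data.frame(name = character())
  md <- c(md, .cn_md_table(gj_df))

  if (!is.null(results)) {
    md <- c(md, "", "## Results")
    fig <- file.path(dir, sprintf("%s_results.svg", stem))
    tagviewer_render(results, NULL, fig)
    figs <- c(figs, fig)
    md <- c(md, sprintf("![results](%s)", basename(fig)))
  }

  if (format == "md") {
    writeLines(md, out_path)
  } else {
    writeLines(.cn_md_to_html(md, sprintf("Simulation summary: %s", sim$name)),
               out_path)
  }
  invisible(structure(out_path, figures = figs))
}
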