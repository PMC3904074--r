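# Scenario verification harness ------------------------------------------
#
# A scenario is a human- and machine-readable text file describing a small
# simulation with <PARAM> placeholders, a sweep of parameter values and a
# table of hand-calculated expected values.  Running a scenario builds the
# corresponding simulation for each parameter set, evaluates windowed
# statistics of recorded symbols ("$V[95:100].mean" = mean of $V over the
# half-open window [95, 100) ms) and compares them with the expectations
# at the scenario tolerance (relative, with an absolute floor of 0.01 in
# the record's unit to avoid blow-ups near zero).
#
# File grammar (blocks in any order after SCENARIO; '#' starts a comment):
#   SCENARIO <name>
#   TOLERANCE <relative fraction>           (optional; default 0.01)
#   DESCRIPTION ... directive lines ...     (see below)
#   UNITS     | symbol | unit |             (parameters and record symbols)
#   RECORD    | $sym | modality | target | location |
#   VALUES    pipe table, one column per <PARAM>, one row per sweep point
#   EXPECTED  pipe table, columns "$sym[t0:t1].stat", rows match VALUES
#
# DESCRIPTION directives (uppercase keywords; values are numbers or
# <PARAM> placeholders; units come from the UNITS block for placeholders
# and from the keyword's conventional unit for literals):
#   SIMULATION DURATION <ms> [DT <ms>]
#   CELL <name> AREA <um2> [CAPACITANCE <uF/cm2>] [RA <Ohm*cm>] [VINIT <mV>]
#   CHANNEL leak <name> ON <cell> GBAR <mS/cm2> EREV <mV>
#   CHANNEL hh_na|hh_k|hh_leak ON <cell> [GBAR <mS/cm2>] [EREV <mV>]
#   STIMULUS step <name> INTO <cell> AMPLITUDE <pA> DELAY <ms> DURATION <ms>
#   STIMULUS ramp <name> INTO <cell> AMPLITUDE0 <pA> AMPLITUDE1 <pA> DELAY <ms> DURATION <ms>
#   STIMULUS sine <name> INTO <cell> AMPLITUDE <pA> FREQ <Hz> [PHASE <rad>] DELAY <ms> DURATION <ms>
#   VCLAMP <name> INTO <cell> LEVEL <mV> [DELAY <ms>] [DURATION <ms>]
#   SYNAPSE <name> ONTO <cell> TAURISE <ms> TAUDECAY <ms> GBAR <nS> EREV <mV> TIMES t1,t2,...
#   GAPJUNCTION <name> BETWEEN <cell1> <cell2> G <nS>

.cn_scn_kw_units <- c(
  DURATION = "ms", DT = "ms", AREA = "um2", CAPACITANCE = "uF/cm2",
  RA = "Ohm*cm", VINIT = "mV", GBAR = NA, EREV = "mV", AMPLITUDE = "pA",
  AMPLITUDE0 = "pA", AMPLITUDE1 = "pA", DELAY = "ms", FREQ = "Hz",
  PHASE = "rad", LEVEL = "mV", TAURISE = "ms", TAUDECAY = "ms", G = "nS")

.cn_scn_err <- function(msg, line = NA) {
  cn_abort(if (is.na(line)) msg else sprintf("scenario line %d: %s", line, msg),
           "cablenet_scenario_error")
}

.cn_parse_pipe_row <- function(ln) {
  trimws(strsplit(gsub("^\\s*\\||\\|\\s*$", "", ln), "\\|")[[1]])
}

#' Parse a scenario file
#'
#' @param path scenario file path.
#' @return object of class `scenario`.
#' @export
parse_scenario <- function(path) {
  raw <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", raw)
  s <- list(name = NULL, tolerance = 0.01, directives = list(),
            units = character(), records = list(),
            values = NULL, expected_cols = list(), expected = NULL,
            path = path)
  block <- NULL
  values_rows <- list(); values_header <- NULL
  expected_rows <- list(); expected_header <- NULL
  record_rows <- list(); unit_rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    first <- sub("\\s.*$", "", ln)
    if (first == "SCENARIO") {
      s$name <- trimws(sub("^SCENARIO", "", ln))
      if (!nzchar(s$name)) .cn_scn_err("SCENARIO needs a name", i)
      next
    }
    if (first == "TOLERANCE") {
      s$tolerance <- suppressWarnings(as.numeric(trimws(sub("^TOLERANCE", "", ln))))
      if (is.na(s$tolerance) || s$tolerance <= 0) .cn_scn_err("bad TOLERANCE", i)
      next
    }
    if (first %in% c("DESCRIPTION", "UNITS", "RECORD", "VALUES", "EXPECTED")) {
      block <- first
      next
    }
    if (is.null(block)) .cn_scn_err(sprintf("unexpected content '%s'", ln), i)
    if (block == "DESCRIPTION") {
      s$directives[[length(s$directives) + 1L]] <- list(text = ln, line = i)
    } else if (block == "UNITS") {
      row <- .cn_parse_pipe_row(ln)
      if (length(row) != 2L) .cn_scn_err("UNITS rows are | symbol | unit |", i)
      .cn_parse_unit(row[2])
      s$units[[sub("^\\$", "", row[1])]] <- row[2]
    } else if (block == "RECORD") {
      row <- .cn_parse_pipe_row(ln)
      if (length(row) != 4L) {
        .cn_scn_err("RECORD rows are | $sym | modality | target | location |", i)
      }
      sym <- sub("^\\$", "", row[1])
      if (!(row[2] %in% c("Voltage", "Conductance", "Current"))) {
        .cn_scn_err(sprintf("unsupported record modality '%s'", row[2]), i)
      }
      s$records[[sym]] <- list(modality = row[2], target = row[3],
                               location = row[4], line = i)
    } else if (block == "VALUES") {
      row <- .cn_parse_pipe_row(ln)
      if (is.null(values_header)) values_header <- row
      else values_rows[[length(values_rows) + 1L]] <- row
    } else if (block == "EXPECTED") {
      row <- .cn_parse_pipe_row(ln)
      if (is.null(expected_header)) expected_header <- row
      else expected_rows[[length(expected_rows) + 1L]] <- row
    }
  }
  if (is.null(s$name)) .cn_scn_err("missing SCENARIO header")
  if (is.null(values_header)) .cn_scn_err("missing VALUES table")
  if (is.null(expected_header)) .cn_scn_err("missing EXPECTED table")
  vals <- matrix(NA_real_, nrow = length(values_rows), ncol = length(values_header),
                 dimnames = list(NULL, values_header))
  for (r in seq_along(values_rows)) {
    if (length(values_rows[[r]]) != length(values_header)) {
      .cn_scn_err("VALUES row width does not match header")
    }
    vals[r, ] <- as.numeric(values_rows[[r]])
  }
  if (anyNA(vals)) .cn_scn_err("non-numeric entry in VALUES")
  s$values <- vals
  # expected columns: $sym[t0:t1].stat (stat optional -> mean)
  cols <- lapply(expected_header, function(h) {
    m <- regmatches(h, regexec(
      "^\\$([A-Za-z0-9_]+)\\[([0-9.eE+-]+):([0-9.eE+-]+)\\](?:\\.(mean|max|min))?$",
      h, perl = TRUE))[[1]]
    if (length(m) == 0L || !nzchar(m[2])) {
      .cn_scn_err(sprintf("malformed expected column '%s' (want $sym[t0:t1].stat)", h))
    }
    t0 <- as.numeric(m[3]); t1 <- as.numeric(m[4])
    if (is.na(t0) || is.na(t1) || t0 >= t1) {
      .cn_scn_err(sprintf("malformed slice in expected column '%s'", h))
    }
    list(sym = m[2], t0 = t0, t1 = t1,
         stat = if (nzchar(m[5])) m[5] else "mean", header = h)
  })
  s$expected_cols <- cols
  exp_m <- matrix(NA_real_, nrow = length(expected_rows), ncol = length(cols),
                  dimnames = list(NULL, expected_header))
  for (r in seq_along(expected_rows)) {
    if (length(expected_rows[[r]]) != length(cols)) {
      .cn_scn_err("EXPECTED row width does not match header")
    }
    exp_m[r, ] <- as.numeric(expected_rows[[r]])
  }
  if (anyNA(exp_m)) .cn_scn_err("non-numeric entry in EXPECTED")
  s$expected <- exp_m
  # cross checks
  if (nrow(exp_m) != nrow(vals)) {
    .cn_scn_err(sprintf("EXPECTED has %d rows but VALUES has %d parameter sets",
                        nrow(exp_m), nrow(vals)))
  }
  for (cl in cols) {
    if (!(cl$sym %in% names(s$records))) {
      .cn_scn_err(sprintf("expected column uses undeclared record $%s", cl$sym))
    }
    if (!(cl$sym %in% names(s$units))) {
      .cn_scn_err(sprintf("record $%s has no entry in UNITS", cl$sym))
    }
  }
  used <- unique(unlist(lapply(s$directives, function(d) {
    m <- gregexpr("<([A-Za-z0-9_]+)>", d$text, perl = TRUE)
    regmatches(d$text, m)[[1]]
  })))
  used <- gsub("[<>]", "", used)
  for (p in used) {
    if (!(p %in% colnames(vals))) {
      .cn_scn_err(sprintf("placeholder <%s> has no VALUES column", p))
    }
    if (!(p %in% names(s$units))) {
      .cn_scn_err(sprintf("placeholder <%s> has no entry in UNITS", p))
    }
  }
  class(s) <- "scenario"
  s
}

#' Render a scenario structure back to its file format
#' @param s a `scenario`.
#' @return character vector of lines.
#' @export
format_scenario <- function(s) {
  out <- c(sprintf("SCENARIO %s", s$name),
           sprintf("TOLERANCE %g", s$tolerance),
           "", "DESCRIPTION")
  out <- c(out, vapply(s$directives, function(d) paste0("  ", d$text), ""))
  out <- c(out, "", "UNITS")
  for (nm in names(s$units)) out <- c(out, sprintf("  | %s | %s |", nm, s$units[[nm]]))
  out <- c(out, "", "RECORD")
  for (nm in names(s$records)) {
    r <- s$records[[nm]]
    out <- c(out, sprintf("  | $%s | %s | %s | %s |", nm, r$modality, r$target, r$location))
  }
  fmt_row <- function(v) paste0("  | ", paste(v, collapse = " | "), " |")
  out <- c(out, "", "VALUES", fmt_row(colnames(s$values)))
  for (r in seq_len(nrow(s$values))) {
    out <- c(out, fmt_row(sprintf("%.10g", s$values[r, ])))
  }
  out <- c(out, "", "EXPECTED", fmt_row(colnames(s$expected)))
  for (r in seq_len(nrow(s$expected))) {
    out <- c(out, fmt_row(sprintf("%.10g", s$expected[r, ])))
  }
  out
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario '%s': %d directives, %d parameter sets, %d expected columns, tol %g>\n",
              x$name, length(x$directives), nrow(x$values),
              length(x$expected_cols), x$tolerance))
  invisible(x)
}

# substitute <PARAM> placeholders and return a quantity string
.cn_scn_value <- function(token, s, row, default_unit, line) {
  m <- regmatches(token, regexec("^<([A-Za-z0-9_]+)>$", token))[[1]]
  if (length(m) == 2L) {
    p <- m[2]
    qty(s$values[row, p], s$units[[p]])
  } else {
    v <- suppressWarnings(as.numeric(token))
    if (is.na(v)) .cn_scn_err(sprintf("expected number or <PARAM>, got '%s'", token), line)
    if (is.na(default_unit)) .cn_scn_err(sprintf("value '%s' needs a unit context", token), line)
    qty(v, default_unit)
  }
}

# build the simulation described by scenario s for parameter-set `row`
.cn_scn_build <- function(s, row, dt = NULL) {
  dur <- NULL; dt_file <- NULL
  # first pass: SIMULATION directive
  for (d in s$directives) {
    w <- strsplit(trimws(d$text), "\\s+")[[1]]
    if (w[1] == "SIMULATION") {
      kv <- .cn_scn_kv(w[-1], d$line)
      if (!is.null(kv$DURATION)) dur <- .cn_scn_value(kv$DURATION, s, row, "ms", d$line)
      if (!is.null(kv$DT)) dt_file <- .cn_scn_value(kv$DT, s, row, "ms", d$line)
    }
  }
  if (is.null(dur)) .cn_scn_err("missing SIMULATION DURATION directive")
  if (is.null(dt)) dt <- if (is.null(dt_file)) qty(0.025, "ms") else dt_file
  sim <- simulation(s$name, dur, dt)
  syn_handles <- list()
  for (d in s$directives) {
    w <- strsplit(trimws(d$text), "\\s+")[[1]]
    ln <- d$line
    val <- function(tok, unit) .cn_scn_value(tok, s, row, unit, ln)
    switch(w[1],
      SIMULATION = NULL,
      CELL = {
        kv <- .cn_scn_kv(w[-(1:2)], ln)
        if (is.null(kv$AREA)) .cn_scn_err("CELL needs AREA", ln)
        cl <- add_cell(sim, w[2], build_soma_from_area(val(kv$AREA, "um2")),
                 capacitance = if (!is.null(kv$CAPACITANCE)) val(kv$CAPACITANCE, "uF/cm2") else "1.0 uF/cm2",
                 axial_resistivity = if (!is.null(kv$RA)) val(kv$RA, "Ohm*cm") else "100 Ohm*cm",
                 initial_voltage = if (!is.null(kv$VINIT)) val(kv$VINIT, "mV") else NULL)
        cl
      },
      CHANNEL = {
        kind <- w[2]
        if (kind == "leak") {
          nm <- w[3]
          kv <- .cn_scn_kv(w[-(1:5)], ln)
          if (w[4] != "ON") .cn_scn_err("CHANNEL leak <name> ON <cell> ...", ln)
          cellname <- w[5]
          if (is.null(kv$GBAR) || is.null(kv$EREV)) .cn_scn_err("leak needs GBAR and EREV", ln)
          chl <- leak_channel(nm, val(kv$GBAR, "mS/cm2"), val(kv$EREV, "mV"))
          apply_channel(sim$cells[[cellname]], chl)
        } else if (kind %in% c("hh_na", "hh_k", "hh_leak")) {
          if (w[3] != "ON") .cn_scn_err("CHANNEL <builtin> ON <cell> ...", ln)
          cellname <- w[4]
          kv <- .cn_scn_kv(w[-(1:4)], ln)
          builder <- switch(kind, hh_na = hh_na_channel, hh_k = hh_k_channel,
                            hh_leak = hh_leak_channel)
          args <- list()
          if (!is.null(kv$GBAR)) args$gbar <- val(kv$GBAR, "mS/cm2")
          if (!is.null(kv$EREV)) args$erev <- val(kv$EREV, "mV")
          apply_channel(sim$cells[[cellname]], do.call(builder, args))
        } else .cn_scn_err(sprintf("unknown channel kind '%s'", kind), ln)
      },
      STIMULUS = {
        proto <- w[2]; nm <- w[3]
        if (w[4] != "INTO") .cn_scn_err("STIMULUS <proto> <name> INTO <cell> ...", ln)
        cellname <- w[5]
        kv <- .cn_scn_kv(w[-(1:5)], ln)
        args <- list(sim = sim, location = loc(cellname, "soma"),
                     protocol = proto, name = nm)
        if (!is.null(kv$DELAY)) args$delay <- val(kv$DELAY, "ms")
        if (!is.null(kv$DURATION)) args$duration <- val(kv$DURATION, "ms")
        if (!is.null(kv$AMPLITUDE)) args$amplitude <- val(kv$AMPLITUDE, "pA")
        if (!is.null(kv$AMPLITUDE0)) args$amplitude0 <- val(kv$AMPLITUDE0, "pA")
        if (!is.null(kv$AMPLITUDE1)) args$amplitude1 <- val(kv$AMPLITUDE1, "pA")
        if (!is.null(kv$FREQ)) args$freq <- val(kv$FREQ, "Hz")
        if (!is.null(kv$PHASE)) args$phase <- val(kv$PHASE, "rad")
        do.call(create_currentclamp, args)
      },
      VCLAMP = {
        nm <- w[2]
        if (w[3] != "INTO") .cn_scn_err("VCLAMP <name> INTO <cell> ...", ln)
        cellname <- w[4]
        kv <- .cn_scn_kv(w[-(1:4)], ln)
        if (is.null(kv$LEVEL)) .cn_scn_err("VCLAMP needs LEVEL", ln)
        args <- list(sim = sim, location = loc(cellname, "soma"),
                     level = val(kv$LEVEL, "mV"), name = nm)
        if (!is.null(kv$DELAY)) args$delay <- val(kv$DELAY, "ms")
        if (!is.null(kv$DURATION)) args$duration <- val(kv$DURATION, "ms")
        do.call(create_voltageclamp, args)
      },
      SYNAPSE = {
        nm <- w[2]
        if (w[3] != "ONTO") .cn_scn_err("SYNAPSE <name> ONTO <cell> ...", ln)
        cellname <- w[4]
        kv <- .cn_scn_kv(w[-(1:4)], ln)
        for (req in c("TAURISE", "TAUDECAY", "GBAR", "EREV", "TIMES")) {
          if (is.null(kv[[req]])) .cn_scn_err(sprintf("SYNAPSE needs %s", req), ln)
        }
        tpl <- psr_template(val(kv$TAURISE, "ms"), val(kv$TAUDECAY, "ms"),
                            val(kv$GBAR, "nS"), val(kv$EREV, "mV"), name = nm)
        times <- as.numeric(strsplit(kv$TIMES, ",")[[1]])
        sy <- add_synapse(sim, tpl, loc(cellname, "soma"), trigger_times(times))
        syn_handles[[nm]] <- sy
      },
      GAPJUNCTION = {
        nm <- w[2]
        if (w[3] != "BETWEEN") .cn_scn_err("GAPJUNCTION <name> BETWEEN <c1> <c2> ...", ln)
        kv <- .cn_scn_kv(w[-(1:5)], ln)
        if (is.null(kv$G)) .cn_scn_err("GAPJUNCTION needs G", ln)
        add_gap_junction(sim, val(kv$G, "nS"),
                         loc(w[4], "soma"), loc(w[5], "soma"))
      },
      .cn_scn_err(sprintf("unknown directive '%s'", w[1]), ln))
  }
  # recordings
  for (sym in names(s$records)) {
    r <- s$records[[sym]]
    if (r$modality == "Voltage") {
      record(sim, "Voltage", loc(r$target, r$location), name = sym)
    } else {
      if (!(r$target %in% names(syn_handles))) {
        .cn_scn_err(sprintf("record $%s targets unknown synapse '%s'", sym, r$target),
                    r$line)
      }
      record(sim, r$modality, synapse = syn_handles[[r$target]], name = sym)
    }
  }
  sim
}

.cn_scn_kv <- function(words, line) {
  kv <- list()
  i <- 1L
  while (i <= length(words)) {
    key <- words[i]
    if (!(key %in% names(.cn_scn_kw_units)) && key != "TIMES") {
      .cn_scn_err(sprintf("unknown keyword '%s'", key), line)
    }
    if (i + 1L > length(words)) .cn_scn_err(sprintf("keyword '%s' needs a value", key), line)
    kv[[key]] <- words[i + 1L]
    i <- i + 2L
  }
  kv
}

#' Run a scenario and compare against its expectation table
#'
#' For every parameter set the described simulation is built and run, each
#' expected cell is evaluated with [window_stat()] in the unit declared
#' for its record symbol, and the relative error is compared with the
#' scenario tolerance (absolute floor 0.01).  A failing simulation marks
#' all cells of its row failed with the diagnostic, and the run
#' continues.
#'
#' @param s a `scenario` (or path to one).
#' @param backend list of solver settings: `method` (`"be"`/`"cn"`) and
#'   optional `dt` (ms) overriding the scenario's.
#' @return a `comparison_report`: data.frame of cells plus an overall
#'   `pass` attribute.
#' @export
run_scenario <- function(s, backend = list(method = "be")) {
  if (is.character(s)) s <- parse_scenario(s)
  method <- if (is.null(backend$method)) "be" else backend$method
  dt <- if (is.null(backend$dt)) NULL else qty(backend$dt, "ms")
  rows <- list()
  for (r in seq_len(nrow(s$values))) {
    res <- tryCatch({
      sim <- .cn_scn_build(s, r, dt = dt)
      run(sim, method = method)
    }, error = function(e) e)
    for (ci in seq_along(s$expected_cols)) {
      cl <- s$expected_cols[[ci]]
      expd <- s$expected[r, ci]
      unit <- s$units[[cl$sym]]
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          row = r, cell = cl$header, expected = expd, observed = NA_real_,
          rel_error = NA_real_, pass = FALSE,
          note = conditionMessage(res), stringsAsFactors = FALSE)
        next
      }
      tr_i <- which(vapply(res$traces, `[[`, "", "name") == cl$sym)
      tr <- res$traces[[tr_i]]
      obs <- qty_in(qty_convert(window_stat(tr, cl$t0, cl$t1, cl$stat), unit), unit)
      err <- abs(obs - expd)
      tol_abs <- max(s$tolerance * abs(expd), 0.01)
      rows[[length(rows) + 1L]] <- data.frame(
        row = r, cell = cl$header, expected = expd, observed = obs,
        rel_error = if (expd != 0) err / abs(expd) else err,
        pass = err <= tol_abs, note = "", stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, rows)
  structure(rep, class = c("comparison_report", class(rep)),
            scenario = s$name, pass = all(rep$pass), tolerance = s$tolerance)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Scenario '%s': %s (%d/%d cells pass, tolerance %g)\n",
              attr(x, "scenario"), if (attr(x, "pass")) "PASS" else "FAIL",
              sum(x$pass), nrow(x), attr(x, "tolerance")))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Run every scenario file in a directory
#' @param dir directory containing `*.scn` files.
#' @param backend solver settings, see [run_scenario()].
#' @return named list of `comparison_report`s; attribute `pass` is the
#'   conjunction.
#' @export
run_scenario_dir <- function(dir, backend = list(method = "be")) {
  files <- sort(list.files(dir, pattern = "\\.scn$", full.names = TRUE))
  if (!length(files)) cn_abort(sprintf("no .scn files in %s", dir), "cablenet_scenario_error")
  reps <- lapply(files, run_scenario, backend = backend)
  names(reps) <- basename(files)
  structure(reps, pass = all(vapply(reps, attr, TRUE, "pass")))
}

#' Compare solver configurations on one scenario
#'
#' Runs the scenario's simulations under each configuration, recording the
#' full traces of every declared symbol, and reports the pairwise maximum
#' relative discrepancy per symbol (relative to the per-sample magnitude
#' with an absolute floor of 0.01).
#'
#' @param s a `scenario` (or path).
#' @param configs list of backend configurations
#'   (`list(method =, dt =)`); at least two.
#' @return data.frame with columns config_a, config_b, symbol,
#'   max_rel_discrepancy.
#' @export
compare_backends <- function(s, configs) {
  if (is.character(s)) s <- parse_scenario(s)
  if (length(configs) < 2L) {
    cn_abort("compare_backends needs at least two configurations",
             "cablenet_comparison_error")
  }
  cfg_name <- function(cfg) {
    sprintf("%s dt=%s", if (is.null(cfg$method)) "be" else cfg$method,
            if (is.null(cfg$dt)) "file" else format(cfg$dt))
  }
  # per config: list over rows of named trace lists
  runs <- lapply(configs, function(cfg) {
    dt <- if (is.null(cfg$dt)) NULL else qty(cfg$dt, "ms")
    lapply(seq_len(nrow(s$values)), function(r) {
      sim <- .cn_scn_build(s, r, dt = dt)
      res <- run(sim, method = if (is.null(cfg$method)) "be" else cfg$method)
      setNames(res$traces, vapply(res$traces, `[[`, "", "name"))
    })
  })
  out <- list()
  for (a in seq_along(configs)) {
    for (b in seq_along(configs)) {
      if (b <= a) next
      for (sym in names(s$records)) {
        dmax <- 0
        for (r in seq_len(nrow(s$values))) {
          ta <- runs[[a]][[r]][[sym]]; tb <- runs[[b]][[r]][[sym]]
          if (is.null(ta) || is.null(tb)) {
            cn_abort("configurations recorded different symbol sets",
                     "cablenet_comparison_error")
          }
          # compare on the coarser time grid
          vb <- if (length(tb$times) == length(ta$times)) tb$values else
            stats::approx(tb$times, tb$values, xout = ta$times)$y
          d <- max(abs(ta$values - vb) / pmax(abs(ta$values), 0.01))
          dmax <- max(dmax, d)
        }
        out[[length(out) + 1L]] <- data.frame(
          config_a = cfg_name(configs[[a]]), config_b = cfg_name(configs[[b]]),
          symbol = sym, max_rel_discrepancy = dmax, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# Fixture generator ---------------------------------------------------------

#' Generate verification scenario files with closed-form expectations
#'
#' Emits six scenario files whose expectation tables are computed from
#' analytic solutions (no simulator involved): passive step response,
#' passive ramp response, input resistance, membrane time constant probed
#' through an early window, gap-junction coupling coefficient and PSR peak
#' under voltage clamp.  The seed perturbs the sweep amplitudes
#' deterministically; identical seeds give byte-identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @return character vector of the files written.
#' @export
generate_fixture_scenarios <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  files <- character()
  emit <- function(name, lines) {
    p <- file.path(out_dir, paste0(name, ".scn"))
    writeLines(lines, p)
    files <<- c(files, p)
  }
  tab <- function(rows) vapply(rows, function(r) paste0("  | ", paste(r, collapse = " | "), " |"), "")
  num <- function(x) sprintf("%.10g", x)

  # shared passive cell: A um2, C uF/cm2, GLK mS/cm2 -> G = GLK*A*1e-8*1e-3 S
  G_of <- function(A, GLK) GLK * 1e-3 * A * 1e-8      # S
  tau_of <- function(A, C, GLK) C / GLK               # uF/cm2 over mS/cm2 -> ms

  # 1. passive step response, window far beyond tau; VS is the starting
  # voltage (transient fully decayed inside the expectation window)
  A <- 1000; C <- 1; GLK <- 0.3; EREV <- -51; VS <- -60
  I3 <- 60 + sample(0:8, 1) * 10
  vss <- function(I) EREV + I * 1e-12 / G_of(A, GLK) * 1e3   # mV
  emit("passive_step", c(
    "# Passive single-compartment step response; expectations from",
    "# V = EREV + I/G in the settled window (>50 tau after onset).",
    sprintf("# generated with seed %d", as.integer(seed)),
    "SCENARIO passive_step", "TOLERANCE 0.01", "",
    "DESCRIPTION",
    "  SIMULATION DURATION 250",
    "  CELL cell1 AREA <A> CAPACITANCE <C> VINIT <VS>",
    "  CHANNEL leak lk ON cell1 GBAR <GLK> EREV <EREV>",
    "  STIMULUS step stim1 INTO cell1 AMPLITUDE <I> DELAY 50 DURATION 250",
    "", "UNITS",
    tab(list(c("A", "um2"), c("VS", "mV"), c("C", "uF/cm2"),
             c("GLK", "mS/cm2"), c("EREV", "mV"), c("I", "pA"),
             c("V", "mV"))),
    "", "RECORD",
    tab(list(c("$V", "Voltage", "cell1", "soma"))),
    "", "VALUES",
    tab(list(c("A", "VS", "C", "GLK", "EREV", "I"),
             num(c(A, VS, C, GLK, EREV, 0)),
             num(c(A, VS, C, GLK, EREV, 100)),
             num(c(A, VS, C, GLK, EREV, I3)))),
    "", "EXPECTED",
    tab(list("$V[245:250].mean",
             num(vss(0)), num(vss(100)), num(vss(I3))))))

  # 2. passive ramp response: I(t) = k t from onset; settled solution
  # V = EREV + (k/G)(t - tau) (transient negligible in the window)
  k_pA_ms <- 1 + sample(0:4, 1) * 0.25
  tau <- tau_of(A, C, GLK)
  # k/G: k*1e-12 A/ms over G S gives V/ms; *1e3 -> mV/ms
  ramp_mean <- EREV + (k_pA_ms * 1e-12 / G_of(A, GLK) * 1e3) * ((195 + 200) / 2 - 50 - tau)
  emit("passive_ramp", c(
    "# Passive cell under a current ramp I = k (t - delay); after several",
    "# tau the response tracks V = EREV + (k/G)(t - delay - tau).",
    sprintf("# generated with seed %d", as.integer(seed)),
    "SCENARIO passive_ramp", "TOLERANCE 0.01", "",
    "DESCRIPTION",
    "  SIMULATION DURATION 200",
    "  CELL cell1 AREA <A> CAPACITANCE <C>",
    "  CHANNEL leak lk ON cell1 GBAR <GLK> EREV <EREV>",
    sprintf("  STIMULUS ramp stim1 INTO cell1 AMPLITUDE0 0 AMPLITUDE1 %s DELAY 50 DURATION 150",
            num(k_pA_ms * 150)),
    "", "UNITS",
    tab(list(c("A", "um2"), c("C", "uF/cm2"), c("GLK", "mS/cm2"),
             c("EREV", "mV"), c("V", "mV"))),
    "", "RECORD",
    tab(list(c("$V", "Voltage", "cell1", "soma"))),
    "", "VALUES",
    tab(list(c("A", "C", "GLK", "EREV"), num(c(A, C, GLK, EREV)))),
    "", "EXPECTED",
    tab(list("$V[195:200].mean", num(ramp_mean)))))

  # 3. input resistance: 1200 um2 at 0.27778 mS/cm2 is 300 MOhm
  A2 <- 1200; GLK2 <- 1 / (300e6 * A2 * 1e-8)  / 1e-3     # mS/cm2
  E2 <- -60
  vss2 <- function(I) E2 + I * 1e-12 * 300e6 * 1e3
  emit("input_resistance", c(
    "# A 1200 um2 cell with 0.27778 mS/cm2 leak has input resistance",
    "# 300 MOhm; steady-state deflection is I * Rin.",
    sprintf("# generated with seed %d", as.integer(seed)),
    "SCENARIO input_resistance", "TOLERANCE 0.01", "",
    "DESCRIPTION",
    "  SIMULATION DURATION 300",
    "  CELL cell1 AREA <A> CAPACITANCE <C>",
    "  CHANNEL leak lk ON cell1 GBAR <GLK> EREV <EREV>",
    "  STIMULUS step stim1 INTO cell1 AMPLITUDE <I> DELAY 50 DURATION 300",
    "", "UNITS",
    tab(list(c("A", "um2"), c("C", "uF/cm2"), c("GLK", "mS/cm2"),
             c("EREV", "mV"), c("I", "pA"), c("V", "mV"))),
    "", "RECORD",
    tab(list(c("$V", "Voltage", "cell1", "soma"))),
    "", "VALUES",
    tab(list(c("A", "C", "GLK", "EREV", "I"),
             num(c(A2, 1, GLK2, E2, 0)),
             num(c(A2, 1, GLK2, E2, 50)),
             num(c(A2, 1, GLK2, E2, 100)))),
    "", "EXPECTED",
    tab(list("$V[290:300].mean",
             num(vss2(0)), num(vss2(50)), num(vss2(100))))))

  # 4. time constant: early-window mean of the exponential charging curve
  # mean over [onset, onset + tau) = E + IR (1 - (1 - exp(-1)))= E + IR/e
  I4 <- 100
  IR <- I4 * 1e-12 / G_of(A, GLK) * 1e3
  w_mean <- function(a, b) {    # window rel. to onset, ms
    EREV + IR * (1 - tau * (exp(-a / tau) - exp(-b / tau)) / (b - a))
  }
  emit("time_constant", c(
    "# Membrane time constant probed through window means of the charging",
    "# curve V = E + IR (1 - exp(-t/tau)), tau = C/GLK = 10/3 ms.",
    sprintf("# generated with seed %d", as.integer(seed)),
    "SCENARIO time_constant", "TOLERANCE 0.01", "",
    "DESCRIPTION",
    "  SIMULATION DURATION 120",
    "  CELL cell1 AREA <A> CAPACITANCE <C>",
    "  CHANNEL leak lk ON cell1 GBAR <GLK> EREV <EREV>",
    "  STIMULUS step stim1 INTO cell1 AMPLITUDE <I> DELAY 50 DURATION 70",
    "", "UNITS",
    tab(list(c("A", "um2"), c("C", "uF/cm2"), c("GLK", "mS/cm2"),
             c("EREV", "mV"), c("I", "pA"), c("V", "mV"))),
    "", "RECORD",
    tab(list(c("$V", "Voltage", "cell1", "soma"))),
    "", "VALUES",
    tab(list(c("A", "C", "GLK", "EREV", "I"),
             num(c(A, C, GLK, EREV, I4)))),
    "", "EXPECTED",
    tab(list(c(sprintf("$V[%s:%s].mean", num(50), num(50 + tau)),
               sprintf("$V[%s:%s].mean", num(50 + tau), num(50 + 2 * tau)),
               "$V[110:120].mean"),
             num(c(w_mean(0, tau), w_mean(tau, 2 * tau), vss(I4)))))))

  # 5. gap-junction coupling: two-node linear system
  g_nS <- 1; Gl <- G_of(A, GLK) * 1e9                      # nS
  I5 <- 100
  u1 <- I5 * 1e-3 * (Gl + g_nS) / (Gl * (Gl + 2 * g_nS)) * 1e3   # pA/nS -> mV
  u2 <- g_nS / (Gl + g_nS) * u1
  emit("gap_coupling", c(
    "# Two identical passive cells joined by a gap junction; steady",
    "# state from the two-node linear system, coupling = g/(G+g).",
    sprintf("# generated with seed %d", as.integer(seed)),
    "SCENARIO gap_coupling", "TOLERANCE 0.01", "",
    "DESCRIPTION",
    "  SIMULATION DURATION 250",
    "  CELL cell1 AREA <A> CAPACITANCE <C>",
    "  CELL cell2 AREA <A> CAPACITANCE <C>",
    "  CHANNEL leak lk1 ON cell1 GBAR <GLK> EREV <EREV>",
    "  CHANNEL leak lk2 ON cell2 GBAR <GLK> EREV <EREV>",
    "  GAPJUNCTION gj1 BETWEEN cell1 cell2 G <GJ>",
    "  STIMULUS step stim1 INTO cell1 AMPLITUDE <I> DELAY 50 DURATION 250",
    "", "UNITS",
    tab(list(c("A", "um2"), c("C", "uF/cm2"), c("GLK", "mS/cm2"),
             c("EREV", "mV"), c("GJ", "nS"), c("I", "pA"),
             c("V1", "mV"), c("V2", "mV"))),
    "", "RECORD",
    tab(list(c("$V1", "Voltage", "cell1", "soma"),
             c("$V2", "Voltage", "cell2", "soma"))),
    "", "VALUES",
    tab(list(c("A", "C", "GLK", "EREV", "GJ", "I"),
             num(c(A, C, GLK, EREV, g_nS, I5)))),
    "", "EXPECTED",
    tab(list(c("$V1[240:250].mean", "$V2[240:250].mean"),
             num(c(EREV + u1, EREV + u2))))))

  # 6. PSR peak under voltage clamp; tail window mean from the analytic
  # double-exponential integral over the window [25, 45) ms after the event
  tp <- 5 * 0.5 / (5 - 0.5) * log(5 / 0.5)
  Npsr <- 1 / (exp(-tp / 5) - exp(-tp / 0.5))
  psr_tail <- 2 * Npsr *
    (5 * (exp(-5 / 5) - exp(-25 / 5)) - 0.5 * (exp(-5 / 0.5) - exp(-25 / 0.5))) / 20
  emit("psr_peak", c(
    "# Voltage-clamped cell receiving one double-exponential synaptic",
    "# event; peak conductance equals gbar by normalisation, at",
    "# t_p = tau_d tau_r/(tau_d - tau_r) ln(tau_d/tau_r) after the event.",
    sprintf("# generated with seed %d", as.integer(seed)),
    "SCENARIO psr_peak", "TOLERANCE 0.01", "",
    "DESCRIPTION",
    "  SIMULATION DURATION 60",
    "  CELL cell1 AREA <A> CAPACITANCE <C>",
    "  CHANNEL leak lk ON cell1 GBAR <GLK> EREV <ECLAMP>",
    "  VCLAMP vc1 INTO cell1 LEVEL <ECLAMP>",
    "  SYNAPSE syn1 ONTO cell1 TAURISE 0.5 TAUDECAY 5 GBAR <GSYN> EREV 0 TIMES 20",
    "", "UNITS",
    tab(list(c("A", "um2"), c("C", "uF/cm2"), c("GLK", "mS/cm2"),
             c("ECLAMP", "mV"), c("GSYN", "nS"),
             c("V", "mV"), c("G", "nS"))),
    "", "RECORD",
    tab(list(c("$V", "Voltage", "cell1", "soma"),
             c("$G", "Conductance", "syn1", "-"))),
    "", "VALUES",
    tab(list(c("A", "C", "GLK", "ECLAMP", "GSYN"),
             num(c(A, C, GLK, -60, 2)))),
    "", "EXPECTED",
    tab(list(c("$V[10:20].mean", "$G[20:30].max", "$G[25:45].mean"),
             num(c(-60, 2, psr_tail))))))
  invisible(files)
}
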