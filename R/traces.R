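# Tagged results and trace analysis -------------------------------------
#
# Every recording yields either a Trace (time-stamped analog signal with
# a unit and a set of string tags) or an EventSet (sorted event times with
# tags).  Tags drive result selection through a small boolean query
# language: ALL{...} / ANY{...} predicates combined with AND, OR, NOT and
# parentheses.  Tag comparison is case-insensitive.

#' Construct a trace
#'
#' @param times strictly increasing sample times, ms.
#' @param values sample values (same length as `times`).
#' @param unit unit string of the values (must parse, e.g. `"mV"`).
#' @param tags character vector of tags.
#' @param name trace name.
#' @export
trace <- function(times, values, unit = "mV", tags = character(), name = "") {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) {
    cn_abort("times and values must have equal length", "cablenet_domain_error")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    cn_abort("trace times must be strictly increasing", "cablenet_domain_error")
  }
  .cn_parse_unit(unit)
  structure(list(times = times, values = values, unit = unit,
                 tags = unique(as.character(tags)), name = name),
            class = "cn_trace")
}

#' Construct an event set
#' @param times event times, ms (sorted internally).
#' @param tags character vector of tags.
#' @param name name.
#' @export
eventset <- function(times, tags = character(), name = "") {
  structure(list(times = sort(as.numeric(times)),
                 tags = unique(as.character(tags)), name = name),
            class = "cn_eventset")
}

#' @export
print.cn_trace <- function(x, ...) {
  cat(sprintf("<trace '%s': %d samples [%g, %g] ms, unit %s, tags {%s}>\n",
              x$name, length(x$times),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA,
              x$unit, paste(x$tags, collapse = ",")))
  invisible(x)
}

#' @export
print.cn_eventset <- function(x, ...) {
  cat(sprintf("<eventset '%s': %d events, tags {%s}>\n",
              x$name, length(x$times), paste(x$tags, collapse = ",")))
  invisible(x)
}

# Tag query language ------------------------------------------------------
# Grammar (AND binds tighter than OR; NOT tightest):
#   expr   := term ('OR' term)*
#   term   := factor ('AND' factor)*
#   factor := 'NOT' factor | '(' expr ')' | ('ALL'|'ANY') '{' tag (',' tag)* '}'
#   tag    := [A-Za-z0-9_:.-]+

#' Parse a tag-selection query
#'
#' @param text query string, e.g.
#'   `"ALL{CONDUCTANCE,SYNAPTIC,PRE:cell1,POST:cell2} AND ANY{NMDA,AMPA}"`.
#' @return a `tag_query` expression tree.
#' @export
parse_query <- function(text) {
  if (!is.character(text) || !nzchar(trimws(text))) {
    cn_abort("empty tag query", "cablenet_query_error")
  }
  toks <- .cn_query_tokens(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$text <- text
  tree <- .cn_q_expr(st)
  if (st$pos <= length(st$toks)) {
    tk <- st$toks[[st$pos]]
    cn_abort(sprintf("unexpected '%s' at position %d in query", tk$v, tk$at),
             "cablenet_query_error")
  }
  structure(tree, class = "tag_query")
}

.cn_query_tokens <- function(text) {
  toks <- list()
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("\\s", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")", "{", "}", ",")) {
      toks[[length(toks) + 1L]] <- list(t = ch, v = ch, at = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(text, i, n), regexpr("^[A-Za-z0-9_:.-]+", substr(text, i, n)))
    if (!length(m)) {
      cn_abort(sprintf("illegal character '%s' at position %d in query", ch, i),
               "cablenet_query_error")
    }
    word <- m[1]
    type <- if (toupper(word) %in% c("ALL", "ANY", "AND", "OR", "NOT")) toupper(word) else "TAG"
    toks[[length(toks) + 1L]] <- list(t = type, v = word, at = i)
    i <- i + nchar(word)
  }
  toks
}

.cn_q_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]]$t else "EOF"
.cn_q_take <- function(st, type) {
  if (.cn_q_peek(st) != type) {
    at <- if (st$pos <= length(st$toks)) st$toks[[st$pos]]$at else nchar(st$text) + 1L
    cn_abort(sprintf("expected %s at position %d in query '%s'", type, at, st$text),
             "cablenet_query_error")
  }
  tk <- st$toks[[st$pos]]
  st$pos <- st$pos + 1L
  tk
}

.cn_q_expr <- function(st) {
  node <- .cn_q_term(st)
  while (.cn_q_peek(st) == "OR") {
    .cn_q_take(st, "OR")
    node <- list(op = "or", lhs = node, rhs = .cn_q_term(st))
  }
  node
}

.cn_q_term <- function(st) {
  node <- .cn_q_factor(st)
  while (.cn_q_peek(st) == "AND") {
    .cn_q_take(st, "AND")
    node <- list(op = "and", lhs = node, rhs = .cn_q_factor(st))
  }
  node
}

.cn_q_factor <- function(st) {
  t <- .cn_q_peek(st)
  if (t == "NOT") {
    .cn_q_take(st, "NOT")
    return(list(op = "not", arg = .cn_q_factor(st)))
  }
  if (t == "(") {
    .cn_q_take(st, "(")
    node <- .cn_q_expr(st)
    .cn_q_take(st, ")")
    return(node)
  }
  if (t %in% c("ALL", "ANY")) {
    kw <- .cn_q_take(st, t)
    .cn_q_take(st, "{")
    tags <- character()
    repeat {
      tags <- c(tags, .cn_q_take(st, "TAG")$v)
      if (.cn_q_peek(st) == ",") { .cn_q_take(st, ","); next }
      break
    }
    .cn_q_take(st, "}")
    return(list(op = tolower(kw$t), tags = tags))
  }
  at <- if (st$pos <= length(st$toks)) st$toks[[st$pos]]$at else nchar(st$text) + 1L
  cn_abort(sprintf("expected predicate at position %d in query '%s'", at, st$text),
           "cablenet_query_error")
}

#' Render a tag query back to text
#' @param x a `tag_query`.
#' @param ... unused.
#' @export
format.tag_query <- function(x, ...) .cn_q_fmt(unclass(x))

.cn_q_fmt <- function(node) {
  switch(node$op,
         all = sprintf("ALL{%s}", paste(node$tags, collapse = ",")),
         any = sprintf("ANY{%s}", paste(node$tags, collapse = ",")),
         not = sprintf("NOT %s", .cn_q_fmt(node$arg)),
         and = sprintf("(%s AND %s)", .cn_q_fmt(node$lhs), .cn_q_fmt(node$rhs)),
         or  = sprintf("(%s OR %s)", .cn_q_fmt(node$lhs), .cn_q_fmt(node$rhs)))
}

#' @export
print.tag_query <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Evaluate a tag query against a tag set
#'
#' `ALL` is a subset test, `ANY` a nonempty-intersection test; operators
#' follow boolean logic. Comparison is case-insensitive.
#' @param q a `tag_query` (or query string).
#' @param tags character vector of tags.
#' @export
query_match <- function(q, tags) {
  if (is.character(q)) q <- parse_query(q)
  .cn_q_eval(unclass(q), tolower(tags))
}

.cn_q_eval <- function(node, tags_lc) {
  switch(node$op,
         all = all(tolower(node$tags) %in% tags_lc),
         any = any(tolower(node$tags) %in% tags_lc),
         not = !.cn_q_eval(node$arg, tags_lc),
         and = .cn_q_eval(node$lhs, tags_lc) && .cn_q_eval(node$rhs, tags_lc),
         or  = .cn_q_eval(node$lhs, tags_lc) || .cn_q_eval(node$rhs, tags_lc))
}

#' Select traces from simulation results by tag query
#'
#' @param results a `simulation_results` object (or plain list of traces
#'   and event sets).
#' @param query query string or `tag_query`.
#' @param events if `TRUE` event sets are eligible too (default; matches
#'   are returned in recording order regardless of kind).
#' @return list of matching traces/event sets, in recording order.
#' @export
filter_traces <- function(results, query, events = TRUE) {
  if (is.character(query)) query <- parse_query(query)
  items <- if (inherits(results, "simulation_results")) results$traces else results
  keep <- vapply(items, function(tr) {
    if (!events && inherits(tr, "cn_eventset")) return(FALSE)
    query_match(query, tr$tags)
  }, TRUE)
  items[keep]
}

# Trace analysis ----------------------------------------------------------

.cn_check_voltage_trace <- function(tr) {
  u <- .cn_parse_unit(tr$unit)
  if (!identical(unname(u$dim), unname(.cn_parse_unit("mV")$dim))) {
    cn_abort(sprintf("spike analysis needs a voltage trace, got unit '%s'", tr$unit),
             "cablenet_dim_error")
  }
}

#' Count threshold crossings (spikes) in a voltage trace
#'
#' A spike is a strict upward crossing: `v[i-1] < threshold <= v[i]`.
#' A trace that starts above threshold does not count a spike until the
#' voltage has fallen below threshold and risen again.
#' @param tr a voltage `cn_trace`.
#' @param threshold threshold, mV (quantity or numeric).
#' @export
spike_count <- function(tr, threshold = 0) {
  length(spike_times(tr, threshold)$times)
}

#' Spike times by linear interpolation at the threshold crossing
#' @param tr a voltage `cn_trace`.
#' @param threshold threshold, mV.
#' @return an `cn_eventset` tagged `Event` plus the trace's tags.
#' @export
spike_times <- function(tr, threshold = 0) {
  .cn_check_voltage_trace(tr)
  th <- if (is.quantity(threshold)) qty_in(threshold, "mV") else threshold
  v <- qty_in(qty_convert(qty(tr$values, tr$unit), "mV"), "mV")
  t <- tr$times
  n <- length(v)
  times <- numeric()
  if (n >= 2L) {
    i <- which(v[-n] < th & v[-1] >= th) + 1L
    if (length(i)) {
      frac <- (th - v[i - 1L]) / (v[i] - v[i - 1L])
      times <- t[i - 1L] + frac * (t[i] - t[i - 1L])
    }
  }
  eventset(times, tags = unique(c("Event", tr$tags)), name = paste0(tr$name, ".spikes"))
}

#' Windowed statistic of a trace
#'
#' Statistic over samples with `t0 <= t < t1` (half-open window), returned
#' in the trace's unit.
#' @param tr a `cn_trace`.
#' @param t0,t1 window bounds, ms; `t0 < t1`.
#' @param stat one of `"mean"`, `"max"`, `"min"`.
#' @export
window_stat <- function(tr, t0, t1, stat = c("mean", "max", "min")) {
  stat <- match.arg(stat)
  t0 <- if (is.quantity(t0)) qty_in(t0, "ms") else t0
  t1 <- if (is.quantity(t1)) qty_in(t1, "ms") else t1
  if (t0 >= t1) cn_abort("window requires t0 < t1", "cablenet_window_error")
  sel <- tr$times >= t0 & tr$times < t1
  if (!any(sel)) {
    cn_abort(sprintf("window [%g, %g) ms contains no samples", t0, t1),
             "cablenet_window_error")
  }
  v <- tr$values[sel]
  qty(switch(stat, mean = mean(v), max = max(v), min = min(v)), tr$unit)
}
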