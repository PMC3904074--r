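# Units-aware quantities ------------------------------------------------
#
# Every user-facing parameter (conductance densities, reversal potentials,
# capacitances, currents, times, areas ...) is carried as a `quantity`:
# a numeric magnitude stored internally in SI base units together with an
# integer exponent vector over the base dimensions (length, mass, time,
# current, amount) and a display unit label.  Canonicalising to SI on entry
# means conversions never accumulate rounding error: converting is a single
# division by the target unit's scale.

.cn_dim_names <- c("m", "kg", "s", "A", "mol")

.cn_dim <- function(m = 0L, kg = 0L, s = 0L, A = 0L, mol = 0L) {
  d <- as.integer(c(m, kg, s, A, mol))
  names(d) <- .cn_dim_names
  d
}

# Unit whitelist.  Each token maps to (scale-to-SI, dimension vector).
# Powers (um2), products (Ohm*cm) and quotients (mS/cm2) of these tokens
# are accepted by the parser; arbitrary unit grammar deliberately is not.
.cn_units <- local({
  u <- list()
  add <- function(base, dim, prefixes) {
    for (k in seq_along(prefixes)) {
      u[[paste0(names(prefixes)[k], base)]] <<- list(scale = prefixes[[k]], dim = dim)
    }
  }
  pref <- function(...) {
    v <- c(...)
    names(v)[names(v) == "_"] <- ""
    v
  }
  add("V",   .cn_dim(2, 1, -3, -1),  pref("_" = 1, m = 1e-3, u = 1e-6))
  add("A",   .cn_dim(A = 1),         pref("_" = 1, m = 1e-3, u = 1e-6, n = 1e-9, p = 1e-12))
  add("s",   .cn_dim(s = 1),         pref("_" = 1, m = 1e-3, u = 1e-6))
  add("m",   .cn_dim(m = 1),         pref("_" = 1, c = 1e-2, m = 1e-3, u = 1e-6, n = 1e-9))
  add("S",   .cn_dim(-2, -1, 3, 2),  pref("_" = 1, m = 1e-3, u = 1e-6, n = 1e-9, p = 1e-12))
  add("Ohm", .cn_dim(2, 1, -3, -2),  pref("_" = 1, k = 1e3, M = 1e6, G = 1e9))
  add("F",   .cn_dim(-2, -1, 4, 2),  pref("_" = 1, m = 1e-3, u = 1e-6, n = 1e-9, p = 1e-12))
  add("Hz",  .cn_dim(s = -1),        pref("_" = 1, k = 1e3))
  add("mol", .cn_dim(mol = 1),       pref("_" = 1, m = 1e-3, u = 1e-6))
  u[["rad"]] <- list(scale = 1, dim = .cn_dim())
  u[["1"]]   <- list(scale = 1, dim = .cn_dim())
  u
})

cn_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "cablenet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Parse a unit expression into (scale, dim).  Grammar:
#   expr  := term (('*' | '.' | '/') term)*
#   term  := TOKEN power?
#   power := '^'? '-'? DIGITS  |  DIGITS        (e.g. um2, cm^2, ms^-1)
# A term following '/' has its exponent negated.  The Unicode micro signs
# are accepted as aliases for 'u'.  Results are memoised: unit strings
# recur constantly (every record sample, every parameter check).
.cn_unit_cache <- new.env(parent = emptyenv())

.cn_parse_unit <- function(text) {
  hit <- .cn_unit_cache[[text]]
  if (!is.null(hit)) return(hit)
  res <- .cn_parse_unit_impl(text)
  .cn_unit_cache[[text]] <- res
  res
}

.cn_parse_unit_impl <- function(text) {
  raw <- text
  text <- gsub("µ|μ", "u", text)
  text <- gsub("\\s+", "", text)
  if (!nzchar(text)) {
    cn_abort("empty unit expression", "cablenet_parse_error")
  }
  parts <- regmatches(text, gregexpr("[*/.]|[^*/.]+", text))[[1]]
  scale <- 1
  dim <- .cn_dim()
  sign <- 1L
  expecting_term <- TRUE
  for (p in parts) {
    if (p %in% c("*", ".", "/")) {
      if (expecting_term) {
        cn_abort(sprintf("malformed unit expression '%s'", raw),
                 "cablenet_parse_error")
      }
      sign <- if (p == "/") -1L else 1L
      expecting_term <- TRUE
      next
    }
    m <- regmatches(p, regexec("^([A-Za-z1]+?)(?:\\^?(-?[0-9]+))?$", p, perl = TRUE))[[1]]
    if (length(m) == 0L || !nzchar(m[2])) {
      cn_abort(sprintf("cannot parse unit term '%s' in '%s'", p, raw),
               "cablenet_parse_error")
    }
    tok <- m[2]
    pow <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    entry <- .cn_units[[tok]]
    if (is.null(entry)) {
      cn_abort(sprintf("unknown unit token '%s' in '%s'", tok, raw),
               "cablenet_parse_error")
    }
    e <- sign * pow
    scale <- scale * entry$scale^e
    dim <- dim + entry$dim * e
    expecting_term <- FALSE
  }
  if (expecting_term) {
    cn_abort(sprintf("malformed unit expression '%s' (trailing operator)", raw),
             "cablenet_parse_error")
  }
  list(scale = scale, dim = dim)
}

.cn_new_qty <- function(mag_si, dim, unit) {
  structure(list(mag = mag_si, dim = dim, unit = unit), class = "quantity")
}

#' Construct a dimensioned quantity
#'
#' @param x numeric scalar or vector, expressed in `unit`.
#' @param unit unit expression drawn from the package whitelist (`mV`,
#'   `pA`, `ms`, `um2`, `mS/cm2`, `Ohm*cm`, `ms^-1`, ...). `"1"` denotes a
#'   dimensionless quantity.
#' @return an object of class `quantity`. Magnitudes are canonicalised to
#'   SI base units internally; `unit` is retained as the display label.
#' @examples
#' qty(0.3, "mS/cm2")
#' qty_in(qty(300, "MOhm"), "Ohm")
#' @export
qty <- function(x, unit = "1") {
  if (!is.numeric(x)) cn_abort("magnitude must be numeric", "cablenet_parse_error")
  u <- .cn_parse_unit(unit)
  .cn_new_qty(as.numeric(x) * u$scale, u$dim, unit)
}

#' Parse a "<number> <unit>" string into a quantity
#'
#' @param text e.g. `"300 MOhm"`, `"0.3 mS/cm2"`, `"-65 mV"`.
#' @return a `quantity`.
#' @export
parse_qty <- function(text) {
  if (is.quantity(text)) return(text)
  if (!is.character(text) || length(text) != 1L) {
    cn_abort("parse_qty expects a single string", "cablenet_parse_error")
  }
  m <- regmatches(text, regexec(
    "^\\s*([-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?)\\s*(\\S.*)?$", text,
    perl = TRUE))[[1]]
  if (length(m) == 0L || !nzchar(m[2])) {
    cn_abort(sprintf("missing magnitude in quantity '%s'", text),
             "cablenet_parse_error")
  }
  unit <- if (length(m) >= 3L && nzchar(m[3])) m[3] else "1"
  qty(as.numeric(m[2]), unit)
}

#' Coerce to quantity
#'
#' Strings are parsed with [parse_qty()]; bare numerics become
#' dimensionless; quantities pass through.
#' @param x input value.
#' @export
as_qty <- function(x) {
  if (is.quantity(x)) return(x)
  if (is.character(x)) return(parse_qty(x))
  if (is.numeric(x)) return(qty(x))
  cn_abort("cannot coerce to quantity", "cablenet_parse_error")
}

#' @export
is.quantity <- function(x) inherits(x, "quantity")

#' Convert a quantity to a compatible unit
#'
#' The underlying physical value is unchanged; only the display magnitude
#' and label change. Incompatible dimensions are a hard error.
#' @param q a `quantity` (or string parseable as one).
#' @param unit target unit expression.
#' @export
qty_convert <- function(q, unit) {
  q <- as_qty(q)
  u <- .cn_parse_unit(unit)
  if (!identical(unname(q$dim), unname(u$dim))) {
    cn_abort(sprintf(
      "incompatible dimensions: cannot convert [%s] to '%s' [%s]",
      .cn_fmt_dim(q$dim), unit, .cn_fmt_dim(u$dim)), "cablenet_dim_error")
  }
  .cn_new_qty(q$mag, q$dim, unit)
}

#' Numeric magnitude of a quantity in a given unit
#'
#' @param q a `quantity` (or string).
#' @param unit unit to express the magnitude in.
#' @return bare numeric vector.
#' @export
qty_in <- function(q, unit) {
  q <- qty_convert(q, unit)
  q$mag / .cn_parse_unit(unit)$scale
}

#' @export
qty_dimensionless <- function(q) all(as_qty(q)$dim == 0L)

.cn_fmt_dim <- function(dim) {
  nz <- dim != 0L
  if (!any(nz)) return("1")
  paste(sprintf("%s^%d", .cn_dim_names[nz], dim[nz]), collapse = " ")
}

.cn_same_dim <- function(a, b) identical(unname(a$dim), unname(b$dim))

#' @export
format.quantity <- function(x, ...) {
  if (!is.na(x$unit[1]) && !is.null(x$unit)) {
    sprintf("%g %s", x$mag / .cn_parse_unit(x$unit)$scale, x$unit)
  } else {
    sprintf("%g [%s]", x$mag, .cn_fmt_dim(x$dim))
  }
}

#' @export
print.quantity <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
Ops.quantity <- function(e1, e2) {
  op <- .Generic
  if (missing(e2)) {
    q <- as_qty(e1)
    if (op == "-") return(.cn_new_qty(-q$mag, q$dim, q$unit))
    if (op == "+") return(q)
    cn_abort(sprintf("unary '%s' undefined for quantities", op), "cablenet_dim_error")
  }
  if (op == "^") {
    q <- as_qty(e1)
    p <- e2
    if (is.quantity(p)) {
      if (!qty_dimensionless(p)) {
        cn_abort("exponent must be dimensionless", "cablenet_dim_error")
      }
      p <- p$mag
    }
    if (length(p) != 1L || p != round(p)) {
      cn_abort("quantity exponents must be single integers", "cablenet_dim_error")
    }
    return(.cn_new_qty(q$mag^p, q$dim * as.integer(p), NA_character_))
  }
  q1 <- as_qty(e1); q2 <- as_qty(e2)
  if (op %in% c("+", "-")) {
    if (!.cn_same_dim(q1, q2)) {
      cn_abort(sprintf("cannot %s [%s] and [%s]",
                       if (op == "+") "add" else "subtract",
                       .cn_fmt_dim(q1$dim), .cn_fmt_dim(q2$dim)),
               "cablenet_dim_error")
    }
    unit <- if (is.quantity(e1)) q1$unit else q2$unit
    return(.cn_new_qty(get(op)(q1$mag, q2$mag), q1$dim, unit))
  }
  if (op == "*") return(.cn_new_qty(q1$mag * q2$mag, q1$dim + q2$dim, NA_character_))
  if (op == "/") return(.cn_new_qty(q1$mag / q2$mag, q1$dim - q2$dim, NA_character_))
  if (op %in% c("==", "!=", "<", ">", "<=", ">=")) {
    if (!.cn_same_dim(q1, q2)) {
      cn_abort(sprintf("cannot compare [%s] with [%s]",
                       .cn_fmt_dim(q1$dim), .cn_fmt_dim(q2$dim)),
               "cablenet_dim_error")
    }
    return(get(op)(q1$mag, q2$mag))
  }
  cn_abort(sprintf("'%s' undefined for quantities", op), "cablenet_dim_error")
}

# Check that q has the dimensions of `unit`; classed error otherwise.
.cn_check_dim <- function(q, unit, what) {
  q <- as_qty(q)
  u <- .cn_parse_unit(unit)
  if (!identical(unname(q$dim), unname(u$dim))) {
    cn_abort(sprintf("%s must have dimensions of '%s', got [%s]",
                     what, unit, .cn_fmt_dim(q$dim)), "cablenet_dim_error")
  }
  q
}

#' Area-specific conductance from input resistance and surface area
#'
#' A cell with input resistance R and membrane area A has uniform specific
#' leak conductance 1 / (R * A). Typical use: translating "a neuron with
#' surface area 1200 um2 and input resistance 300 MOhm" into a channel
#' density.
#' @param input_resistance quantity with resistance dimensions (> 0).
#' @param area quantity with area dimensions (> 0).
#' @return specific conductance as a quantity displayed in `mS/cm2`.
#' @export
area_specific_conductance <- function(input_resistance, area) {
  r <- .cn_check_dim(as_qty(input_resistance), "Ohm", "input_resistance")
  a <- .cn_check_dim(as_qty(area), "m2", "area")
  if (any(r$mag <= 0) || any(a$mag <= 0)) {
    cn_abort("input resistance and area must be positive", "cablenet_domain_error")
  }
  qty_convert(qty(1) / (r * a), "mS/cm2")
}
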