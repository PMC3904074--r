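# Morphologies ----------------------------------------------------------
#
# A morphology is a tree of Sections.  Each Section is a single conical
# frustum with explicit 3D endpoints and end radii (um) plus a Region
# label ("soma", "dendrite", ...).  Exactly one Section is the root
# (parent NA).  Electrical length is the Euclidean distance between the
# endpoints.

.cn_section <- function(id, proximal, distal, r_prox, r_dist, parent, region) {
  list(id = as.character(id),
       proximal = as.numeric(proximal), distal = as.numeric(distal),
       r_prox = as.numeric(r_prox), r_dist = as.numeric(r_dist),
       parent = if (is.null(parent) || is.na(parent)) NA_character_ else as.character(parent),
       region = as.character(region))
}

.cn_section_length <- function(s) sqrt(sum((s$distal - s$proximal)^2))

# Lateral area of a conical frustum: pi (r1 + r2) sqrt(L^2 + (r2 - r1)^2)
.cn_frustum_area <- function(r1, r2, L) pi * (r1 + r2) * sqrt(L^2 + (r2 - r1)^2)

#' Construct a morphology from a list of sections
#'
#' Low-level constructor; most users build morphologies with
#' [build_soma_from_area()], [morphology_builder()] helpers or [read_swc()].
#'
#' @param sections list of sections created with [section()].
#' @param name morphology name.
#' @return object of class `morphology`.
#' @export
morphology <- function(sections, name = "morphology") {
  ids <- vapply(sections, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    cn_abort("section ids must be unique", "cablenet_morph_error")
  }
  names(sections) <- ids
  parents <- vapply(sections, `[[`, "", "parent")
  roots <- sum(is.na(parents))
  if (roots != 1L) {
    cn_abort(sprintf("morphology must have exactly one root section, found %d", roots),
             "cablenet_morph_error")
  }
  bad <- !is.na(parents) & !(parents %in% ids)
  if (any(bad)) {
    cn_abort(sprintf("parent '%s' of section '%s' not in morphology",
                     parents[bad][1], ids[bad][1]), "cablenet_morph_error")
  }
  for (s in sections) {
    if (s$r_prox <= 0 || s$r_dist <= 0) {
      cn_abort(sprintf("section '%s' has non-positive radius", s$id),
               "cablenet_morph_error")
    }
    if (!is.na(s$parent) && .cn_section_length(s) <= 0) {
      cn_abort(sprintf("non-root section '%s' has zero length", s$id),
               "cablenet_morph_error")
    }
  }
  # cycle check: walking parent links from every node must reach the root
  for (id in ids) {
    seen <- character()
    cur <- id
    while (!is.na(sections[[cur]]$parent)) {
      if (cur %in% seen) cn_abort("cycle in section parent links", "cablenet_morph_error")
      seen <- c(seen, cur)
      cur <- sections[[cur]]$parent
    }
  }
  structure(list(sections = sections, name = name), class = "morphology")
}

#' Define one section (conical frustum)
#'
#' @param id unique section id.
#' @param proximal,distal 3-vectors, endpoint coordinates in um.
#' @param r_prox,r_dist end radii in um (> 0).
#' @param parent id of the parent section, or `NA` for the root.
#' @param region region label attached to the section.
#' @export
section <- function(id, proximal, distal, r_prox, r_dist,
                    parent = NA, region = "soma") {
  .cn_section(id, proximal, distal, r_prox, r_dist, parent, region)
}

#' @export
print.morphology <- function(x, ...) {
  cat(sprintf("<morphology '%s': %d sections, regions: %s, area %.4g um2>\n",
              x$name, length(x$sections),
              paste(unique(vapply(x$sections, `[[`, "", "region")), collapse = ","),
              qty_in(surface_area(x), "um2")))
  invisible(x)
}

#' Regions present in a morphology
#' @param m a `morphology`.
#' @export
morph_regions <- function(m) unique(vapply(m$sections, `[[`, "", "region"))

#' Single-section soma of a given membrane area
#'
#' Builds a cylinder with length equal to diameter, chosen so its lateral
#' surface equals the requested area: pi d^2 = A, hence d = sqrt(A/pi).
#'
#' @param area membrane area as a quantity (or string), e.g. `"1000 um2"`.
#' @param region region label, default `"soma"`.
#' @param name morphology name.
#' @export
build_soma_from_area <- function(area, region = "soma", name = "soma") {
  a <- .cn_check_dim(as_qty(area), "um2", "area")
  a_um2 <- qty_in(a, "um2")
  if (a_um2 <= 0) cn_abort("area must be positive", "cablenet_domain_error")
  d <- sqrt(a_um2 / pi)
  morphology(list(
    section("soma", c(0, 0, 0), c(d, 0, 0), d / 2, d / 2,
            parent = NA, region = region)
  ), name = name)
}

#' Total lateral membrane area of a morphology
#'
#' @param m a `morphology`.
#' @param region optional region label; restrict the sum to that region.
#' @return area as a quantity in um2.
#' @export
surface_area <- function(m, region = NULL) {
  secs <- m$sections
  if (!is.null(region)) {
    if (!(region %in% morph_regions(m))) {
      cn_abort(sprintf("unknown region '%s' (have: %s)", region,
                       paste(morph_regions(m), collapse = ", ")),
               "cablenet_key_error")
    }
    secs <- Filter(function(s) s$region == region, secs)
  }
  tot <- sum(vapply(secs, function(s) {
    .cn_frustum_area(s$r_prox, s$r_dist, .cn_section_length(s))
  }, 0))
  qty(tot, "um2")
}

#' Reference a point on a morphology
#'
#' @param section section id.
#' @param fraction_along position along the section arc, in `[0, 1]`
#'   (0 = proximal end, 1 = distal end).
#' @export
morph_location <- function(section, fraction_along = 0.5) {
  if (fraction_along < 0 || fraction_along > 1) {
    cn_abort("fraction_along must lie in [0, 1]", "cablenet_domain_error")
  }
  structure(list(section = as.character(section),
                 fraction_along = fraction_along),
            class = "morph_location")
}

#' Map a morphology location to a segment index
#'
#' Each section is discretised into `nseg` equal-arc segments indexed
#' 0..nseg-1.  `fraction_along` falls in the half-open interval
#' `[i/nseg, (i+1)/nseg)`; the boundary value 1.0 folds into the last
#' segment.
#'
#' @param loc a [morph_location()].
#' @param nseg number of segments of that section (>= 1).
#' @return list with `segment` (0-based index) and `local` (position
#'   within the segment, in `[0, 1)`).
#' @export
resolve_location <- function(loc, nseg) {
  if (nseg < 1) cn_abort("nseg must be >= 1", "cablenet_domain_error")
  f <- loc$fraction_along
  i <- min(floor(f * nseg), nseg - 1)
  list(segment = as.integer(i), local = f * nseg - i)
}

# SWC import/export ------------------------------------------------------

.cn_swc_region <- function(type) {
  switch(as.character(type),
         "1" = "soma", "2" = "axon", "3" = "dendrite", "4" = "apicaldendrite",
         paste0("region", type))
}

.cn_region_swc_type <- function(region) {
  known <- c(soma = 1L, axon = 2L, dendrite = 3L, apicaldendrite = 4L)
  if (region %in% names(known)) return(known[[region]])
  m <- regmatches(region, regexec("^region([0-9]+)$", region))[[1]]
  if (length(m) == 2L) return(as.integer(m[2]))
  5L
}

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`), one root sample
#' with parent -1, `#` comments.  Each consecutive sample pair becomes one
#' frustum Section; chains therefore split automatically at branch points.
#' SWC type codes map to regions (1 soma, 2 axon, 3 dendrite,
#' 4 apicaldendrite, other n "region<n>"); a section takes the region of
#' its proximal sample.  A single-sample file yields the equal-area
#' sphere-to-cylinder convention: one cylinder with L = d = 2 r.
#'
#' A morphology has exactly one root section, so when the root sample has
#' several children the extra child sections are re-parented onto the
#' first one (their own geometry is kept); such files do not round trip
#' through [write_swc()] exactly.
#'
#' @param path SWC file path.
#' @param name morphology name (defaults to the file name).
#' @return a `morphology`.
#' @export
read_swc <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.swc$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0L) cn_abort("SWC file contains no samples", "cablenet_swc_error")
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(vapply(fields, length, 0L) != 7L)
  if (length(bad)) {
    cn_abort(sprintf("SWC line %d: expected 7 columns", rows[bad[1]]),
             "cablenet_swc_error")
  }
  tab <- do.call(rbind, lapply(fields, as.numeric))
  if (anyNA(tab)) {
    ln <- rows[which(apply(is.na(tab), 1, any))[1]]
    cn_abort(sprintf("SWC line %d: non-numeric field", ln), "cablenet_swc_error")
  }
  id <- tab[, 1]; type <- tab[, 2]; xyz <- tab[, 3:5, drop = FALSE]
  radius <- tab[, 6]; parent <- tab[, 7]
  if (anyDuplicated(id)) {
    ln <- rows[which(duplicated(id))[1]]
    cn_abort(sprintf("SWC line %d: duplicate sample id", ln), "cablenet_swc_error")
  }
  if (any(radius <= 0)) {
    ln <- rows[which(radius <= 0)[1]]
    cn_abort(sprintf("SWC line %d: non-positive radius", ln), "cablenet_swc_error")
  }
  nroot <- sum(parent == -1)
  if (nroot != 1L) {
    cn_abort(sprintf("SWC file must have exactly one root (parent -1), found %d", nroot),
             "cablenet_swc_error")
  }
  orphan <- which(parent != -1 & !(parent %in% id))
  if (length(orphan)) {
    cn_abort(sprintf("SWC line %d: parent id %g not present",
                     rows[orphan[1]], parent[orphan[1]]), "cablenet_swc_error")
  }
  idx <- match(parent, id)            # NA for root
  if (nrow(tab) == 1L) {
    # degenerate single-sample soma: sphere -> cylinder with L = d = 2r
    r <- radius[1]
    return(morphology(list(
      section(as.character(id[1]), xyz[1, ], xyz[1, ] + c(2 * r, 0, 0),
              r, r, parent = NA, region = .cn_swc_region(type[1]))
    ), name = name))
  }
  # one frustum section per (parent, child) sample pair; section id is the
  # child sample id, parent section is the grandparent pair (or root stub)
  child_rows <- which(parent != -1)
  secs <- vector("list", length(child_rows))
  root_sample <- id[is.na(idx)]
  for (k in seq_along(child_rows)) {
    i <- child_rows[k]
    p <- idx[i]
    parent_sec <- if (parent[p] == -1) NA else as.character(id[p])
    secs[[k]] <- section(
      id = as.character(id[i]),
      proximal = xyz[p, ], distal = xyz[i, ],
      r_prox = radius[p], r_dist = radius[i],
      parent = parent_sec,
      region = .cn_swc_region(type[p]))
  }
  # sections descending from the root sample: the first child pair is the
  # tree root; additional children of the root sample attach to it
  root_children <- which(vapply(secs, function(s) is.na(s$parent), TRUE))
  if (length(root_children) > 1L) {
    first <- secs[[root_children[1]]]$id
    for (k in root_children[-1]) secs[[k]]$parent <- first
  }
  morphology(secs, name = name)
}

#' Write a morphology to an SWC file
#'
#' Emits one sample for the root's proximal endpoint plus one sample per
#' section distal endpoint. Because [read_swc()] labels a section with its
#' proximal sample's type, each junction sample is written with the region
#' of the child section(s) starting there (leaf samples keep their own
#' section's region). `read_swc(write_swc(m))` then preserves topology,
#' regions, coordinates and radii (to the printed precision, 1e-6 um),
#' provided sibling sections at a junction share one region.
#'
#' @param m a `morphology`.
#' @param path output path.
#' @export
write_swc <- function(m, path) {
  secs <- m$sections
  ids <- names(secs)
  sample_of <- setNames(seq_along(ids) + 1L, ids)   # sample 1 is the root stub
  root <- secs[[which(vapply(secs, function(s) is.na(s$parent), TRUE))]]
  # region of the first child section rooted at a section's distal sample
  child_region <- function(id) {
    for (s in secs) if (!is.na(s$parent) && s$parent == id) return(s$region)
    secs[[id]]$region
  }
  fmt <- function(i, type, p3, r, par) {
    sprintf("%d %d %.6f %.6f %.6f %.6f %d", i, type, p3[1], p3[2], p3[3], r, par)
  }
  out <- character(length(secs) + 1L)
  out[1] <- fmt(1L, .cn_region_swc_type(root$region), root$proximal, root$r_prox, -1L)
  for (k in seq_along(secs)) {
    s <- secs[[k]]
    par <- if (is.na(s$parent)) 1L else sample_of[[s$parent]]
    out[k + 1L] <- fmt(sample_of[[s$id]], .cn_region_swc_type(child_region(s$id)),
                       s$distal, s$r_dist, par)
  }
  writeLines(c("# SWC written by cablenet", out), path)
  invisible(path)
}
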