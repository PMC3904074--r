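# Numerical backend ------------------------------------------------------
#
# Spatial discretisation: each Section contributes nseg equal-arc
# sub-frusta ("segments"); segment membrane area is the exact lateral
# area of its arc, so total area is conserved.  Segments are kept in a
# Hines ordering (parent index < child index), which lets the implicit
# step solve the branched tridiagonal system in O(N) per cell.
#
# Time integration: gating variables advance by the Rush-Larsen exact
# exponential update at the start-of-step voltage; voltages advance by
# backward Euler (default) or Crank-Nicolson.  Gap junctions couple cells
# through an inner fixed-point iteration (<= 5 sweeps, tol 1e-9 mV) so
# each cell keeps its O(N) tree solve.  Double-exponential synapses are
# integrated analytically between events as two decaying states.
#
# Internal unit system: mV, ms, nA, nF, uS (consistent: uS*mV = nA,
# nF*mV/ms = nA).

#' Discretise a cell into segments
#'
#' @param cell a `cell`.
#' @param nseg number of segments per section: a single integer applied to
#'   every section, or a named integer vector keyed by section id
#'   (unnamed sections default to 1).
#' @return object of class `discretized_cell` with per-segment geometry,
#'   passive properties, Hines-ordered parent links and resolved channel
#'   instances.
#' @export
discretize <- function(cell, nseg = 1L) {
  m <- cell$morphology
  secs <- m$sections
  sec_ids <- names(secs)
  nseg_of <- function(id) {
    n <- if (length(nseg) == 1L && is.null(names(nseg))) nseg
         else if (id %in% names(nseg)) nseg[[id]] else 1L
    n <- as.integer(n)
    if (n < 1L) cn_abort("nseg must be >= 1", "cablenet_disc_error")
    n
  }
  # topological order of sections (parents first)
  placed <- character()
  remaining <- sec_ids
  order_ids <- character()
  while (length(remaining)) {
    ready <- vapply(remaining, function(id) {
      p <- secs[[id]]$parent
      is.na(p) || p %in% placed
    }, TRUE)
    if (!any(ready)) cn_abort("section graph is not a tree", "cablenet_disc_error")
    order_ids <- c(order_ids, remaining[ready])
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
  ra <- cell$axial_resistivity    # Ohm*cm
  cm <- cell$capacitance          # uF/cm2
  seg_sec <- character(); seg_region <- character()
  area_cm2 <- numeric(); L_um <- numeric(); r_center <- numeric()
  parent <- integer(); sec_first <- integer(); sec_nseg <- integer()
  names(sec_first) <- character()
  last_seg_of <- integer()
  for (id in order_ids) {
    s <- secs[[id]]
    L <- .cn_section_length(s)
    if (L <= 0) {
      cn_abort(sprintf("section '%s' has zero length; cannot discretise", id),
               "cablenet_disc_error")
    }
    n <- nseg_of(id)
    fr <- seq(0, 1, length.out = n + 1L)
    rr <- s$r_prox + (s$r_dist - s$r_prox) * fr
    first <- length(seg_sec) + 1L
    for (i in seq_len(n)) {
      seg_sec <- c(seg_sec, id)
      seg_region <- c(seg_region, s$region)
      a_um2 <- .cn_frustum_area(rr[i], rr[i + 1L], L / n)
      area_cm2 <- c(area_cm2, a_um2 * 1e-8)
      L_um <- c(L_um, L / n)
      r_center <- c(r_center, (rr[i] + rr[i + 1L]) / 2)
      if (i == 1L) {
        p <- if (is.na(s$parent)) 0L else last_seg_of[[s$parent]]
      } else {
        p <- length(seg_sec) - 1L
      }
      parent <- c(parent, p)
    }
    sec_first[[id]] <- first
    sec_nseg <- c(sec_nseg, setNames(n, id))
    last_seg_of[[id]] <- length(seg_sec)
  }
  nN <- length(seg_sec)
  # axial conductance segment -> parent: g = pi r_bar^2 / (Ra * l), with
  # linear radius interpolation; l is the centre-to-centre distance
  g_ax <- numeric(nN)
  for (i in seq_len(nN)) {
    p <- parent[i]
    if (p == 0L) next
    r_bar_cm <- (r_center[i] + r_center[p]) / 2 * 1e-4
    l_cm <- (L_um[i] + L_um[p]) / 2 * 1e-4
    g_ax[i] <- pi * r_bar_cm^2 / (ra * l_cm) * 1e6   # S -> uS
  }
  resolved <- resolve_distribution(cell$applications, m)
  structure(list(
    cell_name = cell$name, n = nN, parent = parent,
    sec_id = seg_sec, region = seg_region,
    area_cm2 = area_cm2, L_um = L_um, r_center_um = r_center,
    cm_nF = cm * area_cm2 * 1e3,
    g_ax_uS = g_ax, sec_first = sec_first, sec_nseg = sec_nseg,
    resolved = resolved,
    initial_voltage = cell$initial_voltage
  ), class = "discretized_cell")
}

#' Segment index of a cell location within a discretised cell
#' @param disc a `discretized_cell`.
#' @param location a [morph_location()] or [loc()].
#' @export
segment_index <- function(disc, location) {
  ml <- if (inherits(location, "cell_location")) location$location else location
  if (!(ml$section %in% names(disc$sec_first))) {
    cn_abort(sprintf("no section '%s' in discretised cell", ml$section),
             "cablenet_reference_error")
  }
  r <- resolve_location(ml, disc$sec_nseg[[ml$section]])
  disc$sec_first[[ml$section]] + r$segment
}

# fast unchecked rate evaluation (vectorised over V)
.cn_rate_fast <- function(p, V) {
  den <- p[3] + exp((V + p[4]) / p[5])
  r <- (p[1] + p[2] * V) / den
  z <- den == 0
  if (any(z)) r[z] <- p[2] * p[5]
  r
}

# compile the channel instances of one discretised cell into flat arrays
.cn_compile_channels <- function(disc) {
  chls <- list()
  for (sid in names(disc$resolved)) {
    for (cname in names(disc$resolved[[sid]])) {
      inst <- disc$resolved[[sid]][[cname]]
      segs <- disc$sec_first[[sid]] + seq_len(disc$sec_nseg[[sid]]) - 1L
      g_dens <- qty_in(inst$params$gbar, "mS/cm2")
      erev <- qty_in(inst$params$erev, "mV")
      if (is.null(chls[[cname]])) {
        chls[[cname]] <- list(name = cname, channel = inst$channel,
                              idx = integer(), g_dens = numeric(),
                              erev = numeric())
      }
      chls[[cname]]$idx <- c(chls[[cname]]$idx, segs)
      chls[[cname]]$g_dens <- c(chls[[cname]]$g_dens, rep(g_dens, length(segs)))
      chls[[cname]]$erev <- c(chls[[cname]]$erev, rep(erev, length(segs)))
    }
  }
  for (cname in names(chls)) {
    ch <- chls[[cname]]
    ord <- order(ch$idx)
    ch$idx <- ch$idx[ord]; ch$g_dens <- ch$g_dens[ord]; ch$erev <- ch$erev[ord]
    ch$g_uS <- ch$g_dens * disc$area_cm2[ch$idx] * 1e3    # mS -> uS
    ch$gates <- if (ch$channel$kind == "alpha_beta_gated") ch$channel$gates else list()
    ch$state <- NULL
    chls[[cname]] <- ch
  }
  chls
}

# O(N) solve of the Hines tree system:
#   d[i] V[i] + a[i] V[parent[i]] = b[i]  (+ symmetric child terms)
.cn_hines_solve <- function(parent, d, a, b) {
  n <- length(d)
  if (n > 1L) {
    for (i in n:2) {
      f <- a[i] / d[i]
      p <- parent[i]
      d[p] <- d[p] - f * a[i]
      b[p] <- b[p] - f * b[i]
    }
  }
  v <- numeric(n)
  v[1] <- b[1] / d[1]
  if (n > 1L) for (i in 2:n) v[i] <- (b[i] - a[i] * v[parent[i]]) / d[i]
  v
}

#' Upward threshold crossings with hysteresis over a sampled signal
#'
#' Emits the sample time of the first sample at or above threshold after
#' the signal was below it (`v[i-1] < threshold <= v[i]`); a signal
#' starting at or above threshold does not fire until it has fallen below
#' and risen again.  This is the detection rule the solver applies to
#' presynaptic trigger locations, exposed for testing and analysis.
#' @param values sampled values.
#' @param times sample times (ms).
#' @param threshold threshold value.
#' @return numeric vector of crossing-step times.
#' @export
threshold_crossings <- function(values, times, threshold) {
  n <- length(values)
  if (n < 2L) return(numeric())
  i <- which(values[-n] < threshold & values[-1] >= threshold) + 1L
  times[i]
}

# Build the runtime network and integrate.  Called by run().
.cn_integrate <- function(sim, method = "be", nseg = 1L) {
  if (!length(sim$cells)) {
    cn_abort("simulation has no cells", "cablenet_validation_error")
  }
  dt <- sim$dt
  K <- as.integer(round(sim$duration / dt))
  times <- (0:K) * dt
  cn <- identical(method, "cn")

  cells <- sim$cells
  cell_names <- names(cells)
  disc <- lapply(cells, function(cl) {
    ns <- if (is.list(nseg)) (if (cl$name %in% names(nseg)) nseg[[cl$name]] else 1L) else nseg
    discretize(cl, ns)
  })
  chls <- lapply(disc, .cn_compile_channels)

  seg_of <- function(l) segment_index(disc[[l$cell]], l)

  # stimuli: precompute current vectors (pA) or clamp window/level
  stims <- lapply(sim$stimuli, function(st) {
    ci <- st$location$cell
    s <- list(stim = st, cell = ci, seg = seg_of(st$location))
    if (st$kind == "current") {
      s$I_nA <- stimulus_current(st, times) / 1e3
      # per-step average of the injected current over (t_k, t_k+dt], so the
      # charge injected per step is exact for the piecewise-linear step and
      # ramp waveforms (window-edge overlap fractions matter at
      # onset/offset); trapezoidal for sine.  Used by both schemes.
      lo <- pmax(times[-length(times)], st$delay)
      hi <- pmin(times[-1L], st$delay + st$duration)
      ov <- pmax(hi - lo, 0)
      p <- st$params
      s$I_avg_nA <- switch(st$protocol,
        step = p$amp * ov / dt,
        ramp = ifelse(ov > 0,
                      (p$amp0 + (p$amp1 - p$amp0) *
                         ((lo + hi) / 2 - st$delay) / max(st$duration, 1e-12)) * ov / dt,
                      0),
        sine = (s$I_nA[-length(s$I_nA)] + s$I_nA[-1L]) / 2 * 1e3) / 1e3
    } else {
      s$g_uS <- st$params$g_series_uS
      s$level <- st$params$level
      s$on <- times >= st$delay & times < st$delay + st$duration
    }
    s
  })

  fold_up <- function(tt) ceiling(tt / dt - 1e-9) * dt
  syns <- lapply(sim$synapses, function(sy) {
    tpl <- sy$template
    s <- list(name = sy$name, tpl = tpl,
              post_cell = sy$post$cell, post_seg = seg_of(sy$post),
              erev = tpl$erev, g_unit_nS = tpl$gbar * tpl$norm,
              kr = exp(-dt / tpl$tau_rise), kd = exp(-dt / tpl$tau_decay),
              sA = 0, sB = 0, queue = numeric(),
              pre_cell = NA_character_, dropped = 0L)
    if (sy$trigger$kind == "times") {
      s$queue <- sort(fold_up(sy$trigger$times + sy$delay))
    } else {
      s$pre_cell <- sy$trigger$location$cell
      s$pre_seg <- seg_of(sy$trigger$location)
      s$threshold <- sy$trigger$threshold
      s$armed <- TRUE
      s$delay <- sy$delay
    }
    s
  })

  gjs <- lapply(sim$gap_junctions, function(gj) {
    list(g_uS = gj$g_nS / 1e3,
         c1 = gj$loc1$cell, s1 = seg_of(gj$loc1),
         c2 = gj$loc2$cell, s2 = seg_of(gj$loc2))
  })

  # initial state: explicit voltage if given, else conductance-weighted
  # reversal (gates at their steady state for -65 mV); gates then settle
  # at the steady state of the initial voltage
  V <- list()
  for (ci in cell_names) {
    d <- disc[[ci]]
    if (!is.null(d$initial_voltage)) {
      V[[ci]] <- rep(d$initial_voltage, d$n)
    } else {
      Gw <- numeric(d$n); Bw <- numeric(d$n)
      for (ch in chls[[ci]]) {
        open <- 1
        for (gt in ch$gates) {
          aa <- .cn_rate_fast(gt$alpha, -65); bb <- .cn_rate_fast(gt$beta, -65)
          open <- open * (aa / (aa + bb))^gt$exponent
        }
        Gw[ch$idx] <- Gw[ch$idx] + ch$g_uS * open
        Bw[ch$idx] <- Bw[ch$idx] + ch$g_uS * open * ch$erev
      }
      V[[ci]] <- ifelse(Gw > 0, Bw / Gw, -65)
    }
    for (cname in names(chls[[ci]])) {
      ch <- chls[[ci]][[cname]]
      if (length(ch$gates)) {
        st <- matrix(0, nrow = length(ch$gates), ncol = length(ch$idx),
                     dimnames = list(names(ch$gates), NULL))
        for (gi in seq_along(ch$gates)) {
          gt <- ch$gates[[gi]]
          vv <- V[[ci]][ch$idx]
          aa <- .cn_rate_fast(gt$alpha, vv); bb <- .cn_rate_fast(gt$beta, vv)
          st[gi, ] <- aa / (aa + bb)
        }
        chls[[ci]][[cname]]$state <- st
      }
    }
  }

  # static axial structure per cell
  ax <- lapply(cell_names, function(ci) {
    d <- disc[[ci]]
    adiag <- d$g_ax_uS
    if (d$n > 1L) for (i in 2:d$n) adiag[d$parent[i]] <- adiag[d$parent[i]] + d$g_ax_uS[i]
    list(adiag = adiag, offd = -d$g_ax_uS, parent = pmax(d$parent, 1L))
  })
  names(ax) <- cell_names

  # recordings: set up buffers and extractors
  recs <- sim$recordings
  nrec <- length(recs)
  buffers <- vector("list", nrec)
  rec_meta <- vector("list", nrec)
  shadow_v <- list()   # per Events recording we sample voltage
  for (ri in seq_len(nrec)) {
    rc <- recs[[ri]]
    meta <- list(what = rc$what, name = rc$name, user_tags = rc$user_tags)
    if (!is.null(rc$location)) {
      meta$cell <- rc$location$cell
      meta$seg <- seg_of(rc$location)
      meta$section <- rc$location$location$section
    }
    if (!is.null(rc$channel)) {
      ch <- chls[[meta$cell]][[rc$channel]]
      if (is.null(ch)) {
        cn_abort(sprintf("channel '%s' resolves to no instance on cell '%s'",
                         rc$channel, meta$cell), "cablenet_reference_error")
      }
      if (!(meta$seg %in% ch$idx)) {
        cn_abort(sprintf("channel '%s' not present on recorded section of cell '%s'",
                         rc$channel, meta$cell), "cablenet_reference_error")
      }
      meta$channel <- rc$channel
      meta$chpos <- match(meta$seg, ch$idx)
    }
    if (!is.null(rc$stimulus)) {
      meta$stim_i <- which(vapply(stims, function(s) s$stim$name, "") == rc$stimulus)
    }
    if (!is.null(rc$synapse)) {
      meta$syn_i <- which(vapply(syns, `[[`, "", "name") == rc$synapse)
    }
    if (!is.null(rc$threshold)) meta$threshold <- rc$threshold
    rec_meta[[ri]] <- meta
    buffers[[ri]] <- numeric(K + 1L)
  }

  open_of <- function(ch, pos) {
    if (!length(ch$gates)) return(1)
    open <- 1
    for (gi in seq_along(ch$gates)) {
      open <- open * ch$state[gi, pos]^ch$gates[[gi]]$exponent
    }
    open
  }

  sample_rec <- function(k) {       # k: boundary index (1-based, time (k-1)*dt)
    tcur <- times[k]
    for (ri in seq_len(nrec)) {
      meta <- rec_meta[[ri]]
      val <- switch(meta$what,
        Voltage = V[[meta$cell]][meta$seg],
        Events = V[[meta$cell]][meta$seg],
        ConductanceDensity = {
          ch <- chls[[meta$cell]][[meta$channel]]
          ch$g_dens[meta$chpos] * open_of(ch, meta$chpos)
        },
        CurrentDensity = {
          ch <- chls[[meta$cell]][[meta$channel]]
          g <- ch$g_dens[meta$chpos] * open_of(ch, meta$chpos)
          g * (V[[meta$cell]][meta$seg] - ch$erev[meta$chpos]) * 1e-3
        },
        Current = {
          if (!is.null(meta$stim_i)) {
            s <- stims[[meta$stim_i]]
            if (s$stim$kind == "current") s$I_nA[k] * 1e3
            else if (s$on[k]) s$g_uS * (s$level - V[[s$cell]][s$seg]) * 1e3 else 0
          } else {
            sy <- syns[[meta$syn_i]]
            g <- sy$g_unit_nS * (sy$sA - sy$sB)
            g * (V[[sy$post_cell]][sy$post_seg] - sy$erev)
          }
        },
        Conductance = {
          sy <- syns[[meta$syn_i]]
          sy$g_unit_nS * (sy$sA - sy$sB)
        })
      buffers[[ri]][k] <<- val
    }
  }
  sample_rec(1L)

  n_syn <- length(syns)
  n_gj <- length(gjs)
  max_gj_iter <- 0L
  dropped_events <- 0L

  # membrane conductance/source terms (uS, uS*mV) from the *current*
  # channel/synapse states, with the clamp window evaluated at boundary k
  gather_GB <- function(kidx) {
    G <- list(); B <- list()
    for (ci in cell_names) {
      nloc <- disc[[ci]]$n
      G[[ci]] <- numeric(nloc); B[[ci]] <- numeric(nloc)
      for (ch in chls[[ci]]) {
        open <- 1
        if (length(ch$gates)) {
          for (gi in seq_along(ch$gates)) {
            open <- open * ch$state[gi, ]^ch$gates[[gi]]$exponent
          }
        }
        g <- ch$g_uS * open
        G[[ci]][ch$idx] <- G[[ci]][ch$idx] + g
        B[[ci]][ch$idx] <- B[[ci]][ch$idx] + g * ch$erev
      }
    }
    for (s in stims) {
      if (s$stim$kind == "voltage" && s$on[kidx]) {
        G[[s$cell]][s$seg] <- G[[s$cell]][s$seg] + s$g_uS
        B[[s$cell]][s$seg] <- B[[s$cell]][s$seg] + s$g_uS * s$level
      }
    }
    if (n_syn) {
      for (sy in syns) {
        g <- sy$g_unit_nS * (sy$sA - sy$sB) / 1e3    # nS -> uS
        G[[sy$post_cell]][sy$post_seg] <- G[[sy$post_cell]][sy$post_seg] + g
        B[[sy$post_cell]][sy$post_seg] <- B[[sy$post_cell]][sy$post_seg] + g * sy$erev
      }
    }
    list(G = G, B = B)
  }

  # previous-step conductance/source terms for Crank-Nicolson
  prevGB <- if (cn) gather_GB(1L) else NULL

  for (k in seq_len(K)) {
    t1 <- times[k + 1L]
    # 1. gate update (Rush-Larsen at start-of-step voltage)
    for (ci in cell_names) {
      for (cname in names(chls[[ci]])) {
        ch <- chls[[ci]][[cname]]
        if (!length(ch$gates)) next
        vv <- V[[ci]][ch$idx]
        for (gi in seq_along(ch$gates)) {
          gt <- ch$gates[[gi]]
          aa <- .cn_rate_fast(gt$alpha, vv)
          bb <- .cn_rate_fast(gt$beta, vv)
          s <- aa + bb
          inf <- aa / s
          ch$state[gi, ] <- inf + (ch$state[gi, ] - inf) * exp(-dt * s)
        }
        chls[[ci]][[cname]] <- ch
      }
    }
    # 2. synapse states: analytic decay, then deliver due events
    if (n_syn) {
      for (si in seq_len(n_syn)) {
        sy <- syns[[si]]
        sy$sA <- sy$sA * sy$kd
        sy$sB <- sy$sB * sy$kr
        while (length(sy$queue) && sy$queue[1] <= t1 + 1e-9) {
          sy$sA <- sy$sA + 1
          sy$sB <- sy$sB + 1
          sy$queue <- sy$queue[-1]
        }
        syns[[si]] <- sy
      }
    }
    # 3. membrane conductance/source terms at end of step
    curGB <- gather_GB(k + 1L)
    G1 <- curGB$G; B1 <- curGB$B
    Iinj <- list()
    for (ci in cell_names) Iinj[[ci]] <- numeric(disc[[ci]]$n)
    for (s in stims) {
      if (s$stim$kind == "current") {
        icur <- s$I_avg_nA[k]
        Iinj[[s$cell]][s$seg] <- Iinj[[s$cell]][s$seg] + icur
      }
    }
    # 4. implicit voltage solve (with gap-junction fixed point)
    Vguess <- V
    n_iter <- if (n_gj) 5L else 1L
    Vnew <- NULL
    for (it in seq_len(n_iter)) {
      Vnew <- list()
      for (ci in cell_names) {
        d <- disc[[ci]]
        axc <- ax[[ci]]
        Gi <- G1[[ci]]; Bi <- B1[[ci]]
        if (n_gj) {
          for (gj in gjs) {
            if (gj$c1 == ci) {
              Gi[gj$s1] <- Gi[gj$s1] + gj$g_uS
              Bi[gj$s1] <- Bi[gj$s1] + gj$g_uS * Vguess[[gj$c2]][gj$s2]
            }
            if (gj$c2 == ci) {
              Gi[gj$s2] <- Gi[gj$s2] + gj$g_uS
              Bi[gj$s2] <- Bi[gj$s2] + gj$g_uS * Vguess[[gj$c1]][gj$s1]
            }
          }
        }
        cmdt <- d$cm_nF / dt
        if (!cn) {
          dd <- cmdt + Gi + axc$adiag
          bb <- cmdt * V[[ci]] + Bi + Iinj[[ci]]
          Vnew[[ci]] <- .cn_hines_solve(axc$parent, dd, axc$offd, bb)
        } else {
          # explicit half: -G0 V0 + B0 - axial(V0) - gj(V0)
          axf <- axc$adiag * V[[ci]]
          if (d$n > 1L) {
            for (i in 2:d$n) {
              p <- d$parent[i]
              axf[i] <- axf[i] - d$g_ax_uS[i] * V[[ci]][p]
              axf[p] <- axf[p] - d$g_ax_uS[i] * V[[ci]][i]
            }
          }
          gjf <- numeric(d$n)
          if (n_gj) {
            for (gj in gjs) {
              if (gj$c1 == ci) {
                gjf[gj$s1] <- gjf[gj$s1] +
                  gj$g_uS * (V[[gj$c2]][gj$s2] - V[[ci]][gj$s1])
              }
              if (gj$c2 == ci) {
                gjf[gj$s2] <- gjf[gj$s2] +
                  gj$g_uS * (V[[gj$c1]][gj$s1] - V[[ci]][gj$s2])
              }
            }
          }
          dd <- cmdt + Gi / 2 + axc$adiag / 2
          bb <- cmdt * V[[ci]] +
            (Bi + prevGB$B[[ci]] - prevGB$G[[ci]] * V[[ci]]) / 2 -
            axf / 2 + gjf / 2 + Iinj[[ci]]
          Vnew[[ci]] <- .cn_hines_solve(axc$parent, dd, axc$offd / 2, bb)
        }
      }
      if (n_gj) {
        dv <- max(vapply(cell_names, function(ci) {
          max(abs(Vnew[[ci]] - Vguess[[ci]]))
        }, 0))
        Vguess <- Vnew
        if (it > max_gj_iter) max_gj_iter <- it
        if (dv < 1e-9) break
      }
    }
    if (any(vapply(Vnew, function(v) any(!is.finite(v)), TRUE))) {
      cn_abort(sprintf("solver produced non-finite voltage at t = %g ms", t1),
               "cablenet_numeric_error")
    }
    Vold <- V
    V <- Vnew
    if (cn) prevGB <- curGB
    # 5. event detection on presynaptic trigger locations
    if (n_syn) {
      for (si in seq_len(n_syn)) {
        sy <- syns[[si]]
        if (is.na(sy$pre_cell)) next
        vpre <- V[[sy$pre_cell]][sy$pre_seg]
        if (sy$armed && vpre >= sy$threshold &&
            Vold[[sy$pre_cell]][sy$pre_seg] < sy$threshold) {
          tdel <- fold_up(t1 + sy$delay)
          if (tdel <= sim$duration + 1e-9) {
            sy$queue <- sort(c(sy$queue, tdel))
          } else {
            sy$dropped <- sy$dropped + 1L
            dropped_events <- dropped_events + 1L
          }
          sy$armed <- FALSE
        } else if (!sy$armed && vpre < sy$threshold) {
          sy$armed <- TRUE
        }
        syns[[si]] <- sy
      }
    }
    # 6. record boundary
    sample_rec(k + 1L)
  }

  # assemble results in recording order
  out <- vector("list", nrec)
  for (ri in seq_len(nrec)) {
    meta <- rec_meta[[ri]]
    tags <- meta$user_tags
    unit <- "mV"
    if (!is.null(meta$cell)) tags <- c(tags, meta$cell, paste0("loc:", meta$section))
    if (meta$what %in% c("CurrentDensity", "ConductanceDensity")) {
      tags <- c(tags, meta$channel)
      unit <- if (meta$what == "CurrentDensity") "mA/cm2" else "mS/cm2"
    }
    if (!is.null(meta$stim_i)) {
      s <- stims[[meta$stim_i]]
      tags <- c(tags, s$stim$name, s$cell, paste0("loc:", s$stim$location$location$section))
      unit <- "pA"
    }
    if (!is.null(meta$syn_i)) {
      sy <- syns[[meta$syn_i]]
      tags <- c(tags, "SYNAPTIC", sy$tpl$name, paste0("POST:", sy$post_cell))
      if (!is.na(sy$pre_cell)) tags <- c(tags, paste0("PRE:", sy$pre_cell))
      unit <- if (meta$what == "Conductance") "nS" else "pA"
    }
    if (meta$what == "Voltage") unit <- "mV"
    if (meta$what == "Events") {
      vtr <- trace(times, buffers[[ri]], "mV",
                   tags = c(meta$user_tags, meta$cell, paste0("loc:", meta$section)),
                   name = meta$name)
      ev <- spike_times(vtr, meta$threshold)
      ev$tags <- unique(c("Event", vtr$tags))
      ev$name <- meta$name
      out[[ri]] <- ev
    } else {
      out[[ri]] <- trace(times, buffers[[ri]], unit,
                         tags = unique(c(meta$what, tags)), name = meta$name)
    }
  }
  structure(list(
    traces = out,
    metadata = list(simulation = sim$name, duration = sim$duration, dt = dt,
                    method = method, steps = K, seed = sim$seed,
                    gj_max_iterations = max_gj_iter,
                    dropped_events = dropped_events)
  ), class = "simulation_results")
}

#' Run a simulation
#'
#' Validates the object graph, discretises every cell, integrates the
#' branched cable equation and returns one Trace (or EventSet) per
#' recording request, in recording order. Deterministic: identical graphs
#' and settings give bit-identical results.
#'
#' @param sim a `simulation`.
#' @param method `"be"` (backward Euler, default) or `"cn"`
#'   (Crank-Nicolson).
#' @param nseg segments per section: integer, or named list per cell of
#'   (integer | named integer vector per section).
#' @return a `simulation_results` object with `$traces` and `$metadata`.
#' @export
run <- function(sim, method = c("be", "cn"), nseg = 1L) {
  method <- match.arg(method)
  if (!inherits(sim, "simulation")) cn_abort("run() needs a simulation", "cablenet_validation_error")
  .cn_integrate(sim, method = method, nseg = nseg)
}

#' @export
print.simulation_results <- function(x, ...) {
  cat(sprintf("<simulation_results: %d recordings, %d steps @ %g ms (%s)>\n",
              length(x$traces), x$metadata$steps, x$metadata$dt, x$metadata$method))
  for (tr in x$traces) print(tr)
  invisible(x)
}

# Results archive ----------------------------------------------------------

#' Save simulation results to a single-file JSON archive
#'
#' Named numeric arrays plus a metadata block (tags, units, provenance);
#' plain text, loadable with [results_load()].
#' @param results a `simulation_results`.
#' @param path output file.
#' @export
results_save <- function(results, path) {
  doc <- list(
    format = "cablenet-results-v1",
    metadata = results$metadata,
    traces = lapply(results$traces, function(tr) {
      if (inherits(tr, "cn_eventset")) {
        list(kind = "events", name = tr$name, tags = as.list(tr$tags),
             times = tr$times)
      } else {
        list(kind = "trace", name = tr$name, tags = as.list(tr$tags),
             unit = tr$unit, times = tr$times, values = tr$values)
      }
    }))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

#' Load simulation results saved by [results_save()]
#' @param path archive path.
#' @export
results_load <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "cablenet-results-v1")) {
    cn_abort("not a cablenet results archive", "cablenet_parse_error")
  }
  traces <- lapply(doc$traces, function(d) {
    if (identical(d$kind, "events")) {
      eventset(unlist(d$times), tags = unlist(d$tags), name = d$name)
    } else {
      trace(unlist(d$times), unlist(d$values), d$unit,
            tags = unlist(d$tags), name = d$name)
    }
  })
  structure(list(traces = traces, metadata = doc$metadata),
            class = "simulation_results")
}
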