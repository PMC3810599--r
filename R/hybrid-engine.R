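# Hybrid stochastic membrane simulation: per-triangle SSA over
# voltage-dependent gating transitions and GHK single-ion passage events,
# with adaptive-step communication to the field solver, plus a
# deterministic gating-ODE mode.
#
# Communication semantics: SSA events are executed while their exact times
# do not exceed the current sync target (last field update + efield_dt).
# The field update then happens at the time of the last executed event in
# the window (so usually slightly earlier than the target, never later),
# or exactly at the target when no event fell inside the window.  Each
# membrane triangle accumulates the signed charge of its GHK ion passages
# between updates; at a sync the accumulated charge divided by the elapsed
# interval plus the Ohmic and leak currents evaluated at the current
# membrane potential form the per-triangle current passed to the solver.

#' Create a membrane simulation
#'
#' Couples a mesh, a membrane surface and passive electrical properties
#' into a simulation object (mutable, environment-based).  Channels and
#' transported ion pools are added with [add_channel()] / [add_ion()];
#' time is advanced with [advance()].
#'
#' @param mesh a [tet_mesh].
#' @param membrane a [membrane_surface] on that mesh.
#' @param props a [compartment_props] (conductivity, leak, leak reversal).
#' @param dt_efield default field timestep (s).
#' @param ordering an `ordering_permutation` or NULL (raw order).
#' @param V0 initial (resting) potential (V).
#' @param seed RNG seed for the simulation's private stream.
#' @return object of class `membrane_sim`.
#' @export
membrane_sim <- function(mesh, membrane, props, dt_efield = 1e-5,
                         ordering = NULL, V0 = -65e-3, seed = 1L) {
  asm <- vertex_coupling_constants(mesh, props)
  asm <- vertex_capacitances(membrane, asm)
  sys <- assemble_system(asm, dt_efield, perm = ordering,
                         membrane = membrane, V0 = V0)
  sim <- new.env(parent = emptyenv())
  sim$mesh <- mesh
  sim$membrane <- membrane
  sim$props <- props
  sim$assembly <- asm
  sim$system <- sys
  sim$ntri <- length(membrane$tri)
  sim$tri_area <- membrane$tri_area
  sim$inner_tet <- membrane$inner_tet
  sim$V0 <- V0
  sim$V_tri <- rep(V0, sim$ntri)
  sim$time <- 0
  sim$channels <- list()
  sim$ions <- list()
  sim$accum_charge <- numeric(sim$ntri)
  sim$seed <- as.integer(seed)
  sim$rng_state <- NULL
  class(sim) <- "membrane_sim"
  sim
}

#' @export
print.membrane_sim <- function(x, ...) {
  cat("membrane_sim:", x$ntri, "membrane triangles,",
      length(x$channels), "channel type(s),",
      length(x$ions), "ion pool(s), t =", format(x$time), "s\n")
  invisible(x)
}

with_sim_rng <- function(sim, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    outer_state <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", outer_state, envir = globalenv()),
            add = TRUE)
  }
  if (is.null(sim$rng_state)) set.seed(sim$seed) else
    assign(".Random.seed", sim$rng_state, envir = globalenv())
  res <- expr
  sim$rng_state <- get(".Random.seed", envir = globalenv())
  res
}

#' Add a channel population to the membrane
#'
#' Channels are distributed over membrane triangles in proportion to area
#' (`density`) or with an explicit per-triangle count, and initialised to
#' the steady-state distribution at the resting potential (or a named
#' state).
#'
#' @param sim a [membrane_sim].
#' @param model a [channel_model].
#' @param density channels per m^2 of membrane (used if `n_per_tri` is
#'   NULL; counts are rounded per triangle).
#' @param n_per_tri explicit per-triangle channel counts.
#' @param init `"steady"` or one of `model$states`.
#' @export
add_channel <- function(sim, model, density = NULL, n_per_tri = NULL,
                        init = "steady") {
  stopifnot(inherits(sim, "membrane_sim"), inherits(model, "channel_model"))
  if (is.null(n_per_tri)) {
    if (is.null(density)) stop("give density or n_per_tri")
    n_per_tri <- round(density * sim$tri_area)
  }
  n_per_tri <- rep_len(n_per_tri, sim$ntri)
  ns <- length(model$states)
  p0 <- if (identical(init, "steady"))
    channel_steady_state(model, sim$V0)
  else {
    if (!init %in% model$states) stop("unknown init state: ", init)
    setNames(as.numeric(model$states == init), model$states)
  }
  counts <- outer(n_per_tri, p0)          # expected counts; integerised
  colnames(counts) <- model$states        # lazily for stochastic runs
  from <- match(vapply(model$transitions, `[[`, "", "from"), model$states)
  to <- match(vapply(model$transitions, `[[`, "", "to"), model$states)
  cond <- lapply(names(model$conducting), function(st) {
    spec <- model$conducting[[st]]
    list(state = match(st, model$states), spec = spec,
         is_ghk = inherits(spec, "ghk_current_spec"))
  })
  sim$channels[[length(sim$channels) + 1L]] <-
    list(model = model, nstates = ns, from = from, to = to,
         counts = counts, n_per_tri = n_per_tri, cond = cond,
         integerised = FALSE)
  invisible(sim)
}

#' Add a transported ion pool
#'
#' Provides the inner-side concentrations sampled by GHK currents and the
#' pool that receives / supplies transported ions.  Concentrations are
#' stored as discrete ion counts per tetrahedron (or pooled over the whole
#' compartment with `well_mixed = TRUE`); the outer side of a surface
#' membrane is the bath, an infinite reservoir at fixed concentration
#' whose net gain is tracked in a ledger.
#'
#' @param sim a [membrane_sim].
#' @param name ion species name (matched by GHK specs).
#' @param inner_conc initial inner concentration (mol/m^3).
#' @param bath_conc bath concentration (mol/m^3).
#' @param well_mixed pool all tetrahedra into one compartment.
#' @export
add_ion <- function(sim, name, inner_conc, bath_conc = 0,
                    well_mixed = FALSE) {
  stopifnot(inherits(sim, "membrane_sim"))
  NA_ <- phys_const$N_A
  vol <- sim$mesh$vol
  counts <- if (well_mixed) round(inner_conc * sum(vol) * NA_)
            else round(inner_conc * vol * NA_)
  sim$ions[[name]] <- list(inner = counts, bath_conc = bath_conc,
                           bath_ledger = 0, well_mixed = well_mixed,
                           vol = if (well_mixed) sum(vol) else vol)
  invisible(sim)
}

# inner concentration (mol/m^3) seen by the given membrane triangles
ion_inner_conc <- function(sim, ion, tris) {
  io <- sim$ions[[ion]]
  if (is.null(io)) stop("no ion pool named '", ion, "'; add_ion() first")
  NA_ <- phys_const$N_A
  if (io$well_mixed) rep(io$inner / (io$vol * NA_), length(tris))
  else {
    tets <- sim$inner_tet[tris]
    io$inner[tets] / (io$vol[tets] * NA_)
  }
}

# ---- per-triangle currents at a sync point --------------------------------

# Outward Ohmic + leak currents at the current membrane potentials; GHK
# contributes through accumulated discrete charge in stochastic mode, or
# through the expected continuous current in deterministic mode.
ohmic_leak_currents <- function(sim, deterministic_ghk = FALSE) {
  p <- sim$props
  I <- p$g_leak * sim$tri_area * (sim$V_tri - p$E_leak)
  for (ch in sim$channels) {
    for (cd in ch$cond) {
      nopen <- ch$counts[, cd$state]
      if (!cd$is_ghk) {
        I <- I + ohmic_current(cd$spec, sim$V_tri, nopen)
      } else if (deterministic_ghk) {
        Si <- ion_inner_conc(sim, cd$spec$ion, seq_len(sim$ntri))
        I <- I + nopen * ghk_single_channel_current(cd$spec, sim$V_tri, Si,
                                                    cd$spec$bath_conc)
      }
    }
  }
  I
}

# refresh per-triangle membrane potentials from vertex potentials
refresh_vtri <- function(sim) {
  sim$V_tri <- as.numeric(sim$system$tri_mean %*% sim$system$V)
  invisible(sim)
}

# ---- stochastic engine ----------------------------------------------------

integerise_counts <- function(sim) {
  for (k in seq_along(sim$channels)) {
    ch <- sim$channels[[k]]
    if (ch$integerised) next
    counts <- matrix(0, sim$ntri, ch$nstates)
    p <- ch$counts / pmax(ch$n_per_tri, 1)
    for (tr in seq_len(sim$ntri)) {
      n <- ch$n_per_tri[tr]
      if (n > 0)
        counts[tr, ] <- as.numeric(stats::rmultinom(1, n, p[tr, ]))
    }
    colnames(counts) <- ch$model$states
    ch$counts <- counts
    ch$integerised <- TRUE
    sim$channels[[k]] <- ch
  }
  invisible(sim)
}

# recompute gating rate tables and all propensities (after a V update)
ssa_refresh_all <- function(st, sim) {
  for (k in seq_along(sim$channels)) {
    ch <- sim$channels[[k]]
    st$rates[[k]] <- transition_rates(ch$model, sim$V_tri)
    st$prop[[k]] <- st$rates[[k]] * ch$counts[, ch$from, drop = FALSE]
  }
  ssa_refresh_ghk(st, sim, tris = seq_len(sim$ntri))
  st$a_tri <- ssa_tri_totals(st, sim)
  invisible(st)
}

ssa_refresh_ghk <- function(st, sim, tris) {
  for (k in seq_along(sim$channels)) {
    ch <- sim$channels[[k]]
    for (gi in seq_along(st$ghk[[k]])) {
      g <- st$ghk[[k]][[gi]]
      cd <- ch$cond[[g$cond_idx]]
      Si <- ion_inner_conc(sim, cd$spec$ion, tris)
      res <- ghk_transport_rate(cd$spec, sim$V_tri[tris], Si,
                                cd$spec$bath_conc, ch$counts[tris, cd$state])
      st$ghk[[k]][[gi]]$rate[tris] <- res$rate
      st$ghk[[k]][[gi]]$dir[tris] <- res$direction
    }
  }
  invisible(st)
}

ssa_tri_totals <- function(st, sim) {
  a <- numeric(sim$ntri)
  for (k in seq_along(sim$channels)) {
    if (ncol(st$prop[[k]])) a <- a + rowSums(st$prop[[k]])
    for (g in st$ghk[[k]]) a <- a + g$rate
  }
  a
}

# build SSA state: propensity matrices per channel + GHK event entries
ssa_state <- function(sim) {
  st <- new.env(parent = emptyenv())
  st$rates <- vector("list", length(sim$channels))
  st$prop <- vector("list", length(sim$channels))
  st$ghk <- lapply(sim$channels, function(ch) {
    out <- list()
    for (ci in seq_along(ch$cond)) {
      if (ch$cond[[ci]]$is_ghk)
        out[[length(out) + 1L]] <- list(cond_idx = ci,
                                        rate = numeric(sim$ntri),
                                        dir = numeric(sim$ntri))
    }
    out
  })
  # static event catalogue: per channel gating transitions then GHK
  tags <- list()
  for (k in seq_along(sim$channels)) {
    nt <- length(sim$channels[[k]]$from)
    if (nt)
      tags <- c(tags, lapply(seq_len(nt),
                             function(j) list(kind = "gate", ch = k,
                                              tr_idx = j)))
    for (gi in seq_along(st$ghk[[k]]))
      tags <- c(tags, list(list(kind = "ghk", ch = k, gi = gi)))
  }
  st$tags <- tags
  ssa_refresh_all(st, sim)
  st
}

# local propensities of one triangle, in st$tags order
ssa_local_props <- function(st, sim, tr) {
  local <- numeric(0)
  for (k in seq_along(sim$channels)) {
    pk <- st$prop[[k]]
    if (ncol(pk)) local <- c(local, pk[tr, ])
    for (gi in seq_along(st$ghk[[k]]))
      local <- c(local, st$ghk[[k]][[gi]]$rate[tr])
  }
  local
}

# execute one SSA event on triangle `tr`
ssa_execute <- function(st, sim, tr) {
  local <- ssa_local_props(st, sim, tr)
  tot <- sum(local)
  if (tot <= 0) return(invisible(FALSE))
  pick <- st$tags[[sample.int(length(local), 1L, prob = local)]]
  ch <- sim$channels[[pick$ch]]
  if (pick$kind == "gate") {
    j <- pick$tr_idx
    ch$counts[tr, ch$from[j]] <- ch$counts[tr, ch$from[j]] - 1
    ch$counts[tr, ch$to[j]] <- ch$counts[tr, ch$to[j]] + 1
    sim$channels[[pick$ch]] <- ch
    # propensities of this triangle depend on the changed counts
    st$prop[[pick$ch]][tr, ] <- st$rates[[pick$ch]][tr, ] *
      ch$counts[tr, ch$from]
    ssa_refresh_ghk(st, sim, tris = tr)
    st$a_tri[tr] <- ssa_tri_total_one(st, sim, tr)
  } else {
    g <- st$ghk[[pick$ch]][[pick$gi]]
    cd <- ch$cond[[g$cond_idx]]
    dir <- g$dir[tr]                      # +1 outward, -1 inward
    sim$accum_charge[tr] <- sim$accum_charge[tr] +
      dir * cd$spec$z * phys_const$e
    if (cd$spec$transport) {
      io <- sim$ions[[cd$spec$ion]]
      if (io$well_mixed) {
        io$inner <- io$inner - dir
        affected <- seq_len(sim$ntri)
      } else {
        tet <- sim$inner_tet[tr]
        io$inner[tet] <- io$inner[tet] - dir
        affected <- sim$tet_tris[[as.character(tet)]]
      }
      io$bath_ledger <- io$bath_ledger + dir
      sim$ions[[cd$spec$ion]] <- io
      ssa_refresh_ghk(st, sim, tris = affected)
      for (tt in affected) st$a_tri[tt] <- ssa_tri_total_one(st, sim, tt)
    } else {
      ssa_refresh_ghk(st, sim, tris = tr)
      st$a_tri[tr] <- ssa_tri_total_one(st, sim, tr)
    }
  }
  invisible(TRUE)
}

ssa_tri_total_one <- function(st, sim, tr) {
  a <- 0
  for (k in seq_along(sim$channels)) {
    if (ncol(st$prop[[k]])) a <- a + sum(st$prop[[k]][tr, ])
    for (g in st$ghk[[k]]) a <- a + g$rate[tr]
  }
  a
}

#' Advance a membrane simulation (stochastic hybrid mode)
#'
#' Runs the Gillespie direct method over all gating and GHK single-ion
#' events, communicating with the field solver per the adaptive scheme
#' described above.  With no channels the trajectory reduces exactly to
#' the passive field solution stepped at `efield_dt`.
#'
#' @param sim a [membrane_sim].
#' @param t_end stop time (s, absolute).
#' @param efield_dt requested communication step (s), > 0.
#' @param probes named list of vertex-id vectors; the capacitance-weighted
#'   mean potential of each set is recorded at every communication.
#' @param record_interval optional thinning: record only syncs at least
#'   this far apart (s).
#' @return a `voltage_traces` object (time + one column per probe);
#'   the sim is advanced in place.
#' @export
advance <- function(sim, t_end, efield_dt, probes = list(),
                    record_interval = 0) {
  stopifnot(inherits(sim, "membrane_sim"))
  if (efield_dt <= 0) stop("efield_dt must be > 0")
  build_tet_tris(sim)
  with_sim_rng(sim, {
    integerise_counts(sim)
    st <- ssa_state(sim)
    rec <- trace_recorder(sim, probes)
    sync_times <- numeric(0)
    last_sync <- sim$time
    while (last_sync < t_end - 1e-15) {
      target <- min(last_sync + efield_dt, t_end)
      t_last_event <- NA_real_
      repeat {
        a0 <- sum(st$a_tri)
        if (a0 <= 0) { sim$time <- target; break }
        t_next <- sim$time + rexp(1L, a0)
        if (t_next > target) { sim$time <- target; break }
        tr <- sample.int(sim$ntri, 1L, prob = st$a_tri)
        sim$time <- t_next
        ssa_execute(st, sim, tr)
        t_last_event <- t_next
      }
      sync_at <- if (is.na(t_last_event)) target else t_last_event
      elapsed <- sync_at - last_sync
      tri_I <- sim$accum_charge / elapsed + ohmic_leak_currents(sim)
      efield_step(sim$system, tri_I, elapsed = elapsed)
      refresh_vtri(sim)
      sim$accum_charge[] <- 0
      ssa_refresh_all(st, sim)
      last_sync <- sync_at
      sim$time <- sync_at
      rec$record(sync_at, record_interval)
      sync_times <- c(sync_times, sync_at)
    }
    out <- rec$traces()
    attr(out, "sync_times") <- sync_times
    out
  })
}

build_tet_tris <- function(sim) {
  if (!is.null(sim$tet_tris)) return(invisible(sim))
  m <- split(seq_len(sim$ntri), sim$inner_tet)
  sim$tet_tris <- m
  invisible(sim)
}

# ---- deterministic engine -------------------------------------------------

# one adaptive RK45 (Cash-Karp) integration of the gating master equations
# for all triangles of one channel over [0, h_total] at fixed rates R
rk45_gating <- function(P, R, from, to, h_total, rtol = 1e-8, atol = 1e-12) {
  deriv <- function(P) {
    D <- matrix(0, nrow(P), ncol(P))
    for (j in seq_along(from)) {
      flux <- R[, j] * P[, from[j]]
      D[, from[j]] <- D[, from[j]] - flux
      D[, to[j]] <- D[, to[j]] + flux
    }
    D
  }
  a <- c(0, 1/5, 3/10, 3/5, 1, 7/8)
  b <- list(c(1/5),
            c(3/40, 9/40),
            c(3/10, -9/10, 6/5),
            c(-11/54, 5/2, -70/27, 35/27),
            c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096))
  c5 <- c(37/378, 0, 250/621, 125/594, 0, 512/1771)
  c4 <- c(2825/27648, 0, 18575/48384, 13525/55296, 277/14336, 1/4)
  t <- 0; h <- h_total
  while (t < h_total * (1 - 1e-12)) {
    h <- min(h, h_total - t)
    k1 <- deriv(P)
    k2 <- deriv(P + h * b[[1]][1] * k1)
    k3 <- deriv(P + h * (b[[2]][1] * k1 + b[[2]][2] * k2))
    k4 <- deriv(P + h * (b[[3]][1] * k1 + b[[3]][2] * k2 + b[[3]][3] * k3))
    k5 <- deriv(P + h * (b[[4]][1] * k1 + b[[4]][2] * k2 + b[[4]][3] * k3 +
                           b[[4]][4] * k4))
    k6 <- deriv(P + h * (b[[5]][1] * k1 + b[[5]][2] * k2 + b[[5]][3] * k3 +
                           b[[5]][4] * k4 + b[[5]][5] * k5))
    P5 <- P + h * (c5[1] * k1 + c5[3] * k3 + c5[4] * k4 + c5[6] * k6)
    P4 <- P + h * (c4[1] * k1 + c4[3] * k3 + c4[4] * k4 + c4[5] * k5 +
                     c4[6] * k6)
    err <- max(abs(P5 - P4) / (atol + rtol * pmax(abs(P5), 1)))
    if (is.finite(err) && err <= 1) {
      t <- t + h
      P <- P5
      h <- h * min(5, max(0.2, 0.9 * err^(-0.2)))
    } else {
      h <- h * max(0.1, 0.9 * err^(-0.25))
      if (h < h_total * 1e-12)
        stop("gating ODE step collapsed; try a smaller efield_dt")
    }
  }
  P
}

#' Advance a membrane simulation in deterministic mode
#'
#' Per triangle, channel-state fractions evolve by the master-equation
#' ODEs (adaptive embedded Runge-Kutta within each communication window,
#' rates held at the window-start potential); currents use expected open
#' counts, and GHK transport updates concentrations once per window from
#' the expected flux.
#'
#' @inheritParams advance
#' @return a `voltage_traces` object; the sim is advanced in place.
#' @export
deterministic_advance <- function(sim, t_end, efield_dt, probes = list(),
                                  record_interval = 0) {
  stopifnot(inherits(sim, "membrane_sim"))
  if (efield_dt <= 0) stop("efield_dt must be > 0")
  rec <- trace_recorder(sim, probes)
  nch <- length(sim$channels)
  while (sim$time < t_end - 1e-15) {
    elapsed <- min(efield_dt, t_end - sim$time)
    if (nch) {
      for (k in seq_len(nch)) {
        ch <- sim$channels[[k]]
        if (!length(ch$from)) next
        R <- transition_rates(ch$model, sim$V_tri)
        ch$counts <- rk45_gating(ch$counts, R, ch$from, ch$to, elapsed)
        sim$channels[[k]] <- ch
      }
      deterministic_ghk_transport(sim, elapsed)
    }
    tri_I <- ohmic_leak_currents(sim, deterministic_ghk = TRUE)
    efield_step(sim$system, tri_I, elapsed = elapsed)
    refresh_vtri(sim)
    sim$time <- sim$time + elapsed
    rec$record(sim$time, record_interval)
  }
  rec$traces()
}

# expected GHK ion movement over one window (explicit per-window update;
# windows are far shorter than concentration time constants)
deterministic_ghk_transport <- function(sim, elapsed) {
  for (ch in sim$channels) {
    for (cd in ch$cond) {
      if (!cd$is_ghk || !cd$spec$transport) next
      io <- sim$ions[[cd$spec$ion]]
      Si <- ion_inner_conc(sim, cd$spec$ion, seq_len(sim$ntri))
      I <- ghk_single_channel_current(cd$spec, sim$V_tri, Si,
                                      cd$spec$bath_conc)
      ions_out <- I * ch$counts[, cd$state] /
        (cd$spec$z * phys_const$e) * elapsed
      if (io$well_mixed) {
        io$inner <- io$inner - sum(ions_out)
      } else {
        mv <- tapply(ions_out, sim$inner_tet, sum)
        idx <- as.integer(names(mv))
        io$inner[idx] <- io$inner[idx] - as.numeric(mv)
      }
      io$bath_ledger <- io$bath_ledger + sum(ions_out)
      sim$ions[[cd$spec$ion]] <- io
    }
  }
  invisible(sim)
}

# ---- trace recording ------------------------------------------------------

trace_recorder <- function(sim, probes) {
  stopifnot(is.list(probes))
  nm <- names(probes)
  if (length(probes) && (is.null(nm) || any(nm == "")))
    stop("probes must be a named list of vertex-id vectors")
  times <- list(); vals <- list(); last <- -Inf
  list(
    record = function(t, min_gap = 0) {
      if (t - last < min_gap) return(invisible(NULL))
      last <<- t
      times[[length(times) + 1L]] <<- t
      vals[[length(vals) + 1L]] <<-
        vapply(probes, function(pr) {
          if (is.list(pr)) probe_potential(sim$system, pr$vertices,
                                           pr$weights %||% "capacitance")
          else probe_potential(sim$system, pr)
        }, 0)
    },
    traces = function() {
      tt <- unlist(times)
      if (!length(probes)) {
        out <- data.frame(time_s = tt %||% numeric(0))
      } else {
        vm <- do.call(rbind, vals)
        out <- data.frame(time_s = tt, vm)
        names(out) <- c("time_s", nm)
      }
      class(out) <- c("voltage_traces", "data.frame")
      out
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.voltage_traces <- function(x, ...) {
  cat("voltage_traces:", nrow(x), "samples,",
      ncol(x) - 1L, "probe(s):", paste(names(x)[-1L], collapse = ", "), "\n")
  if (nrow(x)) {
    cat(sprintf("  t in [%g, %g] s\n", min(x$time_s), max(x$time_s)))
  }
  invisible(x)
}

#' @export
plot.voltage_traces <- function(x, ...) {
  cols <- seq_len(ncol(x) - 1L) + 1L
  graphics::matplot(x$time_s * 1e3, as.matrix(x[, cols, drop = FALSE]) * 1e3,
                    type = "l", lty = 1, xlab = "time (ms)",
                    ylab = "membrane potential (mV)", ...)
  graphics::legend("bottomright", legend = names(x)[cols], lty = 1,
                   col = seq_along(cols), bty = "n")
  invisible(x)
}

#' Write / read voltage traces as CSV
#'
#' Column 1 is `time_s`, remaining columns one per probe (volts).
#'
#' @param traces a `voltage_traces` data frame.
#' @param path file path.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(as.data.frame(traces), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path)
  if (names(df)[1L] != "time_s") stop("trace file must start with time_s")
  class(df) <- c("voltage_traces", "data.frame")
  df
}
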