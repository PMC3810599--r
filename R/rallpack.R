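# Rallpack benchmark suite: analytic passive-cable references, error
# metrics, and the three benchmark runners (uniform passive cable,
# branched passive cable, Hodgkin-Huxley cable).
#
# Passive parameters follow the published Rallpack specification: axial
# resistivity 1.0 Ohm m, membrane resistance 4.0 Ohm m^2, specific
# capacitance 0.01 F/m^2, rest -65 mV, step current 0.1 nA injected at one
# sealed end.

#' Passive cable parameters
#'
#' @param length cable length (m).
#' @param diameter cable diameter (m).
#' @param Ra axial resistivity (Ohm m).
#' @param Rm specific membrane resistance (Ohm m^2).
#' @param Cm specific membrane capacitance (F/m^2).
#' @param E_rest resting / leak reversal potential (V).
#' @param I injected step current (A), applied at x = 0 from t = 0.
#' @return object of class `cable_params`.
#' @export
cable_params <- function(length = 1e-3, diameter = 1e-6, Ra = 1.0, Rm = 4.0,
                         Cm = 0.01, E_rest = -65e-3, I = 0.1e-9) {
  stopifnot(length > 0, diameter > 0, Ra > 0, Rm > 0, Cm > 0)
  structure(list(length = length, diameter = diameter, Ra = Ra, Rm = Rm,
                 Cm = Cm, E_rest = E_rest, I = I),
            class = "cable_params")
}

cable_derived <- function(p) {
  a <- p$diameter / 2
  r_a <- p$Ra / (pi * a^2)             # axial resistance per length (Ohm/m)
  lambda <- sqrt(p$Rm * a / (2 * p$Ra))
  tau <- p$Rm * p$Cm
  list(a = a, r_a = r_a, lambda = lambda, tau = tau,
       R_inf = r_a * lambda)
}

#' Analytic solution of the finite passive cable with step current
#'
#' Separation-of-variables series for a sealed-end cable at rest, with a
#' step current injected at x = 0 from t = 0:
#' \deqn{v(x,t) = v_{ss}(x) - \sum_{n \ge 0} a_n \cos(n\pi x/L)
#'   e^{-t(1+(n\pi\lambda/L)^2)/\tau}}
#' where \eqn{v_{ss}(x) = I r_a \lambda \cosh((L-x)/\lambda)/\sinh(L/\lambda)}
#' and \eqn{a_n = (2-\delta_{n0}) I r_a \lambda^2/(L(1+(n\pi\lambda/L)^2))}.
#' The series is truncated when the remaining amplitude-times-decay tail
#' is below 1e-9 V at the smallest positive requested time.
#'
#' @param params a [cable_params].
#' @param x probe position(s) along the cable (m).
#' @param t_grid times (s); t = 0 returns the resting potential.
#' @return a `voltage_traces` data frame: `time_s` plus one column per
#'   probe position (absolute potential, V).
#' @export
analytic_cable <- function(params, x, t_grid) {
  d <- cable_derived(params)
  L <- params$length
  vss <- params$I * d$R_inf * cosh((L - x) / d$lambda) / sinh(L / d$lambda)
  t_pos <- t_grid[t_grid > 0]
  tmin <- if (length(t_pos)) min(t_pos) else Inf
  amp0 <- params$I * d$r_a * d$lambda^2 / L
  N <- 8L
  repeat {
    kap <- (N * pi * d$lambda / L)^2
    tailbound <- amp0 * exp(-tmin * (1 + kap) / d$tau) / (1 + kap) * N
    if (tailbound < 1e-9 || N > 2^22) break
    N <- N * 2L
  }
  n <- 0:N
  kn <- (n * pi * d$lambda / L)^2
  an <- (2 - (n == 0)) * amp0 / (1 + kn)
  decay <- exp(-outer(t_pos, (1 + kn) / d$tau))   # |t| x (N+1)
  out <- matrix(0, length(t_grid), length(x))
  for (j in seq_along(x)) {
    cosx <- cos(n * pi * x[j] / L)
    v <- numeric(length(t_grid))
    v[t_grid > 0] <- vss[j] - as.numeric(decay %*% (an * cosx))
    out[, j] <- params$E_rest + v
  }
  df <- data.frame(t_grid, out)
  names(df) <- c("time_s", paste0("x", signif(x * 1e6, 6), "um"))
  class(df) <- c("voltage_traces", "data.frame")
  df
}

#' Branched-cable analytic reference (symmetric 3/2-power-law tree)
#'
#' A symmetric binary tree whose daughters follow the 3/2 power law with
#' equal electrotonic length per level maps exactly onto an equivalent
#' cylinder of the root diameter in which each level contributes a
#' physical length equal to the root length.  The root and tip potentials
#' are then the equivalent cylinder's series solution at x = 0 and
#' x = levels * root_length.
#'
#' @param levels number of levels.
#' @param root_length,root_diameter root branch geometry (m).
#' @param t_grid times (s).
#' @param Ra,Rm,Cm,E_rest,I passive parameters as in [cable_params()].
#' @return a `voltage_traces` data frame with columns `time_s`, `root`,
#'   `tip`.
#' @export
branched_cable_reference <- function(levels, root_length = 32e-6,
                                     root_diameter = 16e-6, t_grid,
                                     Ra = 1.0, Rm = 4.0, Cm = 0.01,
                                     E_rest = -65e-3, I = 0.1e-9) {
  eq <- cable_params(length = levels * root_length,
                     diameter = root_diameter,
                     Ra = Ra, Rm = Rm, Cm = Cm, E_rest = E_rest, I = I)
  tr <- analytic_cable(eq, c(0, levels * root_length), t_grid)
  names(tr) <- c("time_s", "root", "tip")
  tr
}

#' Steady-state potentials on the symmetric tree by recursive impedance
#'
#' Composes input impedances from the sealed tips down to the root
#' (daughter pairs in parallel), then propagates the steady-state voltage
#' distally; an independent check of the equivalent-cylinder mapping.
#'
#' @inheritParams branched_cable_reference
#' @return list with `root` and `tip` steady-state potentials (V) and
#'   `Z_root` (input impedance, Ohm).
#' @export
branched_steady_state <- function(levels, root_length = 32e-6,
                                  root_diameter = 16e-6, Ra = 1.0, Rm = 4.0,
                                  Cm = 0.01, E_rest = -65e-3, I = 0.1e-9) {
  seg <- function(level) {
    d <- root_diameter * 2^(-2 * (level - 1) / 3)
    l <- root_length * 2^(-(level - 1) / 3)
    a <- d / 2
    lambda <- sqrt(Rm * a / (2 * Ra))
    R_inf <- Ra / (pi * a^2) * lambda
    list(l = l, lambda = lambda, R_inf = R_inf)
  }
  z_in <- function(level) {
    s <- seg(level)
    ZL <- if (level == levels) Inf else z_in(level + 1) / 2
    x <- s$l / s$lambda
    if (is.infinite(ZL)) s$R_inf / tanh(x)
    else s$R_inf * (ZL * cosh(x) + s$R_inf * sinh(x)) /
      (ZL * sinh(x) + s$R_inf * cosh(x))
  }
  Z_root <- z_in(1)
  # propagate steady-state voltage from root to tip
  v <- I * Z_root
  for (level in seq_len(levels)) {
    s <- seg(level)
    ZL <- if (level == levels) Inf else z_in(level + 1) / 2
    x <- s$l / s$lambda
    v <- if (is.infinite(ZL)) v / cosh(x)
    else v * ZL / (ZL * cosh(x) + s$R_inf * sinh(x))
  }
  list(root = E_rest + I * Z_root, tip = E_rest + v, Z_root = Z_root)
}

#' RMS difference between two traces
#'
#' Trace `b` is resampled onto `a`'s time grid by linear interpolation;
#' the comparison runs over the overlap of the two time windows (an error
#' if the windows are disjoint).
#'
#' @param a,b `voltage_traces` data frames (first probe column is used)
#'   or two-column data frames `(time, value)`.
#' @param col_a,col_b columns holding the values (default 2).
#' @return root-mean-square difference (V).
#' @export
rms_difference <- function(a, b, col_a = 2L, col_b = 2L) {
  ta <- a[[1L]]; va <- a[[col_a]]
  tb <- b[[1L]]; vb <- b[[col_b]]
  if (min(ta) > max(tb) || min(tb) > max(ta))
    stop("trace time ranges are disjoint")
  keep <- ta >= min(tb) & ta <= max(tb)
  vb_on_a <- approx(tb, vb, xout = ta[keep])$y
  sqrt(mean((va[keep] - vb_on_a)^2))
}

#' Mean spike-timing difference between two traces
#'
#' Spikes are local maxima above a threshold (default 0 mV).  Peaks are
#' paired in order; an error reports the counts when they differ.
#'
#' @inheritParams rms_difference
#' @param threshold spike detection threshold (V).
#' @return mean absolute peak-time difference (s).
#' @export
spike_timing_difference <- function(a, b, threshold = 0, col_a = 2L,
                                    col_b = 2L) {
  peaks <- function(t, v) {
    n <- length(v)
    idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n] &
                   v[2:(n - 1)] > threshold) + 1L
    # keep one peak per contiguous run
    if (length(idx) > 1) idx <- idx[c(TRUE, diff(idx) > 1)]
    t[idx]
  }
  pa <- peaks(a[[1L]], a[[col_a]])
  pb <- peaks(b[[1L]], b[[col_b]])
  if (length(pa) == 0 || length(pb) == 0)
    stop("no spikes above threshold in one of the traces")
  if (length(pa) != length(pb))
    stop(sprintf("unequal spike counts: %d vs %d", length(pa), length(pb)))
  mean(abs(pa - pb))
}

# ---- benchmark runners ----------------------------------------------------

# The benchmark cable is sealed: its ends carry no membrane, so the
# simulated membrane is the side wall only (end caps stay passive
# conductor cross-sections), surface-corrected so total capacitance and
# leak conductance match the ideal cylinder exactly.
benchmark_membrane <- function(fx, params) {
  caps <- if (!is.null(fx$cap_lo)) c(fx$cap_lo, fx$cap_hi)
          else c(fx$root_cap, fx$tip_caps)
  side <- setdiff(fx$mesh$boundary_tris, caps)
  mem <- membrane_surface(fx$mesh, side, C_spec = params$Cm,
                          check_connected = FALSE)
  f <- surface_correction_factor(mem, fx$ideal_side_area)
  mem$C_spec <- params$Cm * f
  list(membrane = mem, f = f)
}

passive_sim_from_fixture <- function(fx, params, ordering, seed = 1L) {
  bm <- benchmark_membrane(fx, params)
  props <- compartment_props(sigma = 1 / params$Ra,
                             g_leak = bm$f / params$Rm,
                             E_leak = params$E_rest)
  sim <- membrane_sim(fx$mesh, bm$membrane, props, ordering = ordering,
                      V0 = params$E_rest, seed = seed)
  sim$surface_factor <- bm$f
  sim
}

# area-weighted probe over an end cap (cap vertices carry no capacitance)
cap_probe <- function(mesh, cap_tris, cap_verts) {
  w <- vertex_area_weights(mesh, cap_tris)
  list(vertices = as.integer(names(w)), weights = as.numeric(w))
}

resolve_ordering <- function(mesh, ordering, bfs_starts = 8L, seed = 1L) {
  if (inherits(ordering, "ordering_permutation") || is.null(ordering))
    return(ordering)
  g <- vertex_graph(mesh)
  switch(ordering,
         raw = raw_order(g),
         axis = principal_axis_order(mesh, g),
         bfs = breadth_first_order(g, start_fraction =
                                     min(1, bfs_starts / g$n), seed = seed),
         stop("unknown ordering: ", ordering))
}

#' Run the uniform passive-cable benchmark
#'
#' Generates the 1 mm x 1 um cylinder fixture, corrects membrane
#' parameters for the mesh's surface-area error, injects 0.1 nA
#' area-weighted over the x = 0 end-cap vertices, advances the passive
#' system, and compares the capacitance-weighted end potentials with the
#' analytic finite-cable series.
#'
#' @param ntets approximate mesh size (tetrahedra).
#' @param efield_dt field timestep (s).
#' @param t_end simulated time (s).
#' @param ordering `"axis"`, `"bfs"`, `"raw"`, an `ordering_permutation`,
#'   or NULL.
#' @param params a [cable_params] (defaults = published benchmark values).
#' @return object of class `rallpack_report` with `rms_mV` (named:
#'   `x0um`, `x1000um`), `traces`, `reference`, mesh / ordering
#'   statistics and timings.
#' @export
run_rallpack1 <- function(ntets = 200000L, efield_dt = 1e-5, t_end = 0.25,
                          ordering = "axis", params = cable_params()) {
  t_start <- proc.time()[["elapsed"]]
  fx <- generate_cylinder_mesh(params$length, params$diameter, ntets)
  ordering <- resolve_ordering(fx$mesh, ordering)
  sim <- passive_sim_from_fixture(fx, params, ordering)
  p0 <- cap_probe(fx$mesh, fx$cap_lo, fx$cap_lo_verts)
  pL <- cap_probe(fx$mesh, fx$cap_hi, fx$cap_hi_verts)
  inject_current(sim$system, p0$vertices, params$I, "area_weighted",
                 weights = p0$weights)
  t_mesh <- proc.time()[["elapsed"]] - t_start

  traces <- deterministic_advance(sim, t_end, efield_dt,
                                  probes = list(x0 = p0, xL = pL))
  t_run <- proc.time()[["elapsed"]] - t_start - t_mesh

  ref <- analytic_cable(params, c(0, params$length), traces$time_s)
  rms <- c(x0um = rms_difference(traces, ref, col_a = 2L, col_b = 2L),
           x1000um = rms_difference(traces, ref, col_a = 3L, col_b = 3L))
  structure(list(
    benchmark = "rallpack1",
    rms_mV = rms * 1e3,
    traces = traces, reference = ref,
    ntets = nrow(fx$mesh$tets), nverts = nrow(fx$mesh$vertices),
    surface_error = fx$surface_error,
    ordering = if (is.null(ordering)) "raw" else ordering$method,
    half_bandwidth = sim$system$half_bandwidth,
    efield_dt = efield_dt, t_end = t_end,
    timings = c(setup_s = t_mesh, run_s = t_run)),
    class = "rallpack_report")
}

#' Run the branched passive-cable benchmark
#'
#' Same protocol as [run_rallpack1()] on the symmetric branched tree,
#' compared against the equivalent-cylinder analytic reference at the
#' root (0 um) and the tips (~130 um for 8 levels).
#'
#' @param levels branching levels (default 8).
#' @param ntets approximate mesh size.
#' @inheritParams run_rallpack1
#' @export
run_rallpack2 <- function(levels = 8L, ntets = 60000L, efield_dt = 1e-5,
                          t_end = 0.25, ordering = "bfs",
                          params = cable_params(length = 32e-6,
                                                diameter = 16e-6)) {
  t_start <- proc.time()[["elapsed"]]
  fx <- generate_branched_mesh(levels, params$length, params$diameter,
                               target_ntets = ntets)
  ordering <- resolve_ordering(fx$mesh, ordering)
  sim <- passive_sim_from_fixture(fx, params, ordering)
  proot <- cap_probe(fx$mesh, fx$root_cap, fx$root_cap_verts)
  ptip <- cap_probe(fx$mesh, fx$tip_caps, fx$tip_verts)
  inject_current(sim$system, proot$vertices, params$I, "area_weighted",
                 weights = proot$weights)
  t_mesh <- proc.time()[["elapsed"]] - t_start

  traces <- deterministic_advance(sim, t_end, efield_dt,
                                  probes = list(root = proot, tip = ptip))
  t_run <- proc.time()[["elapsed"]] - t_start - t_mesh

  ref <- branched_cable_reference(levels, params$length, params$diameter,
                                  traces$time_s, Ra = params$Ra,
                                  Rm = params$Rm, Cm = params$Cm,
                                  E_rest = params$E_rest, I = params$I)
  rms <- c(root = rms_difference(traces, ref, col_a = 2L, col_b = 2L),
           tip = rms_difference(traces, ref, col_a = 3L, col_b = 3L))
  structure(list(
    benchmark = "rallpack2",
    rms_mV = rms * 1e3,
    traces = traces, reference = ref,
    levels = levels, path_length = fx$path_length,
    ntets = nrow(fx$mesh$tets), nverts = nrow(fx$mesh$vertices),
    surface_error = fx$surface_error,
    ordering = if (is.null(ordering)) "raw" else ordering$method,
    half_bandwidth = sim$system$half_bandwidth,
    efield_dt = efield_dt, t_end = t_end,
    timings = c(setup_s = t_mesh, run_s = t_run)),
    class = "rallpack_report")
}

#' Run the Hodgkin-Huxley cable benchmark
#'
#' The Rallpack1 cylinder with squid HH sodium and potassium channels
#' (peak conductances 1200 and 360 S/m^2, reversals +50 / -77 mV) plus
#' the passive leak (1/Rm = 0.25 S/m^2, reversal -65 mV); the stimulus is
#' the same 0.1 nA step.  In deterministic mode gating follows
#' the master-equation ODEs; in stochastic mode channels are discrete with
#' the given single-channel conductance.
#'
#' @inheritParams run_rallpack1
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param g_na,g_k peak conductances per area (S/m^2).
#' @param E_na,E_k reversals (V).
#' @param g_single single-channel conductance (S) for stochastic mode.
#' @param seed RNG seed (stochastic mode).
#' @param reference optional path to a 2-column reference trace CSV
#'   (time_s, volts at x = 0); when given, RMS and spike-timing metrics
#'   are computed against it.
#' @export
run_rallpack3 <- function(ntets = 2000L, efield_dt = 5e-6, t_end = 0.05,
                          mode = c("deterministic", "stochastic"),
                          ordering = "axis", params = cable_params(),
                          g_na = 1200, g_k = 360, E_na = 50e-3,
                          E_k = -77e-3, g_single = 20e-12, seed = 1L,
                          reference = NULL) {
  mode <- match.arg(mode)
  t_start <- proc.time()[["elapsed"]]
  fx <- generate_cylinder_mesh(params$length, params$diameter, ntets)
  ordering <- resolve_ordering(fx$mesh, ordering)
  sim <- passive_sim_from_fixture(fx, params, ordering, seed = seed)
  f <- sim$surface_factor
  # channel counts scaled by the same surface correction so total peak
  # conductance matches the ideal cylinder
  add_channel(sim, hh_na_channel(g_single, E_na),
              n_per_tri = round(g_na * f * sim$membrane$tri_area / g_single))
  add_channel(sim, hh_k_channel(g_single, E_k),
              n_per_tri = round(g_k * f * sim$membrane$tri_area / g_single))
  p0 <- cap_probe(fx$mesh, fx$cap_lo, fx$cap_lo_verts)
  pL <- cap_probe(fx$mesh, fx$cap_hi, fx$cap_hi_verts)
  inject_current(sim$system, p0$vertices, params$I, "area_weighted",
                 weights = p0$weights)
  t_mesh <- proc.time()[["elapsed"]] - t_start

  probes <- list(x0 = p0, xL = pL)
  traces <- if (mode == "deterministic")
    deterministic_advance(sim, t_end, efield_dt, probes = probes)
  else advance(sim, t_end, efield_dt, probes = probes)
  t_run <- proc.time()[["elapsed"]] - t_start - t_mesh

  metrics <- NULL
  if (!is.null(reference)) {
    ref <- read_traces(reference)
    metrics <- list(rms_mV = rms_difference(traces, ref) * 1e3,
                    spike_dt_us = tryCatch(
                      spike_timing_difference(traces, ref) * 1e6,
                      error = function(e) NA_real_))
  }
  structure(list(
    benchmark = "rallpack3", mode = mode,
    traces = traces, metrics = metrics,
    ntets = nrow(fx$mesh$tets), nverts = nrow(fx$mesh$vertices),
    surface_error = fx$surface_error,
    ordering = if (is.null(ordering)) "raw" else ordering$method,
    half_bandwidth = sim$system$half_bandwidth,
    efield_dt = efield_dt, t_end = t_end, seed = seed,
    timings = c(setup_s = t_mesh, run_s = t_run)),
    class = "rallpack_report")
}

#' @export
print.rallpack_report <- function(x, ...) {
  cat("rallpack_report:", x$benchmark,
      if (!is.null(x$mode)) paste0("(", x$mode, ")"), "\n")
  cat("  mesh:", x$ntets, "tets,", x$nverts, "vertices, surface error",
      sprintf("%+.2f%%", 100 * x$surface_error), "\n")
  cat("  ordering:", x$ordering, "- half-bandwidth",
      x$half_bandwidth, "\n")
  if (!is.null(x$rms_mV))
    cat("  RMS vs analytic reference (mV):",
        paste(sprintf("%s=%.4g", names(x$rms_mV), x$rms_mV),
              collapse = ", "), "\n")
  if (!is.null(x$metrics))
    cat("  vs reference trace: RMS", sprintf("%.4g mV", x$metrics$rms_mV),
        "spike dt", sprintf("%.3g us", x$metrics$spike_dt_us), "\n")
  cat(sprintf("  timings: setup %.1f s, run %.1f s\n",
              x$timings[["setup_s"]], x$timings[["run_s"]]))
  invisible(x)
}

#' Write a benchmark report as JSON
#'
#' Traces are omitted (write them separately with [write_traces()]);
#' everything else is serialised.
#'
#' @param report a `rallpack_report`.
#' @param path output path.
#' @export
write_rallpack_report <- function(report, path) {
  keep <- report[setdiff(names(report), c("traces", "reference"))]
  keep$class <- NULL
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
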