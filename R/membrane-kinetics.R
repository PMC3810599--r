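# Channel object model and single-channel current formulas.
#
# A channel is a Markov scheme over named states; transitions carry either
# constant rates (1/s) or voltage-dependent rate tables.  Conducting
# states map to a current specification: Ohmic (single-channel
# conductance + reversal) or GHK (single-channel permeability, constant
# field electrodiffusion, optionally with discrete ion transport).

#' Voltage-dependent rate table
#'
#' Rates are tabulated on a strictly increasing voltage grid and linearly
#' interpolated; membrane voltages outside the grid clamp to the end
#' values (with a one-time warning) rather than extrapolating.
#'
#' @param V voltage grid (V), strictly increasing.
#' @param rate rates (1/s), all >= 0.
#' @return object of class `vdep_rate_table`.
#' @export
vdep_rate_table <- function(V, rate) {
  stopifnot(length(V) == length(rate), length(V) >= 2)
  dV <- diff(V)
  if (any(dV <= 0)) stop("voltage grid must be strictly increasing")
  if (any(rate < 0)) stop("rates must be >= 0 over the tabulated range")
  uniform <- diff(range(dV)) < 1e-9 * mean(dV)
  structure(list(V = as.numeric(V), rate = as.numeric(rate),
                 uniform = uniform,
                 step = if (uniform) mean(dV) else NA_real_,
                 warned = new.env(parent = emptyenv())),
            class = "vdep_rate_table")
}

#' Tabulate a closed-form rate function
#'
#' Default grid: -150 to +100 mV at 0.01 mV resolution.
#'
#' @param fn function of voltage (V) returning a rate (1/s).
#' @param V_min,V_max,step grid limits and spacing (V).
#' @return a [vdep_rate_table].
#' @export
make_vdep_table <- function(fn, V_min = -150e-3, V_max = 100e-3,
                            step = 0.01e-3) {
  V <- seq(V_min, V_max, by = step)
  vdep_rate_table(V, fn(V))
}

#' Evaluate a voltage-dependent rate
#'
#' @param table a [vdep_rate_table] (a bare constant is passed through).
#' @param V_m membrane voltage(s) (V).
#' @return rate(s) (1/s).
#' @export
vdep_rate <- function(table, V_m) {
  if (is.numeric(table)) return(rep_len(table, length(V_m)))
  stopifnot(inherits(table, "vdep_rate_table"))
  grid <- table$V
  out_of_range <- V_m < grid[1L] | V_m > grid[length(grid)]
  if (any(out_of_range) && is.null(table$warned$done)) {
    warning("membrane voltage outside the tabulated range [",
            grid[1L], ", ", grid[length(grid)], "] V; clamping to end values")
    table$warned$done <- TRUE
  }
  Vc <- pmin(pmax(V_m, grid[1L]), grid[length(grid)])
  if (isTRUE(table$uniform)) {
    # direct index arithmetic on the uniform grid (hot path)
    pos <- (Vc - grid[1L]) / table$step
    i0 <- pmin(floor(pos), length(grid) - 2)
    frac <- pos - i0
    r <- table$rate
    r[i0 + 1L] * (1 - frac) + r[i0 + 2L] * frac
  } else {
    approx(grid, table$rate, xout = Vc, method = "linear")$y
  }
}

#' Ohmic single-channel current specification
#'
#' @param g single-channel conductance (S), >= 0.
#' @param E_rev reversal potential (V).
#' @export
ohmic_current_spec <- function(g, E_rev) {
  stopifnot(g >= 0)
  structure(list(g = g, E_rev = E_rev), class = "ohmic_current_spec")
}

#' Ohmic current through open channels
#'
#' `n_open * g * (V_m - E_rev)`; positive = outward.  Ohmic currents do
#' not transport ions between compartments.
#'
#' @param spec an [ohmic_current_spec].
#' @param V_m membrane voltage (V).
#' @param n_open number of open channels (may be fractional in
#'   deterministic mode).
#' @return current (A), vectorised over `V_m`/`n_open`.
#' @export
ohmic_current <- function(spec, V_m, n_open) {
  n_open * spec$g * (V_m - spec$E_rev)
}

#' GHK single-channel current specification
#'
#' @param P single-channel permeability (m^3/s), >= 0.
#' @param z ion valence (non-zero integer).
#' @param T temperature (K), > 0.
#' @param ion ion species name (used to locate the transported pool).
#' @param transport move discrete ions between compartments when the
#'   current fires (TRUE) or act as a pure current (FALSE).
#' @param bath_conc outer (bath) concentration (mol/m^3) used for surface
#'   membranes whose outer side is the bath.
#' @export
ghk_current_spec <- function(P, z, T = 293.15, ion = "ion",
                             transport = TRUE, bath_conc = 0) {
  stopifnot(P >= 0, T > 0)
  z <- as.integer(z)
  if (z == 0L) stop("ion valence must be non-zero")
  structure(list(P = P, z = z, T = T, ion = ion, transport = transport,
                 bath_conc = bath_conc),
            class = "ghk_current_spec")
}

#' Goldman-Hodgkin-Katz single-channel current
#'
#' Constant-field electrodiffusion current of one open channel:
#' \deqn{I_s = P_s z_s^2 \frac{V_m F^2}{RT}
#'   \frac{[S]_i - [S]_o \exp(-z_s V_m F/RT)}{1 - \exp(-z_s V_m F/RT)}}
#' with the convention that membrane voltage is inside minus outside and
#' positive current is outward flux of positive charge.  For
#' \eqn{|z_s V_m F/RT| < 10^{-4}} a second-order series expansion removes
#' the 0/0 at the origin while keeping relative error below 1e-9.
#'
#' @param spec a [ghk_current_spec].
#' @param V_m membrane voltage (V), vectorised.
#' @param S_i,S_o inner / outer concentrations (mol/m^3), >= 0.
#' @return current (A).
#' @export
ghk_single_channel_current <- function(spec, V_m, S_i, S_o) {
  if (any(S_i < 0) || any(S_o < 0)) stop("concentrations must be >= 0")
  FF <- phys_const$F; RR <- phys_const$R
  z <- spec$z
  u <- z * V_m * FF / (RR * spec$T)
  pref <- spec$P * z * FF
  small <- abs(u) < 1e-4
  out <- numeric(length(u))
  if (any(small)) {
    us <- u[small]
    out[small] <- pref * ((S_i - S_o) * (1 + us^2 / 12) +
                            us * (S_i + S_o) / 2)
  }
  if (any(!small)) {
    ub <- u[!small]
    em <- exp(-ub)
    out[!small] <- pref * ub * (S_i - S_o * em) / (1 - em)
  }
  out
}

#' GHK transport rate (single-ion events per second)
#'
#' The single-channel current divided by the charge of one ion gives the
#' ion passage rate; multiplied by the open-channel population it is the
#' total event rate, treated as an ordinary SSA propensity.  The sign of
#' the current gives the direction: positive (outward) moves one ion from
#' the inner to the outer compartment per event.
#'
#' @inheritParams ghk_single_channel_current
#' @param n_open open-channel population (>= 0).
#' @return list with `rate` (events/s), `direction` (+1 outward, -1
#'   inward, 0 at reversal) and `charge` (signed charge moved outward per
#'   event, C).
#' @export
ghk_transport_rate <- function(spec, V_m, S_i, S_o, n_open) {
  stopifnot(all(n_open >= 0))
  I <- ghk_single_channel_current(spec, V_m, S_i, S_o)
  e <- phys_const$e
  list(rate = abs(I) / (abs(spec$z) * e) * n_open,
       direction = sign(I),
       charge = sign(I) * spec$z * e)
}

#' Markov channel model
#'
#' @param name channel name.
#' @param states character vector of state names.
#' @param transitions list of lists `list(from=, to=, rate=)`, where
#'   `rate` is a constant (1/s), a [vdep_rate_table], or a function of
#'   voltage (tabulated internally via [make_vdep_table()]).
#' @param conducting named list mapping conducting state names to current
#'   specs ([ohmic_current_spec] or [ghk_current_spec]).
#' @return object of class `channel_model`.
#' @export
channel_model <- function(name, states, transitions, conducting = list()) {
  states <- as.character(states)
  if (anyDuplicated(states)) stop("duplicate state names")
  for (tr in transitions) {
    if (!all(c(tr$from, tr$to) %in% states))
      stop("transition references undeclared state: ", tr$from, "->", tr$to)
  }
  transitions <- lapply(transitions, function(tr) {
    if (is.function(tr$rate)) tr$rate <- make_vdep_table(tr$rate)
    if (inherits(tr$rate, "vdep_rate_table") || (is.numeric(tr$rate) &&
        length(tr$rate) == 1L && tr$rate >= 0)) tr else
      stop("rate must be a nonnegative constant, table or function")
  })
  if (length(conducting) && !all(names(conducting) %in% states))
    stop("conducting map references undeclared states")
  structure(list(name = name, states = states, transitions = transitions,
                 conducting = conducting),
            class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat("channel_model", x$name, ":", length(x$states), "states,",
      length(x$transitions), "transitions,",
      length(x$conducting), "conducting state(s)\n")
  invisible(x)
}

# rate matrix entries for all transitions at the given voltages:
# returns a length(V) x n_transitions matrix (1/s)
transition_rates <- function(model, V_m) {
  r <- vapply(model$transitions, function(tr) vdep_rate(tr$rate, V_m),
              numeric(length(V_m)))
  if (!is.matrix(r)) r <- matrix(r, nrow = length(V_m))
  r
}
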