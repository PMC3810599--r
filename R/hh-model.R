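# Squid-axon Hodgkin-Huxley channel models as Markov schemes.
#
# Rate functions use the modern convention (rest at -65 mV); voltages in
# volts, rates in 1/s.  The x/(1-exp(-x)) singularities are removed with a
# series branch.

xexpm1 <- function(x) {
  # x / (1 - exp(-x)), stable through x = 0
  out <- numeric(length(x))
  small <- abs(x) < 1e-6
  out[small] <- 1 + x[small] / 2 + x[small]^2 / 12
  out[!small] <- x[!small] / (-expm1(-x[!small]))
  out
}

#' Hodgkin-Huxley gating rate functions
#'
#' Classic squid-axon alpha/beta rate functions (rest -65 mV), returned in
#' SI units (1/s) for voltage in volts.
#'
#' @param V membrane voltage (V), vectorised.
#' @return rate (1/s).
#' @name hh_rates
NULL

#' @rdname hh_rates
#' @export
hh_alpha_m <- function(V) {
  v <- V * 1e3
  1e3 * xexpm1((v + 40) / 10)
}

#' @rdname hh_rates
#' @export
hh_beta_m <- function(V) {
  v <- V * 1e3
  1e3 * 4 * exp(-(v + 65) / 18)
}

#' @rdname hh_rates
#' @export
hh_alpha_h <- function(V) {
  v <- V * 1e3
  1e3 * 0.07 * exp(-(v + 65) / 20)
}

#' @rdname hh_rates
#' @export
hh_beta_h <- function(V) {
  v <- V * 1e3
  1e3 / (1 + exp(-(v + 35) / 10))
}

#' @rdname hh_rates
#' @export
hh_alpha_n <- function(V) {
  v <- V * 1e3
  1e3 * 0.1 * xexpm1((v + 55) / 10)
}

#' @rdname hh_rates
#' @export
hh_beta_n <- function(V) {
  v <- V * 1e3
  1e3 * 0.125 * exp(-(v + 65) / 80)
}

#' Hodgkin-Huxley sodium channel (8-state Markov scheme)
#'
#' States `m0h0 ... m3h1`; the three activation steps carry multiplicities
#' 3:2:1 in alpha_m (1:2:3 in beta_m) and every state toggles
#' inactivation with alpha_h/beta_h.  State `m3h1` conducts.
#'
#' @param g_single single-channel conductance (S).
#' @param E_rev sodium reversal potential (V).
#' @return a [channel_model].
#' @export
hh_na_channel <- function(g_single = 20e-12, E_rev = 50e-3) {
  states <- c(outer(paste0("m", 0:3), paste0("h", 0:1), paste0))
  trs <- list()
  for (h in 0:1) {
    for (m in 0:2) {
      mult <- 3 - m
      trs <- c(trs, list(
        list(from = sprintf("m%dh%d", m, h), to = sprintf("m%dh%d", m + 1, h),
             rate = local({ mm <- mult; function(V) mm * hh_alpha_m(V) })),
        list(from = sprintf("m%dh%d", m + 1, h), to = sprintf("m%dh%d", m, h),
             rate = local({ mm <- m + 1; function(V) mm * hh_beta_m(V) }))))
    }
    }
  for (m in 0:3) {
    trs <- c(trs, list(
      list(from = sprintf("m%dh0", m), to = sprintf("m%dh1", m),
           rate = hh_alpha_h),
      list(from = sprintf("m%dh1", m), to = sprintf("m%dh0", m),
           rate = hh_beta_h)))
  }
  channel_model("Na", states, trs,
                conducting = list(m3h1 = ohmic_current_spec(g_single, E_rev)))
}

#' Hodgkin-Huxley potassium channel (5-state Markov scheme)
#'
#' States `n0 ... n4` with activation multiplicities 4:3:2:1; `n4`
#' conducts.
#'
#' @param g_single single-channel conductance (S).
#' @param E_rev potassium reversal potential (V).
#' @return a [channel_model].
#' @export
hh_k_channel <- function(g_single = 20e-12, E_rev = -77e-3) {
  states <- paste0("n", 0:4)
  trs <- list()
  for (n in 0:3) {
    trs <- c(trs, list(
      list(from = paste0("n", n), to = paste0("n", n + 1),
           rate = local({ mm <- 4 - n; function(V) mm * hh_alpha_n(V) })),
      list(from = paste0("n", n + 1), to = paste0("n", n),
           rate = local({ mm <- n + 1; function(V) mm * hh_beta_n(V) }))))
  }
  channel_model("K", states, trs,
                conducting = list(n4 = ohmic_current_spec(g_single, E_rev)))
}

#' Steady-state distribution over channel states at a holding voltage
#'
#' For the HH schemes this is the product-binomial distribution implied by
#' the independent-gate steady states; computed generically as the
#' stationary vector of the transition-rate matrix.
#'
#' @param model a [channel_model].
#' @param V holding voltage (V).
#' @return named probability vector over `model$states`.
#' @export
channel_steady_state <- function(model, V) {
  ns <- length(model$states)
  Q <- matrix(0, ns, ns, dimnames = list(model$states, model$states))
  for (tr in model$transitions) {
    r <- vdep_rate(tr$rate, V)
    Q[tr$from, tr$to] <- Q[tr$from, tr$to] + r
    Q[tr$from, tr$from] <- Q[tr$from, tr$from] - r
  }
  # solve pi Q = 0, sum(pi) = 1
  A <- rbind(t(Q), rep(1, ns))
  b <- c(numeric(ns), 1)
  p <- qr.solve(A, b)
  p[p < 0] <- 0
  p <- p / sum(p)
  names(p) <- model$states
  p
}
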