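test_that("with no events the clock jumps to each communication target", {
  sim <- patch_sim(seed = 2)
  add_channel(sim, two_state_channel(0, 0), n_per_tri = c(10, 0, 0, 0),
              init = "C")
  tr <- advance(sim, 1e-3, 1e-4)
  expect_equal(attr(tr, "sync_times"), seq(1e-4, 1e-3, by = 1e-4),
               tolerance = 1e-12)
  # zero rates: state fractions constant in deterministic mode too
  sim2 <- patch_sim(seed = 2)
  add_channel(sim2, two_state_channel(0, 0), n_per_tri = c(10, 0, 0, 0),
              init = "C")
  deterministic_advance(sim2, 1e-3, 1e-4)
  expect_equal(unname(sim2$channels[[1]]$counts[1, "C"]), 10)
})

test_that("hybrid advance with passive leak only equals the pure field path", {
  fx <- small_cylinder()
  mem <- fx$membrane
  props <- compartment_props(sigma = 1, g_leak = 0.25, E_leak = -65e-3)
  sim <- membrane_sim(fx$mesh, mem, props, V0 = -60e-3, seed = 1)
  inject_current(sim$system, fx$cap_lo_verts, 1e-10, "area_weighted")
  tr <- advance(sim, 2e-4, 1e-5, probes = list(x0 = fx$cap_lo_verts))

  asm <- vertex_capacitances(mem, vertex_coupling_constants(fx$mesh, props))
  sys <- assemble_system(asm, 1e-5, membrane = mem, V0 = -60e-3)
  inject_current(sys, fx$cap_lo_verts, 1e-10, "area_weighted")
  V <- NULL
  for (k in 1:20) {
    Vtri <- membrane_potentials(sys)
    efield_step(sys, props$g_leak * mem$tri_area * (Vtri - props$E_leak))
    V <- c(V, probe_potential(sys, fx$cap_lo_verts))
  }
  expect_equal(tr$x0, V, tolerance = 1e-12)
})

test_that("two-state SSA occupancy converges to alpha/(alpha+beta)", {
  alpha <- 200; beta <- 300
  sim <- patch_sim(seed = 13)
  add_channel(sim, two_state_channel(alpha, beta),
              n_per_tri = c(60, 0, 0, 0), init = "C")
  # time-average occupancy after a burn-in; > 1e5 events in total
  invisible(advance(sim, 0.5, 0.5))
  Ttot <- 10; dt_obs <- 0.025
  acc <- 0; nobs <- Ttot / dt_obs
  for (k in seq_len(nobs)) {
    invisible(advance(sim, sim$time + dt_obs, dt_obs))
    acc <- acc + sim$channels[[1]]$counts[1, "O"]
  }
  phat <- acc / nobs / 60
  p <- alpha / (alpha + beta)
  # occupancy is sampled every dt_obs >> 1/(alpha+beta), so the samples
  # are effectively independent binomial(60, p) draws
  se <- sqrt(p * (1 - p) / (60 * nobs))
  expect_lt(abs(phat - p), 3 * se)
})

test_that("GHK events move whole ions and book z*e of charge", {
  sim <- patch_sim(seed = 3, g_leak = 0.25, E_leak = -65e-3)
  ghk <- ghk_current_spec(P = 1e-21, z = 2, T = 293.15, ion = "Ca",
                          transport = TRUE, bath_conc = 1)
  ch <- channel_model("ca", c("closed", "open"),
                      list(list(from = "closed", to = "open", rate = 50),
                           list(from = "open", to = "closed", rate = 50)),
                      conducting = list(open = ghk))
  add_channel(sim, ch, n_per_tri = c(200, 0, 0, 0), init = "open")
  add_ion(sim, "Ca", inner_conc = 2, bath_conc = 1)
  n0 <- sum(sim$ions$Ca$inner)
  invisible(advance(sim, 2e-3, 1e-4))
  io <- sim$ions$Ca
  moved <- n0 - sum(io$inner)
  expect_gt(abs(moved), 0)                       # events did fire
  expect_equal(moved, io$bath_ledger)            # exact ion conservation
  expect_true(all(io$inner == round(io$inner)))  # whole ions only
})

test_that("seeded simulations reproduce bit-identical trajectories", {
  mk <- function() {
    sim <- patch_sim(seed = 99, g_leak = 0.25, E_leak = -65e-3)
    add_channel(sim, hh_na_channel(2e-12), n_per_tri = c(80, 0, 0, 0))
    add_channel(sim, hh_k_channel(2e-12), n_per_tri = c(30, 0, 0, 0))
    inject_current(sim$system, 1:4, 1e-14, "equal")
    advance(sim, 3e-3, 5e-5, probes = list(v = 1:4))
  }
  a <- mk(); b <- mk()
  expect_identical(attr(a, "sync_times"), attr(b, "sync_times"))
  expect_identical(a$v, b$v)
})

test_that("sim RNG stream is independent of the session RNG", {
  set.seed(123); before <- runif(3)
  sim <- patch_sim(seed = 5)
  add_channel(sim, two_state_channel(), n_per_tri = c(20, 0, 0, 0))
  set.seed(123)
  invisible(advance(sim, 0.01, 1e-3))
  expect_identical(runif(3), before)
})

test_that("deterministic gating follows the closed-form relaxation", {
  alpha <- 200; beta <- 300
  sim <- patch_sim(seed = 1)
  add_channel(sim, two_state_channel(alpha, beta),
              n_per_tri = c(40, 0, 0, 0), init = "C")
  deterministic_advance(sim, 0.004, 1e-4)
  pO <- unname(sim$channels[[1]]$counts[1, "O"]) / 40
  expect_equal(pO, alpha / (alpha + beta) * (1 - exp(-(alpha + beta) *
                                                       0.004)),
               tolerance = 1e-6)
})

test_that("HH patch under current clamp matches an independent ODE oracle", {
  skip_if_not_installed("deSolve")
  area <- patch_sim()$membrane$area
  Iinj <- 3e-12
  g_na <- 1200; g_k <- 360; gl <- 0.25
  # independent gate-variable HH integration (m^3 h, n^4 form)
  rhs <- function(t, y, parms) {
    V <- y[1]; m <- y[2]; h <- y[3]; n <- y[4]
    I_ion <- area * (g_na * m^3 * h * (V - 50e-3) +
                       g_k * n^4 * (V + 77e-3) + gl * (V + 65e-3))
    list(c((Iinj - I_ion) / (1e-2 * area),
           hh_alpha_m(V) * (1 - m) - hh_beta_m(V) * m,
           hh_alpha_h(V) * (1 - h) - hh_beta_h(V) * h,
           hh_alpha_n(V) * (1 - n) - hh_beta_n(V) * n))
  }
  inf <- function(a, b) a(-65e-3) / (a(-65e-3) + b(-65e-3))
  y0 <- c(-65e-3, inf(hh_alpha_m, hh_beta_m), inf(hh_alpha_h, hh_beta_h),
          inf(hh_alpha_n, hh_beta_n))
  times <- seq(0, 0.02, by = 1e-6)
  ref <- deSolve::ode(y0, times, rhs, NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-12)

  # package path: huge per-channel counts so gating is effectively exact
  nNa <- 2e6; nK <- 6e5
  sim <- patch_sim(seed = 1, g_leak = gl, E_leak = -65e-3)
  add_channel(sim, hh_na_channel(g_na * area / nNa, 50e-3),
              n_per_tri = c(nNa, 0, 0, 0))
  add_channel(sim, hh_k_channel(g_k * area / nK, -77e-3),
              n_per_tri = c(nK, 0, 0, 0))
  inject_current(sim$system, 1:4, Iinj, "equal")
  tr <- deterministic_advance(sim, 0.02, 1e-6, probes = list(v = 1:4))
  Vref <- approx(times, ref[, 2], xout = tr$time_s)$y
  expect_lt(max(abs(tr$v - Vref)), 1e-3)
})

test_that("stochastic mean matches deterministic mode within 3 SE", {
  mk <- function(seed) {
    sim <- patch_sim(seed = seed, g_leak = 0.25, E_leak = -65e-3,
                     scale = 2e-6)
    A <- sim$membrane$area
    add_channel(sim, hh_na_channel(1200 * A / 10000, 50e-3),
                n_per_tri = c(10000, 0, 0, 0))
    add_channel(sim, hh_k_channel(360 * A / 3000, -77e-3),
                n_per_tri = c(3000, 0, 0, 0))
    inject_current(sim$system, 1:4, 1e-14, "equal")    # subthreshold
    sim
  }
  simd <- mk(1)
  trd <- deterministic_advance(simd, 2e-3, 2e-6, probes = list(v = 1:4))
  # compare at a handful of decorrelated times (membrane tau ~ ms): the
  # pointwise 3-SE bound is not meant as a simultaneous band over every
  # sample of the trace
  t_cmp <- seq(0.25e-3, 2e-3, by = 0.25e-3)
  vd <- approx(trd$time_s, trd$v, xout = t_cmp, rule = 2)$y
  nrun <- 12
  runs <- vapply(seq_len(nrun), function(s) {
    sim <- mk(s + 20)
    tr <- advance(sim, 2e-3, 2e-6, probes = list(v = 1:4))
    approx(tr$time_s, tr$v, xout = t_cmp, rule = 2)$y
  }, numeric(length(t_cmp)))
  mu <- rowMeans(runs)
  se <- apply(runs, 1, stats::sd) / sqrt(nrun)
  expect_lt(max(abs(mu - vd) / (se + 1e-9)), 3)
})

test_that("trace CSV output round-trips", {
  d <- withr::local_tempdir()
  sim <- patch_sim(seed = 1, g_leak = 0.25, E_leak = -65e-3)
  tr <- deterministic_advance(sim, 1e-3, 1e-4, probes = list(v = 1:4))
  p <- file.path(d, "tr.csv")
  write_traces(tr, p)
  back <- read_traces(p)
  expect_equal(back$time_s, tr$time_s)
  expect_equal(back$v, tr$v)
  expect_equal(names(back)[1], "time_s")
})
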