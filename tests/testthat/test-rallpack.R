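# 1D backward-Euler finite-difference oracle for the passive cable
fd_cable <- function(params, t_out, nx = 800, dtf = 2e-6) {
  d <- tetvolt:::cable_derived(params)
  dx <- params$length / nx
  g_ax <- 1 / (d$r_a * dx)
  cmem <- params$Cm * pi * params$diameter * dx
  gmem <- pi * params$diameter * dx / params$Rm
  cm <- rep(cmem, nx + 1); cm[c(1, nx + 1)] <- cmem / 2
  gm <- rep(gmem, nx + 1); gm[c(1, nx + 1)] <- gmem / 2
  n <- nx + 1
  L <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(rep(-g_ax, n - 1),
                                           c(g_ax, rep(2 * g_ax, n - 2),
                                             g_ax),
                                           rep(-g_ax, n - 1)))
  M <- Matrix::Diagonal(x = cm / dtf + gm) + L
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE)
  V <- rep(params$E_rest, n)
  I <- numeric(n); I[1] <- params$I
  steps <- round(max(t_out) / dtf)
  out0 <- numeric(length(t_out)); outL <- numeric(length(t_out))
  nxt <- 1L
  for (s in seq_len(steps)) {
    V <- as.numeric(Matrix::solve(ch, cm / dtf * V + gm * params$E_rest + I,
                                  system = "A"))
    t <- s * dtf
    while (nxt <= length(t_out) && t_out[nxt] <= t + dtf / 2) {
      out0[nxt] <- V[1]; outL[nxt] <- V[n]; nxt <- nxt + 1L
    }
  }
  list(x0 = out0, xL = outL)
}

test_that("analytic cable series: rest, steady state and FD oracle", {
  p <- cable_params()
  d <- tetvolt:::cable_derived(p)
  # t = 0 is exactly rest everywhere
  tr0 <- analytic_cable(p, c(0, 5e-4, 1e-3), 0)
  expect_true(all(tr0[1, -1] == p$E_rest))
  # t -> infinity: I R_inf coth(L/lambda) above rest at x = 0
  trss <- analytic_cable(p, 0, 100)
  expect_equal(trss[[2]], p$E_rest +
                 p$I * d$R_inf / tanh(p$length / d$lambda),
               tolerance = 1e-12)
  # series vs brute-force finite differences on a fine 1D grid
  t_out <- seq(2e-3, 0.05, by = 2e-3)
  fd <- fd_cable(p, t_out, nx = 800, dtf = 2e-6)
  an <- analytic_cable(p, c(0, p$length), t_out)
  expect_lt(max(abs(fd$x0 - an[[2]])), 1e-5)
  expect_lt(max(abs(fd$xL - an[[3]])), 1e-5)
})

test_that("rms_difference matches hand-computed cases", {
  t <- c(0, 1, 2)
  a <- data.frame(time_s = t, v = c(0, 3, 4))
  z <- data.frame(time_s = t, v = c(0, 0, 0))
  expect_equal(rms_difference(a, a), 0)
  expect_equal(rms_difference(a, z), sqrt(25 / 3))
  off <- data.frame(time_s = t, v = a$v + 2)
  expect_equal(rms_difference(a, off), 2)
  disj <- data.frame(time_s = t + 10, v = c(1, 1, 1))
  expect_error(rms_difference(a, disj), "disjoint")
})

test_that("spike timing pairs peaks in order", {
  t <- seq(0, 0.1, by = 1e-5)
  bump <- function(mu) 0.1 * exp(-((t - mu) / 1e-3)^2) - 0.065
  two <- function(m1, m2) data.frame(time_s = t,
                                     v = pmax(bump(m1), bump(m2)))
  a <- two(0.02, 0.06)
  expect_equal(spike_timing_difference(a, a), 0)
  b <- data.frame(time_s = t + 100e-6, v = a$v)
  expect_equal(spike_timing_difference(a, b), 100e-6, tolerance = 1e-9)
  cshift <- two(0.02 + 10e-6, 0.06 + 30e-6)
  expect_equal(spike_timing_difference(a, cshift), 20e-6, tolerance = 1e-6)
  one <- data.frame(time_s = t, v = bump(0.02))
  expect_error(spike_timing_difference(a, one), "2 vs 1")
})

test_that("recursive-impedance steady state matches a branched FD oracle", {
  levels <- 4
  # build the 1D resistive tree: nodes along each branch, daughters in
  # parallel at junctions, leak to rest everywhere, current at the root
  Ra <- 1.0; Rm <- 4.0; E <- -65e-3; I <- 0.1e-9
  nseg <- 60
  nodes <- 0L
  ii <- jj <- vv <- numeric(0)
  gleak <- numeric(0)
  add_branch <- function(level, attach) {
    d <- 16e-6 * 2^(-2 * (level - 1) / 3)
    l <- 32e-6 * 2^(-(level - 1) / 3)
    dx <- l / nseg
    g_ax <- pi * (d / 2)^2 / (Ra * dx)
    ids <- nodes + seq_len(nseg)
    nodes <<- nodes + nseg
    gl <- pi * d * dx / Rm
    gleak[ids] <<- gl
    prev <- attach
    for (k in seq_along(ids)) {
      if (!is.na(prev)) {
        ii <<- c(ii, prev); jj <<- c(jj, ids[k]); vv <<- c(vv, g_ax)
      } else {
        # root proximal end: half segment to a sealed end, nothing to add
      }
      prev <- ids[k]
    }
    if (level < levels) {
      add_branch(level + 1, prev)
      add_branch(level + 1, prev)
    }
    ids
  }
  gleak <- numeric(0)
  root_ids <- add_branch(1, NA)
  n <- nodes
  G <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(vv, vv),
                            dims = c(n, n))
  Lap <- Matrix::Diagonal(x = as.numeric(Matrix::rowSums(G))) - G
  A <- Lap + Matrix::Diagonal(x = gleak)
  rhs <- gleak * E
  rhs[root_ids[1]] <- rhs[root_ids[1]] + I
  V <- as.numeric(Matrix::solve(A, rhs))
  ref <- branched_steady_state(levels)
  expect_lt(abs(V[root_ids[1]] - ref$root), 1e-5)
  expect_lt(abs(V[n] - ref$tip), 1e-5)
  # and the equivalent-cylinder series agrees at late time
  tr <- branched_cable_reference(levels, t_grid = 10)
  expect_lt(abs(tr$root - ref$root), 1e-9)
  expect_lt(abs(tr$tip - ref$tip), 1e-9)
})

test_that("rallpack1 runner at desk scale is accurate and dt-robust", {
  r1 <- run_rallpack1(ntets = 6000, efield_dt = 1e-5, t_end = 0.03)
  expect_s3_class(r1, "rallpack_report")
  expect_lt(r1$rms_mV[["x0um"]], 0.05)
  expect_lt(r1$rms_mV[["x1000um"]], 0.05)
  # halving the timestep changes the RMS by a bounded amount
  r2 <- run_rallpack1(ntets = 6000, efield_dt = 5e-6, t_end = 0.03)
  expect_lt(abs(r2$rms_mV[["x1000um"]] - r1$rms_mV[["x1000um"]]),
            0.6 * r1$rms_mV[["x1000um"]])
  expect_output(print(r1), "rallpack1")
})

test_that("rallpack reports serialise to JSON without the traces", {
  d <- withr::local_tempdir()
  r <- run_rallpack1(ntets = 2000, efield_dt = 1e-5, t_end = 5e-3)
  p <- file.path(d, "rep.json")
  write_rallpack_report(r, p)
  j <- jsonlite::read_json(p)
  expect_equal(j$benchmark, "rallpack1")
  expect_null(j$traces)
  expect_true(is.numeric(j$rms_mV$x0um) || is.numeric(j$rms_mV[[1]]))
})
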