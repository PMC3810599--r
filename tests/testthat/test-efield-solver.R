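test_that("median-dual coupling constants equal the P1 stiffness oracle", {
  for (fixture in list(unit_tet_mesh(), five_tet_cube(),
                       small_tree()$mesh)) {
    asm <- vertex_coupling_constants(fixture, compartment_props(sigma = 0.7))
    L <- as.matrix(tetvolt:::conductance_laplacian(asm))
    K <- p1_stiffness_oracle(fixture, 0.7)
    expect_lt(max(abs(L - K)) / max(abs(K)), 1e-9)
    # uniform potential -> exactly zero net flux at every vertex
    expect_lt(max(abs(L %*% rep(1, asm$n))), 1e-9 * max(abs(K)))
  }
})

test_that("median-dual flux of a unit gradient through a unit right tet is 1/6", {
  # E = (1,0,0): rho_tet = (1/6) E . (axb + bxc + cxa) with the median
  # normal x = (1,1,1) for the unit right tetrahedron
  a <- c(1, 0, 0); b <- c(0, 1, 0); cc <- c(0, 0, 1)
  x <- tetvolt:::cross3(matrix(a, ncol = 3), matrix(b, ncol = 3)) +
    tetvolt:::cross3(matrix(b, ncol = 3), matrix(cc, ncol = 3)) +
    tetvolt:::cross3(matrix(cc, ncol = 3), matrix(a, ncol = 3))
  expect_equal(as.numeric(x), c(1, 1, 1))
  expect_equal(sum(c(1, 0, 0) * x) / 6, 1 / 6)
  # the assembled operator reproduces it: net flux into p under Phi = x
  m <- unit_tet_mesh()
  asm <- vertex_coupling_constants(m, compartment_props(sigma = 1))
  L <- as.matrix(tetvolt:::conductance_laplacian(asm))
  phi <- m$vertices[, 1]
  expect_equal(-(L %*% phi)[1], 1 / 6, tolerance = 1e-12)
})

test_that("vertex capacitances: single triangle thirds and conservation", {
  m <- unit_tet_mesh()
  mem <- membrane_surface(m, tris = m$boundary_tris[1], C_spec = 2e-2,
                          check_connected = FALSE)
  C <- vertex_capacitances(mem)
  inv <- setdiff(seq_len(4), as.vector(mem$tri_verts))
  expect_equal(sum(C > 0), 3L)
  expect_equal(unique(C[C > 0]), 2e-2 * mem$tri_area / 3)
  expect_equal(C[inv], 0)                # interior / off-membrane vertex
  # closed surface conservation
  fx <- small_cylinder()
  asm <- vertex_capacitances(fx$membrane,
                             vertex_coupling_constants(fx$mesh))
  expect_equal(sum(asm$C), fx$membrane$C_spec * fx$membrane$area,
               tolerance = 1e-10)
})

test_that("two-vertex RC pair reproduces the closed-form recursion", {
  C <- c(2e-12, 3e-12); G <- 5e-9; dt <- 1e-5
  asm <- manual_assembly(C, matrix(c(1, 2), 1), G)
  sys <- assemble_system(asm, dt, solver = "sparse", V0 = c(10e-3, 0))
  M <- rbind(c(C[1] + dt * G, -dt * G), c(-dt * G, C[2] + dt * G))
  V <- c(10e-3, 0)
  for (k in 1:50) {
    efield_step(sys)
    V <- solve(M, C * V)
    expect_equal(sys$V, V, tolerance = 1e-12)
  }
  # over many steps the pair relaxes toward the analytic exponential
  # with O(dt) error: V1 - V2 ~ exp(-t G (1/C1 + 1/C2))
  tau <- 1 / (G * (1 / C[1] + 1 / C[2]))
  t50 <- 50 * dt
  expect_equal(sys$V[1] - sys$V[2], 10e-3 * exp(-t50 / tau),
               tolerance = 2 * dt / tau)
})

test_that("an isolated capacitor charges by I dt / C", {
  C <- 4e-12
  asm <- manual_assembly(C)
  sys <- assemble_system(asm, 1e-5, solver = "sparse", V0 = 0)
  inject_current(sys, 1L, 2e-12, "equal")
  efield_step(sys)
  expect_equal(sys$V, 2e-12 * 1e-5 / C, tolerance = 1e-12)
})

test_that("dt -> 0 makes the system matrix approach diag(C)", {
  C <- c(1e-12, 1e-12); G <- 1e-8
  asm <- manual_assembly(C, matrix(c(1, 2), 1), G)
  sys <- assemble_system(asm, 1e-18, solver = "sparse", V0 = c(1, -1))
  efield_step(sys)
  expect_equal(sys$V, c(1, -1), tolerance = 1e-8)
})

test_that("banded solve equals a dense solve of the same system", {
  fx <- small_cylinder()
  asm <- vertex_capacitances(fx$membrane,
                             vertex_coupling_constants(
                               fx$mesh, compartment_props(sigma = 1)))
  g <- vertex_graph(fx$mesh)
  sys <- assemble_system(asm, 1e-5, principal_axis_order(fx$mesh, g),
                         membrane = fx$membrane, V0 = -65e-3)
  inject_current(sys, fx$cap_lo_verts, 1e-10, "area_weighted")
  efield_step(sys)
  Vdense <- dense_be_step(asm, rep(-65e-3, asm$n), 1e-5, sys$injected)
  expect_lt(max(abs(sys$V - Vdense)) / max(abs(Vdense)), 1e-10)
})

test_that("solutions are invariant under the vertex ordering", {
  fx <- small_cylinder()
  asm <- vertex_capacitances(fx$membrane, vertex_coupling_constants(fx$mesh))
  g <- vertex_graph(fx$mesh)
  run <- function(ord) {
    sys <- assemble_system(asm, 1e-5, ord, membrane = fx$membrane,
                           V0 = -65e-3)
    inject_current(sys, fx$cap_lo_verts, 1e-10, "area_weighted")
    for (k in 1:20) efield_step(sys)
    sys$V
  }
  V1 <- run(principal_axis_order(fx$mesh, g))
  V2 <- run(breadth_first_order(g, start_fraction = 2 / g$n, seed = 1))
  V3 <- run(raw_order(g))
  expect_lt(max(abs(V1 - V2)) / max(abs(V1)), 1e-10)
  expect_lt(max(abs(V1 - V3)) / max(abs(V1)), 1e-10)
})

test_that("solutions are invariant under mesh vertex relabeling", {
  fx <- small_cylinder()
  mesh <- fx$mesh
  set.seed(5)
  relab <- sample(nrow(mesh$vertices))         # new id of each old vertex
  inv <- integer(length(relab)); inv[relab] <- seq_along(relab)
  mesh2 <- tet_mesh(mesh$vertices[inv, ],
                    matrix(relab[mesh$tets], ncol = 4))
  run <- function(m, caps) {
    mem <- membrane_surface(m, C_spec = 1e-2, check_connected = FALSE)
    asm <- vertex_capacitances(mem, vertex_coupling_constants(m))
    sys <- assemble_system(asm, 1e-5, membrane = mem, V0 = -65e-3)
    inject_current(sys, caps, 1e-10, "area_weighted")
    for (k in 1:10) efield_step(sys)
    sys$V
  }
  V1 <- run(mesh, fx$cap_lo_verts)
  V2 <- run(mesh2, relab[fx$cap_lo_verts])
  expect_lt(max(abs(V1 - V2[relab])) / max(abs(V1)), 1e-10)
})

test_that("charge is conserved without injection and with it", {
  fx <- small_cylinder()
  asm <- vertex_capacitances(fx$membrane, vertex_coupling_constants(fx$mesh))
  sys <- assemble_system(asm, 1e-5, membrane = fx$membrane)
  set.seed(1)
  mv <- unique(as.vector(fx$membrane$tri_verts))
  sys$V <- rnorm(asm$n, 0, 1e-2)
  Q0 <- sum(asm$C * sys$V)
  for (k in 1:50) efield_step(sys)
  expect_lt(abs(sum(asm$C * sys$V) - Q0) / abs(Q0 + 1e-30), 1e-9)
  # with injection, d(sum C V) = sum I dt exactly
  inject_current(sys, fx$cap_lo_verts, 1e-10, "equal")
  Q1 <- sum(asm$C * sys$V)
  efield_step(sys)
  expect_equal(sum(asm$C * sys$V) - Q1, 1e-10 * 1e-5, tolerance = 1e-6)
})

test_that("clamps pin potentials exactly and interact with injection", {
  fx <- small_cylinder()
  asm <- vertex_capacitances(fx$membrane, vertex_coupling_constants(fx$mesh))
  sys <- assemble_system(asm, 1e-5, membrane = fx$membrane, V0 = 5e-3)
  set_clamp(sys, seq_len(asm$n), 0)
  efield_step(sys)
  expect_true(all(sys$V == 0))
  # clamp wins over injection, with a warning
  sys2 <- assemble_system(asm, 1e-5, membrane = fx$membrane, V0 = 0)
  set_clamp(sys2, fx$cap_lo_verts, -1e-3)
  expect_warning(inject_current(sys2, fx$cap_lo_verts, 1e-10, "equal"),
                 "clamp wins")
  efield_step(sys2)
  expect_true(all(sys2$V[fx$cap_lo_verts] == -1e-3))
})

test_that("equal current split divides exactly", {
  asm <- manual_assembly(rep(1e-12, 5))
  sys <- assemble_system(asm, 1e-5, solver = "sparse")
  inject_current(sys, 1:5, 0.1e-9, "equal")
  expect_equal(sys$injected, rep(0.02e-9, 5))
})

test_that("discrete maximum principle holds on a star-of-cube fixture", {
  # cube coned to its centre: one interior vertex, well-shaped tets
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1),
             c(0.5, 0.5, 0.5))
  faces <- rbind(c(1, 2, 4), c(1, 4, 3), c(5, 6, 8), c(5, 8, 7),
                 c(1, 2, 6), c(1, 6, 5), c(3, 4, 8), c(3, 8, 7),
                 c(1, 3, 7), c(1, 7, 5), c(2, 4, 8), c(2, 8, 6))
  m <- tet_mesh(v, cbind(faces, 9L))
  asm <- vertex_coupling_constants(m)
  L <- tetvolt:::conductance_laplacian(asm)
  bnd <- 1:8
  Vb <- v[bnd, 1]^2 - v[bnd, 2]                # non-linear boundary data
  Vi <- as.numeric(Matrix::solve(L[9, 9, drop = FALSE],
                                 -L[9, bnd, drop = FALSE] %*% Vb))
  expect_true(Vi >= min(Vb) - 1e-12 && Vi <= max(Vb) + 1e-12)
})
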