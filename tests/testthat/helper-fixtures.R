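# Shared small fixtures, built once per test session.

.fx_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- force(expr)
  .fx_cache[[key]]
}

unit_tet_mesh <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1))
}

# unit cube split into 5 tetrahedra (4 corner tets + 1 central)
five_tet_cube <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  t4 <- rbind(c(1, 2, 3, 5), c(2, 4, 3, 8), c(2, 6, 5, 8),
              c(3, 5, 7, 8), c(2, 3, 5, 8))
  tet_mesh(v, t4)
}

small_cylinder <- function() {
  cached("small_cylinder", generate_cylinder_mesh(20e-6, 2e-6, 800))
}

rod_cylinder <- function() {
  cached("rod_cylinder", generate_cylinder_mesh(400e-6, 2e-6, 8000))
}

small_tree <- function() {
  cached("small_tree", generate_branched_mesh(3, target_ntets = 2500))
}

# micro single-tet membrane patch for kinetics/hybrid tests
patch_sim <- function(seed = 1L, g_leak = 0, E_leak = 0, V0 = -65e-3,
                      scale = 1e-6) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * scale
  mesh <- tet_mesh(v, matrix(1:4, 1))
  mem <- membrane_surface(mesh, C_spec = 1e-2)
  membrane_sim(mesh, mem,
               compartment_props(sigma = 1, g_leak = g_leak,
                                 E_leak = E_leak),
               V0 = V0, seed = seed)
}

two_state_channel <- function(alpha = 200, beta = 300) {
  channel_model("two", c("C", "O"),
                list(list(from = "C", to = "O", rate = alpha),
                     list(from = "O", to = "C", rate = beta)))
}

# classical piecewise-linear Galerkin stiffness matrix, assembled from
# barycentric gradients (independent of the median-dual flux route)
p1_stiffness_oracle <- function(mesh, sigma) {
  n <- nrow(mesh$vertices)
  K <- matrix(0, n, n)
  for (t in seq_len(nrow(mesh$tets))) {
    vid <- mesh$tets[t, ]
    A <- cbind(1, mesh$vertices[vid, ])
    G <- t(solve(A)[2:4, ])              # rows: grad of each basis fn
    K[vid, vid] <- K[vid, vid] + sigma * mesh$vol[t] * (G %*% t(G))
  }
  K
}

# dense backward-Euler reference for a coupling assembly (oracle)
dense_be_step <- function(assembly, V, dt, I_vert) {
  L <- as.matrix(tetvolt:::conductance_laplacian(assembly))
  M <- diag(assembly$C, nrow = assembly$n) + dt * L
  solve(M, assembly$C * V + dt * I_vert)
}

# build a coupling assembly directly (for lumped-circuit tests)
manual_assembly <- function(C, edges = matrix(0, 0, 2), G = numeric(0)) {
  structure(list(edges = edges, G = G, n = length(C), C = C,
                 sigma = 1, n_negative = sum(G < 0)),
            class = "coupling_assembly")
}
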