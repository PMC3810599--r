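# Field solver: median-dual finite-volume coupling constants, vertex
# capacitances, and backward-Euler time stepping on a banded SPD system.
#
# For a tetrahedron with corners p, a, b, c (a, b, c right-handed as seen
# from p), a linear potential has constant gradient g satisfying
# (Phi_a - Phi_p, ...) = A g with A the matrix of rows a-p, b-p, c-p.  The
# median-dual surface separating p from the rest of the tet has
# area-weighted normal x = (axb + bxc + cxa)/3 (the sum over its six
# facet triangles), so the flux out of p's control volume through this tet
# is sigma * g . x / 2.  Gathering coefficients of the neighbour
# potentials yields the edge conductances G_pq; summed over tets these are
# algebraically identical to the P1 finite-element stiffness entries.

#' Compartment properties
#'
#' @param sigma cytoplasmic conductivity (S/m), > 0.
#' @param g_leak membrane leak conductance per area (S/m^2).
#' @param E_leak leak reversal potential (V).
#' @return object of class `compartment_props`.
#' @export
compartment_props <- function(sigma = 1, g_leak = 0, E_leak = 0) {
  stopifnot(sigma > 0, g_leak >= 0)
  structure(list(sigma = sigma, g_leak = g_leak, E_leak = E_leak),
            class = "compartment_props")
}

#' Vertex coupling constants (edge conductances)
#'
#' Assembles, for every mesh edge (p, q), the conductance G_pq (siemens)
#' linking the two vertex control volumes, by accumulating the median-dual
#' flux contributions of every tetrahedron containing the edge.
#'
#' @param mesh a [tet_mesh].
#' @param props a [compartment_props] (only `sigma` is used).
#' @return object of class `coupling_assembly` with `edges` (E x 2, i < j),
#'   `G` (edge conductances, S), `n` (vertex count), `C` (per-vertex
#'   capacitance, F; zero until [vertex_capacitances()] fills it),
#'   `n_negative` (count of negative edge conductances, reported for
#'   meshes with obtuse tets, never altered).
#' @export
vertex_coupling_constants <- function(mesh, props = compartment_props()) {
  v <- mesh$vertices
  t4 <- mesh$tets
  nt <- nrow(t4)
  # right-handed corner orderings for each of the four roles of p
  roles <- list(c(1L, 2L, 3L, 4L), c(2L, 1L, 4L, 3L),
                c(3L, 1L, 2L, 4L), c(4L, 1L, 3L, 2L))
  ii <- jj <- integer(12L * nt)
  xx <- numeric(12L * nt)
  pos <- 0L
  for (role in roles) {
    p <- t4[, role[1L]]
    qa <- t4[, role[2L]]; qb <- t4[, role[3L]]; qc <- t4[, role[4L]]
    a <- v[qa, , drop = FALSE] - v[p, , drop = FALSE]
    b <- v[qb, , drop = FALSE] - v[p, , drop = FALSE]
    cc <- v[qc, , drop = FALSE] - v[p, , drop = FALSE]
    bxc <- cross3(b, cc); cxa <- cross3(cc, a); axb <- cross3(a, b)
    x <- (axb + bxc + cxa) / 3
    det <- rowSums(a * bxc)              # = 6 * tet volume (positive)
    if (any(det <= 0))
      stop("degenerate tetrahedron (singular coordinate matrix): tet ",
           which(det <= 0)[1L])
    s <- props$sigma / (2 * det)
    wa <- s * rowSums(bxc * x)
    wb <- s * rowSums(cxa * x)
    wc <- s * rowSums(axb * x)
    idx <- pos + seq_len(3L * nt)
    ii[idx] <- rep.int(p, 3L)
    jj[idx] <- c(qa, qb, qc)
    xx[idx] <- c(wa, wb, wc)
    pos <- pos + 3L * nt
  }
  n <- nrow(v)
  iu <- pmin(ii, jj); ju <- pmax(ii, jj)
  Gs <- Matrix::sparseMatrix(i = iu, j = ju, x = xx, dims = c(n, n))
  tg <- Matrix::summary(Gs)
  # each unordered edge was accumulated twice (once per endpoint role);
  # exact symmetry means both halves are equal, so halve the total
  edges <- cbind(tg$i, tg$j)
  G <- tg$x / 2
  structure(list(edges = edges, G = G, n = n, C = numeric(n),
                 sigma = props$sigma, n_negative = sum(G < 0)),
            class = "coupling_assembly")
}

#' Vertex capacitances from a membrane surface
#'
#' Each membrane triangle contributes `C_spec * area / 3` to each of its
#' three vertices; vertices not on the membrane have zero capacitance.
#'
#' @param membrane a [membrane_surface].
#' @param assembly optional [coupling_assembly] whose `C` field is filled;
#'   if omitted, a bare per-vertex capacitance vector is returned.
#' @return the updated assembly, or the capacitance vector (F).
#' @export
vertex_capacitances <- function(membrane, assembly = NULL) {
  n <- membrane$n_vertices
  contr <- membrane$C_spec * membrane$tri_area / 3
  C <- numeric(n)
  for (k in 1:3) {
    add <- tapply(contr, membrane$tri_verts[, k], sum)
    idx <- as.integer(names(add))
    C[idx] <- C[idx] + as.numeric(add)
  }
  if (is.null(assembly)) return(C)
  stopifnot(inherits(assembly, "coupling_assembly"), assembly$n == n)
  assembly$C <- assembly$C + C
  assembly
}

#' @export
print.coupling_assembly <- function(x, ...) {
  cat("coupling_assembly:", x$n, "vertices,", nrow(x$edges), "edges,",
      "total C", format(sum(x$C)), "F,",
      x$n_negative, "negative edge conductances\n")
  invisible(x)
}

# Laplacian as a symmetric sparse matrix: L = diag(rowsum G) - G
conductance_laplacian <- function(assembly) {
  e <- assembly$edges
  g <- assembly$G
  n <- assembly$n
  gsum <- numeric(n)
  for (col in 1:2) {
    add <- tapply(g, e[, col], sum)
    idx <- as.integer(names(add))
    gsum[idx] <- gsum[idx] + as.numeric(add)
  }
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2], seq_len(n)),
                       j = c(e[, 2], e[, 1], seq_len(n)),
                       x = c(-g, -g, gsum), dims = c(n, n))
}

#' Assemble the backward-Euler field system
#'
#' Builds the banded matrix `diag(C) + dt * L` under the given vertex
#' ordering and factorises it once (LAPACK banded Cholesky); the factor is
#' reused for every step until `dt` or the conductances change.  A general
#' sparse-Cholesky path is used when clamps are present or the bandwidth
#' under the ordering would exceed `band_cap` stored entries.
#'
#' @param assembly a [coupling_assembly] with capacitances filled in.
#' @param dt timestep (s), > 0.
#' @param perm an `ordering_permutation` (default: raw ordering).
#' @param membrane optional [membrane_surface]; enables per-triangle
#'   current input and membrane-potential readout in [efield_step()].
#' @param V0 initial potential (V), scalar or per-vertex.
#' @param solver `"band"` or `"sparse"`.
#' @param band_cap maximum allowed `(kd+1)*n` band storage entries.
#' @return a mutable object of class `efield_system`.
#' @export
assemble_system <- function(assembly, dt, perm = NULL, membrane = NULL,
                            V0 = 0, solver = c("band", "sparse"),
                            band_cap = 3e8) {
  stopifnot(inherits(assembly, "coupling_assembly"), dt > 0)
  solver <- match.arg(solver)
  n <- assembly$n
  p <- if (is.null(perm)) seq_len(n) else as_perm_vector(perm, n)

  sys <- new.env(parent = emptyenv())
  sys$n <- n
  sys$assembly <- assembly
  sys$perm <- p
  sys$iperm <- integer(n); sys$iperm[p] <- seq_len(n)
  sys$C <- assembly$C
  sys$V <- rep_len(as.numeric(V0), n)
  sys$injected <- numeric(n)
  sys$clamped <- logical(n)
  sys$clamp_val <- numeric(n)
  sys$solver <- solver
  sys$band_cap <- band_cap
  sys$L <- conductance_laplacian(assembly)
  if (!is.null(membrane)) attach_membrane(sys, membrane)
  class(sys) <- "efield_system"
  set_dt(sys, dt)
  sys
}

attach_membrane <- function(sys, membrane) {
  ntri <- length(membrane$tri)
  tv <- membrane$tri_verts
  # scatter: vertex x triangle incidence with weight 1/3 (equal-thirds
  # split, consistent with the equal-area median subdivision of the caps)
  sys$membrane <- membrane
  sys$scatter <- Matrix::sparseMatrix(
    i = as.vector(tv), j = rep(seq_len(ntri), 3L),
    x = rep(1 / 3, 3L * ntri), dims = c(sys$n, ntri))
  sys$tri_mean <- Matrix::t(sys$scatter)   # rows sum to 1
  invisible(sys)
}

# (re)build and factorise the matrix for a new dt
set_dt <- function(sys, dt) {
  sys$dt <- dt
  sys$half_bandwidth <- NA_integer_
  asm <- sys$assembly
  if (sys$solver == "band" && !any(sys$clamped)) {
    e <- asm$edges
    iu <- pmin(sys$perm[e[, 1]], sys$perm[e[, 2]])
    ju <- pmax(sys$perm[e[, 1]], sys$perm[e[, 2]])
    kd <- if (nrow(e)) max(ju - iu) else 0L
    if ((kd + 1) * as.double(sys$n) > sys$band_cap)
      stop("bandwidth ", kd, " exceeds the band storage cap; reorder the ",
           "vertices (breadth_first_order) or use solver = \"sparse\"")
    sys$old_of_new <- order(sys$perm)
    diag_new <- (sys$C + dt * Matrix::diag(sys$L))[sys$old_of_new]
    ab <- matrix(0, kd + 1L, sys$n)
    ab[kd + 1L, ] <- diag_new
    if (nrow(e))
      ab[cbind(kd + 1L + iu - ju, ju)] <- -dt * asm$G
    sys$factor <- .Call("tv_band_factor", ab, as.integer(kd),
                        PACKAGE = "tetvolt")
    sys$half_bandwidth <- kd
    sys$factor_kind <- "band"
  } else {
    M <- Matrix::Diagonal(x = sys$C) + dt * sys$L
    free <- !sys$clamped
    sys$free <- free
    Mff <- M[free, free, drop = FALSE]
    sys$Mfs <- M[free, !free, drop = FALSE]
    sys$factor <- Matrix::Cholesky(Matrix::forceSymmetric(Mff), LDL = FALSE)
    sys$factor_kind <- "sparse"
  }
  invisible(sys)
}

#' Pin vertices to a fixed potential
#'
#' Clamped vertices are eliminated from the solve and their potential held
#' exactly; a clamp overrides any injected current on the same vertex
#' (with a warning).
#'
#' @param system an `efield_system`.
#' @param vertices vertex ids.
#' @param V clamp potential (V), scalar or per-vertex.
#' @export
set_clamp <- function(system, vertices, V) {
  vertices <- as.integer(vertices)
  stopifnot(length(vertices) > 0)
  if (any(system$injected[vertices] != 0))
    warning("clamped vertices also carry injected current; clamp wins")
  system$clamped[vertices] <- TRUE
  system$clamp_val[vertices] <- V
  system$V[vertices] <- system$clamp_val[vertices]
  system$solver_requested <- system$solver
  set_dt(system, system$dt)      # refactorise on the free set
  invisible(system)
}

#' Inject current over a vertex set
#'
#' Divides `total_I` (amps, positive = depolarising, into the cell)
#' across the vertices either equally or in proportion to each vertex's
#' membrane capacitance (equivalently its share of membrane area).
#'
#' @param system an `efield_system`.
#' @param vertices vertex ids.
#' @param total_I total injected current (A).
#' @param split `"equal"` or `"area_weighted"`.
#' @param weights explicit per-vertex weights for the `area_weighted`
#'   split (e.g. from [vertex_area_weights()]); defaults to the vertices'
#'   membrane capacitances.
#' @export
inject_current <- function(system, vertices, total_I,
                           split = c("equal", "area_weighted"),
                           weights = NULL) {
  split <- match.arg(split)
  vertices <- as.integer(vertices)
  stopifnot(length(vertices) > 0)
  if (any(system$clamped[vertices]))
    warning("injection on clamped vertices has no effect; clamp wins")
  w <- switch(split,
              equal = rep(1, length(vertices)),
              area_weighted = {
                cw <- if (is.null(weights)) system$C[vertices] else
                  rep_len(weights, length(vertices))
                if (all(cw == 0))
                  stop("area_weighted split needs membrane capacitance or ",
                       "explicit weights on the target vertices")
                cw
              })
  system$injected[vertices] <- system$injected[vertices] +
    total_I * w / sum(w)
  invisible(system)
}

#' Advance the potential by one backward-Euler step
#'
#' Per-triangle membrane currents (sign convention: positive = outward
#' flux of positive charge) are split in equal thirds onto triangle
#' vertices, combined with injected currents, and the banded system is
#' solved for the new vertex potentials.  If `elapsed` differs from the
#' factorised `dt` the system is re-assembled for the new step, which
#' supports the adaptive communication step of the hybrid engine.
#'
#' @param system an `efield_system`.
#' @param tri_currents per-membrane-triangle outward current (A), or NULL.
#' @param injected extra per-vertex inward current (A), or NULL (persistent
#'   injections set via [inject_current()] always apply).
#' @param elapsed timestep (s); defaults to the assembled `dt`.
#' @return invisibly, the updated potential vector (V).
#' @export
efield_step <- function(system, tri_currents = NULL, injected = NULL,
                        elapsed = NULL) {
  dt <- if (is.null(elapsed)) system$dt else elapsed
  if (dt <= 0) stop("elapsed must be > 0")
  if (dt != system$dt) set_dt(system, dt)
  Ivert <- system$injected
  if (!is.null(injected)) Ivert <- Ivert + injected
  if (!is.null(tri_currents)) {
    if (is.null(system$membrane))
      stop("system was assembled without a membrane; cannot map triangle ",
           "currents")
    if (any(!is.finite(tri_currents))) stop("non-finite triangle currents")
    Ivert <- Ivert - as.numeric(system$scatter %*% tri_currents)
  }
  if (any(!is.finite(Ivert))) stop("non-finite currents")
  rhs <- system$C * system$V + dt * Ivert
  if (system$factor_kind == "band") {
    x <- .Call("tv_band_solve", system$factor,
               as.integer(system$half_bandwidth), rhs[system$old_of_new],
               PACKAGE = "tetvolt")
    system$V <- x[system$perm]
  } else {
    free <- system$free
    b <- rhs[free]
    if (any(!free))
      b <- b - as.numeric(system$Mfs %*% system$clamp_val[!free])
    x <- as.numeric(Matrix::solve(system$factor, b, system = "A"))
    V <- system$V
    V[free] <- x
    V[!free] <- system$clamp_val[!free]
    system$V <- V
  }
  invisible(system$V)
}

#' Membrane potential per membrane triangle
#'
#' The mean of the triangle's three vertex potentials.
#'
#' @param system an `efield_system` assembled with a membrane.
#' @return numeric vector (V), one entry per membrane triangle.
#' @export
membrane_potentials <- function(system) {
  if (is.null(system$membrane)) stop("system has no membrane attached")
  as.numeric(system$tri_mean %*% system$V)
}

#' Capacitance-weighted mean potential over a vertex set
#'
#' @param system an `efield_system`.
#' @param vertices vertex ids.
#' @param weights `"capacitance"` (default), `"equal"`, or a numeric
#'   vector of per-vertex weights.
#' @return scalar potential (V).
#' @export
probe_potential <- function(system, vertices, weights = "capacitance") {
  v <- as.integer(vertices)
  w <- if (is.numeric(weights)) rep_len(weights, length(v))
  else switch(match.arg(weights, c("capacitance", "equal")),
              capacitance = system$C[v],
              equal = rep(1, length(v)))
  if (sum(w) == 0) w <- rep(1, length(v))
  sum(system$V[v] * w) / sum(w)
}

#' Per-vertex area weights of a triangle set
#'
#' Each triangle contributes a third of its area to each of its vertices;
#' useful for area-weighted current injection or probing over an end cap.
#'
#' @param mesh a [tet_mesh].
#' @param tris triangle ids (rows of `mesh$tri`).
#' @return named numeric vector: weight per involved vertex id (m^2).
#' @export
vertex_area_weights <- function(mesh, tris) {
  tv <- mesh$tri[tris, , drop = FALSE]
  contr <- rep(mesh$tri_area[tris] / 3, 3L)
  w <- tapply(contr, as.vector(tv), sum)
  out <- as.numeric(w)
  names(out) <- names(w)
  out
}

#' @export
print.efield_system <- function(x, ...) {
  cat("efield_system:", x$n, "vertices, dt", format(x$dt), "s,",
      if (x$factor_kind == "band")
        paste("banded solver (half-bandwidth", x$half_bandwidth, ")")
      else "sparse Cholesky solver", "\n")
  cat("  clamped:", sum(x$clamped), " injected total:",
      format(sum(x$injected)), "A\n")
  invisible(x)
}
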