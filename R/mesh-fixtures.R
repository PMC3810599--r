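# Structured fixture meshes: cylinder and symmetric branched tree.
#
# Both generators stack "slabs" along a branch axis.  A slab is bounded by
# two triangulated cross-section discs and a strip of wall quads; it is
# tetrahedralised by coning every face to an interior apex point.  Because
# consecutive slabs share the disc triangulation verbatim, interfaces are
# conforming with no diagonal bookkeeping, and the same primitive handles
# the junction plugs of the branched tree, where the lower disc is half of
# the parent's split end-disc.

# ---- vertex registry ------------------------------------------------------

new_registry <- function() {
  env <- new.env(parent = emptyenv())
  env$blocks <- list()
  env$n <- 0L
  env
}

reg_add <- function(reg, coords) {
  coords <- matrix(coords, ncol = 3L)
  reg$blocks[[length(reg$blocks) + 1L]] <- coords
  ids <- reg$n + seq_len(nrow(coords))
  reg$n <- reg$n + nrow(coords)
  ids
}

reg_coords <- function(reg) do.call(rbind, reg$blocks)

# ---- rings ----------------------------------------------------------------

# A ring is a triangulated cross-section disc: $chain is the ordered cycle
# of boundary vertex ids (with coordinates in $pos), $cap the triangle list
# covering the disc.

full_ring <- function(reg, center, e1, e2, radius, m) {
  phi <- -pi / 2 + 2 * pi * (seq_len(m) - 1L) / m
  pos <- rep(center, each = m) +
    radius * (outer(cos(phi), e1) + outer(sin(phi), e2))
  rim <- reg_add(reg, pos)
  ctr <- reg_add(reg, center)
  nxt <- c(rim[-1L], rim[1L])
  list(chain = rim, pos = pos, cap = cbind(ctr, rim, nxt), center = ctr)
}

# Split end disc at a junction: rim as in full_ring (m even, so vertices sit
# at +-90 deg on the split axis e2), a chain of interior points along the
# splitting diameter, and one centroid per half-disc.  The e1 > 0 half
# feeds one daughter, the e1 < 0 half the other.
split_ring <- function(reg, center, e1, e2, radius, m) {
  stopifnot(m %% 2L == 0L, m >= 6L)
  phi <- -pi / 2 + 2 * pi * (seq_len(m) - 1L) / m
  rim_pos <- rep(center, each = m) +
    radius * (outer(cos(phi), e1) + outer(sin(phi), e2))
  rim <- reg_add(reg, rim_pos)
  h <- m %/% 2L
  frac <- 1 - 2 * seq_len(h - 1L) / h            # from +R to -R exclusive
  dia_pos <- rep(center, each = h - 1L) + radius * outer(frac, e2)
  dia <- reg_add(reg, dia_pos)
  cen_off <- 4 / (3 * pi) * radius
  hup <- reg_add(reg, center + cen_off * e1)
  hdn <- reg_add(reg, center - cen_off * e1)
  up_idx <- 1:(h + 1L)
  dn_idx <- c((h + 1L):m, 1L)
  up_chain <- c(rim[up_idx], dia)                # -90 .. +90 then diameter
  up_pos <- rbind(rim_pos[up_idx, , drop = FALSE], dia_pos)
  dn_chain <- c(rim[dn_idx], rev(dia))
  dn_pos <- rbind(rim_pos[dn_idx, , drop = FALSE],
                  dia_pos[rev(seq_len(h - 1L)), , drop = FALSE])
  fan <- function(apex, chain) {
    nxt <- c(chain[-1L], chain[1L])
    cbind(apex, chain, nxt)
  }
  up_cap <- fan(hup, up_chain)
  dn_cap <- fan(hdn, dn_chain)
  list(chain = rim, pos = rim_pos, cap = rbind(up_cap, dn_cap),
       center = NA_integer_,
       half_up = list(chain = up_chain, pos = up_pos, cap = up_cap),
       half_dn = list(chain = dn_chain, pos = dn_pos, cap = dn_cap))
}

# ---- slabs ----------------------------------------------------------------

# Wall triangles between two boundary chains of equal length, assumed in
# rotational correspondence.
wall_tris <- function(bc, tc) {
  bn <- c(bc[-1L], bc[1L])
  tn <- c(tc[-1L], tc[1L])
  rbind(cbind(bc, bn, tc), cbind(bn, tn, tc))
}

# Cone every face of the slab (two caps + wall) to an apex placed at the
# chain centroid; exact for star-shaped slabs, which all generated slabs
# are by construction (verified globally by check_volume_consistency).
add_slab <- function(reg, tets, bottom, top, apex_pos = NULL) {
  if (length(bottom$chain) != length(top$chain))
    stop("slab chains differ in length")
  if (is.null(apex_pos))
    apex_pos <- colMeans(rbind(bottom$pos, top$pos))
  apex <- reg_add(reg, apex_pos)
  faces <- rbind(bottom$cap, top$cap, wall_tris(bottom$chain, top$chain))
  tets[[length(tets) + 1L]] <- cbind(faces, apex)
  tets
}

# Align chain (tc, tc_pos) to the reference chain positions bc_pos by cyclic
# shift and possible reversal so matched vertices point in similar radial
# directions.
align_chain <- function(bc_pos, tc, tc_pos) {
  unitize <- function(p) {
    d <- sweep(p, 2L, colMeans(p))
    d / sqrt(rowSums(d^2))
  }
  ub <- unitize(bc_pos)
  ut <- unitize(tc_pos)
  n <- length(tc)
  best_perm <- NULL; best_s <- -Inf
  for (rev_ in c(FALSE, TRUE)) {
    idx0 <- if (rev_) rev(seq_len(n)) else seq_len(n)
    for (sh in 0:(n - 1L)) {
      perm <- idx0[((seq_len(n) + sh - 1L) %% n) + 1L]
      s <- sum(ub * ut[perm, , drop = FALSE])
      if (s > best_s) { best_s <- s; best_perm <- perm }
    }
  }
  list(chain = tc[best_perm], pos = tc_pos[best_perm, , drop = FALSE])
}

# ---- cylinder -------------------------------------------------------------

#' Generate a structured cylinder mesh
#'
#' Builds a polygonal-prism approximation of a cylinder as a stack of
#' disc slabs, each tetrahedralised by coning to an interior point.  The
#' polygon order m grows with the tet budget so that rim chord length and
#' slab thickness stay comparable.  With `match_volume` the cross-section
#' is scaled so the total mesh volume equals the ideal cylinder volume
#' exactly; the polygon-vs-circle perimeter deficit then leaves a
#' percent-scale surface-area error, which is reported so membrane
#' parameters can be corrected with [surface_correction_factor()].
#'
#' @param length cylinder length (m).
#' @param diameter cylinder diameter (m).
#' @param target_ntets approximate number of tetrahedra (>= 24).
#' @param match_volume scale the cross-section so mesh volume equals
#'   \eqn{\pi r^2 L} (default TRUE).
#' @return an object of class `cylinder_fixture`: a list with `mesh`,
#'   `membrane` (the whole boundary, specific capacitance 0.01 F/m^2 until
#'   reset by the caller), `surface_error` (relative, vs \eqn{\pi d L}),
#'   `cap_lo`/`cap_hi` (boundary triangle ids of the end discs),
#'   `cap_lo_verts`/`cap_hi_verts`, `m` (polygon order), `n_slices`.
#' @export
generate_cylinder_mesh <- function(length, diameter, target_ntets = 5000L,
                                   match_volume = TRUE) {
  stopifnot(length > 0, diameter > 0)
  if (target_ntets < 24) stop("target_ntets too small to form a prism stack")
  r <- diameter / 2
  # chord ~ slab thickness balance: 4 L m^2 / (pi d) = target
  m <- round(sqrt(target_ntets * pi * diameter / (4 * length)))
  m <- max(6L, min(96L, as.integer(m)))
  k <- max(1L, as.integer(round(target_ntets / (4 * m))))
  R <- if (match_volume) r * sqrt(2 * pi / (m * sin(2 * pi / m))) else r

  reg <- new_registry()
  tets <- list()
  ax <- c(0, 0, 1); e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  z <- seq(0, length, length.out = k + 1L)
  rings <- vector("list", k + 1L)
  for (j in seq_len(k + 1L))
    rings[[j]] <- full_ring(reg, z[j] * ax, e1, e2, R, m)
  for (j in seq_len(k))
    tets <- add_slab(reg, tets, rings[[j]], rings[[j + 1L]],
                     apex_pos = c(0, 0, (z[j] + z[j + 1L]) / 2))

  mesh <- tet_mesh(reg_coords(reg), do.call(rbind, tets))
  check_volume_consistency(mesh)
  membrane <- membrane_surface(mesh, C_spec = 1e-2, check_connected = FALSE)
  ideal_side <- pi * diameter * length
  surface_error <- (membrane$area - ideal_side) / ideal_side

  lo_verts <- c(rings[[1L]]$chain, rings[[1L]]$center)
  hi_verts <- c(rings[[k + 1L]]$chain, rings[[k + 1L]]$center)
  structure(list(
    mesh = mesh, membrane = membrane, surface_error = surface_error,
    cap_lo = boundary_tris_within(mesh, lo_verts),
    cap_hi = boundary_tris_within(mesh, hi_verts),
    cap_lo_verts = lo_verts, cap_hi_verts = hi_verts,
    m = m, n_slices = k, length = length, diameter = diameter,
    ideal_volume = pi * r^2 * length, ideal_side_area = ideal_side),
    class = "cylinder_fixture")
}

# boundary triangles all of whose vertices lie in `vids`
boundary_tris_within <- function(mesh, vids) {
  bt <- mesh$boundary_tris
  tv <- mesh$tri[bt, , drop = FALSE]
  inside <- matrix(tv %in% vids, nrow = nrow(tv))
  bt[rowSums(inside) == 3L]
}

check_volume_consistency <- function(mesh, tol = 1e-9) {
  v1 <- mesh_volume(mesh, "tets")
  v2 <- mesh_volume(mesh, "divergence")
  if (abs(v1 - v2) > tol * v1)
    stop(sprintf(paste0("internal mesh inconsistency: tet volume sum %.12g",
                        " != divergence volume %.12g (folded slab?)"),
                 v1, v2))
  invisible(TRUE)
}

#' @export
print.cylinder_fixture <- function(x, ...) {
  cat(sprintf(paste0("cylinder_fixture: L=%.3g m d=%.3g m, %d tets ",
                     "(m=%d, %d slices), surface error %+.2f%%\n"),
              x$length, x$diameter, nrow(x$mesh$tets), x$m, x$n_slices,
              100 * x$surface_error))
  invisible(x)
}

# ---- branched tree --------------------------------------------------------

#' Generate a symmetric branched dendrite mesh
#'
#' Builds a symmetric binary tree of cylindrical branches.  At each branch
#' point the daughter diameter is \eqn{d\,2^{-2/3}} (the 3/2 power law:
#' the summed \eqn{d^{3/2}} is conserved) and the daughter length is
#' \eqn{l\,2^{-1/3}}, which keeps the electrotonic length of every level
#' equal; an 8-level tree grown from a 32 um x 16 um root then spans about
#' 130 um from root to tip.  Branch pairs diverge by a fixed half-angle in
#' planes that rotate 90 degrees per level.  Each parent ends in a split
#' disc whose two halves feed conforming junction plugs into the daughter
#' base discs.
#'
#' @param levels number of branching levels, 1..8 (1 = plain cylinder).
#' @param root_length root branch length (m), default 32 um.
#' @param root_diameter root branch diameter (m), default 16 um.
#' @param target_ntets approximate tetrahedron budget.
#' @param match_volume scale cross-sections so total mesh volume equals the
#'   ideal union-of-cylinders volume (default TRUE).
#' @param half_angle daughter divergence half-angle (radians).
#' @return an object of class `branched_fixture`: `mesh`, `membrane`,
#'   `surface_error` (vs the summed ideal side areas), `root_cap`,
#'   `root_cap_verts`, `tip_verts`, `branches` (data frame of the
#'   skeleton), `path_length` (root-to-tip, m).
#' @export
generate_branched_mesh <- function(levels, root_length = 32e-6,
                                   root_diameter = 16e-6,
                                   target_ntets = 60000L,
                                   match_volume = TRUE,
                                   half_angle = 0.5) {
  stopifnot(levels >= 1, levels <= 8)
  levels <- as.integer(levels)
  if (levels == 1L) {
    cyl <- generate_cylinder_mesh(root_length, root_diameter, target_ntets,
                                  match_volume)
    out <- list(mesh = cyl$mesh, membrane = cyl$membrane,
                surface_error = cyl$surface_error,
                root_cap = cyl$cap_lo, root_cap_verts = cyl$cap_lo_verts,
                tip_caps = cyl$cap_hi, tip_verts = cyl$cap_hi_verts,
                branches = data.frame(level = 1L, length = root_length,
                                      radius = root_diameter / 2),
                path_length = root_length,
                ideal_volume = cyl$ideal_volume,
                ideal_side_area = cyl$ideal_side_area,
                radial_scale = 1)
    class(out) <- "branched_fixture"
    return(out)
  }

  skel <- tree_skeleton(levels, root_length, root_diameter / 2, half_angle)
  check_skeleton_intersections(skel)

  build <- function(s) build_tree_mesh(skel, levels, radial_scale = s,
                                       target_ntets = target_ntets)
  ideal_volume <- sum(pi * skel$radius^2 * skel$length)
  ideal_side <- sum(2 * pi * skel$radius * skel$length)

  s_star <- 1
  if (match_volume) {
    f <- function(s) sum(build(s)$mesh$vol) - ideal_volume
    lo <- 0.9; hi <- 1.1
    while (f(lo) > 0) lo <- lo * 0.95
    while (f(hi) < 0) hi <- hi * 1.05
    s_star <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }
  b <- build(s_star)
  mesh <- b$mesh
  check_volume_consistency(mesh)
  membrane <- membrane_surface(mesh, C_spec = 1e-2, check_connected = FALSE)
  surface_error <- (membrane$area - ideal_side) / ideal_side

  structure(list(
    mesh = mesh, membrane = membrane, surface_error = surface_error,
    root_cap = boundary_tris_within(mesh, b$root_cap_verts),
    root_cap_verts = b$root_cap_verts,
    tip_caps = boundary_tris_within(mesh, b$tip_verts),
    tip_verts = b$tip_verts,
    branches = skel,
    path_length = sum(root_length * 2^(-(0:(levels - 1)) / 3)),
    ideal_volume = ideal_volume, ideal_side_area = ideal_side,
    radial_scale = s_star),
    class = "branched_fixture")
}

#' @export
print.branched_fixture <- function(x, ...) {
  cat(sprintf(paste0("branched_fixture: %d branches, %d tets, path length ",
                     "%.3g m, surface error %+.2f%%\n"),
              nrow(x$branches), nrow(x$mesh$tets), x$path_length,
              100 * x$surface_error))
  invisible(x)
}

# Skeleton: one row per branch with start point, unit axis u, split axis n
# and separation direction e1 at its distal end.
tree_skeleton <- function(levels, root_length, root_radius, half_angle) {
  rot <- function(v, axis, ang) {  # Rodrigues rotation
    axis <- axis / sqrt(sum(axis^2))
    as.numeric(v * cos(ang) +
                 cross3(matrix(axis, ncol = 3), matrix(v, ncol = 3)) *
                 sin(ang) + axis * sum(axis * v) * (1 - cos(ang)))
  }
  rows <- list()
  grow <- function(level, start, u, n, l, r, parent) {
    id <- length(rows) + 1L
    e1 <- as.numeric(cross3(matrix(n, ncol = 3), matrix(u, ncol = 3)))
    e1 <- e1 / sqrt(sum(e1^2))
    rows[[id]] <<- data.frame(
      id = id, level = level, parent = parent,
      sx = start[1], sy = start[2], sz = start[3],
      ux = u[1], uy = u[2], uz = u[3],
      nx = n[1], ny = n[2], nz = n[3],
      e1x = e1[1], e1y = e1[2], e1z = e1[3],
      length = l, radius = r)
    if (level < levels) {
      endp <- start + l * u
      for (sgn in c(1, -1)) {
        ud <- rot(u, n, sgn * half_angle)
        nd <- as.numeric(cross3(matrix(ud, ncol = 3), matrix(n, ncol = 3)))
        nd <- nd / sqrt(sum(nd^2))
        grow(level + 1L, endp, ud, nd, l * 2^(-1 / 3), r * 2^(-2 / 3), id)
      }
    }
  }
  grow(1L, c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), root_length, root_radius, 0L)
  do.call(rbind, rows)
}

# minimum distance between segments (p1,p2) and (q1,q2)
segseg_dist <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  c_ <- sum(d1 * r); b <- sum(d1 * d2)
  denom <- a * e - b * b
  s <- if (denom > 1e-30) min(1, max(0, (b * f - c_ * e) / denom)) else 0
  t <- (b * s + f) / e
  if (t < 0) { t <- 0; s <- min(1, max(0, -c_ / a)) }
  else if (t > 1) { t <- 1; s <- min(1, max(0, (b - c_) / a)) }
  sqrt(sum((p1 + s * d1 - (q1 + t * d2))^2))
}

check_skeleton_intersections <- function(skel, margin = 0.95) {
  n <- nrow(skel)
  S <- as.matrix(skel[, c("sx", "sy", "sz")])
  U <- as.matrix(skel[, c("ux", "uy", "uz")])
  E <- S + skel$length * U
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip parent/child and sibling pairs, which legitimately touch
      if (skel$parent[j] == i || skel$parent[i] == j) next
      if (skel$parent[i] == skel$parent[j]) next
      d <- segseg_dist(S[i, ], E[i, ], S[j, ], E[j, ])
      if (d < margin * (skel$radius[i] + skel$radius[j]))
        stop(sprintf(paste0("geometric self-intersection between branches ",
                            "at levels %d and %d"),
                     skel$level[i], skel$level[j]))
    }
  }
  invisible(TRUE)
}

build_tree_mesh <- function(skel, levels, radial_scale = 1,
                            target_ntets = 60000L) {
  m <- 8L
  n_internal <- sum(skel$level < levels)
  # slab budget; plugs and split-end slabs cost ~2.25 extra slabs per
  # internal branch
  total_len <- sum(skel$length)
  s_target <- max(nrow(skel) * 2, target_ntets / (4 * m) - 2.25 * n_internal)
  h_nom <- total_len / s_target

  reg <- new_registry()
  tets <- list()
  base_rings <- vector("list", nrow(skel))   # filled for daughters by parent
  tip_verts <- integer(0)
  root_cap_verts <- NULL

  for (b in seq_len(nrow(skel))) {
    u <- as.numeric(skel[b, c("ux", "uy", "uz")])
    n <- as.numeric(skel[b, c("nx", "ny", "nz")])
    e1 <- as.numeric(skel[b, c("e1x", "e1y", "e1z")])
    start <- as.numeric(skel[b, c("sx", "sy", "sz")])
    l <- skel$length[b]; r <- skel$radius[b] * radial_scale
    internal <- skel$level[b] < levels
    R <- r * sqrt(2 * pi / (m * sin(2 * pi / m)))   # area-matched polygon

    if (b == 1L) {
      ring0 <- full_ring(reg, start, e1, n, R, m)
      root_cap_verts <- c(ring0$chain, ring0$center)
      z0 <- 0
      off <- c(0, 0, 0)
    } else {
      ring0 <- base_rings[[b]]
      z0 <- ring0$z0
      off <- ring0$off
    }

    ns <- max(2L, as.integer(round((l - z0) / h_nom)))
    zs <- seq(z0, l, length.out = ns + 1L)
    prev <- ring0
    for (jj in 2:(ns + 1L)) {
      # the lateral base-ring offset decays to zero along the branch so the
      # distal end sits exactly on the skeleton
      pos <- start + zs[jj] * u + off * (l - zs[jj]) / (l - z0)
      last <- jj == ns + 1L
      ring <- if (last && internal) split_ring(reg, pos, e1, n, R, m)
              else full_ring(reg, pos, e1, n, R, m)
      tets <- add_slab(reg, tets, prev, ring)
      prev <- ring
    }
    end_ring <- prev
    endp <- start + l * u

    if (!internal) {
      tip_verts <- c(tip_verts, end_ring$chain, end_ring$center)
      next
    }

    # junction plugs: the e1 > 0 half-disc feeds the daughter on that side
    kids <- which(skel$parent == b)
    stopifnot(length(kids) == 2L)
    ud1 <- as.numeric(skel[kids[1L], c("ux", "uy", "uz")])
    kid_up <- if (sum(ud1 * e1) >= 0) kids[1L] else kids[2L]
    kid_dn <- setdiff(kids, kid_up)
    r_d <- skel$radius[kid_up] * radial_scale
    R_d <- r_d * sqrt(2 * pi / (m * sin(2 * pi / m)))
    c_off <- 4 / (3 * pi) * R
    h_plug <- 0.9 * R
    for (kk in c(kid_up, kid_dn)) {
      sgn <- if (kk == kid_up) 1 else -1
      half <- if (kk == kid_up) end_ring$half_up else end_ring$half_dn
      ud <- as.numeric(skel[kk, c("ux", "uy", "uz")])
      nd <- as.numeric(skel[kk, c("nx", "ny", "nz")])
      e1d <- as.numeric(skel[kk, c("e1x", "e1y", "e1z")])
      off_d <- sgn * c_off * e1
      cen <- endp + off_d + h_plug * ud
      dring <- full_ring(reg, cen, e1d, nd, R_d, m)
      al <- align_chain(half$pos, dring$chain, dring$pos)
      plug_top <- list(chain = al$chain, pos = al$pos, cap = dring$cap)
      tets <- add_slab(reg, tets, half, plug_top)
      dring$z0 <- h_plug
      dring$off <- off_d
      base_rings[[kk]] <- dring
    }
  }

  mesh <- tet_mesh(reg_coords(reg), do.call(rbind, tets))
  list(mesh = mesh, root_cap_verts = root_cap_verts, tip_verts = tip_verts)
}
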