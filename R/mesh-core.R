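# Tetrahedral mesh representation, geometry and I/O.
#
# A tet_mesh stores vertices (n x 3, metres), tets (m x 4, 1-based vertex
# indices, canonically oriented so every signed volume is positive), the
# derived unique-triangle table and the tet<->triangle incidence from which
# the boundary surface is read off (a triangle belonging to exactly one tet
# is boundary).

#' Volume of a tetrahedron
#'
#' Computes |det[a-p, b-p, c-p]| / 6.  Arguments may be single points
#' (length-3 vectors) or row-wise matrices of points, in which case the
#' volumes are computed row by row.
#'
#' @param p,a,b,c corner coordinates (length-3 vectors or n x 3 matrices).
#' @return numeric vector of volumes (m^3); zero for degenerate corners.
#' @export
tet_volume <- function(p, a, b, c) {
  abs(signed_tet_volume(p, a, b, c))
}

signed_tet_volume <- function(p, a, b, c) {
  as3 <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 3L)
  p <- as3(p); a <- as3(a); b <- as3(b); c <- as3(c)
  u <- a - p; v <- b - p; w <- c - p
  # det via scalar triple product u . (v x w), vectorised over rows
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) +
   u[, 2] * (v[, 3] * w[, 1] - v[, 1] * w[, 3]) +
   u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Construct a tetrahedral mesh
#'
#' Builds the canonical internal mesh representation: vertices are kept as
#' given, tetrahedra are re-oriented so all signed volumes are positive,
#' and the unique triangle table, triangle areas, per-tet volumes and the
#' boundary surface are derived.
#'
#' @param vertices n x 3 numeric matrix of coordinates (m).
#' @param tets m x 4 integer matrix of 1-based vertex indices.
#' @return an object of class `tet_mesh` with elements `vertices`, `tets`,
#'   `tri` (unique triangles, vertex triples sorted ascending),
#'   `tri_tets` (two adjacent tet ids per triangle, `NA` where absent),
#'   `boundary_tris` (triangle ids on the boundary), `vol` (per-tet, m^3),
#'   `tri_area` (per-triangle, m^2).
#' @export
tet_mesh <- function(vertices, tets) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(tets) != 4L) stop("tets must be an m x 4 matrix")
  if (min(tets) < 1L || max(tets) > nrow(vertices))
    stop("tet vertex indices out of range [1, ", nrow(vertices), "]")

  sv <- signed_tet_volume(vertices[tets[, 1], , drop = FALSE],
                          vertices[tets[, 2], , drop = FALSE],
                          vertices[tets[, 3], , drop = FALSE],
                          vertices[tets[, 4], , drop = FALSE])
  degen <- which(sv == 0)
  if (length(degen))
    stop("degenerate (zero-volume) tetrahedra: ",
         paste(utils::head(degen, 10L), collapse = ", "),
         if (length(degen) > 10L) " ...")
  flip <- sv < 0
  if (any(flip)) {          # swap two vertices to make orientation positive
    tmp <- tets[flip, 3L]
    tets[flip, 3L] <- tets[flip, 4L]
    tets[flip, 4L] <- tmp
  }

  m <- structure(list(vertices = vertices, tets = tets, vol = abs(sv)),
                 class = "tet_mesh")
  m <- derive_triangles(m)
  m
}

# Unique triangle table and tet incidence.  Faces are keyed by their sorted
# vertex triple; interior faces appear in exactly two tets, boundary in one.
derive_triangles <- function(mesh) {
  tets <- mesh$tets
  nt <- nrow(tets)
  # the four faces of each tet
  faces <- rbind(tets[, c(2L, 3L, 4L)],
                 tets[, c(1L, 3L, 4L)],
                 tets[, c(1L, 2L, 4L)],
                 tets[, c(1L, 2L, 3L)])
  owner <- rep.int(seq_len(nt), 4L)
  opp   <- c(tets[, 1L], tets[, 2L], tets[, 3L], tets[, 4L])
  # fast row sort for 3 columns
  a <- pmin(faces[, 1], faces[, 2], faces[, 3])
  c_ <- pmax(faces[, 1], faces[, 2], faces[, 3])
  b <- faces[, 1] + faces[, 2] + faces[, 3] - a - c_
  fs <- cbind(a, b, c_)
  o <- order(fs[, 1], fs[, 2], fs[, 3])
  fso <- fs[o, , drop = FALSE]
  new_grp <- c(TRUE, rowSums(fso[-1, , drop = FALSE] !=
                             fso[-nrow(fso), , drop = FALSE]) > 0)
  grp_of_sorted <- cumsum(new_grp)
  grp <- integer(length(o)); grp[o] <- grp_of_sorted
  ngrp <- grp_of_sorted[length(grp_of_sorted)]
  tri <- fso[new_grp, , drop = FALSE]
  colnames(tri) <- NULL
  cnt <- tabulate(grp, ngrp)
  if (any(cnt > 2L))
    stop("invalid mesh: a face is shared by more than two tetrahedra")
  tri_tets <- matrix(NA_integer_, ngrp, 2L)
  first <- new_grp
  tri_tets[grp_of_sorted[first], 1L] <- owner[o][first]
  second <- !new_grp
  tri_tets[grp_of_sorted[second], 2L] <- owner[o][second]
  tri_opp <- matrix(NA_integer_, ngrp, 2L)
  tri_opp[grp_of_sorted[first], 1L] <- opp[o][first]
  tri_opp[grp_of_sorted[second], 2L] <- opp[o][second]

  v <- mesh$vertices
  e1 <- v[tri[, 2], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  e2 <- v[tri[, 3], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  cr <- cross3(e1, e2)
  mesh$tri <- tri
  mesh$tri_tets <- tri_tets
  mesh$tri_opp <- tri_opp   # vertex of each adjacent tet opposite the face
  mesh$tri_area <- 0.5 * sqrt(rowSums(cr^2))
  mesh$boundary_tris <- which(is.na(tri_tets[, 2L]))
  mesh
}

#' Total mesh volume
#'
#' Either the sum of tetrahedron volumes or, as an independent geometric
#' check, the divergence-theorem surface integral
#' \eqn{V = (1/3)\oint x \cdot n \, dS} over the boundary triangles with
#' outward-oriented normals.
#'
#' @param mesh a `tet_mesh`.
#' @param method `"tets"` (default) or `"divergence"`.
#' @return volume in m^3.
#' @export
mesh_volume <- function(mesh, method = c("tets", "divergence")) {
  method <- match.arg(method)
  if (method == "tets") return(sum(mesh$vol))
  v <- mesh$vertices
  bt <- mesh$boundary_tris
  tri <- mesh$tri[bt, , drop = FALSE]
  p1 <- v[tri[, 1], , drop = FALSE]
  p2 <- v[tri[, 2], , drop = FALSE]
  p3 <- v[tri[, 3], , drop = FALSE]
  n <- 0.5 * cross3(p2 - p1, p3 - p1)       # area-weighted normal
  cen <- (p1 + p2 + p3) / 3
  # orient outward: away from the opposite vertex of the owning tet
  oppv <- v[mesh$tri_opp[bt, 1L], , drop = FALSE]
  s <- sign(rowSums(n * (cen - oppv)))
  sum(rowSums(cen * n) * s) / 3
}

#' Membrane surface on a mesh
#'
#' A membrane is a set of mesh triangles that carries specific capacitance
#' and, later, leak and channels.  Each triangle has a defined inner
#' tetrahedron; for boundary triangles the outer side is the bath.  The
#' triangles must form a single edge-connected surface (open or closed).
#'
#' @param mesh a `tet_mesh`.
#' @param tris triangle ids (rows of `mesh$tri`); defaults to the whole
#'   boundary surface.
#' @param C_spec specific membrane capacitance (F/m^2).
#' @param check_connected verify edge-connectivity (default TRUE).
#' @return object of class `membrane_surface` with `tri`, `inner_tet`,
#'   `outer` (`NA` = bath), `area`, `C_spec`.
#' @export
membrane_surface <- function(mesh, tris = mesh$boundary_tris,
                             C_spec = 1e-2, check_connected = TRUE) {
  stopifnot(inherits(mesh, "tet_mesh"))
  tris <- as.integer(tris)
  if (!length(tris)) stop("membrane must contain at least one triangle")
  if (min(tris) < 1L || max(tris) > nrow(mesh$tri))
    stop("triangle ids out of range")
  inner <- mesh$tri_tets[tris, 1L]
  if (anyNA(inner)) stop("every membrane triangle needs an inner tetrahedron")
  outer <- mesh$tri_tets[tris, 2L]   # NA -> bath
  if (check_connected && length(tris) > 1L) {
    comp <- membrane_components(mesh, tris)
    if (max(comp) > 1L)
      stop("membrane triangles do not form a single edge-connected surface (",
           max(comp), " components)")
  }
  structure(list(tri = tris, inner_tet = inner, outer = outer,
                 tri_verts = mesh$tri[tris, , drop = FALSE],
                 tri_area = mesh$tri_area[tris],
                 n_vertices = nrow(mesh$vertices),
                 area = sum(mesh$tri_area[tris]), C_spec = C_spec),
            class = "membrane_surface")
}

# Connected components of the membrane triangle adjacency (shared edges).
membrane_components <- function(mesh, tris) {
  tv <- mesh$tri[tris, , drop = FALSE]
  n <- nrow(mesh$vertices)
  ek <- function(i, j) pmin(i, j) * (n + 1) + pmax(i, j)  # exact in double
  keys <- c(ek(tv[, 1], tv[, 2]), ek(tv[, 2], tv[, 3]), ek(tv[, 1], tv[, 3]))
  tid <- rep.int(seq_along(tris), 3L)
  eid <- match(keys, unique(keys))
  # union-find over triangles sharing an edge
  parent <- seq_along(tris)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  o <- order(eid)
  eo <- eid[o]; to <- tid[o]
  brk <- c(which(diff(eo) != 0), length(eo))
  start <- c(1L, utils::head(brk, -1L) + 1L)
  for (g in seq_along(start)) {
    if (brk[g] > start[g]) {
      r0 <- find(to[start[g]])
      for (k in (start[g] + 1L):brk[g]) {
        r1 <- find(to[k])
        if (r1 != r0) parent[r1] <- r0
      }
    }
  }
  roots <- vapply(seq_along(tris), find, integer(1))
  match(roots, unique(roots))
}

#' Surface-area correction factor
#'
#' A generated mesh approximates a curved surface by flat triangles, so its
#' membrane area differs from the ideal geometric area by a few percent.
#' Multiplying the specific capacitance and the leak conductance per area
#' by `ideal_area / mesh_area` makes total membrane capacitance and total
#' leak conductance equal those of the ideal geometry.
#'
#' @param membrane a `membrane_surface`.
#' @param ideal_area ideal surface area (m^2), > 0.
#' @return dimensionless scale factor.
#' @export
surface_correction_factor <- function(membrane, ideal_area) {
  stopifnot(ideal_area > 0)
  if (membrane$area <= 0) stop("membrane has zero area")
  ideal_area / membrane$area
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh:", nrow(x$vertices), "vertices,", nrow(x$tets), "tets,",
      nrow(x$tri), "triangles (", length(x$boundary_tris), "boundary )\n")
  cat(sprintf("  volume %.6g m^3, boundary area %.6g m^2\n",
              sum(x$vol), sum(x$tri_area[x$boundary_tris])))
  invisible(x)
}

#' @export
summary.tet_mesh <- function(object, ...) {
  out <- list(
    n_vertices = nrow(object$vertices),
    n_tets = nrow(object$tets),
    n_triangles = nrow(object$tri),
    n_boundary = length(object$boundary_tris),
    volume = sum(object$vol),
    boundary_area = sum(object$tri_area[object$boundary_tris]),
    tet_volume_range = range(object$vol))
  class(out) <- "summary.tet_mesh"
  out
}

#' @export
print.summary.tet_mesh <- function(x, ...) {
  cat("Tetrahedral mesh\n")
  cat("  vertices :", x$n_vertices, "\n")
  cat("  tets     :", x$n_tets, "\n")
  cat("  triangles:", x$n_triangles, "(", x$n_boundary, "boundary )\n")
  cat(sprintf("  volume   : %.6g m^3\n", x$volume))
  cat(sprintf("  area     : %.6g m^2 (boundary)\n", x$boundary_area))
  cat(sprintf("  tet vol  : [%.3g, %.3g] m^3\n",
              x$tet_volume_range[1], x$tet_volume_range[2]))
  invisible(x)
}

#' @export
print.membrane_surface <- function(x, ...) {
  cat("membrane_surface:", length(x$tri), "triangles, area",
      format(x$area), "m^2, C_spec", format(x$C_spec), "F/m^2\n")
  invisible(x)
}
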