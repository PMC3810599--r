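path_graph <- function(n) {
  tetvolt:::graph_from_edges(n, cbind(1:(n - 1), 2:n))
}

complete_graph <- function(n) {
  e <- t(combn(n, 2))
  tetvolt:::graph_from_edges(n, e)
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  e <- t(combn(n, 2))
  keep <- runif(nrow(e)) < p
  e <- e[keep, , drop = FALSE]
  # ensure connectivity by adding a random spanning path
  perm <- sample(n)
  e <- unique(rbind(e, cbind(pmin(perm[-n], perm[-1]),
                             pmax(perm[-n], perm[-1]))))
  tetvolt:::graph_from_edges(n, e)
}

brute_force_bandwidth <- function(graph) {
  perms <- as.matrix(expand.grid(rep(list(seq_len(graph$n)), graph$n)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ,
                 drop = FALSE]
  min(apply(perms, 1, function(p)
    max(abs(p[graph$edges[, 1]] - p[graph$edges[, 2]]))))
}

test_that("bandwidth matches hand cases and validates bijectivity", {
  g <- path_graph(6)
  expect_equal(bandwidth(g, 1:6), 1L)
  expect_equal(bandwidth(complete_graph(5), sample(5)), 4L)
  expect_error(bandwidth(g, c(1, 1, 2, 3, 4, 5)), "bijection")
})

test_that("BFS orderings beat raw ones and respect exhaustive optima", {
  # chain from an end
  g <- path_graph(8)
  expect_equal(breadth_first_order(g, 1)$bandwidth, 1L)
  # star: hub + k leaves; a BFS numbering is forced to k (hub start) or
  # k-1 (leaf start, hub in second position), so the scan returns k-1
  k <- 5
  star <- tetvolt:::graph_from_edges(k + 1, cbind(1, 2:(k + 1)))
  expect_equal(breadth_first_order(star, 1)$bandwidth, k - 1L)
  for (s in seq_len(k + 1)) {
    perm <- integer(k + 1)
    perm[tetvolt:::bfs_numbering(star, s, TRUE)] <- seq_len(k + 1)
    expect_true(bandwidth(star, perm) %in% c(k - 1L, k))
  }
  # exhaustive oracle on 6-vertex random graphs: heuristics never beat it
  for (seed in 1:8) {
    g <- random_graph(6, 0.4, seed)
    opt <- brute_force_bandwidth(g)
    bw_cm <- breadth_first_order(g, 1)$bandwidth
    bw_plain <- breadth_first_order(g, 1, refine = "plain")$bandwidth
    expect_gte(bw_cm, opt)
    expect_gte(bw_plain, opt)
  }
  # Cuthill-McKee is at least as good as plain BFS in the vast majority
  # of random trials
  wins <- 0L; total <- 0L
  for (seed in 1:60) {
    g <- random_graph(10, 0.25, seed)
    total <- total + 1L
    if (breadth_first_order(g, 1)$bandwidth <=
        breadth_first_order(g, 1, refine = "plain")$bandwidth)
      wins <- wins + 1L
  }
  expect_gte(wins / total, 0.9)
})

test_that("principal-axis ordering is rotation invariant and sorts rods", {
  fx <- small_cylinder()
  g <- vertex_graph(fx$mesh)
  pa <- principal_axis_order(fx$mesh, g)
  # rotate the rod arbitrarily: same ordering up to global direction flip
  th <- 0.7; ph <- 1.1
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  R <- Rx %*% Rz
  vrot <- fx$mesh$vertices %*% t(R)
  mrot <- tet_mesh(vrot, fx$mesh$tets)
  pa2 <- principal_axis_order(mrot, vertex_graph(mrot))
  # the achieved bandwidth is rotation invariant up to tie resolution
  # within rings (the cross-section covariance is degenerate, so the
  # minor-axis tie-break directions are arbitrary under rotation), and
  # the ordering still sorts vertices along the (rotated) rod axis
  expect_lte(abs(pa2$bandwidth - pa$bandwidth), 2)
  axis_rot <- as.numeric(R %*% c(0, 0, 1))
  proj_in_order <- (vrot %*% axis_rot)[order(pa2$perm)]
  slab <- fx$length / fx$n_slices
  mono_up <- all(diff(proj_in_order) > -slab / 2)
  mono_dn <- all(diff(proj_in_order) < slab / 2)
  expect_true(mono_up || mono_dn)
  # the unrotated rod along z is already sorted by construction
  proj0 <- fx$mesh$vertices[order(pa$perm), 3]
  expect_true(all(diff(proj0) > -slab / 2) || all(diff(proj0) < slab / 2))
})

test_that("orderings give >=100x bandwidth reduction on a rod", {
  fx <- rod_cylinder()
  g <- vertex_graph(fx$mesh)
  set.seed(42)
  bw_rand <- bandwidth(g, sample(g$n))
  pa <- principal_axis_order(fx$mesh, g)
  bfs <- breadth_first_order(g, start_fraction = 4 / g$n, seed = 1)
  expect_lte(bfs$bandwidth, 2 * pa$bandwidth)
  expect_lte(pa$bandwidth, bw_rand)
  expect_gte(bw_rand / pa$bandwidth, 100)
  expect_gte(bw_rand / bfs$bandwidth, 100)
})

test_that("disconnected graphs are refused with component sizes", {
  g <- tetvolt:::graph_from_edges(5, rbind(c(1, 2), c(3, 4), c(4, 5)))
  expect_error(breadth_first_order(g, 1), "component sizes: 2, 3")
})

test_that("ordering files round-trip and detect mesh mismatch", {
  d <- withr::local_tempdir()
  fx <- small_cylinder()
  g <- vertex_graph(fx$mesh)
  ord <- breadth_first_order(g, start_fraction = 2 / g$n, seed = 3)
  p <- file.path(d, "ord.txt")
  save_ordering(ord, g, p)
  back <- load_ordering(g, p)
  expect_identical(back$perm, ord$perm)
  expect_equal(back$bandwidth, ord$bandwidth)
  # different mesh -> checksum error
  g2 <- vertex_graph(small_tree()$mesh)
  expect_error(load_ordering(g2, p), "vertices|checksum")
  # duplicate index -> bijection guard
  lines <- readLines(p)
  lines[3] <- lines[2]
  writeLines(lines, p)
  expect_error(load_ordering(g, p), "bijection")
})
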