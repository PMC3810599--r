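# Mesh file I/O: TetGen .node/.ele pairs and Gmsh MSH v2 ASCII.
#
# Both dialects are normalised to the internal 1-based representation.
# TetGen files may be numbered from 0 or 1 depending on the generator
# version; the reader sniffs the first index and an explicit override is
# available.

#' Read a tetrahedral mesh from file
#'
#' @param path for `format = "tetgen"`, the basename of a `.node`/`.ele`
#'   pair (with or without either extension); for `format = "msh2"`, a
#'   Gmsh MSH v2 ASCII file.
#' @param format `"tetgen"` or `"msh2"`.
#' @param index_base `"auto"` (sniff the first node index), `0` or `1`.
#' @return a [tet_mesh].
#' @export
read_mesh <- function(path, format = c("tetgen", "msh2"),
                      index_base = "auto") {
  format <- match.arg(format)
  switch(format,
         tetgen = read_tetgen(path, index_base),
         msh2 = read_msh2(path, index_base))
}

parse_error <- function(path, line, msg) {
  stop(sprintf("parse error in '%s' line %d: %s", path, line, msg),
       call. = FALSE)
}

tokenize <- function(lines) {
  strsplit(trimws(lines), "[ \t]+")
}

# strip blank and comment lines but remember original line numbers
content_lines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#.*)?$", raw))
  list(text = raw[keep], lineno = keep)
}

read_tetgen <- function(path, index_base = "auto") {
  base <- sub("\\.(node|ele)$", "", path)
  nodef <- paste0(base, ".node")
  elef <- paste0(base, ".ele")
  if (!file.exists(nodef)) stop("file not found: ", nodef)
  if (!file.exists(elef)) stop("file not found: ", elef)

  nd <- content_lines(nodef)
  hdr <- suppressWarnings(as.numeric(tokenize(nd$text[1])[[1]]))
  if (length(hdr) < 2 || anyNA(hdr[1:2]))
    parse_error(nodef, nd$lineno[1], "expected '<n_points> <dim> ...' header")
  np <- as.integer(hdr[1])
  if (length(nd$text) < np + 1)
    parse_error(nodef, nd$lineno[length(nd$lineno)],
                sprintf("expected %d node lines", np))
  ntok <- tokenize(nd$text[2:(np + 1)])
  bad <- which(lengths(ntok) < 4L)
  if (length(bad))
    parse_error(nodef, nd$lineno[1 + bad[1]], "expected '<id> <x> <y> <z>'")
  nm <- matrix(suppressWarnings(as.numeric(unlist(
    lapply(ntok, `[`, 1:4)))), ncol = 4L, byrow = TRUE)
  if (anyNA(nm)) {
    bad <- which(apply(is.na(nm), 1, any))[1]
    parse_error(nodef, nd$lineno[1 + bad], "non-numeric node entry")
  }
  ids <- nm[, 1]

  el <- content_lines(elef)
  ehdr <- suppressWarnings(as.numeric(tokenize(el$text[1])[[1]]))
  if (length(ehdr) < 2 || anyNA(ehdr[1:2]))
    parse_error(elef, el$lineno[1], "expected '<n_tets> <nodes_per_tet> ...'")
  nt <- as.integer(ehdr[1])
  if (as.integer(ehdr[2]) != 4L)
    parse_error(elef, el$lineno[1], "only 4-node tetrahedra are supported")
  if (length(el$text) < nt + 1)
    parse_error(elef, el$lineno[length(el$lineno)],
                sprintf("expected %d element lines", nt))
  etok <- tokenize(el$text[2:(nt + 1)])
  bad <- which(lengths(etok) < 5L)
  if (length(bad))
    parse_error(elef, el$lineno[1 + bad[1]],
                "expected '<id> <v1> <v2> <v3> <v4>'")
  em <- matrix(suppressWarnings(as.numeric(unlist(
    lapply(etok, `[`, 1:5)))), ncol = 5L, byrow = TRUE)
  if (anyNA(em)) {
    bad <- which(apply(is.na(em), 1, any))[1]
    parse_error(elef, el$lineno[1 + bad], "non-numeric element entry")
  }

  # Elements are matched to nodes by file id, which normalises 0- and
  # 1-based dialects alike; an explicit index_base is checked for
  # consistency with the file rather than trusted blindly.
  if (!identical(index_base, "auto")) {
    declared0 <- sniff_base(index_base, ids)
    if (declared0 != (min(ids) == 0))
      stop(sprintf("'%s' is numbered from %d but index_base=%s was given",
                   nodef, min(ids), index_base))
  }
  # map file node ids -> row positions (ids need not be contiguous)
  pos <- match(as.vector(em[, 2:5]), ids)
  if (anyNA(pos))
    parse_error(elef, el$lineno[2], "element references unknown node id")
  tets <- matrix(as.integer(pos), ncol = 4L)
  tet_mesh(nm[, 2:4, drop = FALSE], tets)
}

sniff_base <- function(index_base, ids) {
  if (identical(index_base, "auto")) return(min(ids) == 0)
  b <- as.integer(index_base)
  if (!b %in% c(0L, 1L)) stop("index_base must be 'auto', 0 or 1")
  b == 0L
}

#' Write a mesh as a TetGen .node/.ele pair
#'
#' Files are written 1-based (TetGen's default).
#'
#' @param mesh a [tet_mesh].
#' @param base output basename; `.node` and `.ele` are appended.
#' @export
write_tetgen <- function(mesh, base) {
  v <- mesh$vertices
  nodef <- paste0(base, ".node")
  elef <- paste0(base, ".ele")
  con <- file(nodef, "w")
  writeLines(sprintf("%d 3 0 0", nrow(v)), con)
  writeLines(sprintf("%d %.17g %.17g %.17g",
                     seq_len(nrow(v)), v[, 1], v[, 2], v[, 3]), con)
  close(con)
  con <- file(elef, "w")
  writeLines(sprintf("%d 4 0", nrow(mesh$tets)), con)
  t4 <- mesh$tets
  writeLines(sprintf("%d %d %d %d %d", seq_len(nrow(t4)),
                     t4[, 1], t4[, 2], t4[, 3], t4[, 4]), con)
  close(con)
  invisible(c(nodef, elef))
}

read_msh2 <- function(path, index_base = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  sec <- function(name) {
    i0 <- which(raw == paste0("$", name))
    i1 <- which(raw == paste0("$End", name))
    if (length(i0) != 1 || length(i1) != 1 || i1 <= i0)
      parse_error(path, if (length(i0)) i0[1] else 1,
                  paste0("missing or malformed $", name, " section"))
    c(i0, i1)
  }
  mf <- sec("MeshFormat")
  ver <- tokenize(raw[mf[1] + 1])[[1]]
  if (!startsWith(ver[1], "2"))
    parse_error(path, mf[1] + 1, paste0("unsupported MSH version ", ver[1],
                                        " (need v2 ASCII)"))
  nd <- sec("Nodes")
  nn <- suppressWarnings(as.integer(raw[nd[1] + 1]))
  if (is.na(nn)) parse_error(path, nd[1] + 1, "expected node count")
  ntok <- tokenize(raw[(nd[1] + 2):(nd[1] + 1 + nn)])
  nm <- matrix(suppressWarnings(as.numeric(unlist(
    lapply(ntok, `[`, 1:4)))), ncol = 4L, byrow = TRUE)
  if (anyNA(nm)) parse_error(path, nd[1] + 2, "non-numeric node entry")
  ids <- nm[, 1]

  elsec <- sec("Elements")
  ne <- suppressWarnings(as.integer(raw[elsec[1] + 1]))
  if (is.na(ne)) parse_error(path, elsec[1] + 1, "expected element count")
  etok <- tokenize(raw[(elsec[1] + 2):(elsec[1] + 1 + ne)])
  # element line: id type ntags tags... nodes...; type 4 = 4-node tet
  tets <- lapply(seq_along(etok), function(k) {
    tk <- suppressWarnings(as.numeric(etok[[k]]))
    if (anyNA(tk) || length(tk) < 3)
      parse_error(path, elsec[1] + 1 + k, "malformed element line")
    if (tk[2] != 4) return(NULL)
    ntags <- tk[3]
    nodes <- tk[(4 + ntags):length(tk)]
    if (length(nodes) != 4)
      parse_error(path, elsec[1] + 1 + k, "tetrahedron needs 4 nodes")
    nodes
  })
  tets <- do.call(rbind, tets[!vapply(tets, is.null, logical(1))])
  if (is.null(tets) || nrow(tets) == 0)
    parse_error(path, elsec[1], "no tetrahedral elements found")
  pos <- match(as.vector(tets), ids)
  if (anyNA(pos)) parse_error(path, elsec[1], "element references unknown node")
  tet_mesh(nm[, 2:4, drop = FALSE], matrix(as.integer(pos), ncol = 4L))
}

#' Write a mesh as Gmsh MSH v2 ASCII
#'
#' @param mesh a [tet_mesh].
#' @param path output file path.
#' @export
write_msh2 <- function(mesh, path) {
  v <- mesh$vertices
  t4 <- mesh$tets
  con <- file(path, "w")
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               sprintf("%d", nrow(v))), con)
  writeLines(sprintf("%d %.17g %.17g %.17g",
                     seq_len(nrow(v)), v[, 1], v[, 2], v[, 3]), con)
  writeLines(c("$EndNodes", "$Elements", sprintf("%d", nrow(t4))), con)
  writeLines(sprintf("%d 4 2 0 0 %d %d %d %d", seq_len(nrow(t4)),
                     t4[, 1], t4[, 2], t4[, 3], t4[, 4]), con)
  writeLines("$EndElements", con)
  close(con)
  invisible(path)
}
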