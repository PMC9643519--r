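# Low-level quadratic-element mesh machinery shared by the 2D cross-section
# and 3D shell builders. Meshes are built patch-wise from structured grids of
# mapped quads/hexes, split into tri6/tet10 with midside nodes evaluated on
# the mapped geometry (so curved boundaries are quadratically resolved), and
# merged on coincident nodes.

MERGE_DIGITS <- 7L

node_key <- function(coords) {
  apply(round(coords, MERGE_DIGITS) + 0, 1, paste, collapse = "|")
}

#' Construct a region-tagged mesh object
#'
#' @param nodes Numeric matrix of node coordinates (mm), one row per node;
#'   2 columns (x = nasal, z = posterior) in cross-section mode, 3 in 3D.
#' @param elems Integer connectivity, one row per element: 6 columns
#'   (quadratic triangles) or 10 (quadratic tetrahedra), 1-based.
#' @param region Character vector of per-element region labels.
#' @param facets Named list of oriented boundary facet matrices.
#' @param node_sets Named list of node-index vectors.
#' @param landmarks Named list of landmark coordinates.
#' @return An object of class `rt_mesh`.
#' @export
rt_mesh <- function(nodes, elems, region, facets = list(), node_sets = list(),
                    landmarks = list()) {
  nodes <- as.matrix(nodes)
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  stopifnot(length(region) == nrow(elems))
  dim <- ncol(nodes)
  if (!(dim == 2 && ncol(elems) == 6) && !(dim == 3 && ncol(elems) == 10))
    stop("unsupported element family for dimension ", dim)
  structure(list(dim = dim, nodes = nodes, elems = elems,
                 region = as.character(region), facets = facets,
                 node_sets = node_sets, landmarks = landmarks),
            class = "rt_mesh")
}

#' @export
print.rt_mesh <- function(x, ...) {
  cat(sprintf("Region-tagged %dD mesh: %d nodes, %d quadratic elements\n",
              x$dim, nrow(x$nodes), nrow(x$elems)))
  tab <- table(x$region)
  for (r in names(tab)) cat(sprintf("  %-22s %5d\n", r, tab[[r]]))
  if (length(x$facets))
    cat("  facet sets:", paste(names(x$facets), collapse = ", "), "\n")
  if (length(x$node_sets))
    cat("  node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  invisible(x)
}

# Structured tri6 patch from a mapping (s, t) in [0,1]^2 -> (x, z).
# Returns list(nodes, elems) in local numbering; elements counter-clockwise.
tri6_patch <- function(map, n1, n2) {
  N1 <- 2L * n1 + 1L; N2 <- 2L * n2 + 1L
  s <- seq(0, 1, length.out = N1)
  t <- seq(0, 1, length.out = N2)
  nodes <- matrix(0, N1 * N2, 2)
  for (j in seq_len(N2)) for (i in seq_len(N1))
    nodes[i + (j - 1L) * N1, ] <- map(s[i], t[j])
  idx <- function(i, j) i + (j - 1L) * N1
  elems <- matrix(0L, 2L * n1 * n2, 6)
  e <- 0L
  for (cj in seq_len(n2)) for (ci in seq_len(n1)) {
    i0 <- 2L * ci - 1L; j0 <- 2L * cj - 1L
    a <- idx(i0, j0); b <- idx(i0 + 2L, j0)
    cc <- idx(i0 + 2L, j0 + 2L); d <- idx(i0, j0 + 2L)
    e <- e + 1L
    elems[e, ] <- c(a, b, cc, idx(i0 + 1L, j0), idx(i0 + 2L, j0 + 1L),
                    idx(i0 + 1L, j0 + 1L))
    e <- e + 1L
    elems[e, ] <- c(a, cc, d, idx(i0 + 1L, j0 + 1L), idx(i0 + 1L, j0 + 2L),
                    idx(i0, j0 + 1L))
  }
  fix_orientation2d(list(nodes = nodes, elems = elems))
}

fix_orientation2d <- function(patch) {
  nd <- patch$nodes; el <- patch$elems
  a <- nd[el[, 1], , drop = FALSE]
  b <- nd[el[, 2], , drop = FALSE]
  cc <- nd[el[, 3], , drop = FALSE]
  area2 <- (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
    (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])
  flip <- area2 < 0
  if (any(flip))
    el[flip, ] <- el[flip, c(1, 3, 2, 6, 5, 4), drop = FALSE]
  list(nodes = nd, elems = el)
}

# Merge a list of patches (each list(nodes, elems, region)) into one node set,
# identifying nodes that coincide to MERGE_DIGITS decimals.
merge_patches <- function(patches) {
  all_nodes <- do.call(rbind, lapply(patches, `[[`, "nodes"))
  keys <- node_key(all_nodes)
  uk <- !duplicated(keys)
  new_id <- match(keys, keys[uk])
  nodes <- all_nodes[uk, , drop = FALSE]
  offset <- 0L
  elems <- list(); region <- list()
  for (p in patches) {
    elems[[length(elems) + 1L]] <- matrix(new_id[p$elems + offset],
                                          nrow = nrow(p$elems))
    region[[length(region) + 1L]] <- rep(p$region, length.out = nrow(p$elems))
    offset <- offset + nrow(p$nodes)
  }
  list(nodes = nodes, elems = do.call(rbind, elems),
       region = unlist(region))
}

# Oriented boundary edges of a tri6 mesh: rows (n1, n2, mid) in the parent
# element's counter-clockwise order, so (t2, -t1) is the outward normal.
boundary_edges <- function(elems) {
  ed <- rbind(elems[, c(1, 2, 4)], elems[, c(2, 3, 5)], elems[, c(3, 1, 6)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  ed[cnt[key] == 1L, , drop = FALSE]
}

# Oriented boundary faces of a tet10 mesh: rows of 6 node ids
# (c1, c2, c3, m12, m23, m31) with outward x_,xi x x_,eta.
boundary_faces <- function(nodes, elems) {
  # local faces as (corner triple, mid triple, opposite corner)
  lf <- list(c(1, 2, 3, 5, 6, 7, 4), c(1, 2, 4, 5, 9, 8, 3),
             c(2, 3, 4, 6, 10, 9, 1), c(3, 1, 4, 7, 8, 10, 2))
  faces <- NULL; opp <- NULL
  for (f in lf) {
    faces <- rbind(faces, elems[, f[1:6], drop = FALSE])
    opp <- c(opp, elems[, f[7]])
  }
  key <- apply(faces[, 1:3, drop = FALSE], 1, function(r) paste(sort(r), collapse = " "))
  cnt <- table(key)
  keep <- cnt[key] == 1L
  faces <- faces[keep, , drop = FALSE]; opp <- opp[keep]
  # orient outward: normal of (c1,c2,c3) must point away from opposite corner
  for (i in seq_len(nrow(faces))) {
    a <- nodes[faces[i, 1], ]; b <- nodes[faces[i, 2], ]; cc <- nodes[faces[i, 3], ]
    n <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
           (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
           (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    if (sum(n * (nodes[opp[i], ] - a)) > 0)
      faces[i, ] <- faces[i, c(1, 3, 2, 6, 5, 4)]
  }
  faces
}

# Subset of boundary facets whose midpoint satisfies a predicate on coords.
select_facets <- function(nodes, facets, pred) {
  midn <- if (ncol(facets) == 3) facets[, 3] else facets[, 4] # edge/face mid-ish node
  keep <- vapply(seq_len(nrow(facets)), function(i) {
    ctr <- colMeans(nodes[facets[i, 1:min(3, ncol(facets))], , drop = FALSE])
    isTRUE(pred(ctr))
  }, logical(1))
  facets[keep, , drop = FALSE]
}

# Structured tet10 patch from a mapping (s,t,r) in [0,1]^3.
# Hexes are split into six tetrahedra around the main diagonal, a subdivision
# that is face-consistent across a structured grid.
tet10_patch <- function(map, n1, n2, n3) {
  N1 <- 2L * n1 + 1L; N2 <- 2L * n2 + 1L; N3 <- 2L * n3 + 1L
  s <- seq(0, 1, length.out = N1)
  t <- seq(0, 1, length.out = N2)
  r <- seq(0, 1, length.out = N3)
  nodes <- matrix(0, N1 * N2 * N3, 3)
  for (k in seq_len(N3)) for (j in seq_len(N2)) for (i in seq_len(N1))
    nodes[i + (j - 1L) * N1 + (k - 1L) * N1 * N2, ] <- map(s[i], t[j], r[k])
  idx <- function(i, j, k) i + (j - 1L) * N1 + (k - 1L) * N1 * N2
  # corner offsets in binary order 0..7 -> (dx,dy,dz)
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
              c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  tets <- rbind(c(0, 1, 3, 7), c(0, 3, 2, 7), c(0, 2, 6, 7),
                c(0, 6, 4, 7), c(0, 4, 5, 7), c(0, 5, 1, 7)) + 1L
  elems <- matrix(0L, 6L * n1 * n2 * n3, 10)
  e <- 0L
  for (ck in seq_len(n3)) for (cj in seq_len(n2)) for (ci in seq_len(n1)) {
    base <- c(2L * ci - 1L, 2L * cj - 1L, 2L * ck - 1L)
    cidx <- integer(8)
    gpos <- matrix(0L, 8, 3)
    for (v in 1:8) {
      gpos[v, ] <- base + 2L * co[v, ]
      cidx[v] <- idx(gpos[v, 1], gpos[v, 2], gpos[v, 3])
    }
    for (tt in seq_len(6)) {
      cs <- tets[tt, ]
      p <- gpos[cs, , drop = FALSE]
      mid <- function(a, b) {
        m <- (p[a, ] + p[b, ]) %/% 2L
        idx(m[1], m[2], m[3])
      }
      e <- e + 1L
      elems[e, ] <- c(cidx[cs[1]], cidx[cs[2]], cidx[cs[3]], cidx[cs[4]],
                      mid(1, 2), mid(2, 3), mid(3, 1),
                      mid(1, 4), mid(2, 4), mid(3, 4))
    }
  }
  fix_orientation3d(list(nodes = nodes, elems = elems))
}

fix_orientation3d <- function(patch) {
  nd <- patch$nodes; el <- patch$elems
  v <- function(i) nd[el[, i], , drop = FALSE]
  a <- v(1); b <- v(2) - a; cc <- v(3) - a; d <- v(4) - a
  det6 <- b[, 1] * (cc[, 2] * d[, 3] - cc[, 3] * d[, 2]) -
    b[, 2] * (cc[, 1] * d[, 3] - cc[, 3] * d[, 1]) +
    b[, 3] * (cc[, 1] * d[, 2] - cc[, 2] * d[, 1])
  flip <- det6 < 0
  if (any(flip))
    el[flip, ] <- el[flip, c(1, 3, 2, 4, 7, 6, 5, 8, 10, 9), drop = FALSE]
  list(nodes = nd, elems = el)
}

#' Element reference measures and Jacobian check
#'
#' @param mesh An `rt_mesh`.
#' @return A list with per-element `volume` (area in 2D, mm^2; volume in 3D,
#'   mm^3) and `minJ`, the minimum quadrature-point Jacobian determinant.
#' @export
mesh_measure <- function(mesh) {
  stopifnot(inherits(mesh, "rt_mesh"))
  fem_measure_cpp(mesh$nodes, mesh$elems)
}

#' Validate mesh invariants
#'
#' Checks positive Jacobians at every quadrature point, exactly one region
#' label per element, and that all facet sets lie on the mesh boundary.
#'
#' @param mesh An `rt_mesh`.
#' @return `TRUE` invisibly; errors with diagnostics otherwise.
#' @export
check_mesh <- function(mesh) {
  m <- mesh_measure(mesh)
  if (any(m$minJ <= 0))
    stop("inverted element(s): ", paste(head(which(m$minJ <= 0)), collapse = ", "))
  if (anyNA(mesh$region) || any(!nzchar(mesh$region)))
    stop("every element must carry exactly one region label")
  if (length(mesh$facets)) {
    bnd <- if (mesh$dim == 2) boundary_edges(mesh$elems)
           else boundary_faces(mesh$nodes, mesh$elems)
    bkey <- apply(bnd[, seq_len(mesh$dim), drop = FALSE], 1,
                  function(r) paste(sort(r), collapse = " "))
    for (fs in names(mesh$facets)) {
      fmat <- mesh$facets[[fs]]
      if (!nrow(fmat)) next
      fkey <- apply(fmat[, seq_len(mesh$dim), drop = FALSE], 1,
                    function(r) paste(sort(r), collapse = " "))
      if (!all(fkey %in% bkey))
        stop("facet set '", fs, "' contains non-boundary facets")
    }
  }
  invisible(TRUE)
}

# Element-to-element adjacency (shared nodes) as an adjacency list; used by
# the contiguous region-summary selection.
element_adjacency <- function(elems) {
  ne <- nrow(elems)
  node2el <- split(rep(seq_len(ne), ncol(elems)), as.vector(elems))
  adj <- vector("list", ne)
  for (els in node2el) {
    if (length(els) < 2) next
    for (e in els) adj[[e]] <- c(adj[[e]], els)
  }
  lapply(adj, function(v) sort(unique(v)))
}

element_centroids <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems
  nc <- if (mesh$dim == 2) 3 else 4
  ctr <- 0
  for (i in seq_len(nc)) ctr <- ctr + nd[el[, i], , drop = FALSE]
  ctr / nc
}
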