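# 3D quadratic-tetrahedral shell meshes built on cube-sphere mappings
# (degeneracy-free at the poles). Used for the spherical-shell volume check
# and the thick-walled inflation verification benchmark.

cube_panels <- function(octant = FALSE) {
  if (octant) {
    # three faces of the unit-cube corner at the origin; normalized points
    # cover the +++ octant with lateral boundaries on the coordinate planes
    list(function(u, v) c(1, u, v),
         function(u, v) c(u, 1, v),
         function(u, v) c(u, v, 1))
  } else {
    list(function(u, v) c(1, 2 * u - 1, 2 * v - 1),
         function(u, v) c(-1, 2 * u - 1, 2 * v - 1),
         function(u, v) c(2 * u - 1, 1, 2 * v - 1),
         function(u, v) c(2 * u - 1, -1, 2 * v - 1),
         function(u, v) c(2 * u - 1, 2 * v - 1, 1),
         function(u, v) c(2 * u - 1, 2 * v - 1, -1))
  }
}

#' Quadratic-tetrahedral mesh of a spherical shell
#'
#' Cube-sphere construction: each cube panel is mapped radially onto the
#' sphere, extruded through the (possibly direction-dependent) thickness and
#' split into 10-node tetrahedra. With `octant = TRUE` only the x,y,z >= 0
#' octant is meshed, with lateral faces lying exactly on the coordinate
#' planes — the configuration used for the pressurized-sphere benchmark
#' under symmetry (roller) conditions.
#'
#' @param outer_radius Outer radius (mm).
#' @param thickness Constant thickness (mm) or a function of the unit
#'   direction vector returning thickness.
#' @param n Panel subdivisions per edge.
#' @param nr Radial subdivisions.
#' @param octant Mesh only the positive octant?
#' @return An `rt_mesh` with region `"shell"`, facet sets `inner_surface` and
#'   `outer_surface`, and (octant mode) node sets `sym_x`, `sym_y`, `sym_z`.
#' @export
sphere_shell_mesh <- function(outer_radius = 12, thickness = 1, n = 4, nr = 2,
                              octant = FALSE) {
  tfun <- if (is.function(thickness)) thickness else function(dir) thickness
  panels <- cube_panels(octant)
  patches <- lapply(panels, function(pan) {
    map <- function(s, t, r) {
      p <- pan(s, t)
      dir <- p / sqrt(sum(p^2))
      th <- tfun(dir)
      ((outer_radius - th) + r * th) * dir
    }
    p <- tet10_patch(map, n, n, nr)
    list(nodes = p$nodes, elems = p$elems, region = "shell")
  })
  mg <- merge_patches(patches)
  faces <- boundary_faces(mg$nodes, mg$elems)
  # classify by the corner nodes, which sit exactly on the mapped surfaces
  crad <- t(vapply(seq_len(nrow(faces)), function(i)
    sqrt(rowSums(mg$nodes[faces[i, 1:3], , drop = FALSE]^2)), numeric(3)))
  rad <- rowMeans(crad)
  ctr <- t(vapply(seq_len(nrow(faces)),
                  function(i) colMeans(mg$nodes[faces[i, 1:3], , drop = FALSE]),
                  numeric(3)))
  tmid <- vapply(seq_len(nrow(ctr)),
                 function(i) tfun(ctr[i, ] / sqrt(sum(ctr[i, ]^2))), numeric(1))
  is_outer <- rad > outer_radius - 1e-6 * outer_radius
  is_inner <- rad < outer_radius - tmid + 1e-6 * outer_radius
  on_plane <- function(k) vapply(seq_len(nrow(faces)), function(i)
    max(abs(mg$nodes[faces[i, 1:3], k])) < 1e-7 * outer_radius, logical(1))
  lateral <- if (octant) (on_plane(1) | on_plane(2) | on_plane(3)) else FALSE
  facets <- list(inner_surface = faces[is_inner & !lateral, , drop = FALSE],
                 outer_surface = faces[is_outer & !lateral, , drop = FALSE])
  node_sets <- list()
  if (octant) {
    for (k in 1:3) {
      nm <- paste0("sym_", c("x", "y", "z")[k])
      node_sets[[nm]] <- which(abs(mg$nodes[, k]) < 1e-7 * outer_radius)
    }
  }
  rt_mesh(mg$nodes, mg$elems, mg$region, facets = facets,
          node_sets = node_sets)
}

#' Inflation of an incompressible hyperelastic spherical shell (closed form)
#'
#' Independent quadrature oracle for the pressure-inflation relation of a
#' thick-walled, incompressible one-term (neo-Hookean, `mu = 2 C10`) sphere:
#' integrates `dP = 2 mu (lambda^2 - lambda^-4) / (lambda (1 - lambda^3))
#' dlambda` through the wall, with `lambda = r/R` and
#' `r^3 = R^3 + a^3 - A^3`.
#'
#' @param C10 Material constant (MPa).
#' @param A,B Inner and outer reference radii (mm).
#' @param a Deformed inner radius (mm).
#' @return Internal pressure (MPa).
#' @export
sphere_inflation_pressure <- function(C10, A, B, a) {
  mu <- 2 * C10
  lam_a <- a / A
  b3 <- B^3 + a^3 - A^3
  lam_b <- b3^(1 / 3) / B
  if (abs(lam_a - lam_b) < 1e-14) return(0)
  f <- function(lam) 2 * mu * (lam^2 - lam^-4) / (lam * (1 - lam^3))
  stats::integrate(f, lam_a, lam_b, rel.tol = 1e-10)$value
}
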