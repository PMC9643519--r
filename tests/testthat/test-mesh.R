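# Mesh generation: element validity, region tagging, facet sets,
# refinement behaviour, and the 3D shell primitives against a quadrature
# oracle.

geom <- build_geometry()
mesh <- generate_mesh(geom) # default density, shared across tests

test_that("cross-section mesh satisfies its invariants", {
  m <- mesh_measure(mesh)
  expect_true(all(m$minJ > 0))
  expect_true(all(nzchar(mesh$region)))
  expect_true(check_mesh(mesh))
  expect_setequal(unique(mesh$region),
                  c("anterior_sclera", "equatorial_sclera", "posterior_sclera",
                    "peripapillary_sclera", "lamina_cribrosa",
                    "on_homogenized", "on_sheath"))
})

test_that("facet sets lie on the boundary and are where they should be", {
  for (fs in c("inner_scleral_surface", "csf_gap", "sheath_outer"))
    expect_gt(nrow(mesh$facets[[fs]]), 0)
  # inner surface midpoints are at or below the LC inner radius
  im <- mesh$facets$inner_scleral_surface
  mid <- (mesh$nodes[im[, 1], ] + mesh$nodes[im[, 2], ]) / 2
  expect_true(all(sqrt(rowSums(mid^2)) <= geom$lc_r_in + 1e-3))
  # CSF facets sit outside the globe, along the nerve/sheath complex
  cg <- mesh$facets$csf_gap
  midc <- (mesh$nodes[cg[, 1], ] + mesh$nodes[cg[, 2], ]) / 2
  expect_true(all(sqrt(rowSums(midc^2)) >= geom$R_out - 1e-3))
})

test_that("node sets capture the anterior shell and the apex", {
  expect_gt(length(mesh$node_sets$anterior_rotation_set), 20)
  phi <- geom$phi_of(atan2(mesh$nodes[, 1], mesh$nodes[, 2]))
  expect_true(all(phi[mesh$node_sets$anterior_rotation_set] <= pi / 3 + 1e-9))
  expect_true(all(mesh$nodes[mesh$node_sets$apex_fixed_set, 2] >= 41 - 1e-9))
  expect_identical(mesh$node_sets$symmetry_plane, integer(0))
})

test_that("region partition of the shell is exhaustive and exclusive", {
  # every shell element centroid classifies to its own stored label
  ctr <- (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
            mesh$nodes[mesh$elems[, 3], ]) / 3
  shell_regions <- c("anterior_sclera", "equatorial_sclera",
                     "posterior_sclera", "peripapillary_sclera")
  idx <- which(mesh$region %in% shell_regions)
  relabel <- vapply(idx, function(e) classify_region(ctr[e, ], geom, tol = 0.05),
                    character(1))
  expect_identical(relabel, mesh$region[idx])
})

test_that("halving the target edge length strictly increases element count", {
  m2 <- generate_mesh(geom, list(fine = 0.45, coarse = 3.5))
  expect_gt(nrow(mesh$elems), nrow(m2$elems))
  expect_gt(nrow(mesh$nodes), nrow(m2$nodes))
})

test_that("degenerate mesher inputs are rejected", {
  expect_error(generate_mesh(geom, list(fine = -1, coarse = 2)), "positive")
  expect_error(generate_mesh(geom, list(fine = 3, coarse = 1)),
               "finest edge length")
  expect_error(generate_mesh(geom, mode = "3d"), "cross-section")
})

test_that("3D spherical shell volume matches the quadrature oracle", {
  tf <- function(dir) {
    phi <- acos(pmin(pmax(dir[3], -1), 1))
    0.4 + 0.6 * phi / pi
  }
  m3 <- sphere_shell_mesh(12, tf, n = 8, nr = 2)
  expect_true(all(mesh_measure(m3)$minJ > 0))
  v_mesh <- sum(mesh_measure(m3)$volume)
  # independent oracle: numerical quadrature of the exact shell volume
  f <- function(phi) {
    t <- 0.4 + 0.6 * phi / pi
    (12^3 - (12 - t)^3) / 3 * sin(phi) * 2 * pi
  }
  v_exact <- stats::integrate(f, 0, pi, rel.tol = 1e-10)$value
  expect_lt(abs(v_mesh - v_exact) / v_exact, 0.02)
})

test_that("octant shell exposes symmetry-plane node sets on coordinate planes", {
  mo <- sphere_shell_mesh(10, 2, n = 3, nr = 2, octant = TRUE)
  for (k in 1:3) {
    ns <- mo$node_sets[[paste0("sym_", c("x", "y", "z")[k])]]
    expect_gt(length(ns), 10)
    expect_true(all(abs(mo$nodes[ns, k]) < 1e-6))
  }
  expect_gt(nrow(mo$facets$inner_surface), 0)
  expect_gt(nrow(mo$facets$outer_surface), 0)
})

test_that("solution and summaries are invariant under element reordering", {
  perm <- rev(seq_len(nrow(mesh$elems)))
  m2 <- rt_mesh(mesh$nodes, mesh$elems[perm, ], mesh$region[perm],
                facets = mesh$facets, node_sets = mesh$node_sets,
                landmarks = mesh$landmarks)
  mats <- list(blk = rp_params(0.3, D = 0.1))
  mats <- setNames(rep(mats, length(unique(mesh$region))), unique(mesh$region))
  u <- numeric(nrow(mesh$nodes) * 2)
  bcs <- boundary_condition_set(pressures = c(inner_scleral_surface = 10))
  a1 <- assemble(mesh, mats, u, bcs, want_tangent = FALSE)
  a2 <- assemble(m2, mats, u, bcs, want_tangent = FALSE)
  expect_equal(a2$residual, a1$residual, tolerance = 1e-13)
})
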