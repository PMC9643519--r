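# Scalar field extraction, the contiguous region-summary rule, LC edge
# displacement, and field export round-trips.

test_that("von Mises identities: hydrostatic, uniaxial, shear, rotation", {
  expect_equal(von_mises(diag(c(5, 5, 5))), 0)
  s <- 3.7
  expect_equal(von_mises(diag(c(s, 0, 0))), s)
  tau <- 1.3
  sh <- matrix(0, 3, 3); sh[1, 2] <- sh[2, 1] <- tau
  expect_equal(von_mises(sh), sqrt(3) * tau)
  set.seed(5)
  for (i in 1:10) {
    S <- crossprod(matrix(rnorm(9), 3))
    R <- random_rotation3()
    expect_equal(von_mises(R %*% S %*% t(R)), von_mises(S), tolerance = 1e-10)
  }
  expect_error(von_mises(matrix(rnorm(9), 3)), "symmetric")
})

test_that("maximum principal strain: zero, uniaxial log stretch, ordering", {
  expect_equal(max_principal_strain(diag(0, 3)), 0)
  lam <- 1.23
  # logarithmic strain of a uniaxial incompressible stretch
  E <- diag(c(log(lam), -log(lam) / 2, -log(lam) / 2))
  expect_equal(max_principal_strain(E), log(lam))
  ev <- max_principal_strain(diag(c(0.1, -0.3, 0.25)), all = TRUE)
  expect_identical(ev, sort(ev, decreasing = TRUE))
  expect_error(max_principal_strain(matrix(rnorm(9), 3)), "symmetric")
})

test_that("the summary rule enforces the 12-16 element window", {
  expect_error(summary_rule(k = 11), "12-16")
  expect_error(summary_rule(k = 17), "12-16")
  expect_error(summary_rule(aggregation = "max"), "mean")
  expect_identical(summary_rule()$k, 14L)
})

# a tiny synthetic solution on a structured block for summary tests
block_solution <- function(n = 6, vm_values = NULL) {
  tp <- ontether:::tri6_patch(function(s, t) c(s, t), n, n)
  mesh <- rt_mesh(tp$nodes, tp$elems, rep("blk", nrow(tp$elems)),
                  landmarks = list(corner = c(0, 0)))
  ne <- nrow(mesh$elems)
  stress <- matrix(0, ne, 6)
  if (is.null(vm_values)) vm_values <- rep(2.5, ne)
  stress[, 1] <- vm_values # uniaxial: von Mises equals the value
  sol <- structure(list(u = numeric(nrow(mesh$nodes) * 2), stress = stress,
                        logstrain = matrix(0, ne, 6), J = rep(1, ne),
                        volume = rep(1, ne), log = NULL, mesh = mesh),
                   class = "solution_state")
  sol
}

test_that("a spatially uniform field summarizes to that value for any k", {
  sol <- block_solution(6)
  for (k in c(12L, 14L, 16L))
    expect_equal(region_summary(sol, summary_rule(k), c(0.5, 0.5), "stress"),
                 2500) # 2.5 MPa -> kPa
})

test_that("summary is the mean of the k nearest contiguous elements", {
  # values equal to the element index; pick 12 hand-verified nearest the
  # corner landmark of a 6x6 block and compare with the selection the rule
  # makes (deterministic: distance order, ties by index)
  sol <- block_solution(6, vm_values = seq_len(72))
  sel <- ontether:::select_contiguous(sol$mesh, summary_rule(12), c(0, 0))
  expect_length(sel, 12)
  # contiguity: each selected element shares a node with another
  adj <- ontether:::element_adjacency(sol$mesh$elems)
  for (e in sel[-1]) expect_true(length(intersect(adj[[e]], sel)) > 1)
  expect_equal(region_summary(sol, summary_rule(12), c(0, 0), "stress"),
               mean(sel) * 1000)
})

test_that("region smaller than k instructs mesh refinement", {
  sol <- block_solution(2) # 8 elements only
  expect_error(region_summary(sol, summary_rule(12), c(0, 0)), "refine")
})

test_that("LC edge displacement: zero field, rigid translation, rotation", {
  geom <- build_geometry()
  mesh <- generate_mesh(geom, list(fine = 0.45, coarse = 3.5))
  ndof <- nrow(mesh$nodes) * 2
  zero <- structure(list(u = numeric(ndof), mesh = mesh),
                    class = "solution_state")
  d0 <- lc_edge_displacement(zero, mesh)
  expect_equal(c(d0$nasal_um, d0$posterior_um), c(0, 0))
  # rigid translation (a, b) mm -> (1000 a, 1000 b) um in the orbit frame
  a <- 0.12; b <- -0.07
  tr <- zero
  tr$u <- as.numeric(t(cbind(rep(a, nrow(mesh$nodes)), rep(b, nrow(mesh$nodes)))))
  dt <- lc_edge_displacement(tr, mesh, frame = "orbit")
  expect_equal(c(dt$nasal_um, dt$posterior_um), c(1000 * a, 1000 * b))
  # a rigid 6-degree rotation of the whole mesh equals the rotation-matrix
  # displacement in the orbit frame and vanishes in the globe frame
  R <- adduction_rotation(6)
  disp <- mesh$nodes %*% t(R) - mesh$nodes
  rot <- zero; rot$u <- as.numeric(t(disp))
  lmn <- mesh$landmarks$lc_temporal_edge
  nid <- which.min(colSums((t(mesh$nodes) - lmn)^2))
  dr <- lc_edge_displacement(rot, mesh, frame = "orbit")
  expect_equal(c(dr$nasal_um, dr$posterior_um), 1000 * disp[nid, ],
               tolerance = 1e-9)
  dg <- lc_edge_displacement(rot, mesh, adduction_deg = 6, frame = "globe")
  expect_equal(c(dg$nasal_um, dg$posterior_um), c(0, 0), tolerance = 1e-9)
})

test_that("VTU export round-trips displacements bitwise and fields recompute", {
  geom <- build_geometry()
  mesh <- generate_mesh(geom, list(fine = 0.45, coarse = 3.5))
  set.seed(9)
  ne <- nrow(mesh$elems)
  sol <- structure(list(
    u = rnorm(nrow(mesh$nodes) * 2, 0, 0.01),
    stress = matrix(rnorm(ne * 6), ne, 6),
    logstrain = matrix(rnorm(ne * 6, 0, 0.01), ne, 6),
    J = rep(1, ne), volume = rep(1, ne), log = NULL, mesh = mesh),
    class = "solution_state")
  sol$stress[, 4:6] <- sol$stress[, 4:6] / 2 # keep shear symmetric-scaled
  tf <- tempfile(fileext = ".vtu")
  export_fields(sol, mesh, tf)
  back <- read_vtu(tf)
  U <- displacement_field(sol)
  expect_identical(back$point_data$displacement[, 1:2], U)
  expect_identical(back$elems, unname(mesh$elems))
  expect_identical(back$region, mesh$region)
  # exported von Mises recomputes from the exported stress to 1e-10
  expect_equal(back$cell_data$von_mises, von_mises(back$cell_data$stress),
               tolerance = 1e-10)
  expect_error(export_fields(sol, mesh, file.path(tempdir(), "no/such/dir/x.vtu")),
               "cannot write")
})

test_that("MSH export round-trips nodes, connectivity and regions", {
  geom <- build_geometry()
  mesh <- generate_mesh(geom, list(fine = 0.45, coarse = 3.5))
  tf <- tempfile(fileext = ".msh")
  write_msh(mesh, tf)
  back <- read_msh(tf)
  expect_identical(back$nodes, unname(mesh$nodes))
  expect_identical(back$elems, unname(mesh$elems))
  expect_identical(back$region, mesh$region)
  # 3D meshes round-trip through the gmsh tet10 node-order permutation
  m3 <- sphere_shell_mesh(10, 2, n = 2, nr = 1, octant = TRUE)
  tf3 <- tempfile(fileext = ".msh")
  write_msh(m3, tf3)
  b3 <- read_msh(tf3)
  expect_identical(b3$elems, unname(m3$elems))
  expect_true(all(mesh_measure(b3)$minJ > 0))
})
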