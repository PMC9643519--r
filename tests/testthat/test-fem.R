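# Solver verification: reference equilibrium, consistent linearization,
# linear patch test, follower pressure properties, rigid-body objectivity,
# and the thick-walled sphere inflation benchmark against the closed-form
# oracle.

square_mesh <- function(n = 4) {
  tp <- ontether:::tri6_patch(function(s, t) c(s, t), n, n)
  bnd <- ontether:::boundary_edges(tp$elems)
  rt_mesh(tp$nodes, tp$elems, rep("blk", nrow(tp$elems)),
          facets = list(all = bnd),
          node_sets = list(boundary = sort(unique(as.vector(bnd)))))
}

blk <- list(blk = rp_params(C = c(0.3, 0.05), D = c(0.1, NA)))

test_that("zero displacement and zero loads give an exactly zero residual", {
  m <- square_mesh(3)
  a <- assemble(m, blk, numeric(nrow(m$nodes) * 2), boundary_condition_set(),
                want_tangent = FALSE)
  expect_identical(max(abs(a$residual)), 0)
})

test_that("assembled tangent matches finite differences, pressure included", {
  set.seed(2)
  m <- square_mesh(3)
  bcs <- boundary_condition_set(pressures = c(all = 8))
  u0 <- rnorm(nrow(m$nodes) * 2, 0, 1e-3)
  a0 <- assemble(m, blk, u0, bcs)
  h <- 1e-7
  for (j in sample(length(u0), 10)) {
    up <- u0; up[j] <- up[j] + h
    um <- u0; um[j] <- um[j] - h
    fd <- (assemble(m, blk, up, bcs, want_tangent = FALSE)$residual -
             assemble(m, blk, um, bcs, want_tangent = FALSE)$residual) / (2 * h)
    expect_equal(as.numeric(a0$tangent[, j]), fd, tolerance = 1e-4)
  }
})

test_that("linear patch test: uniform strain reproduced to machine precision", {
  m <- square_mesh(4)
  A <- matrix(c(1e-3, 4e-4, -2e-4, 5e-4), 2, 2)
  bn <- m$node_sets$boundary
  vals <- m$nodes[bn, ] %*% t(A)
  dir <- data.frame(node = rep(bn, 2), dof = rep(1:2, each = length(bn)),
                    value = c(vals[, 1], vals[, 2]))
  sol <- solve_fem(m, blk, boundary_condition_set(dirichlet = dir),
                   solve_schedule(increments = 1))
  U <- displacement_field(sol)
  expect_lt(max(abs(U - m$nodes %*% t(A))), 1e-13)
  # constant stress field: spread across elements at roundoff level
  expect_lt(max(apply(sol$stress, 2, function(cc) diff(range(cc)))), 1e-12)
})

test_that("zero pressure yields a zero load vector", {
  m <- square_mesh(2)
  expect_identical(max(abs(apply_pressure(m, "all", 0))), 0)
})

test_that("pressure on a closed surface has vanishing net resultant", {
  ann <- ontether:::tri6_patch(function(s, t) {
    th <- 2 * pi * s; r <- 1 + t
    c(r * cos(th), r * sin(th))
  }, 48, 2)
  mg <- ontether:::merge_patches(list(c(ann, list(region = "blk"))))
  bnd <- ontether:::boundary_edges(mg$elems)
  mid <- (mg$nodes[bnd[, 1], ] + mg$nodes[bnd[, 2], ]) / 2
  inner <- bnd[sqrt(rowSums(mid^2)) < 1.5, ]
  m <- rt_mesh(mg$nodes, mg$elems, mg$region, facets = list(inner = inner))
  f <- apply_pressure(m, "inner", 10)
  p <- mmHg_to_MPa(10)
  net <- c(sum(f[c(TRUE, FALSE)]), sum(f[c(FALSE, TRUE)]))
  expect_lt(sqrt(sum(net^2)), 1e-8 * p * 2 * pi * 1)
})

test_that("a single flat facet carries pressure x length along the normal", {
  # one straight edge of the unit square: y = 0, outward normal (0, -1)
  m <- square_mesh(2)
  bnd <- m$facets$all
  mid <- (m$nodes[bnd[, 1], ] + m$nodes[bnd[, 2], ]) / 2
  bottom <- bnd[abs(mid[, 2]) < 1e-12, , drop = FALSE]
  m$facets$bottom <- bottom
  f <- apply_pressure(m, "bottom", 20)
  p <- mmHg_to_MPa(20)
  fx <- sum(f[c(TRUE, FALSE)]); fy <- sum(f[c(FALSE, TRUE)])
  expect_equal(fx, 0, tolerance = 1e-14)
  expect_equal(fy, p * 1, tolerance = 1e-12) # -p * n = -p * (0,-1): pushes up
})

test_that("prescribed adduction is a rigid rotation of the constrained set", {
  m <- square_mesh(3)
  m$node_sets$anterior_rotation_set <- m$node_sets$boundary
  d <- prescribe_adduction(m, 37, center = c(0.2, 0.4))
  X <- m$nodes[m$node_sets$boundary, ]
  disp <- cbind(d$value[d$dof == 1], d$value[d$dof == 2])
  Y <- X + disp
  # pairwise distances preserved to near machine precision
  i <- seq_len(min(12, nrow(X)))
  dx <- as.matrix(dist(X[i, ])); dy <- as.matrix(dist(Y[i, ]))
  expect_lt(max(abs(dx - dy)), 1e-12)
  # positive adduction carries a node on the -z side toward +x (nasally)
  mref <- rt_mesh(matrix(c(12, 0), 1), matrix(rep(1L, 6), 1), "blk",
                  node_sets = list(anterior_rotation_set = 1L))
  d6 <- prescribe_adduction(mref, 6)
  R <- adduction_rotation(6)
  expect_equal(c(d6$value[1] + 12, d6$value[2]),
               as.numeric(R %*% c(12, 0)), tolerance = 1e-14)
})

test_that("no loads and no rotation give identically zero solution", {
  m <- square_mesh(2)
  sol <- solve_fem(m, blk, boundary_condition_set(
    dirichlet = data.frame(node = m$node_sets$boundary[1:2], dof = 1, value = 0)),
    solve_schedule(increments = 1))
  expect_identical(max(abs(sol$u)), 0)
  expect_lt(max(abs(sol$stress)), 1e-14)
})

test_that("prescribed rigid rotation of the whole boundary leaves the body
          stress-free (discrete objectivity)", {
  m <- square_mesh(4)
  m$node_sets$anterior_rotation_set <- m$node_sets$boundary
  sol <- solve_fem(m, blk, boundary_condition_set(
    rotation = list(set = "anterior_rotation_set", angle_deg = 10,
                    center = c(0.5, 0.5))),
    solve_schedule(increments = seq(0.25, 1, 0.25)))
  expect_lt(max(abs(sol$stress)), 1e-6)
})

test_that("thick-walled incompressible sphere inflation matches the
          closed-form pressure-inflation oracle within 2%", {
  A <- 8; B <- 10; C10 <- 0.2
  a_target <- 8.8
  P <- sphere_inflation_pressure(C10, A, B, a_target)
  mo <- sphere_shell_mesh(B, B - A, n = 3, nr = 2, octant = TRUE)
  dir <- rbind(
    data.frame(node = mo$node_sets$sym_x, dof = 1, value = 0),
    data.frame(node = mo$node_sets$sym_y, dof = 2, value = 0),
    data.frame(node = mo$node_sets$sym_z, dof = 3, value = 0))
  bcs <- boundary_condition_set(
    dirichlet = dir, pressures = c(inner_surface = P / mmHg_to_MPa(1)))
  sol <- solve_fem(mo, list(shell = rp_params(C10)), bcs,
                   solve_schedule(increments = seq(0.1, 1, 0.1), tol = 1e-7,
                                  pressure_ramp = 1))
  U <- displacement_field(sol)
  rad <- sqrt(rowSums(mo$nodes^2))
  inner <- which(rad < A + 1e-6)
  ur <- rowSums(U[inner, ] * mo$nodes[inner, ]) / rad[inner]
  expect_lt(abs(mean(ur) - (a_target - A)) / (a_target - A), 0.02)
})

test_that("solver diagnostics: unknown sets and malformed schedules", {
  m <- square_mesh(2)
  expect_error(apply_pressure(m, "nope", 5), "unknown facet set")
  expect_error(prescribe_adduction(m, 5, set = "nope"), "unknown node set")
  expect_error(solve_schedule(increments = c(0.5, 0.2)), "increasing")
  expect_error(solve_schedule(tol = -1), "positive")
  expect_error(solve_schedule(pressure_ramp = 0), "pressure_ramp")
})
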