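# Reduced-polynomial hyperelasticity: energies, stresses, tangents, and the
# closed-form uniaxial response, verified against independent oracles
# (direct polynomial evaluation, finite differences, small-strain limits).

test_that("strain energy vanishes at the undeformed state for every card", {
  st <- deformation_state(diag(3))
  for (nm in names(all_rp_cards())) {
    expect_identical(strain_energy_density(all_rp_cards()[[nm]], st), 0,
                     label = nm)
    expect_equal(max(abs(cauchy_stress(all_rp_cards()[[nm]], st))), 0,
                 tolerance = 1e-14, label = nm)
  }
})

test_that("single-term incompressible energy matches hand evaluation", {
  p <- rp_params(C = 0.5)
  # uniaxial stretch 2: Ibar1 = 4 + 2/2 = 5, U = 0.5 * (5 - 3) = 1
  st <- deformation_state(F_uniaxial(2))
  expect_equal(strain_energy_density(p, st), 1.0, tolerance = 1e-12)
})

test_that("posterior sclera average energy matches direct polynomial oracle", {
  card <- material_card(ont_lib, "posterior_sclera", "average")
  lam <- 1.05
  # independent oracle: evaluate the polynomial sum directly from the
  # invariants of the incompressible uniaxial path
  x <- lam^2 + 2 / lam - 3
  U_oracle <- sum(card$C * x^seq_along(card$C)) # J = 1: volumetric terms zero
  st <- deformation_state(F_uniaxial(lam))
  expect_equal(strain_energy_density(card, st), U_oracle, tolerance = 1e-12)
})

test_that("invalid deformation states are rejected", {
  expect_error(deformation_state(diag(c(1, 1, -1))), "positive")
  expect_error(deformation_state(matrix(NA_real_, 3, 3)), "finite")
  expect_error(rp_params(C = numeric(0)), "order N")
  expect_error(rp_params(C = rep(0.1, 7)), "order N")
  expect_error(rp_params(C = -1), "C_10")
  expect_error(rp_params(C = 0.5, D = -0.1), "D_i")
})

test_that("energy is objective: U(RF) = U(F) for random rotations", {
  set.seed(42)
  card <- material_card(ont_lib, "on_sheath", "average")
  for (i in 1:20) {
    F <- random_F(0.1)
    R <- random_rotation3()
    u1 <- strain_energy_density(card, deformation_state(F))
    u2 <- strain_energy_density(card, deformation_state(R %*% F))
    expect_equal(u2, u1, tolerance = 1e-10)
  }
})

test_that("Cauchy stress vanishes for pure rotations and is symmetric", {
  set.seed(7)
  for (nm in c("posterior_sclera average", "peripapillary_sclera compliant")) {
    card <- all_rp_cards()[[nm]]
    R <- random_rotation3()
    s <- cauchy_stress(card, deformation_state(R))
    expect_lt(max(abs(s)), 1e-10)
    F <- random_F(0.08)
    sig <- cauchy_stress(card, deformation_state(F))
    expect_equal(sig, t(sig), tolerance = 1e-12)
  }
})

test_that("PK1 stress matches finite differences of the energy", {
  set.seed(11)
  h <- 1e-6
  for (nm in names(all_rp_cards())) {
    card <- all_rp_cards()[[nm]]
    F <- random_F(0.04, J_target = 1.001)
    P <- pk1_stress(card, deformation_state(F))
    Pfd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      Pfd[i, j] <- (strain_energy_density(card, deformation_state(Fp)) -
                      strain_energy_density(card, deformation_state(Fm))) / (2 * h)
    }
    expect_equal(P, Pfd, tolerance = 1e-5, label = nm)
  }
})

test_that("material tangent matches finite differences of the stress", {
  set.seed(13)
  h <- 1e-6
  for (nm in c("anterior_sclera average", "posterior_sclera stiff",
               "on_connective compliant", "lamina_cribrosa average")) {
    card <- all_rp_cards()[[nm]]
    F <- random_F(0.03, J_target = 1.002)
    A <- material_tangent(card, deformation_state(F))
    for (k in 1:3) for (L in 1:3) {
      Fp <- F; Fp[k, L] <- Fp[k, L] + h
      Fm <- F; Fm[k, L] <- Fm[k, L] - h
      dP <- (pk1_stress(card, deformation_state(Fp)) -
               pk1_stress(card, deformation_state(Fm))) / (2 * h)
      expect_equal(A[, , k, L], dP, tolerance = 1e-4, label = nm)
    }
  }
})

test_that("tangent has the major symmetry of a hyperelastic potential", {
  set.seed(17)
  card <- material_card(ont_lib, "posterior_sclera")
  for (i in 1:5) {
    A <- material_tangent(card, deformation_state(random_F(0.05)))
    M <- matrix(A, 9, 9) # (i,J) x (k,L) flattening
    expect_equal(M, t(M), tolerance = 1e-10)
  }
})

test_that("tangent at identity reduces to isotropic linear elasticity", {
  C10 <- 0.4; D1 <- 0.05
  p <- rp_params(C = C10, D = D1)
  mu <- 2 * C10; kappa <- 2 / D1
  A <- material_tangent(p, deformation_state(diag(3)))
  expect_equal(A[1, 1, 1, 1], kappa + 4 / 3 * mu, tolerance = 1e-12)
  expect_equal(A[1, 1, 2, 2], kappa - 2 / 3 * mu, tolerance = 1e-12)
  expect_equal(A[1, 2, 1, 2], mu, tolerance = 1e-12)
})

test_that("uniaxial nominal stress: reference state, finite-difference and
          neo-Hookean slope oracles", {
  expect_identical(uniaxial_nominal_stress(rp_params(0.3), 1), 0)
  expect_error(uniaxial_nominal_stress(rp_params(0.3), -1), "domain")
  h <- 1e-6
  for (nm in names(all_rp_cards())) {
    card <- all_rp_cards()[[nm]]
    for (lam in c(1.02, 1.05, 1.1)) {
      # oracle: central finite difference of the energy along the
      # incompressible uniaxial path
      Up <- strain_energy_density(card, deformation_state(F_uniaxial(lam + h)))
      Um <- strain_energy_density(card, deformation_state(F_uniaxial(lam - h)))
      expect_equal(uniaxial_nominal_stress(card, lam), (Up - Um) / (2 * h),
                   tolerance = 1e-6, label = paste(nm, lam))
    }
    # small-strain Young's modulus of the incompressible one-term limit:
    # dP/dlambda at 1 equals 6 C10 plus nothing from higher-order terms
    slope <- (uniaxial_nominal_stress(card, 1 + h) -
                uniaxial_nominal_stress(card, 1 - h)) / (2 * h)
    expect_equal(slope, 6 * card$C[1], tolerance = 1e-4, label = nm)
  }
})

test_that("stiff cards lie above compliant cards over the fitted range", {
  lam <- seq(1.02, 1.08, by = 0.005)
  for (region in c("posterior_sclera", "peripapillary_sclera", "on_sheath",
                   "on_connective")) {
    Ps <- uniaxial_nominal_stress(material_card(ont_lib, region, "stiff"), lam)
    Pc <- uniaxial_nominal_stress(material_card(ont_lib, region, "compliant"), lam)
    expect_true(all(Ps > Pc), label = region)
  }
})

test_that("linear-elastic conversion preserves the small-strain moduli", {
  le <- le_params(E = 0.001195, nu = 0.48)
  rp <- as_rp_params(le)
  mu <- le$E / (2 * (1 + le$nu))
  expect_equal(2 * rp$C[1], mu, tolerance = 1e-14)
  expect_equal(2 * rp$K[1], le$E / (3 * (1 - 2 * le$nu)), tolerance = 1e-14)
  expect_error(le_params(E = -1, nu = 0.3), "E must be")
  expect_error(le_params(E = 1, nu = 0.5), "nu must be")
})
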