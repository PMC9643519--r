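# Case definitions, the sensitivity matrix machinery, and scenario
# composition/determinism properties.

test_that("labels A-H expand exactly per the sensitivity matrix", {
  expand <- function(lbl) {
    cs <- case_spec(lbl)
    c(cs$posterior, cs$peripapillary, cs$sheath)
  }
  expect_identical(expand("A"), c("stiff", "stiff", "stiff"))
  expect_identical(expand("B"), c("stiff", "stiff", "compliant"))
  expect_identical(expand("C"), c("stiff", "compliant", "stiff"))
  expect_identical(expand("D"), c("stiff", "compliant", "compliant"))
  expect_identical(expand("E"), c("compliant", "stiff", "stiff"))
  expect_identical(expand("F"), c("compliant", "stiff", "compliant"))
  expect_identical(expand("G"), c("compliant", "compliant", "stiff"))
  expect_identical(expand("H"), c("compliant", "compliant", "compliant"))
  avg <- case_spec("average")
  expect_identical(c(avg$posterior, avg$peripapillary, avg$sheath, avg$on),
                   rep("average", 4))
  expect_error(case_spec("Z"), "valid labels")
})

test_that("case materials pull the right stiffness level per region", {
  mats <- make_case_materials(case_spec("G"), ont_lib)
  expect_identical(mats$posterior_sclera$label, "posterior_sclera compliant")
  expect_identical(mats$peripapillary_sclera$label, "peripapillary_sclera compliant")
  expect_identical(mats$on_sheath$label, "on_sheath stiff")
  expect_identical(mats$anterior_sclera$label, "anterior_sclera average")
  expect_s3_class(mats$on_neural, "le_params")
})

test_that("load-case validation", {
  expect_error(load_case(iop = -1), "non-negative")
  expect_error(load_case(adduction_deg = -2), "non-negative")
  expect_error(run_matrix(cases = c("average", "A", "A")), "duplicate")
  expect_error(run_matrix(cases = character(0)), "nonempty")
})

test_that("degenerate case (no pressures, no rotation) is stress-free", {
  b <- run_case(load_case(iop = 0, icp = 0, adduction_deg = 0),
                library = ont_lib,
                target_edge_length = list(fine = 0.45, coarse = 3.5))
  expect_true(all(abs(b$summaries$stress_kPa) < 1e-8))
  expect_true(all(abs(b$summaries$strain_pct) < 1e-8))
  expect_equal(c(b$lc_nasal_um, b$lc_posterior_um), c(0, 0), tolerance = 1e-8)
})

test_that("the default matrix holds the average case plus A-H", {
  mat <- get_case_matrix()
  expect_s3_class(mat, "results_matrix")
  expect_identical(names(mat), c("average", LETTERS[1:8]))
  for (nm in names(mat))
    expect_s3_class(mat[[nm]], "results_bundle")
  df <- as.data.frame(mat)
  expect_identical(nrow(df), 9L * 6L)
  expect_true(all(df$error == ""))
})

test_that("a rerun with identical inputs reproduces the summaries exactly", {
  mat <- get_case_matrix()
  again <- run_case("average", library = ont_lib)
  expect_identical(again$summaries, mat$average$summaries)
  expect_identical(c(again$lc_nasal_um, again$lc_posterior_um),
                   c(mat$average$lc_nasal_um, mat$average$lc_posterior_um))
})

test_that("ON variants reuse one mesh and compose like plain run_case calls", {
  vr <- get_on_variants()
  expect_identical(names(vr), c("compliant", "average", "stiff"))
  # controlled comparison: identical meshes across the three variants
  expect_identical(vr$compliant$mesh$nodes, vr$stiff$mesh$nodes)
  expect_identical(vr$compliant$mesh$elems, vr$stiff$mesh$elems)
  # composition: the compliant variant equals a direct run with the same
  # custom case spec on the same mesh
  cs <- case_spec("custom", posterior = "stiff", peripapillary = "stiff",
                  sheath = "compliant", on = "compliant")
  direct <- run_case(load_case(cs), library = ont_lib, mesh = vr$compliant$mesh)
  expect_identical(direct$summaries[, c("stress_kPa", "strain_pct")],
                   vr$compliant$summaries[, c("stress_kPa", "strain_pct")])
})

test_that("pressure scenarios return the four tethering x pressure bundles", {
  pr <- get_pressure_scenarios()
  expect_setequal(names(pr), c("pressure_only_normal", "pressure_only_extreme",
                               "tether_normal", "tether_extreme"))
  expect_false(pr$pressure_only_extreme$case$tethering)
  expect_true(pr$tether_extreme$case$tethering)
  expect_equal(pr$tether_extreme$case$iop, 40)
  expect_equal(pr$tether_extreme$case$icp, 4)
})

test_that("equal pressures on both LC faces leave the lamina nearly unloaded
          relative to a translaminar gradient", {
  # no rotation, IOP = ICP: the LC sees balanced pressure on its two faces
  mesh <- generate_mesh(build_geometry())
  bal <- run_case(load_case(iop = 10, icp = 10, tethering = FALSE),
                  library = ont_lib, mesh = mesh)
  grad <- run_case(load_case(iop = 40, icp = 4, tethering = FALSE),
                   library = ont_lib, mesh = mesh)
  rule <- summary_rule(12, "lamina_cribrosa")
  vm_bal <- region_summary(bal$solution, rule, "lc_temporal_edge", "stress")
  vm_grad <- region_summary(grad$solution, rule, "lc_temporal_edge", "stress")
  expect_lt(vm_bal, 0.35 * vm_grad)
})
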