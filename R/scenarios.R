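# The experiment grid: the average model, the eight-case stiff/compliant
# sensitivity matrix over {posterior sclera, peripapillary sclera, ON
# sheath}, pressure scenarios (normal vs extreme translaminar gradient,
# with and without tethering), and the ON-stiffness variants.

#' Case specification
#'
#' The sensitivity matrix varies three regions between their 95th-percentile
#' ("stiff") and 5th-percentile ("compliant") behaviours, all other regions
#' pinned to average. Labels A-H expand as: posterior sclera stiff for A-D
#' and compliant for E-H; (peripapillary, sheath) cycling (stiff, stiff),
#' (stiff, compliant), (compliant, stiff), (compliant, compliant) within
#' each block.
#'
#' @param label `"average"`, one of `"A"`-`"H"`, or `"custom"`.
#' @param posterior,peripapillary,sheath,on Stiffness levels for a custom
#'   case (ignored for the named labels, except `on`, which may vary
#'   independently of the lettered matrix).
#' @return An object of class `case_spec` with per-region stiffness levels.
#' @export
#' @examples
#' case_spec("A") # stiff posterior + peripapillary sclera and sheath
case_spec <- function(label = "average", posterior = "average",
                      peripapillary = "average", sheath = "average",
                      on = "average") {
  lv <- c("average", "stiff", "compliant")
  stopifnot(posterior %in% lv, peripapillary %in% lv, sheath %in% lv, on %in% lv)
  if (label %in% LETTERS[1:8]) {
    i <- match(label, LETTERS[1:8])
    posterior <- if (i <= 4) "stiff" else "compliant"
    pp_sh <- list(c("stiff", "stiff"), c("stiff", "compliant"),
                  c("compliant", "stiff"), c("compliant", "compliant"))[[
                    (i - 1) %% 4 + 1]]
    peripapillary <- pp_sh[1]
    sheath <- pp_sh[2]
  } else if (!label %in% c("average", "custom")) {
    stop("unknown case label '", label, "'; valid labels: average, ",
         paste(LETTERS[1:8], collapse = ", "), ", custom")
  }
  structure(list(label = label, posterior = posterior,
                 peripapillary = peripapillary, sheath = sheath, on = on),
            class = "case_spec")
}

#' @export
print.case_spec <- function(x, ...) {
  cat(sprintf("Case %s: posterior=%s, peripapillary=%s, sheath=%s, ON=%s\n",
              x$label, x$posterior, x$peripapillary, x$sheath, x$on))
  invisible(x)
}

#' Per-region material assignment for a case
#'
#' @param case A [case_spec()].
#' @param library A [load_material_library()] result.
#' @return Named list mapping every canonical region to its card.
#' @export
make_case_materials <- function(case, library) {
  stopifnot(inherits(case, "case_spec"))
  list(
    anterior_sclera = material_card(library, "anterior_sclera"),
    equatorial_sclera = material_card(library, "equatorial_sclera"),
    posterior_sclera = material_card(library, "posterior_sclera", case$posterior),
    peripapillary_sclera = material_card(library, "peripapillary_sclera",
                                         case$peripapillary),
    on_sheath = material_card(library, "on_sheath", case$sheath),
    lamina_cribrosa = material_card(library, "lamina_cribrosa"),
    on_connective = material_card(library, "on_connective", case$on),
    on_neural = material_card(library, "on_neural"))
}

#' Load case: a complete simulation scenario
#'
#' @param case A [case_spec()] (or a case label string).
#' @param iop Intraocular pressure, mmHg (vitreous side).
#' @param icp Intracranial pressure, mmHg (CSF side).
#' @param adduction_deg Adduction increment beyond the tethering threshold,
#'   degrees.
#' @param tethering If `FALSE` the rotation is suppressed (pressure-only
#'   run).
#' @return An object of class `on_load_case`.
#' @export
load_case <- function(case = case_spec("average"), iop = 15, icp = 10,
                      adduction_deg = 6, tethering = TRUE) {
  if (is.character(case)) case <- case_spec(case)
  stopifnot(inherits(case, "case_spec"))
  if (iop < 0 || icp < 0) stop("pressures must be non-negative")
  if (adduction_deg < 0) stop("adduction increment must be non-negative")
  structure(list(case = case, iop = iop, icp = icp,
                 adduction_deg = adduction_deg, tethering = isTRUE(tethering)),
            class = "on_load_case")
}

# canonical summary locations of a ResultsBundle (all on the temporal side)
bundle_rules <- function(k = 14L) {
  list(
    disc_junction_temporal = list(
      rule = summary_rule(k, c("lamina_cribrosa", "on_homogenized",
                               "peripapillary_sclera")),
      landmark = "junction_temporal"),
    disc_junction_nasal = list(
      rule = summary_rule(k, c("lamina_cribrosa", "on_homogenized",
                               "peripapillary_sclera")),
      landmark = "junction_nasal"),
    peripapillary_temporal = list(
      rule = summary_rule(k, "peripapillary_sclera"),
      landmark = "pp_temporal"),
    sheath_sclera_junction = list(
      rule = summary_rule(k, c("on_sheath", "peripapillary_sclera")),
      landmark = "sheath_junction_temporal"),
    retrolaminar_neural = list(
      rule = summary_rule(k, "on_homogenized"),
      landmark = "retrolaminar"),
    on_sheath = list(
      rule = summary_rule(k, "on_sheath"),
      landmark = "sheath_mid_temporal"))
}

#' Run one load case
#'
#' Meshes the geometry (or reuses a supplied mesh), assigns the case's
#' material cards (the ON interior homogenized by the rule of mixtures),
#' solves the quasi-static equilibrium, and summarizes: von Mises stress
#' (kPa) and maximum principal strain (%) at the canonical temporal-side
#' locations, and the LC temporal-edge displacement (um, globe frame).
#'
#' @param case An [load_case()] (or a [case_spec()], or a label).
#' @param config An [ocular_geometry_config()].
#' @param library A material library (loaded from the packaged cards if
#'   omitted).
#' @param mesh Optional pre-built mesh (for controlled comparisons).
#' @param target_edge_length Mesh density, see [generate_mesh()].
#' @param schedule Newton/load-stepping controls; the default ramps the
#'   pressures over the first half of ten increments.
#' @param k Summary-rule element count.
#' @return A `results_bundle`.
#' @export
run_case <- function(case, config = ocular_geometry_config(), library = NULL,
                     mesh = NULL,
                     target_edge_length = list(fine = 0.25, coarse = 2.2),
                     schedule = NULL, k = 14L) {
  if (is.character(case) || inherits(case, "case_spec")) case <- load_case(case)
  stopifnot(inherits(case, "on_load_case"))
  if (is.null(library)) library <- load_material_library()
  if (is.null(schedule))
    schedule <- solve_schedule(increments = seq(0.1, 1, 0.1),
                               pressure_ramp = 0.5)
  geom <- build_geometry(config)
  if (is.null(mesh)) mesh <- generate_mesh(geom, target_edge_length)
  mats <- make_case_materials(case$case, library)
  mats$on_homogenized <- homogenize_on(mats$on_connective, mats$on_neural,
                                       config$on_connective_fraction)
  rot <- if (case$tethering && case$adduction_deg > 0)
    list(set = "anterior_rotation_set", angle_deg = case$adduction_deg,
         center = c(0, 0)) else NULL
  fixed <- "apex_fixed_set"
  if (is.null(rot)) fixed <- c(fixed, "anterior_rotation_set")
  bcs <- boundary_condition_set(
    fixed_sets = fixed, rotation = rot,
    pressures = c(inner_scleral_surface = case$iop, csf_gap = case$icp,
                  sheath_outer = case$icp))
  sol <- tryCatch(solve_fem(mesh, mats, bcs, schedule),
                  error = function(e)
                    stop("case ", case$case$label, ": ", conditionMessage(e),
                         call. = FALSE))
  rules <- bundle_rules(k)
  summaries <- do.call(rbind, lapply(names(rules), function(nm) {
    r <- rules[[nm]]
    data.frame(location = nm,
               stress_kPa = region_summary(sol, r$rule, r$landmark, "stress"),
               strain_pct = region_summary(sol, r$rule, r$landmark, "strain"))
  }))
  add <- if (case$tethering) case$adduction_deg else 0
  lc <- lc_edge_displacement(sol, mesh, adduction_deg = add)
  structure(list(case = case, summaries = summaries,
                 lc_nasal_um = lc$nasal_um, lc_posterior_um = lc$posterior_um,
                 solution = sol, mesh = mesh),
            class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("Results, case", x$case$case$label,
      sprintf("(IOP %g / ICP %g mmHg, %s%g deg)\n", x$case$iop, x$case$icp,
              if (x$case$tethering) "adduction " else "no tethering, ",
              x$case$adduction_deg))
  df <- x$summaries
  df$stress_kPa <- round(df$stress_kPa, 1)
  df$strain_pct <- round(df$strain_pct, 2)
  print(df, row.names = FALSE)
  cat(sprintf("LC temporal edge (globe frame): %+.0f um nasal, %+.0f um posterior\n",
              x$lc_nasal_um, x$lc_posterior_um))
  invisible(x)
}

#' Summary value accessor
#'
#' @param bundle A `results_bundle`.
#' @param location One of the canonical summary locations.
#' @param field `"stress"` (kPa) or `"strain"` (percent).
#' @return Scalar.
#' @export
bundle_value <- function(bundle, location, field = c("stress", "strain")) {
  field <- match.arg(field)
  i <- match(location, bundle$summaries$location)
  if (is.na(i)) stop("unknown summary location '", location, "'")
  bundle$summaries[[if (field == "stress") "stress_kPa" else "strain_pct"]][i]
}

#' Run the sensitivity case matrix
#'
#' One bundle per case; per-case failures are isolated (reported in the
#' result, not aborting the matrix). All cases share one mesh, so runs
#' differ only in material cards.
#'
#' @param cases Character vector of case labels (default the average case
#'   plus A-H).
#' @inheritParams run_case
#' @return Named list of `results_bundle` (or `try-error`) objects, class
#'   `results_matrix`.
#' @export
run_matrix <- function(cases = c("average", LETTERS[1:8]),
                       config = ocular_geometry_config(), library = NULL,
                       target_edge_length = list(fine = 0.25, coarse = 2.2),
                       schedule = NULL, k = 14L) {
  if (!length(cases)) stop("nonempty case list required")
  if (anyDuplicated(cases)) stop("duplicate case labels")
  if (is.null(library)) library <- load_material_library()
  mesh <- generate_mesh(build_geometry(config), target_edge_length)
  out <- lapply(cases, function(lbl)
    tryCatch(run_case(lbl, config, library, mesh = mesh,
                      target_edge_length = target_edge_length,
                      schedule = schedule, k = k),
             error = function(e) e))
  names(out) <- cases
  structure(out, class = "results_matrix")
}

#' Tabulate a results matrix
#'
#' @param x A `results_matrix`.
#' @param ... Unused.
#' @return Data frame: one row per case and summary location, with the LC
#'   edge displacement columns repeated per case.
#' @export
as.data.frame.results_matrix <- function(x, ...) {
  rows <- lapply(names(x), function(lbl) {
    b <- x[[lbl]]
    if (inherits(b, "error"))
      return(data.frame(case = lbl, location = NA, stress_kPa = NA,
                        strain_pct = NA, lc_nasal_um = NA, lc_posterior_um = NA,
                        error = conditionMessage(b)))
    cbind(case = lbl, b$summaries, lc_nasal_um = b$lc_nasal_um,
          lc_posterior_um = b$lc_posterior_um, error = "")
  })
  do.call(rbind, rows)
}

#' Pressure scenarios: tethering and translaminar gradient
#'
#' Four runs for one material case: with and without the adduction rotation,
#' each at normal pressures (IOP 15 / ICP 10 mmHg) and at the extreme
#' translaminar gradient (IOP 40 / ICP 4 mmHg).
#'
#' @inheritParams run_case
#' @param normal,extreme Length-2 vectors `c(iop, icp)` in mmHg.
#' @return Named list of four `results_bundle`s:
#'   `pressure_only_normal`, `pressure_only_extreme`, `tether_normal`,
#'   `tether_extreme`.
#' @export
run_pressure_scenarios <- function(case = case_spec("average"),
                                   config = ocular_geometry_config(),
                                   library = NULL,
                                   normal = c(15, 10), extreme = c(40, 4),
                                   target_edge_length = list(fine = 0.25, coarse = 2.2),
                                   schedule = NULL, k = 14L) {
  if (is.character(case)) case <- case_spec(case)
  if (is.null(library)) library <- load_material_library()
  mesh <- generate_mesh(build_geometry(config), target_edge_length)
  one <- function(p, tether)
    run_case(load_case(case, iop = p[1], icp = p[2], tethering = tether),
             config, library, mesh = mesh, schedule = schedule, k = k)
  list(pressure_only_normal = one(normal, FALSE),
       pressure_only_extreme = one(extreme, FALSE),
       tether_normal = one(normal, TRUE),
       tether_extreme = one(extreme, TRUE))
}

#' ON-stiffness variants
#'
#' Reruns a base case (default the least favorable combination, Case B)
#' with compliant, average and stiff ON connective tissue on one shared
#' mesh, optionally adding the extreme-pressure variant of the stiff ON.
#'
#' @inheritParams run_case
#' @param base_case Case label or `case_spec` whose other regions are held.
#' @param extreme_pressure_stiff Also run the stiff-ON case at IOP 40 /
#'   ICP 4 mmHg?
#' @return Named list of `results_bundle`s (`compliant`, `average`,
#'   `stiff`, and optionally `stiff_extreme_pressure`).
#' @export
run_on_stiffness_variants <- function(base_case = "B",
                                      config = ocular_geometry_config(),
                                      library = NULL,
                                      extreme_pressure_stiff = FALSE,
                                      target_edge_length = list(fine = 0.25, coarse = 2.2),
                                      schedule = NULL, k = 14L) {
  if (is.character(base_case)) base_case <- case_spec(base_case)
  if (is.null(library)) library <- load_material_library()
  mesh <- generate_mesh(build_geometry(config), target_edge_length)
  variant <- function(level) {
    cs <- case_spec("custom", posterior = base_case$posterior,
                    peripapillary = base_case$peripapillary,
                    sheath = base_case$sheath, on = level)
    cs$label <- paste0(base_case$label, "_on_", level)
    cs
  }
  out <- lapply(c(compliant = "compliant", average = "average", stiff = "stiff"),
                function(lv) run_case(load_case(variant(lv)), config, library,
                                      mesh = mesh, schedule = schedule, k = k))
  if (extreme_pressure_stiff)
    out$stiff_extreme_pressure <- run_case(
      load_case(variant("stiff"), iop = 40, icp = 4), config, library,
      mesh = mesh, schedule = schedule, k = k)
  out
}
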