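# Parametric geometry of the adducted eye-optic nerve complex.
#
# Model frame: origin at the globe centre; +z runs from the globe centre
# toward the orbital apex (the orbital axis of the 26-degree adducted pose,
# taken as the stress-free reference); +x is nasal; +y superior (the
# hemi-symmetry normal). The 2D cross-section mode works in the (x, z)
# horizontal plane. Adduction increments rotate the anterior sclera about
# +y so that the cornea moves nasally.
#
# Angular bookkeeping (signed disc angles u, measured from +z toward +x):
# at the tethering threshold the visual axis has adducted by
# `initial_adduction` from primary gaze while the orbital axis stays put at
# `apex_axis_to_medial_wall_angle` nasal of the sagittal plane, so the optic
# disc centre sits at
#   u_disc = -(apex_angle + initial_adduction - fovea_disc_angle)
# (about -31 degrees: temporal of the apex axis), and the straight ON runs
# obliquely from there to the apex point (0, apex_distance). This offset is
# what lets ON tension pull the disc nasally during further adduction. The
# posterior geometric pole sits a further (fovea_disc_angle - angle_kappa)
# temporal of the disc.

#' Ocular geometry configuration
#'
#' All printed anatomical dimensions defining the 26-degree-adducted
#' reference configuration in which the ON has just straightened (zero
#' slack, zero pretension).
#'
#' @param globe_diameter Globe (outer scleral) diameter, mm.
#' @param scleral_thickness_equator Scleral thickness at the equator, mm.
#' @param scleral_thickness_posterior_pole Thickness at the posterior pole, mm.
#' @param peripapillary_radius Geodesic radius of the peripapillary annulus
#'   measured from the optic disc centre along the shell, mm.
#' @param lc_diameter,lc_thickness Lamina cribrosa diameter and thickness, mm.
#' @param on_diameter_anterior,on_diameter_posterior ON diameter at the globe
#'   and at the orbital apex, mm (gradual taper between).
#' @param sheath_thickness,csf_thickness ON sheath and cerebrospinal-fluid
#'   gap thicknesses, mm.
#' @param apex_distance Globe centre to orbital apex, mm.
#' @param apex_axis_to_medial_wall_angle Angle between the centre-apex line
#'   and the medial orbital wall (taken parallel to the sagittal plane),
#'   degrees.
#' @param angle_kappa Angle between visual and pupillary axis, degrees.
#' @param fovea_disc_angle Angle between fovea and optic disc, degrees.
#' @param initial_adduction Adduction angle of the reference pose, degrees.
#' @param on_connective_fraction Connective-tissue volume fraction of the ON
#'   interior (9:16 connective:neural area ratio gives 9/25).
#' @param anterior_zone_deg,equatorial_zone_deg Polar angles (from the
#'   corneal pole) bounding the anterior and equatorial scleral zones.
#' @param canal_thickness Scleral thickness at the scleral canal rim, mm.
#' @param canal_taper_width Width of the annulus over which the shell thins
#'   toward the canal, mm.
#' @return An object of class `ocular_geometry_config`.
#' @export
ocular_geometry_config <- function(globe_diameter = 24,
                                   scleral_thickness_equator = 0.4,
                                   scleral_thickness_posterior_pole = 1.0,
                                   peripapillary_radius = 4,
                                   lc_diameter = 1.8,
                                   lc_thickness = 0.3,
                                   on_diameter_anterior = 4,
                                   on_diameter_posterior = 3.5,
                                   sheath_thickness = 0.74,
                                   csf_thickness = 0.59,
                                   apex_distance = 41,
                                   apex_axis_to_medial_wall_angle = 22,
                                   angle_kappa = 5,
                                   fovea_disc_angle = 17,
                                   initial_adduction = 26,
                                   on_connective_fraction = 9 / 25,
                                   anterior_zone_deg = 60,
                                   equatorial_zone_deg = 120,
                                   canal_thickness = 0.5,
                                   canal_taper_width = 1.0) {
  cfg <- as.list(environment())
  lens <- c("globe_diameter", "scleral_thickness_equator",
            "scleral_thickness_posterior_pole", "peripapillary_radius",
            "lc_diameter", "lc_thickness", "on_diameter_anterior",
            "on_diameter_posterior", "sheath_thickness", "csf_thickness",
            "apex_distance", "canal_thickness", "canal_taper_width")
  for (f in lens)
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      stop("construction error: ", f, " must be a positive length")
  if (cfg$lc_diameter >= cfg$on_diameter_anterior)
    stop("construction error: lc_diameter must be smaller than on_diameter_anterior")
  if (cfg$on_connective_fraction <= 0 || cfg$on_connective_fraction > 1)
    stop("construction error: on_connective_fraction must be in (0, 1]")
  structure(cfg, class = "ocular_geometry_config")
}

#' Read / write a geometry configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_geometry_config`, an `ocular_geometry_config`.
#' @export
read_geometry_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(ocular_geometry_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown geometry field(s): ", paste(unknown, collapse = ", "))
  do.call(ocular_geometry_config, vals)
}

#' @rdname read_geometry_config
#' @param config An `ocular_geometry_config`.
#' @export
write_geometry_config <- function(config, path) {
  stopifnot(inherits(config, "ocular_geometry_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build the parametric solid geometry
#'
#' Derives, from the configuration, the boundary representation of the
#' adducted eye-ON complex: the spherical scleral shell with its
#' equator-to-pole thickness interpolation and canal-rim thinning, the
#' lamina cribrosa cap plugging the scleral canal (posterior surface flush
#' with the scleral outer sphere), the tapered ON running straight from the
#' (temporally displaced) disc to the apex point on the +z axis, the sheath
#' tube anchored to the peripapillary sclera and the apex, and the
#' pressurized CSF gap between them. Returns the derived angles and the
#' closed-form boundary functions that the mesher and the point classifier
#' share.
#'
#' @param config An [ocular_geometry_config()].
#' @return An object of class `on_geometry`.
#' @export
#' @examples
#' geom <- build_geometry(ocular_geometry_config())
#' geom$R_out # globe outer radius, 12 mm
build_geometry <- function(config = ocular_geometry_config()) {
  stopifnot(inherits(config, "ocular_geometry_config"))
  R <- config$globe_diameter / 2
  if (config$apex_distance <= R + 2)
    stop("construction error: apex_distance must clear the globe (apex inside or too close)")
  deg <- pi / 180
  u_disc <- -(config$apex_axis_to_medial_wall_angle + config$initial_adduction -
                config$fovea_disc_angle) * deg
  delta <- (config$fovea_disc_angle - config$angle_kappa) * deg
  u_pole <- u_disc - delta          # posterior geometric pole
  u_cornea <- u_pole + pi           # corneal pole (nasal-anterior)
  theta_canal <- asin(config$lc_diameter / 2 / R)
  theta_on <- asin(config$on_diameter_anterior / 2 / R)
  x_sheath_in <- config$on_diameter_anterior / 2 + config$csf_thickness
  x_sheath_out <- x_sheath_in + config$sheath_thickness
  if (x_sheath_out >= R * sin(pi / 3))
    stop("construction error: sheath overlaps the equatorial sclera (sheath too wide for the globe)")
  theta_sheath_in <- asin(x_sheath_in / R)
  theta_sheath_out <- asin(x_sheath_out / R)
  if (config$lc_thickness >= config$canal_thickness + 0.35)
    stop("construction error: lamina cribrosa thicker than the canal-rim shell can seat")

  wrap_pi <- function(u) ((u + pi) %% (2 * pi)) - pi
  # polar angle from the corneal pole of a signed disc angle u
  phi_of <- function(u) abs(wrap_pi(u - u_cornea))
  # geodesic angle from the disc centre
  dtheta <- function(u) abs(wrap_pi(u - u_disc))
  t_eq <- config$scleral_thickness_equator
  t_pole <- config$scleral_thickness_posterior_pole
  thickness <- function(u) {
    phi <- phi_of(u)
    t <- ifelse(phi > pi / 2, t_eq + (t_pole - t_eq) * (phi - pi / 2) / (pi / 2),
                t_eq)
    # linear taper to the canal-rim thickness over the adjacent annulus
    d <- (dtheta(u) - theta_canal) * R
    w <- config$canal_taper_width
    tc <- config$canal_thickness
    ifelse(d < w, tc + (t - tc) * pmax(d, 0) / w, t)
  }
  inner_radius <- function(u) R - thickness(u)

  zs <- config$apex_distance
  disc_pos <- R * c(sin(u_disc), cos(u_disc))
  # ON centreline: the straight tether from disc centre to apex
  on_center_x <- function(z) {
    disc_pos[1] * (zs - z) / (zs - disc_pos[2])
  }
  w_ant <- config$on_diameter_anterior
  w_post <- config$on_diameter_posterior
  on_halfwidth <- function(z) {
    s <- pmin(pmax((z - disc_pos[2]) / (zs - disc_pos[2]), 0), 1)
    (w_ant + (w_post - w_ant) * s) / 2
  }
  # sheath boundary lines: from the scleral attachment arc to the apex
  # cross-section, per side (+1 nasal, -1 temporal)
  x_apex_in <- w_post / 2 + config$csf_thickness
  x_apex_out <- x_apex_in + config$sheath_thickness
  sheath_x <- function(z, side, which = c("inner", "outer")) {
    which <- match.arg(which)
    th <- if (which == "inner") theta_sheath_in else theta_sheath_out
    xa <- if (which == "inner") x_apex_in else x_apex_out
    u0 <- u_disc + side * th
    p0 <- R * c(sin(u0), cos(u0))
    p0[1] + (side * xa - p0[1]) * (z - p0[2]) / (zs - p0[2])
  }
  structure(list(
    config = config, R_out = R, delta = delta, u_disc = u_disc,
    u_pole = u_pole, u_cornea = u_cornea,
    theta_canal = theta_canal, theta_on = theta_on,
    theta_sheath_in = theta_sheath_in, theta_sheath_out = theta_sheath_out,
    apex = c(0, zs), disc_pos = disc_pos,
    phi_of = phi_of, dtheta = dtheta, thickness = thickness,
    inner_radius = inner_radius, on_center_x = on_center_x,
    on_halfwidth = on_halfwidth, sheath_x = sheath_x,
    lc_r_in = R - config$lc_thickness
  ), class = "on_geometry")
}

#' @export
print.on_geometry <- function(x, ...) {
  cat("Adducted eye-ON geometry (stress-free at",
      x$config$initial_adduction, "deg adduction)\n")
  cat(sprintf("  globe outer radius %.1f mm, apex at %.0f mm, disc at %.1f deg (temporal of apex axis)\n",
              x$R_out, x$apex[2], x$u_disc * 180 / pi))
  cat(sprintf("  canal half-angle %.2f deg, ON attachment %.2f deg, sheath band %.2f-%.2f deg\n",
              x$theta_canal * 180 / pi, x$theta_on * 180 / pi,
              x$theta_sheath_in * 180 / pi, x$theta_sheath_out * 180 / pi))
  invisible(x)
}

#' Classify a point into a tissue region
#'
#' Deterministic single-label classification. The scleral shell is
#' partitioned into the peripapillary annulus (geodesic distance from the
#' disc centre below `peripapillary_radius`) and, by polar angle from the
#' corneal pole, anterior (< `anterior_zone_deg`), equatorial and posterior
#' zones. In cross-section mode the ON interior carries the single
#' homogenized label `on_homogenized`.
#'
#' @param point Numeric length-2 (x, z) or length-3 (x, y, z) point, mm. A
#'   3D point is reduced rotationally about the shell's disc axis.
#' @param geometry An `on_geometry`.
#' @param tol Geometric tolerance, mm.
#' @return Region label string.
#' @export
#' @examples
#' geom <- build_geometry()
#' classify_region(geom$disc_pos * 0.985, geom) # lamina cribrosa interior
classify_region <- function(point, geometry, tol = 1e-6) {
  stopifnot(inherits(geometry, "on_geometry"))
  point <- as.numeric(point)
  if (length(point) == 3) {
    # reduce to the cross-section: shell structures by the 3D angle from the
    # disc axis, nerve/sheath by distance from the oblique ON axis
    p <- point
    d3 <- c(sin(geometry$u_disc), 0, cos(geometry$u_disc))
    a3 <- c(0, 0, geometry$apex[2])
    disc3 <- geometry$R_out * d3
    r3 <- sqrt(sum(p^2))
    axis <- a3 - disc3
    t_ax <- sum((p - disc3) * axis) / sum(axis^2)
    z_eq <- disc3[3] + t_ax * axis[3]
    rho <- sqrt(sum((p - (disc3 + t_ax * axis))^2))
    if (r3 <= geometry$R_out + tol) {
      # inside the globe radius: shell or LC; angle from the disc direction
      dth3 <- acos(pmin(pmax(sum(p * d3) / r3, -1), 1))
      point <- c(sin(geometry$u_disc + dth3), cos(geometry$u_disc + dth3)) * r3
    } else {
      # nerve/sheath territory: place at the equivalent transverse offset
      point <- c(geometry$on_center_x(z_eq) + rho, z_eq)
    }
  }
  x <- point[1]; z <- point[2]
  R <- geometry$R_out
  r <- sqrt(x^2 + z^2)
  u <- atan2(x, z)
  cfg <- geometry$config
  dth <- geometry$dtheta(u)
  # lamina cribrosa: cap plugging the canal
  if (dth <= geometry$theta_canal + tol / R &&
      r >= geometry$lc_r_in - tol && r <= R + tol)
    return("lamina_cribrosa")
  # scleral shell
  if (r <= R + tol && r >= geometry$inner_radius(u) - tol) {
    if (dth * R <= cfg$peripapillary_radius)
      return("peripapillary_sclera")
    phi <- geometry$phi_of(u) * 180 / pi
    if (phi < cfg$anterior_zone_deg) return("anterior_sclera")
    if (phi < cfg$equatorial_zone_deg) return("equatorial_sclera")
    return("posterior_sclera")
  }
  zs <- geometry$apex[2]
  if (r >= R - tol && z <= zs + tol && z >= geometry$disc_pos[2] - 2) {
    dx <- x - geometry$on_center_x(z)
    hw <- geometry$on_halfwidth(z)
    if (abs(dx) <= hw + tol) return("on_homogenized")
    side <- sign(dx)
    xi <- geometry$sheath_x(z, side, "inner")
    xo <- geometry$sheath_x(z, side, "outer")
    if ((x - xi) * side >= -tol && (xo - x) * side >= -tol)
      return("on_sheath")
  }
  stop("classification error: point (", paste(signif(point, 6), collapse = ", "),
       ") lies outside the meshed solid")
}
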