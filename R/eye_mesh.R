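# Cross-section (horizontal symmetry plane) mesh of the eye-ON complex.
# Built from conforming transfinite patches: scleral shell ring (minus the
# canal), lamina cribrosa cap, oblique tapered ON strip, and two sheath
# strips. Shared interface nodes are constructed from identical station
# lists so that patch merging is exact.

# piecewise-linear warp: uniform s in [0,1] over n cells -> station values
pwl_warp <- function(s, stations) {
  n <- length(stations) - 1L
  k <- pmin(pmax(floor(s * n), 0), n - 1L)
  frac <- s * n - k
  stations[k + 1L] + frac * (stations[k + 2L] - stations[k + 1L])
}

# graded cell fractions over [0, 1]: sizes grow geometrically from h0 toward
# h1 (both in physical units over total length L), then are rescaled to fit.
graded_fractions <- function(L, h0, h1, ratio = 1.35) {
  sizes <- c()
  h <- h0
  while (sum(sizes) < L) {
    sizes <- c(sizes, min(h, h1))
    h <- h * ratio
  }
  sizes <- sizes * (L / sum(sizes))
  cumsum(c(0, sizes)) / L
}

# symmetric grading: fine at both ends, coarse in the middle
graded_fractions_sym <- function(L, h0, h1, ratio = 1.35) {
  half <- graded_fractions(L / 2, h0, h1, ratio)
  c(half / 2, 1 - rev(half)[-1] / 2)
}

#' Generate the region-tagged quadratic mesh
#'
#' In `"2d"` mode (the analysis default) produces the horizontal
#' cross-section of the eye-ON complex meshed with 6-node plane-strain
#' triangles: conforming scleral ring, lamina cribrosa, homogenized ON
#' strip and sheath strips, with the canonical facet sets
#' (`inner_scleral_surface`, `csf_gap`) and node sets
#' (`anterior_rotation_set`, `apex_fixed_set`, `symmetry_plane` — empty in
#' cross-section mode, where hemi-symmetry is carried by the plane-strain
#' contract itself). Mesh density is finest in the peripapillary / LC / ON
#' junction zone and graded coarse elsewhere.
#'
#' `"3d"` mode is provided for the spherical-shell primitives (see
#' [sphere_shell_mesh()]); the coupled eye-ON assembly is a cross-section
#' model and `"3d"` is rejected for it.
#'
#' @param geometry A [build_geometry()] result.
#' @param target_edge_length List with elements `fine` (edge length around
#'   the optic nerve head, mm) and `coarse` (far-field edge length, mm).
#' @param mode `"2d"` or `"3d"`.
#' @return An `rt_mesh` with per-element region labels, facet sets, node
#'   sets and the summary landmarks.
#' @export
generate_mesh <- function(geometry,
                          target_edge_length = list(fine = 0.25, coarse = 2.2),
                          mode = c("2d", "3d")) {
  stopifnot(inherits(geometry, "on_geometry"))
  mode <- match.arg(mode)
  if (mode == "3d")
    stop("mesher failure (eye assembly): the coupled eye-ON model is meshed ",
         "in 2d cross-section mode; 3d meshing is available for the ",
         "spherical-shell primitives via sphere_shell_mesh()")
  hf <- target_edge_length$fine
  hc <- target_edge_length$coarse
  if (!is.finite(hf) || !is.finite(hc) || hf <= 0 || hc <= 0)
    stop("mesher failure: edge lengths must be positive")
  if (hf > hc)
    stop("mesher failure: the finest edge length belongs to the optic nerve head zone")

  R <- geometry$R_out
  cfg <- geometry$config
  ud <- geometry$u_disc
  thc <- geometry$theta_canal
  tho <- geometry$theta_on
  tsi <- geometry$theta_sheath_in
  tso <- geometry$theta_sheath_out
  zs <- geometry$apex[2]

  # --- station lists (shared between patches for conformity) ---------------
  n_lc <- max(3L, ceiling(cfg$lc_diameter / hf))
  n_ann <- max(2L, ceiling((tho - thc) * R / hf))
  n_mid <- max(1L, ceiling((tsi - tho) * R / hf))
  n_band <- max(2L, ceiling((tso - tsi) * R / hf))
  ann <- seq(thc, tho, length.out = n_ann + 1L)
  mid <- seq(tho, tsi, length.out = n_mid + 1L)
  band <- seq(tsi, tso, length.out = n_band + 1L)
  far_len <- (2 * pi - 2 * tso) * R
  far <- tso + graded_fractions_sym(far_len, 1.5 * hf, hc) * (2 * pi - 2 * tso)
  v_shell <- ud + c(ann, mid[-1], band[-1], far[-1],
                    2 * pi - rev(band)[-1], 2 * pi - rev(mid)[-1],
                    2 * pi - rev(ann)[-1])
  lc_st <- ud + seq(-thc, thc, length.out = n_lc + 1L)

  # --- scleral shell ring (minus canal), 2 radial layers -------------------
  # radial interface fraction chosen so the interface meets the LC inner
  # radius exactly at the canal rim (thickness = canal_thickness there)
  fr_if <- (cfg$canal_thickness - cfg$lc_thickness) / cfg$canal_thickness
  shell_map <- function(s, t) {
    u <- pwl_warp(s, v_shell)
    rin <- geometry$inner_radius(u)
    tt <- pwl_warp(t, c(0, fr_if, 1))
    r <- rin + tt * (R - rin)
    r * c(sin(u), cos(u))
  }
  shell <- tri6_patch(shell_map, length(v_shell) - 1L, 2L)
  shell$region <- "shell"

  # --- lamina cribrosa cap -------------------------------------------------
  lc_map <- function(s, t) {
    u <- pwl_warp(s, lc_st)
    r <- geometry$lc_r_in + t * cfg$lc_thickness
    r * c(sin(u), cos(u))
  }
  lc <- tri6_patch(lc_map, n_lc, 1L)
  lc$region <- "lamina_cribrosa"

  # --- optic nerve strip (oblique tether to the apex) ----------------------
  u_on <- ud + c(-rev(ann), seq(-thc, thc, length.out = n_lc + 1L)[c(-1L, -(n_lc + 1L))], ann)
  z_on0 <- min(R * cos(u_on))
  ax_fr <- graded_fractions(zs - z_on0, hf, hc)
  w_apex <- cfg$on_diameter_posterior / 2
  on_map <- function(s, t) {
    u <- pwl_warp(t, u_on)
    a <- R * c(sin(u), cos(u))
    b <- c(sin(u - ud) / sin(tho) * w_apex, zs)
    sh <- pwl_warp(s, ax_fr)
    (1 - sh) * a + sh * b
  }
  on <- tri6_patch(on_map, length(ax_fr) - 1L, length(u_on) - 1L)
  on$region <- "on_homogenized"

  # --- sheath strips -------------------------------------------------------
  x_apex_in <- w_apex + cfg$csf_thickness
  sheath_patch <- function(side) {
    map <- function(s, t) {
      rel <- pwl_warp(t, band)
      u <- ud + side * rel
      a <- R * c(sin(u), cos(u))
      fr <- (rel - tsi) / (tso - tsi)
      b <- c(side * (x_apex_in + fr * cfg$sheath_thickness), zs)
      sh <- pwl_warp(s, ax_fr)
      (1 - sh) * a + sh * b
    }
    p <- tri6_patch(map, length(ax_fr) - 1L, n_band)
    p$region <- "on_sheath"
    p
  }
  mg <- merge_patches(list(shell, lc, on, sheath_patch(+1), sheath_patch(-1)))

  # --- region labels for the shell ----------------------------------------
  ctr <- (mg$nodes[mg$elems[, 1], ] + mg$nodes[mg$elems[, 2], ] +
            mg$nodes[mg$elems[, 3], ]) / 3
  shell_el <- which(mg$region == "shell")
  for (e in shell_el)
    mg$region[e] <- classify_region(ctr[e, ], geometry, tol = 0.05)

  # --- facet sets ----------------------------------------------------------
  bnd <- boundary_edges(mg$elems)
  bmid <- (mg$nodes[bnd[, 1], , drop = FALSE] + mg$nodes[bnd[, 2], , drop = FALSE]) / 2
  br <- sqrt(rowSums(bmid^2))
  bu <- atan2(bmid[, 1], bmid[, 2])
  bdth <- geometry$dtheta(bu)
  tol <- 1e-6
  inner <- br <= geometry$lc_r_in + 1e-4
  on_arc <- abs(br - R) < 5e-4
  exposed <- on_arc & bdth > tho - 1e-3 & bdth < tsi + 1e-3
  # off-arc facets of the nerve/sheath complex, classified by transverse
  # offset from the ON centreline
  off <- !inner & !on_arc & bmid[, 2] < zs - tol & br > R - 1e-3
  dx <- abs(bmid[, 1] - geometry$on_center_x(bmid[, 2]))
  hw <- geometry$on_halfwidth(bmid[, 2])
  side <- sign(bmid[, 1] - geometry$on_center_x(bmid[, 2]))
  xin <- abs(vapply(seq_along(br), function(i)
    geometry$sheath_x(bmid[i, 2], side[i], "inner") -
      geometry$on_center_x(bmid[i, 2]), numeric(1)))
  xout <- abs(vapply(seq_along(br), function(i)
    geometry$sheath_x(bmid[i, 2], side[i], "outer") -
      geometry$on_center_x(bmid[i, 2]), numeric(1)))
  on_lat <- off & dx <= (hw + xin) / 2
  sh_in <- off & dx > (hw + xin) / 2 & dx < (xin + xout) / 2
  sh_out <- off & dx >= (xin + xout) / 2
  # sheath_outer carries the same ICP as the gap in cross-section mode: the
  # balanced pair stands in for the hoop equilibrium of the 3D dural tube,
  # which a plane strip cannot supply (an unbalanced gap pressure would
  # bow the free sheath span, a plane-model artifact).
  facets <- list(
    inner_scleral_surface = bnd[inner, , drop = FALSE],
    csf_gap = bnd[exposed | on_lat | sh_in, , drop = FALSE],
    sheath_outer = bnd[sh_out, , drop = FALSE])

  # --- node sets -----------------------------------------------------------
  nr <- sqrt(rowSums(mg$nodes^2))
  nu <- atan2(mg$nodes[, 1], mg$nodes[, 2])
  phi <- geometry$phi_of(nu) * 180 / pi
  in_shell <- nr <= R + tol & nr >= geometry$inner_radius(nu) - tol
  node_sets <- list(
    anterior_rotation_set = which(in_shell & phi <= cfg$anterior_zone_deg),
    apex_fixed_set = which(mg$nodes[, 2] >= zs - tol),
    symmetry_plane = integer(0))

  # --- landmarks (temporal side per the reporting convention) --------------
  lcr <- (geometry$lc_r_in + R) / 2
  u_pp <- ud - thc - 1.5 / R
  z_rl <- geometry$disc_pos[2] + 0.9
  z_sm <- geometry$disc_pos[2] + 4
  landmarks <- list(
    lc_temporal_edge = lcr * c(sin(ud - thc), cos(ud - thc)),
    lc_nasal_edge = lcr * c(sin(ud + thc), cos(ud + thc)),
    junction_temporal = R * c(sin(ud - thc), cos(ud - thc)),
    junction_nasal = R * c(sin(ud + thc), cos(ud + thc)),
    pp_temporal = (geometry$inner_radius(u_pp) + R) / 2 * c(sin(u_pp), cos(u_pp)),
    sheath_junction_temporal = R * c(sin(ud - (tsi + tso) / 2),
                                     cos(ud - (tsi + tso) / 2)),
    retrolaminar = c(geometry$on_center_x(z_rl) - 0.45, z_rl),
    sheath_mid_temporal = c((geometry$sheath_x(z_sm, -1, "inner") +
                               geometry$sheath_x(z_sm, -1, "outer")) / 2, z_sm))

  mesh <- rt_mesh(mg$nodes, mg$elems, mg$region, facets = facets,
                  node_sets = node_sets, landmarks = landmarks)
  check_mesh(mesh)
  mesh
}
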