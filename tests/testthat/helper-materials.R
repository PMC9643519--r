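# shared fixtures: the packaged material library and card collections
ont_lib <- load_material_library()

# every hyperelastic card in the library, flat-named
all_rp_cards <- function() {
  out <- list()
  for (r in names(ont_lib)) for (lv in names(ont_lib[[r]])) {
    card <- ont_lib[[r]][[lv]]
    if (inherits(card, "rp_params")) out[[paste(r, lv)]] <- card
  }
  out
}

# uniaxial incompressible deformation gradient
F_uniaxial <- function(lam) diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))

random_rotation3 <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc - a * d), 2 * (b * d + a * cc),
           2 * (b * cc + a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d - a * b),
           2 * (b * d - a * cc), 2 * (cc * d + a * b), a^2 - b^2 - cc^2 + d^2),
         3, 3, byrow = TRUE)
}

# random deformation gradient near a given volume ratio
random_F <- function(scale = 0.05, J_target = NULL) {
  F <- diag(3) + matrix(rnorm(9, 0, scale), 3, 3)
  if (det(F) <= 0.05) F <- diag(3) + 0.1 * (F - diag(3))
  if (!is.null(J_target)) F <- F * (J_target / det(F))^(1 / 3)
  F
}
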