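#' @useDynLib ontether, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats setNames
NULL

#' Unit conversion: mmHg to MPa
#'
#' The package works in a millimetre-MPa-Newton unit system; clinical
#' pressures quoted in mmHg are converted with 1 mmHg = 133.322 Pa.
#'
#' @param p Pressure in mmHg.
#' @return Pressure in MPa.
#' @export
#' @examples
#' mmHg_to_MPa(15) # normal intraocular pressure
mmHg_to_MPa <- function(p) p * 1.33322e-4

#' Reduced-polynomial hyperelastic parameters
#'
#' A single tissue region's strain-energy function at one stiffness level,
#' in the reduced-polynomial (Yeoh-family) form
#' \deqn{U = \sum_{i=1}^{N} C_{i0}(\bar I_1 - 3)^i +
#'           \sum_{i=1}^{N} \frac{1}{D_i}(J - 1)^{2i}}
#' with deviatoric coefficients \eqn{C_{i0}} in MPa and volumetric
#' coefficients \eqn{D_i} in 1/MPa. A missing (`NA`) \eqn{D_i} means the
#' corresponding volumetric term is absent; when \eqn{D_1} itself is absent
#' or zero the material is treated as nearly incompressible through a
#' penalty bulk modulus \eqn{\kappa = 1000\,\mu} with \eqn{\mu = 2 C_{10}}
#' (when \eqn{D_1 > 0}, \eqn{\kappa = 2/D_1}).
#'
#' @param C Numeric vector of deviatoric coefficients `C_{i0}` (MPa),
#'   `i = 1..N`, `1 <= N <= 6`.
#' @param D Numeric vector of volumetric coefficients `D_i` (1/MPa), recycled
#'   or padded with `NA` to length `N`. `NA` or 0 entries mark absent terms.
#' @param label Human-readable label (region and stiffness level).
#'
#' Fitted polynomials are trusted only where their deviatoric tangent
#' stiffness is positive. If the card's `dU/dIbar1` turns negative over
#' some band (possible for 5th-percentile fits evaluated beyond their
#' calibration range), the slope is floored at 5% of its small-strain
#' value across that band (energy continued linearly, resuming the
#' polynomial — shifted for continuity — once it recovers). This keeps the
#' material response stable and single-valued everywhere while leaving the
#' card untouched below the onset `x1`. The band, if any, is stored in the
#' `reg` element as `(x1, x2, slope, shift)`.
#'
#' @return An object of class `rp_params` with elements `N`, `C`, `D`,
#'   `K` (internal volumetric stiffness coefficients, `K_i = 1/D_i` plus the
#'   incompressibility penalty), `reg` (Maxwell band, `numeric(0)` if the
#'   card is stable), and `label`.
#' @export
#' @examples
#' neo <- rp_params(C = 0.5) # one-term, nearly incompressible
#' strain_energy_density(neo, deformation_state(diag(3)))
rp_params <- function(C, D = NULL, label = "") {
  C <- as.numeric(C)
  N <- length(C)
  if (N < 1 || N > 6) stop("parameter error: polynomial order N must be in 1..6")
  if (!is.finite(C[1]) || C[1] <= 0) stop("parameter error: C_10 must be positive")
  if (anyNA(C)) stop("parameter error: deviatoric coefficients must be contiguous (no NA)")
  if (is.null(D)) D <- rep(NA_real_, N)
  D <- as.numeric(D)
  length(D) <- N
  if (any(!is.na(D) & D < 0)) stop("parameter error: D_i must be >= 0")
  K <- ifelse(!is.na(D) & D > 0, 1 / D, 0)
  if (is.na(D[1]) || D[1] == 0) {
    mu <- 2 * C[1]
    K[1] <- 1000 * mu / 2 # kappa/2 with kappa = 1000 mu
  }
  structure(list(N = N, C = C, D = D, K = K,
                 reg = stability_floor(C), label = label),
            class = "rp_params")
}

# dU/dIbar1 of the raw polynomial
rp_slope <- function(C, x) {
  a <- 0
  for (i in seq_along(C)) a <- a + i * C[i] * x^(i - 1)
  a
}

rp_poly <- function(C, x) {
  U <- 0
  for (i in seq_along(C)) U <- U + C[i] * x^i
  U
}

# Stability floor across a softening band of the deviatoric slope
# a(x) = dU/dIbar1: where a(x) would drop below 5% of a(0) = C10, it is held
# at that floor until the polynomial recovers. Returns (x1, x2, slope,
# energy shift) or numeric(0) for cards whose slope stays above the floor
# over the working range (x up to 4, far beyond physiologic strain).
stability_floor <- function(C, frac = 0.05, xmax = 4) {
  a0 <- C[1]
  floor_a <- frac * a0
  xs <- seq(1e-6, xmax, length.out = 4001)
  a <- rp_slope(C, xs)
  low <- which(a < floor_a)
  if (!length(low)) return(numeric(0))
  ilast <- low[length(low)]
  if (ilast == length(xs))
    stop("parameter error: deviatoric stiffness does not recover within the ",
         "working strain range; the card cannot be stabilized")
  x1 <- stats::uniroot(function(x) rp_slope(C, x) - floor_a,
                       c(1e-8, xs[low[1]]), tol = 1e-14)$root
  x2 <- stats::uniroot(function(x) rp_slope(C, x) - floor_a,
                       c(xs[ilast], xmax), tol = 1e-14)$root
  shift <- rp_poly(C, x1) + floor_a * (x2 - x1) - rp_poly(C, x2)
  c(x1 = x1, x2 = x2, aM = floor_a, shift = shift)
}

#' @export
print.rp_params <- function(x, ...) {
  cat("Reduced-polynomial hyperelastic card", if (nzchar(x$label)) paste0("[", x$label, "]"), "\n")
  cat("  N =", x$N, "\n")
  cat("  C_i0 (MPa):", format(x$C, digits = 6), "\n")
  cat("  D_i (1/MPa):", ifelse(is.na(x$D), "-", format(x$D)), "\n")
  invisible(x)
}

#' Linear-elastic parameters
#'
#' Used for the ON neural tissue, the only region the model treats as
#' linearly elastic.
#'
#' @param E Young's modulus (MPa), positive.
#' @param nu Poisson ratio, in `[0, 0.5)`.
#' @param label Optional label.
#' @return An object of class `le_params`.
#' @export
le_params <- function(E, nu, label = "") {
  if (!is.finite(E) || E <= 0) stop("parameter error: E must be positive")
  if (!is.finite(nu) || nu < 0 || nu >= 0.5) stop("parameter error: nu must be in [0, 0.5)")
  structure(list(E = E, nu = nu, label = label), class = "le_params")
}

#' @export
print.le_params <- function(x, ...) {
  cat("Linear-elastic card", if (nzchar(x$label)) paste0("[", x$label, "]"), "\n")
  cat("  E =", x$E, "MPa, nu =", x$nu, "\n")
  invisible(x)
}

#' Convert linear-elastic parameters to an equivalent hyperelastic card
#'
#' Builds the compressible neo-Hookean (one-term reduced-polynomial) card
#' whose small-strain limit reproduces `E` and `nu`: `C_10 = mu/2`,
#' `D_1 = 2/kappa`. This is how the linear neural-tissue card enters the
#' large-deformation solver.
#'
#' @param params An `le_params` object.
#' @return An `rp_params` object.
#' @export
as_rp_params <- function(params) {
  stopifnot(inherits(params, "le_params"))
  mu <- params$E / (2 * (1 + params$nu))
  kappa <- params$E / (3 * (1 - 2 * params$nu))
  rp_params(C = mu / 2, D = 2 / kappa, label = params$label)
}

#' Deformation state
#'
#' Wraps a deformation gradient and its derived invariants: volume ratio
#' `J = det F` and first deviatoric invariant
#' `Ibar1 = J^(-2/3) tr(F'F)`. No thermal or growth split is modelled, so
#' the elastic volume ratio equals `J`.
#'
#' @param F 3x3 deformation gradient (dimensionless).
#' @return An object of class `deformation_state` with `F`, `J`, `Ibar1`.
#' @export
deformation_state <- function(F) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3, 3)) || anyNA(F) || any(!is.finite(F)))
    stop("invalid deformation: F must be a finite 3x3 matrix")
  J <- det(F)
  if (J <= 0) stop("invalid deformation: det(F) must be positive")
  Ibar1 <- J^(-2 / 3) * sum(F * F)
  structure(list(F = F, J = J, Ibar1 = Ibar1), class = "deformation_state")
}

card_CK <- function(params) {
  if (inherits(params, "le_params")) params <- as_rp_params(params)
  stopifnot(inherits(params, "rp_params"))
  list(C = params$C, K = params$K,
       reg = if (is.null(params$reg)) numeric(0) else unname(params$reg))
}

#' Strain energy per unit reference volume
#'
#' @param params An `rp_params` (or `le_params`, converted internally) card.
#' @param state A `deformation_state`.
#' @return Scalar strain-energy density (MPa).
#' @export
#' @examples
#' p <- rp_params(C = 0.5)
#' lam <- 2
#' F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
#' strain_energy_density(p, deformation_state(F)) # 0.5 * (5 - 3) = 1
strain_energy_density <- function(params, state) {
  stopifnot(inherits(state, "deformation_state"))
  ck <- card_CK(params)
  rp_energy_cpp(ck$C, ck$K, ck$reg, state$F)
}

#' Cauchy stress tensor
#'
#' Push-forward of the first Piola-Kirchhoff stress derived from the
#' reduced-polynomial energy: `sigma = J^{-1} P F'`.
#'
#' @inheritParams strain_energy_density
#' @return Symmetric 3x3 Cauchy stress (MPa).
#' @export
cauchy_stress <- function(params, state) {
  stopifnot(inherits(state, "deformation_state"))
  ck <- card_CK(params)
  rp_cauchy_cpp(ck$C, ck$K, ck$reg, state$F)
}

#' First Piola-Kirchhoff stress tensor
#'
#' @inheritParams strain_energy_density
#' @return 3x3 nominal stress tensor (MPa), `P = dU/dF`.
#' @export
pk1_stress <- function(params, state) {
  stopifnot(inherits(state, "deformation_state"))
  ck <- card_CK(params)
  rp_pk1_cpp(ck$C, ck$K, ck$reg, state$F)
}

#' Consistent material tangent
#'
#' The fourth-order tensor `A_{iJkL} = dP_{iJ}/dF_{kL}` used in the Newton
#' linearization; possesses the minor symmetries inherited from the
#' hyperelastic potential (`A_{iJkL} = A_{kLiJ}`).
#'
#' @inheritParams strain_energy_density
#' @return Numeric array of dimension `c(3, 3, 3, 3)` (MPa).
#' @export
material_tangent <- function(params, state) {
  stopifnot(inherits(state, "deformation_state"))
  ck <- card_CK(params)
  M <- rp_tangent_cpp(ck$C, ck$K, ck$reg, state$F)
  A <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (J in 1:3) for (k in 1:3) for (L in 1:3)
    A[i, J, k, L] <- M[i + 3 * (J - 1), k + 3 * (L - 1)]
  A
}

#' Uniaxial nominal stress along the incompressible path
#'
#' Closed-form uniaxial response of a reduced-polynomial card under the
#' isochoric constraint (`lambda, lambda^{-1/2}, lambda^{-1/2}`):
#' \deqn{P(\lambda) = 2(\lambda - \lambda^{-2})
#'   \sum_i i\,C_{i0}(\bar I_1 - 3)^{i-1}, \quad
#'   \bar I_1 = \lambda^2 + 2/\lambda.}
#' Used to plot and validate each material card's stress-strain curve.
#'
#' @param params An `rp_params` card.
#' @param lambda Stretch ratio(s), positive.
#' @return Nominal (first Piola-Kirchhoff) stress (MPa), vectorized over
#'   `lambda`.
#' @export
uniaxial_nominal_stress <- function(params, lambda) {
  if (inherits(params, "le_params")) params <- as_rp_params(params)
  stopifnot(inherits(params, "rp_params"))
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("domain error: lambda must be positive")
  x <- lambda^2 + 2 / lambda - 3
  a <- rp_slope(params$C, x)
  if (length(params$reg) == 4) {
    rg <- unname(params$reg)
    a <- ifelse(x > rg[1] & x <= rg[2], rg[3], a)
  }
  unname(2 * (lambda - lambda^-2) * a)
}

#' Mixture specification for the optic nerve composite
#'
#' The ON is a composite of stiff connective tissue and soft neural tissue;
#' `f` is the connective volume fraction. The histologically observed
#' connective:neural area ratio of 9:16 gives the default `f = 9/25`.
#'
#' @param f Connective-tissue volume fraction, in `(0, 1]`.
#' @param E_ON Whole-nerve tensile modulus (MPa).
#' @param E_Neural Neural-tissue modulus (MPa); defaults to the neural card
#'   value 0.001195 MPa.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(f = 9 / 25, E_ON, E_Neural = 0.001195) {
  if (!is.finite(f) || f <= 0 || f > 1) {
    if (identical(f, 0)) stop("division error: f must be positive")
    stop("parameter error: f must be in (0, 1]")
  }
  if (!is.finite(E_ON) || E_ON <= 0 || !is.finite(E_Neural) || E_Neural <= 0)
    stop("parameter error: moduli must be positive")
  structure(list(f = f, E_ON = E_ON, E_Neural = E_Neural), class = "mixture_spec")
}

#' Connective-tissue modulus from the rule of mixtures
#'
#' Inverts the general rule of mixtures
#' `E_ON = f E_Connective + (1 - f) E_Neural` to recover the modulus of the
#' ON's intrinsic connective tissue from the measured whole-nerve modulus.
#'
#' @param spec A `mixture_spec`.
#' @return `E_Connective` (MPa).
#' @export
#' @examples
#' connective_modulus_from_mixture(mixture_spec(f = 1, E_ON = 0.5)) # 0.5
connective_modulus_from_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  E_c <- (spec$E_ON - (1 - spec$f) * spec$E_Neural) / spec$f
  if (E_c <= 0)
    stop("inconsistency error: rule of mixtures yields non-positive E_Connective")
  E_c
}

#' Forward rule of mixtures
#'
#' @param E_Connective Connective-tissue modulus (MPa).
#' @param E_Neural Neural-tissue modulus (MPa).
#' @param f Connective volume fraction.
#' @return Composite modulus `E_ON` (MPa).
#' @export
mixture_modulus <- function(E_Connective, E_Neural, f = 9 / 25) {
  f * E_Connective + (1 - f) * E_Neural
}

#' Homogenized optic-nerve material (Voigt mixture)
#'
#' For the 2D cross-section model the ON interior (connective honeycomb plus
#' neural channels) is homogenized into one material by mixing the two
#' strain-energy functions with the connective volume fraction `f` — the
#' rule of mixtures applied at the energy level, which reduces exactly to
#' `E_ON = f E_C + (1-f) E_N` in the small-strain limit.
#'
#' @param connective An `rp_params` card for the ON connective tissue.
#' @param neural An `le_params` card for the neural tissue.
#' @param f Connective volume fraction (default 9/25).
#' @return An `rp_params` card labelled as homogenized.
#' @export
homogenize_on <- function(connective, neural, f = 9 / 25) {
  stopifnot(inherits(connective, "rp_params"), inherits(neural, "le_params"))
  if (f <= 0 || f > 1) stop("parameter error: f must be in (0, 1]")
  nrp <- as_rp_params(neural)
  N <- max(connective$N, nrp$N)
  C <- f * c(connective$C, rep(0, N - connective$N)) +
    (1 - f) * c(nrp$C, rep(0, N - nrp$N))
  K <- f * c(connective$K, rep(0, N - connective$N)) +
    (1 - f) * c(nrp$K, rep(0, N - nrp$N))
  out <- rp_params(C = C, D = NULL,
                   label = paste0("on_homogenized (", connective$label, ")"))
  out$K <- K # exact Voigt volumetric mixture, overriding the default penalty
  out
}
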