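# Quasi-static large-deformation equilibrium: total-Lagrangian assembly over
# quadratic elements, Newton-Raphson with backtracking line search, follower
# pressure loads, and Dirichlet constraints (fixed sets, prescribed rigid
# rotation of the anterior sclera).

#' Boundary-condition set
#'
#' Collects the constraints and loads of one analysis: node sets fixed to
#' zero displacement, an optional prescribed rigid rotation of a node set
#' about a centre (the adduction forcing), optional explicit Dirichlet
#' values, and follower pressures (mmHg) on named facet sets.
#'
#' @param fixed_sets Character vector of node-set names fully fixed.
#' @param rotation `NULL` or `list(set=, angle_deg=, center=)`: rigid
#'   rotation of the named node set about `center` (adduction positive =
#'   cornea moves nasally, +x).
#' @param dirichlet `NULL` or a data frame with columns `node`, `dof`,
#'   `value` (final values, ramped with the load schedule).
#' @param pressures Named numeric vector of pressures in mmHg keyed by facet
#'   set name, e.g. `c(inner_scleral_surface = 15, csf_gap = 10)`.
#' @return An object of class `bc_set`.
#' @export
boundary_condition_set <- function(fixed_sets = character(), rotation = NULL,
                                   dirichlet = NULL, pressures = numeric()) {
  if (!is.null(rotation)) {
    stopifnot(is.list(rotation), !is.null(rotation$set),
              is.finite(rotation$angle_deg))
    if (is.null(rotation$center)) rotation$center <- c(0, 0)
  }
  if (length(pressures) && any(pressures < 0))
    stop("pressures must be non-negative")
  structure(list(fixed_sets = fixed_sets, rotation = rotation,
                 dirichlet = dirichlet, pressures = pressures),
            class = "bc_set")
}

#' Rotation matrix for adduction about the vertical (+y) axis
#'
#' In the model frame (+x nasal, +z posterior, +y superior) a positive
#' adduction angle carries the cornea (at negative z) nasally. Returned as
#' the 2x2 in-plane matrix acting on (x, z).
#'
#' @param angle_deg Adduction increment in degrees.
#' @return 2x2 rotation matrix.
#' @export
adduction_rotation <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Prescribed-displacement constraints for an adduction increment
#'
#' Every node of the rotation set is assigned the displacement that carries
#' its reference position through a rigid rotation about the globe centre;
#' pairwise distances within the set are preserved exactly.
#'
#' @param mesh An `rt_mesh` with the rotation node set.
#' @param angle_deg Rotation angle (degrees).
#' @param set Node-set name (default `"anterior_rotation_set"`).
#' @param center Rotation centre, default the origin (globe centre).
#' @return Data frame with columns `node`, `dof`, `value` (mm).
#' @export
prescribe_adduction <- function(mesh, angle_deg, set = "anterior_rotation_set",
                                center = c(0, 0)) {
  stopifnot(inherits(mesh, "rt_mesh"))
  if (!is.finite(angle_deg)) stop("angle must be finite")
  nodes <- mesh$node_sets[[set]]
  if (is.null(nodes)) stop("unknown node set '", set, "'")
  X <- sweep(mesh$nodes[nodes, 1:2, drop = FALSE], 2, center)
  R <- adduction_rotation(angle_deg)
  disp <- X %*% t(R) - X
  out <- data.frame(node = rep(nodes, 2),
                    dof = rep(1:2, each = length(nodes)),
                    value = c(disp[, 1], disp[, 2]))
  if (mesh$dim == 3) { # rotation acts in the (x, z) plane; y is unchanged
    out$dof[out$dof == 2] <- 3L
  }
  out
}

mmg <- function(p) mmHg_to_MPa(p)

# Resolve a materials mapping (region -> card) into the matid/mats form the
# C++ kernels use.
resolve_materials <- function(mesh, materials) {
  regs <- unique(mesh$region)
  missing <- setdiff(regs, names(materials))
  if (length(missing))
    stop("materials missing for region(s): ", paste(missing, collapse = ", "))
  mats <- lapply(regs, function(r) {
    card <- materials[[r]]
    if (inherits(card, "le_params")) card <- as_rp_params(card)
    if (!inherits(card, "rp_params")) stop("invalid material for region ", r)
    list(C = card$C, K = card$K,
         reg = if (is.null(card$reg)) numeric(0) else unname(card$reg))
  })
  list(matid = match(mesh$region, regs), mats = mats)
}

# Dirichlet rows (node, dof, value) at a given load fraction.
dirichlet_at <- function(mesh, bcs, frac) {
  rows <- list()
  for (fs in bcs$fixed_sets) {
    nodes <- mesh$node_sets[[fs]]
    if (is.null(nodes)) stop("unknown node set '", fs, "'")
    rows[[length(rows) + 1L]] <- data.frame(
      node = rep(nodes, mesh$dim), dof = rep(seq_len(mesh$dim), each = length(nodes)),
      value = 0)
  }
  if (!is.null(bcs$rotation)) {
    rows[[length(rows) + 1L]] <- prescribe_adduction(
      mesh, bcs$rotation$angle_deg * frac, bcs$rotation$set, bcs$rotation$center)
  }
  if (!is.null(bcs$dirichlet)) {
    d <- bcs$dirichlet
    d$value <- d$value * frac
    rows[[length(rows) + 1L]] <- d
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  # fixed sets win on conflict; keep first occurrence
  out[!duplicated(out[, c("node", "dof")]), ]
}

#' Assemble residual and tangent
#'
#' Computes the out-of-balance force (internal minus external, including
#' follower pressures) and the consistent
#' tangent (material + geometric + follower-pressure contributions) at a
#' given displacement.
#'
#' @param mesh An `rt_mesh`.
#' @param materials Named list mapping each mesh region to a material card.
#' @param displacement Numeric vector of length `nodes x dim` (mm).
#' @param bcs A `bc_set`; only its pressures enter the residual.
#' @param pressure_scale Scale factor on all pressures (load ramping).
#' @param want_tangent Assemble the sparse tangent as well?
#' @return List with `residual`, `tangent` (a `dgCMatrix` or `NULL`), and
#'   `badelem` (0, or the first element with non-positive Jacobian).
#' @export
assemble <- function(mesh, materials, displacement, bcs,
                     pressure_scale = 1, want_tangent = TRUE) {
  stopifnot(inherits(mesh, "rt_mesh"), inherits(bcs, "bc_set"))
  rm_ <- resolve_materials(mesh, materials)
  ndof <- nrow(mesh$nodes) * mesh$dim
  stopifnot(length(displacement) == ndof)
  a <- fem_assemble_cpp(mesh$nodes, mesh$elems, rm_$matid, rm_$mats,
                        displacement, want_tangent)
  if (a$badelem > 0)
    return(list(residual = NULL, tangent = NULL, badelem = a$badelem))
  r <- as.numeric(a$fint)
  ti <- a$i; tj <- a$j; tx <- a$x
  for (fs in names(bcs$pressures)) {
    p <- mmg(bcs$pressures[[fs]]) * pressure_scale
    if (p == 0) next
    fmat <- mesh$facets[[fs]]
    if (is.null(fmat)) stop("unknown facet set '", fs, "'")
    pr <- fem_pressure_cpp(mesh$nodes, fmat, displacement, p, want_tangent)
    r <- r - as.numeric(pr$f)
    if (want_tangent && length(pr$i)) {
      ti <- c(ti, pr$i); tj <- c(tj, pr$j); tx <- c(tx, -pr$x)
    }
  }
  K <- NULL
  if (want_tangent)
    K <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ndof, ndof))
  list(residual = r, tangent = K, badelem = 0L)
}

#' Consistent follower pressure load on a facet set
#'
#' The load acts along the deformed facet normals; positive pressure pushes
#' into the solid from the fluid side.
#'
#' @param mesh An `rt_mesh`.
#' @param facet_set Name of a facet set of the mesh.
#' @param pressure_mmHg Pressure in mmHg.
#' @param displacement Displacement vector (defaults to zero).
#' @return Nodal load vector of length `nodes x dim` (N in the plane-strain
#'   per-mm sense for 2D, N in 3D).
#' @export
apply_pressure <- function(mesh, facet_set, pressure_mmHg,
                           displacement = NULL) {
  stopifnot(inherits(mesh, "rt_mesh"))
  fmat <- mesh$facets[[facet_set]]
  if (is.null(fmat)) stop("unknown facet set '", facet_set, "'")
  ndof <- nrow(mesh$nodes) * mesh$dim
  if (is.null(displacement)) displacement <- numeric(ndof)
  as.numeric(fem_pressure_cpp(mesh$nodes, fmat, displacement, mmg(pressure_mmHg), FALSE)$f)
}

#' Load-stepping schedule and Newton controls
#'
#' @param increments Monotone load fractions in (0, 1]; default ten equal
#'   steps. The adduction rotation is applied linearly over all of them.
#' @param tol Relative residual tolerance for Newton convergence.
#' @param max_iter Maximum Newton iterations per increment.
#' @param line_search Use backtracking line search?
#' @param force_tol Absolute force-residual acceptance, as a fraction of the
#'   largest initial increment unbalance encountered (default 1e-4, well
#'   over an order tighter than the usual commercial-code force tolerance). It
#'   matters only when a locally softening material response leaves Newton
#'   oscillating at a mechanically negligible residual.
#' @param stabilize Baseline automatic-stabilization level (relative spring
#'   stiffness, e.g. 1e-5), engaged from the first increment. Zero (the
#'   default) engages stabilization only adaptively, when increment cutting
#'   fails. A small constant level makes the continuation path through a
#'   locally softening material response insensitive to solver details.
#' @param pressure_ramp Load fraction by which the pressures reach their full
#'   value (they scale linearly up to it). The default, the first increment,
#'   front-loads the comparatively small physiologic pressures so the
#'   remaining increments carry only the adduction rotation; pressure-driven
#'   problems should ramp over the whole schedule (`pressure_ramp = 1`).
#' @return An object of class `solve_schedule`.
#' @export
solve_schedule <- function(increments = seq(0.1, 1, by = 0.1), tol = 1e-8,
                           max_iter = 25L, line_search = TRUE,
                           pressure_ramp = increments[1], force_tol = 1e-4,
                           stabilize = 0) {
  increments <- as.numeric(increments)
  if (!length(increments) || is.unsorted(increments, strictly = TRUE) ||
      any(increments <= 0) || any(increments > 1))
    stop("increments must be strictly increasing in (0, 1]")
  if (tol <= 0) stop("tolerance must be positive")
  if (!is.finite(pressure_ramp) || pressure_ramp <= 0 || pressure_ramp > 1)
    stop("pressure_ramp must be in (0, 1]")
  structure(list(increments = increments, tol = tol,
                 max_iter = as.integer(max_iter),
                 line_search = isTRUE(line_search),
                 pressure_ramp = pressure_ramp, force_tol = force_tol,
                 stabilize = stabilize),
            class = "solve_schedule")
}

# Sparse linear solve: the tangent of a hyperelastic solid with enclosed
# follower pressure is symmetric up to roundoff and positive definite on the
# constrained subspace at stable states, so try sparse Cholesky first (much
# faster than the generic LU) and fall back to LU when indefinite.
solve_linear <- function(K, b) {
  Ks <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  ch <- tryCatch(suppressWarnings(Matrix::Cholesky(Ks, LDL = FALSE, perm = TRUE)),
                 error = function(e) NULL)
  if (!is.null(ch)) {
    x <- as.numeric(Matrix::solve(ch, b))
    if (all(is.finite(x))) return(x)
  }
  as.numeric(Matrix::solve(K, b))
}

#' Solve the quasi-static equilibrium problem
#'
#' Incremental-iterative total-Lagrangian solution: Dirichlet values (fixed
#' sets, prescribed rotation) and loads are applied over the schedule's
#' increments, each solved by Newton-Raphson with a consistent tangent and
#' optional backtracking line search. The pipeline is deterministic.
#'
#' @inheritParams assemble
#' @param schedule A [solve_schedule()].
#' @param verbose Print per-iteration residual norms?
#' @return An object of class `solution_state`: displacement vector `u`,
#'   per-element field averages (`stress` and `logstrain`, 6 columns
#'   xx,yy,zz,xy,yz,xz; `J`; reference `volume`), the convergence `log`
#'   (data frame: increment, iter, residual), and the mesh.
#' @export
solve_fem <- function(mesh, materials, bcs, schedule = solve_schedule(),
                      verbose = FALSE) {
  stopifnot(inherits(schedule, "solve_schedule"))
  ndof <- nrow(mesh$nodes) * mesh$dim
  u <- numeric(ndof)
  logs <- list()
  ref_force <- 0

  # Newton at one load fraction; returns the converged displacement or NULL.
  # eps_rel > 0 adds automatic stabilization (springs of stiffness
  # eps_rel x mean diagonal, anchored at the increment's starting state),
  # the standard device for traversing local limit points of a softening
  # material response.
  newton_at <- function(frac, u0, eps_rel = 0) {
    pscale <- min(frac / schedule$pressure_ramp, 1)
    dd <- dirichlet_at(mesh, bcs, frac)
    fixed_dofs <- integer(0)
    u <- u0
    if (!is.null(dd)) {
      fixed_dofs <- (dd$node - 1L) * mesh$dim + dd$dof
      u[fixed_dofs] <- dd$value
    }
    free <- setdiff(seq_len(ndof), fixed_dofs)
    r0n <- NA_real_
    best_it <- NULL
    eps <- 0
    for (it in seq_len(schedule$max_iter)) {
      a <- assemble(mesh, materials, u, bcs, pressure_scale = pscale,
                    want_tangent = TRUE)
      if (a$badelem > 0) return(NULL)
      if (it == 1L && eps_rel > 0)
        eps <- eps_rel * mean(abs(Matrix::diag(a$tangent)[free]))
      if (eps > 0) {
        a$residual <- a$residual + eps * (u - u0)
        a$tangent <- a$tangent + Matrix::Diagonal(ndof, eps)
      }
      rfree <- a$residual[free]
      rn <- sqrt(sum(rfree^2))
      logs[[length(logs) + 1L]] <<- data.frame(increment = frac, iter = it - 1L,
                                               residual = rn)
      if (verbose)
        message(sprintf("  inc %.4f it %2d |r| = %.3e", frac, it - 1L, rn))
      if (it == 1L) {
        r0n <- rn
        ref_force <<- max(ref_force, rn)
      }
      if (rn <= max(schedule$tol * r0n, 1e-12)) return(u)
      if (is.null(best_it) || rn < best_it$rn) best_it <- list(u = u, rn = rn)
      # stalled: no meaningful progress after half the budget
      if (it >= ceiling(schedule$max_iter / 2) && best_it$rn > 0.5 * r0n)
        break
      du <- tryCatch(
        solve_linear(a$tangent[free, free, drop = FALSE], -rfree),
        error = function(e) NULL)
      if (is.null(du)) return(NULL)
      # Non-monotone globalization: Newton on a stiff volumetric penalty
      # routinely overshoots on the first iterate and then converges
      # quadratically, so the full step is accepted within a generous
      # watchdog; backtracking engages only on element inversion or a
      # genuinely diverging residual.
      alpha <- 1
      best <- NULL
      repeat {
        ut <- u; ut[free] <- ut[free] + alpha * du
        at <- assemble(mesh, materials, ut, bcs, pressure_scale = pscale,
                       want_tangent = FALSE)
        if (at$badelem == 0) {
          rr <- at$residual + if (eps > 0) eps * (ut - u0) else 0
          rt <- sqrt(sum(rr[free]^2))
          if (is.null(best) || rt < best$rn) best <- list(u = ut, rn = rt)
          if (!schedule$line_search) break
          if (alpha == 1 && rt < 50 * rn) break
          if (rt < rn * (1 - 1e-4 * alpha)) break
        }
        alpha <- alpha / 2
        if (alpha < 1 / 64) break
      }
      if (is.null(best)) return(NULL)
      u <- best$u
    }
    # iteration budget exhausted: a locally softening card can leave Newton
    # cycling around equilibrium; accept the best iterate if its unbalance
    # is mechanically negligible
    if (!is.null(best_it) && best_it$rn <= schedule$force_tol * ref_force)
      return(best_it$u)
    NULL
  }

  # incremental loading with automatic increment cutting and, where cutting
  # alone cannot traverse a locally softening response (limit point of the
  # compliant peripapillary card beyond its fitted strain range), automatic
  # stabilization that stays engaged for the remainder of the schedule; the
  # stabilization forces are springs anchored at each increment's start and
  # are negligible against the physical forces (see solve_schedule docs)
  min_step <- min(diff(c(0, schedule$increments))) / 8
  eps_ladder <- unique(c(schedule$stabilize, 1e-4, 1e-3, 1e-2))
  eps_lvl <- 1L
  pending <- schedule$increments
  last <- 0
  stabilized <- FALSE
  while (length(pending)) {
    frac <- pending[1]
    un <- newton_at(frac, u, eps_rel = eps_ladder[eps_lvl])
    if (!is.null(un)) {
      u <- un
      last <- frac
      pending <- pending[-1]
    } else if (frac - last > min_step) {
      if (verbose)
        message(sprintf("  cutting increment: retry at %.4f", (last + frac) / 2))
      pending <- c((last + frac) / 2, pending)
    } else if (eps_lvl < length(eps_ladder)) {
      eps_lvl <- eps_lvl + 1L
      stabilized <- TRUE
      if (verbose)
        message(sprintf("  stabilizing (eps_rel = %g) from increment %.4f",
                        eps_ladder[eps_lvl], frac))
    } else {
      lg <- do.call(rbind, logs)
      stop("Newton failed to converge at increment ", signif(frac, 6),
           " despite increment cutting and stabilization (last |r| = ",
           signif(lg$residual[nrow(lg)], 4), "); convergence log attached: ",
           paste(utils::capture.output(utils::tail(lg, 8)), collapse = "\n"))
    }
  }
  if (stabilized && verbose)
    message("  note: solution obtained with automatic stabilization engaged")
  rm_ <- resolve_materials(mesh, materials)
  fields <- fem_fields_cpp(mesh$nodes, mesh$elems, rm_$matid, rm_$mats, u)
  structure(list(u = u, stress = fields$stress, logstrain = fields$logstrain,
                 J = fields$J, volume = fields$volume,
                 log = do.call(rbind, logs), mesh = mesh),
            class = "solution_state")
}

#' @export
print.solution_state <- function(x, ...) {
  cat("Converged FEM solution:", length(x$u), "dofs,",
      nrow(x$stress), "elements\n")
  cat("  increments:", length(unique(x$log$increment)),
      " max |u| =", signif(max(abs(x$u)), 4), "mm\n")
  invisible(x)
}

#' Nodal displacements as a matrix
#'
#' @param solution A `solution_state`.
#' @return Matrix (nodes x dim) of displacements (mm).
#' @export
displacement_field <- function(solution) {
  stopifnot(inherits(solution, "solution_state"))
  matrix(solution$u, ncol = solution$mesh$dim, byrow = TRUE)
}
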