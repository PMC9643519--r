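# Scalar field extraction and the region-summary rule: von Mises stress,
# maximum principal logarithmic strain, contiguous-element landmark
# averages, lamina cribrosa edge displacement, and mesh-convergence tables.

sym6 <- function(m) {
  if (is.matrix(m) && all(dim(m) == c(3, 3))) {
    if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
      stop("tensor must be symmetric")
    c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[2, 3], m[1, 3])
  } else if (is.numeric(m) && length(m) == 6) {
    as.numeric(m)
  } else stop("expected a symmetric 3x3 matrix or a 6-component vector")
}

#' von Mises equivalent stress
#'
#' `sqrt(3/2 * dev(sigma) : dev(sigma))`, invariant under rotations of the
#' stress tensor.
#'
#' @param stress A symmetric 3x3 stress tensor, a 6-component vector
#'   (xx, yy, zz, xy, yz, xz), or a matrix with 6 such columns (one row per
#'   element).
#' @return Scalar(s) in the units of the input.
#' @export
#' @examples
#' von_mises(diag(c(5, 5, 5))) # pure hydrostatic -> 0
von_mises <- function(stress) {
  if (is.matrix(stress) && ncol(stress) == 6 && !all(dim(stress) == c(3, 3))) {
    s <- stress
  } else {
    s <- matrix(sym6(stress), 1)
  }
  p <- rowMeans(s[, 1:3, drop = FALSE])
  dev <- s
  dev[, 1:3] <- dev[, 1:3] - p
  sqrt(1.5 * (rowSums(dev[, 1:3, drop = FALSE]^2) +
                2 * rowSums(dev[, 4:6, drop = FALSE]^2)))
}

#' Maximum principal strain
#'
#' Largest eigenvalue of a (logarithmic) strain tensor; with `all = TRUE`
#' the full spectrum in non-increasing order.
#'
#' @param strain Symmetric 3x3 tensor, 6-component vector, or ne x 6 matrix.
#' @param all Return all eigenvalues (single-tensor input only)?
#' @return Largest eigenvalue(s), or the sorted spectrum.
#' @export
max_principal_strain <- function(strain, all = FALSE) {
  one <- function(v) {
    m <- matrix(c(v[1], v[4], v[6], v[4], v[2], v[5], v[6], v[5], v[3]), 3, 3)
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (all) ev else ev[1]
  }
  if (is.matrix(strain) && ncol(strain) == 6 && !all(dim(strain) == c(3, 3))) {
    if (all) stop("all = TRUE requires a single tensor")
    apply(strain, 1, one)
  } else {
    one(sym6(strain))
  }
}

#' Region-summary rule
#'
#' Local representative stress and strain are quantified as the mean over
#' `k` contiguous elements (12-16) nearest a landmark, optionally restricted
#' to named regions.
#'
#' @param k Element count, between 12 and 16 (default 14).
#' @param regions `NULL` (any region) or a character vector of admissible
#'   region labels.
#' @param aggregation Only `"mean"` is defined.
#' @return An object of class `summary_rule`.
#' @export
summary_rule <- function(k = 14L, regions = NULL, aggregation = "mean") {
  k <- as.integer(k)
  if (k < 12L || k > 16L)
    stop("the region-summary rule averages 12-16 contiguous elements")
  if (!identical(aggregation, "mean")) stop("aggregation must be 'mean'")
  structure(list(k = k, regions = regions, aggregation = aggregation),
            class = "summary_rule")
}

# deterministic contiguous selection: start from the element nearest the
# landmark, grow by always adding the nearest admissible element that shares
# a node with the selection (ties broken by element index)
select_contiguous <- function(mesh, rule, landmark) {
  adm <- if (is.null(rule$regions)) seq_len(nrow(mesh$elems))
         else which(mesh$region %in% rule$regions)
  if (length(adm) < rule$k)
    stop("region holds only ", length(adm), " elements; the summary rule ",
         "needs ", rule$k, " - refine the mesh")
  ctr <- element_centroids(mesh)
  d <- sqrt(colSums((t(ctr[adm, , drop = FALSE]) - landmark)^2))
  ord <- adm[order(d, adm)]
  adj <- element_adjacency(mesh$elems)
  sel <- ord[1]
  cand <- setdiff(ord, sel)
  while (length(sel) < rule$k) {
    nb <- unique(unlist(adj[sel]))
    nxt <- cand[cand %in% nb][1]
    if (is.na(nxt)) nxt <- cand[1] # disconnected remainder: fall back to nearest
    sel <- c(sel, nxt)
    cand <- setdiff(cand, nxt)
  }
  sel
}

#' Landmark region summary
#'
#' Mean of a per-element scalar field (element tensors are already
#' quadrature-point averages) over the `k` contiguous elements nearest a
#' landmark. Stresses are reported in kPa, strains in percent.
#'
#' @param solution A `solution_state`.
#' @param rule A [summary_rule()].
#' @param landmark Length-2 (or 3) coordinates, or the name of a mesh
#'   landmark.
#' @param field `"stress"` (von Mises, kPa) or `"strain"` (maximum principal
#'   logarithmic strain, percent).
#' @return Scalar summary value.
#' @export
region_summary <- function(solution, rule, landmark,
                           field = c("stress", "strain")) {
  stopifnot(inherits(solution, "solution_state"), inherits(rule, "summary_rule"))
  field <- match.arg(field)
  mesh <- solution$mesh
  if (is.character(landmark)) {
    if (is.null(mesh$landmarks[[landmark]]))
      stop("landmark not found: ", landmark)
    landmark <- mesh$landmarks[[landmark]]
  }
  sel <- select_contiguous(mesh, rule, landmark)
  if (field == "stress") {
    mean(von_mises(solution$stress[sel, , drop = FALSE])) * 1000 # MPa -> kPa
  } else {
    mean(max_principal_strain(solution$logstrain[sel, , drop = FALSE])) * 100
  }
}

#' Lamina cribrosa edge displacement
#'
#' Displacement of the temporal (or nasal) LC edge landmark node, reported
#' as nasal (+x) and posterior (+z) components in micrometres. The landmark
#' is tracked in material coordinates. By default the displacement is
#' expressed relative to the rigidly adducted globe (the co-rotating frame
#' in which the initial and final rigid anterior sclera coincide) — the
#' frame in which LC displacement is clinically quantified; `frame =
#' "orbit"` gives the raw components.
#'
#' @param solution A `solution_state`.
#' @param mesh The mesh (defaults to the solution's).
#' @param adduction_deg The adduction increment of the solved case, needed
#'   for the globe frame.
#' @param edge `"temporal"` or `"nasal"`.
#' @param frame `"globe"` or `"orbit"`.
#' @param center Rotation centre of the adduction.
#' @return An object of class `lc_displacement`: list with `nasal_um` and
#'   `posterior_um`.
#' @export
lc_edge_displacement <- function(solution, mesh = solution$mesh,
                                 adduction_deg = 0,
                                 edge = c("temporal", "nasal"),
                                 frame = c("globe", "orbit"),
                                 center = c(0, 0)) {
  stopifnot(inherits(solution, "solution_state"))
  edge <- match.arg(edge)
  frame <- match.arg(frame)
  lm_name <- paste0("lc_", edge, "_edge")
  lm <- mesh$landmarks[[lm_name]]
  if (is.null(lm)) stop("landmark not found: ", lm_name)
  nid <- which.min(colSums((t(mesh$nodes[, 1:2, drop = FALSE]) - lm)^2))
  U <- displacement_field(solution)
  u <- U[nid, c(1, if (mesh$dim == 3) 3 else 2)]
  if (frame == "globe" && adduction_deg != 0) {
    X <- mesh$nodes[nid, c(1, if (mesh$dim == 3) 3 else 2)] - center
    u <- u - (as.numeric(adduction_rotation(adduction_deg) %*% X) - X)
  }
  structure(list(nasal_um = 1000 * u[1], posterior_um = 1000 * u[2],
                 edge = edge, frame = frame), class = "lc_displacement")
}

#' @export
print.lc_displacement <- function(x, ...) {
  cat(sprintf("LC %s edge displacement (%s frame): %+.0f um nasal, %+.0f um posterior\n",
              x$edge, x$frame, x$nasal_um, x$posterior_um))
  invisible(x)
}
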