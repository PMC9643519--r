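# Mesh-convergence study: the same load case re-solved over a ladder of
# mesh densities, tracking mean and maximum element von Mises stress over
# the whole model.

#' Mesh-convergence table
#'
#' Solves one load case at each density and tabulates element count, mean
#' and maximum von Mises stress (kPa, volume-weighted mean over all
#' elements), flagging the relative change between the two finest levels.
#'
#' @param case A [load_case()] (or case label).
#' @param config An [ocular_geometry_config()].
#' @param library Material library.
#' @param densities List of `list(fine=, coarse=)` edge-length pairs,
#'   coarsest first.
#' @param schedule Optional solver schedule.
#' @return An object of class `convergence_table`: data frame with columns
#'   `fine`, `coarse`, `elements`, `mean_vm_kPa`, `max_vm_kPa`, `error`
#'   (per-row solver failure message, empty on success), plus attribute
#'   `rel_change_mean` comparing the two finest successful levels.
#' @export
convergence_study <- function(case = "average",
                              config = ocular_geometry_config(),
                              library = NULL,
                              densities = list(list(fine = 0.45, coarse = 3.5),
                                               list(fine = 0.25, coarse = 2.2),
                                               list(fine = 0.2, coarse = 1.8)),
                              schedule = NULL) {
  if (length(densities) < 2) stop("at least two densities required")
  key <- vapply(densities, function(d) paste(d$fine, d$coarse), character(1))
  if (anyDuplicated(key)) stop("duplicate densities")
  if (is.null(library)) library <- load_material_library()
  rows <- lapply(densities, function(d) {
    b <- tryCatch(run_case(case, config, library, target_edge_length = d,
                           schedule = schedule),
                  error = function(e) e)
    if (inherits(b, "error"))
      return(data.frame(fine = d$fine, coarse = d$coarse, elements = NA,
                        mean_vm_kPa = NA, max_vm_kPa = NA,
                        error = conditionMessage(b)))
    vm <- von_mises(b$solution$stress) * 1000
    w <- b$solution$volume
    data.frame(fine = d$fine, coarse = d$coarse,
               elements = nrow(b$mesh$elems),
               mean_vm_kPa = sum(vm * w) / sum(w), max_vm_kPa = max(vm),
               error = "")
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$error == "")
  rel <- NA_real_
  if (length(ok) >= 2) {
    f2 <- ok[order(tab$fine[ok])][1:2] # two finest successful
    rel <- abs(diff(tab$mean_vm_kPa[f2])) / max(tab$mean_vm_kPa[f2])
  }
  structure(tab, rel_change_mean = rel, class = c("convergence_table",
                                                  class(tab)))
}

#' @export
print.convergence_table <- function(x, ...) {
  cat("Mesh-convergence study (whole-model von Mises):\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("relative change of mean between two finest levels: %.3f\n",
              attr(x, "rel_change_mean")))
  invisible(x)
}
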