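#' Tissue regions of the model
#' @keywords internal
ON_REGIONS <- c("anterior_sclera", "equatorial_sclera", "posterior_sclera",
                "peripapillary_sclera", "on_sheath", "lamina_cribrosa",
                "on_connective", "on_neural")

normalize_region <- function(region) {
  r <- tolower(trimws(region))
  r <- gsub("[ -]+", "_", r)
  r <- sub("^optic_nerve", "on", r)
  r <- sub("^on_neural_tissue$", "on_neural", r)
  r <- sub("^on_connective_tissue$", "on_connective", r)
  r
}

#' Load the regional material-card library
#'
#' Reads the packaged card file (one record per region and stiffness level)
#' into a `material_library`: a nested mapping region -> stiffness level ->
#' parameter object. The hyperelastic rows become [rp_params()] (with the
#' `C30..C60` columns rescaled from their printed 1000x representation);
#' the ON neural row becomes [le_params()].
#'
#' Levels published per region: `average`, `stiff` and `compliant` for the
#' posterior sclera, peripapillary sclera, ON sheath and ON connective
#' tissue; `average` only for the anterior sclera, equatorial sclera and
#' lamina cribrosa; the ON neural tissue is linear elastic (`average`).
#'
#' @param card_source Path to a card CSV. Defaults to the packaged file.
#' @return An object of class `material_library`.
#' @export
#' @examples
#' lib <- load_material_library()
#' material_card(lib, "posterior_sclera", "average")
load_material_library <- function(card_source = NULL) {
  if (is.null(card_source))
    card_source <- system.file("extdata", "material_cards.csv", package = "ontether")
  if (!file.exists(card_source)) stop("card source not found: ", card_source)
  df <- utils::read.csv(card_source, comment.char = "#",
                        stringsAsFactors = FALSE)
  need <- c("region", "stiffness", "C10", "C20", "C30e3", "C40e3", "C50e3",
            "C60e3", "D1", "E", "nu")
  if (!all(need %in% names(df)))
    stop("malformed card file: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  lib <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    region <- normalize_region(row$region)
    level <- tolower(trimws(row$stiffness))
    label <- paste(region, level)
    if (!is.na(row$E)) {
      card <- le_params(E = row$E, nu = row$nu, label = label)
    } else {
      C <- c(row$C10, row$C20, row$C30e3 / 1000, row$C40e3 / 1000,
             row$C50e3 / 1000, row$C60e3 / 1000)
      n <- max(which(!is.na(C)))
      if (anyNA(C[seq_len(n)]))
        stop("malformed card for ", label,
             ": deviatoric coefficients must be contiguous")
      D <- c(row$D1, rep(NA_real_, n - 1))
      card <- rp_params(C = C[seq_len(n)], D = D, label = label)
    }
    if (is.null(lib[[region]])) lib[[region]] <- list()
    lib[[region]][[level]] <- card
  }
  lib <- structure(lib, class = "material_library")
  validate_material_library(lib)
  lib
}

validate_material_library <- function(lib) {
  if (!setequal(names(lib), ON_REGIONS))
    stop("malformed card file: regions must be exactly {",
         paste(ON_REGIONS, collapse = ", "), "}")
  three <- c("posterior_sclera", "peripapillary_sclera", "on_sheath",
             "on_connective")
  for (r in three)
    if (!setequal(names(lib[[r]]), c("average", "stiff", "compliant")))
      stop("malformed card file: ", r,
           " must have average, stiff and compliant levels")
  for (r in c("anterior_sclera", "equatorial_sclera", "lamina_cribrosa"))
    if (!setequal(names(lib[[r]]), "average"))
      stop("malformed card file: ", r, " must have only the average level")
  if (!inherits(lib$on_neural$average, "le_params"))
    stop("malformed card file: on_neural must be linear elastic")
  invisible(lib)
}

#' Look up one material card
#'
#' @param library A `material_library`.
#' @param region Region name (e.g. `"posterior_sclera"`; human-readable
#'   variants such as `"posterior sclera"` are normalized).
#' @param level Stiffness level: `"average"`, `"stiff"` or `"compliant"`.
#' @return The `rp_params` or `le_params` card.
#' @export
material_card <- function(library, region, level = "average") {
  stopifnot(inherits(library, "material_library"))
  region <- normalize_region(region)
  level <- tolower(trimws(level))
  if (!region %in% names(library))
    stop("lookup error: unknown region '", region, "'")
  if (!level %in% names(library[[region]]))
    stop("lookup error: region '", region, "' has no published '", level,
         "' level (available: ", paste(names(library[[region]]), collapse = ", "), ")")
  library[[region]][[level]]
}

#' @export
print.material_library <- function(x, ...) {
  cat("Material library:", length(unclass(x)), "regions\n")
  for (r in names(x))
    cat(sprintf("  %-22s %s\n", r, paste(names(x[[r]]), collapse = ", ")))
  invisible(x)
}

#' Write a material library back to a card file
#'
#' Inverse of [load_material_library()]; coefficients in the `C30..C60`
#' columns are written at 1000x their value, mirroring the card file layout.
#'
#' @param library A `material_library`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_material_library <- function(library, path) {
  stopifnot(inherits(library, "material_library"))
  rows <- list()
  for (r in names(library)) for (lv in names(library[[r]])) {
    card <- library[[r]][[lv]]
    if (inherits(card, "le_params")) {
      rows[[length(rows) + 1]] <- data.frame(
        region = r, stiffness = lv, C10 = NA, C20 = NA, C30e3 = NA,
        C40e3 = NA, C50e3 = NA, C60e3 = NA, D1 = NA, E = card$E, nu = card$nu)
    } else {
      C <- c(card$C, rep(NA_real_, 6 - card$N))
      rows[[length(rows) + 1]] <- data.frame(
        region = r, stiffness = lv, C10 = C[1], C20 = C[2],
        C30e3 = C[3] * 1000, C40e3 = C[4] * 1000, C50e3 = C[5] * 1000,
        C60e3 = C[6] * 1000, D1 = card$D[1], E = NA, nu = NA)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
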