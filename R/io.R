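# Field and mesh exchange: VTU (VTK XML unstructured grid) exports of
# converged solutions, and Gmsh MSH 2.2 mesh export/import. All ASCII, full
# double precision, so displacement round-trips are bitwise.

fmt_g <- function(x) sprintf("%.17g", x)

vtk_cell_type <- function(dim) if (dim == 2) 22L else 24L # quadratic tri / tet

#' Export solution fields to a VTU file
#'
#' Writes nodes, quadratic connectivity, nodal displacements, per-element
#' Cauchy stress and logarithmic strain tensors (6 components), the derived
#' von Mises (MPa) and maximum principal strain fields, region ids (with
#' the label table in the field data) and volume ratio J. 2D cross-section
#' meshes are embedded in the z=0 plane as (x, z, 0).
#'
#' @param solution A `solution_state` (or `NULL` to export the mesh only).
#' @param mesh An `rt_mesh`; defaults to the solution's mesh.
#' @param path Output file path (`.vtu`).
#' @return `path`, invisibly.
#' @export
export_fields <- function(solution, mesh = solution$mesh, path) {
  stopifnot(inherits(mesh, "rt_mesh"))
  con <- try(suppressWarnings(file(path, "w")), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems); nen <- ncol(mesh$elems)
  pts <- if (mesh$dim == 2) cbind(mesh$nodes, 0) else mesh$nodes
  regs <- sort(unique(mesh$region))
  rid <- match(mesh$region, regs)
  w <- function(...) writeLines(paste0(...), con)
  da <- function(name, vals, ncomp = 1, type = "Float64") {
    w(sprintf('        <DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">',
              type, name, ncomp))
    v <- if (type == "Float64") fmt_g(t(vals)) else as.integer(t(vals))
    writeLines(paste(v, collapse = " "), con)
    w("        </DataArray>")
  }
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <FieldData>')
  w(sprintf('      <DataArray type="String" Name="region_labels" format="ascii">%s</DataArray>',
            paste(regs, collapse = " ")))
  w('    </FieldData>')
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, ne))
  w('      <Points>')
  da("Points", pts, 3)
  w('      </Points>')
  w('      <Cells>')
  da("connectivity", mesh$elems - 1L, 1, "Int64")
  da("offsets", seq_len(ne) * nen, 1, "Int64")
  da("types", rep(vtk_cell_type(mesh$dim), ne), 1, "UInt8")
  w('      </Cells>')
  w('      <PointData>')
  if (!is.null(solution)) {
    U <- displacement_field(solution)
    if (mesh$dim == 2) U <- cbind(U, 0)
    da("displacement", U, 3)
  }
  w('      </PointData>')
  w('      <CellData>')
  da("region_id", rid, 1, "Int64")
  if (!is.null(solution)) {
    da("stress", solution$stress, 6)
    da("logstrain", solution$logstrain, 6)
    da("von_mises", von_mises(solution$stress), 1)
    da("max_principal_strain", max_principal_strain(solution$logstrain), 1)
    da("J", solution$J, 1)
  }
  w('      </CellData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Read a VTU file written by [export_fields()]
#'
#' @param path `.vtu` file path.
#' @return List with `nodes`, `elems` (1-based), `region`, `point_data` and
#'   `cell_data` (named lists of matrices/vectors).
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  n <- as.integer(xml2::xml_attr(piece, "NumberOfPoints"))
  ne <- as.integer(xml2::xml_attr(piece, "NumberOfCells"))
  get_da <- function(xpath) {
    nd <- xml2::xml_find_first(doc, xpath)
    if (is.na(nd)) return(NULL)
    scan(text = xml2::xml_text(nd), quiet = TRUE)
  }
  pts <- matrix(get_da(".//Points/DataArray"), ncol = 3, byrow = TRUE)
  conn <- get_da(".//Cells/DataArray[@Name='connectivity']")
  nen <- length(conn) / ne
  elems <- matrix(as.integer(conn), ncol = nen, byrow = TRUE) + 1L
  regs <- strsplit(xml2::xml_text(
    xml2::xml_find_first(doc, ".//FieldData/DataArray[@Name='region_labels']")),
    " ")[[1]]
  read_block <- function(where) {
    out <- list()
    for (nd in xml2::xml_find_all(doc, paste0(".//", where, "/DataArray"))) {
      nm <- xml2::xml_attr(nd, "Name")
      ncomp <- as.integer(xml2::xml_attr(nd, "NumberOfComponents"))
      v <- scan(text = xml2::xml_text(nd), quiet = TRUE)
      out[[nm]] <- if (ncomp > 1) matrix(v, ncol = ncomp, byrow = TRUE) else v
    }
    out
  }
  cd <- read_block("CellData")
  dim <- if (all(pts[, 3] == 0) && nen == 6) 2L else 3L
  nodes <- if (dim == 2) pts[, 1:2, drop = FALSE] else pts
  list(nodes = nodes, elems = elems,
       region = regs[cd$region_id],
       point_data = read_block("PointData"), cell_data = cd)
}

MSH_TYPES <- c("9" = 6L, "11" = 10L) # gmsh type -> nodes per element

#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Region labels are carried as physical groups (`$PhysicalNames`); facet
#' sets and landmarks are not part of the format and are not written.
#'
#' @param mesh An `rt_mesh`.
#' @param path Output `.msh` path.
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  stopifnot(inherits(mesh, "rt_mesh"))
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  regs <- sort(unique(mesh$region))
  rid <- match(mesh$region, regs)
  w("$MeshFormat"); w("2.2 0 8"); w("$EndMeshFormat")
  w("$PhysicalNames"); w(length(regs))
  for (i in seq_along(regs)) w(sprintf('%d %d "%s"', mesh$dim, i, regs[i]))
  w("$EndPhysicalNames")
  n <- nrow(mesh$nodes)
  w("$Nodes"); w(n)
  pts <- if (mesh$dim == 2) cbind(mesh$nodes, 0) else mesh$nodes
  writeLines(sprintf("%d %s %s %s", seq_len(n), fmt_g(pts[, 1]),
                     fmt_g(pts[, 2]), fmt_g(pts[, 3])), con)
  w("$EndNodes")
  etype <- if (mesh$dim == 2) 9L else 11L
  ne <- nrow(mesh$elems)
  w("$Elements"); w(ne)
  # gmsh tet10 swaps the (3-4) and (1-4)... no: gmsh node order for type 11
  # matches corners + mids (1-2),(2-3),(3-1),(1-4),(3-4),(2-4); ours is
  # (1-4),(2-4),(3-4) in slots 8,9,10 -> permute 9 and 10
  el <- mesh$elems
  if (mesh$dim == 3) el <- el[, c(1:8, 10, 9), drop = FALSE]
  writeLines(paste(seq_len(ne), etype, 2L, rid, rid,
                   apply(el, 1, paste, collapse = " ")), con)
  w("$EndElements")
  invisible(path)
}

#' Read a Gmsh MSH 2.2 ASCII mesh
#'
#' @param path `.msh` path.
#' @return An `rt_mesh` (no facet sets, node sets or landmarks).
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) stop("malformed MSH file: missing $", name)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  pn <- sec("PhysicalNames")
  regs <- character(0)
  for (l in pn[-1]) {
    p <- strsplit(l, " ", fixed = TRUE)[[1]]
    regs[as.integer(p[2])] <- gsub('"', "", paste(p[-(1:2)], collapse = " "))
  }
  nd <- sec("Nodes")
  nmat <- matrix(scan(text = nd[-1], quiet = TRUE), ncol = 4, byrow = TRUE)
  nodes3 <- nmat[order(nmat[, 1]), 2:4, drop = FALSE]
  el_lines <- sec("Elements")[-1]
  rows <- lapply(el_lines, function(l) scan(text = l, quiet = TRUE))
  etype <- rows[[1]][2]
  if (!as.character(etype) %in% names(MSH_TYPES))
    stop("unsupported element type ", etype)
  nen <- MSH_TYPES[[as.character(etype)]]
  conn <- t(vapply(rows, function(r) r[(length(r) - nen + 1L):length(r)],
                   numeric(nen)))
  rid <- vapply(rows, function(r) r[4], numeric(1))
  dim <- if (etype == 9) 2L else 3L
  el <- matrix(as.integer(conn), ncol = nen)
  if (dim == 3) el <- el[, c(1:8, 10, 9), drop = FALSE]
  nodes <- if (dim == 2) nodes3[, 1:2, drop = FALSE] else nodes3
  rt_mesh(nodes, el, regs[rid])
}
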