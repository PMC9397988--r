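#' Export a mesh (with optional fields) as ASCII VTU
#'
#' Writes an XML unstructured-grid file readable by ParaView/VTK.  Quadratic
#' triangles are written as VTK cell type 22; region ids go into a cell-data
#' array `region_id` (with the label map in a comment header), nodal fields
#' into point-data arrays.
#'
#' @param mesh a `labeled_mesh`.
#' @param path output file (conventionally `.vtu`).
#' @param point_data named list of per-node vectors (length N) or matrices
#'   (N x k).
#' @param cell_data named list of per-element vectors.
#' @param nodes optional N x 2 replacement coordinates (deformed geometry).
#' @return invisibly, the path.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list(),
                      nodes = NULL) {
  if (is.null(nodes)) nodes <- mesh$nodes
  n <- nrow(nodes); m <- nrow(mesh$tri)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(x) paste(format(x, digits = 10, scientific = TRUE,
                                  trim = TRUE), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<!-- region label map: %s -->',
    paste(mesh$labels$region_id, mesh$labels$label, sep = "=",
          collapse = "; "))
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(format(nodes[, 1], digits = 10, trim = TRUE),
                   format(nodes[, 2], digits = 10, trim = TRUE), "0"), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$tri - 1L, 1, paste, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  w('%s', paste(seq_len(m) * 6L, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  w('%s', paste(rep(22L, m), collapse = " "))   # VTK_QUADRATIC_TRIANGLE
  w('        </DataArray>')
  w('      </Cells>')
  w('      <PointData>')
  for (nm in names(point_data)) {
    v <- point_data[[nm]]
    if (is.null(dim(v))) v <- matrix(v, ncol = 1)
    w('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
      nm, ncol(v))
    writeLines(apply(v, 1, num), con)
    w('        </DataArray>')
  }
  w('      </PointData>')
  w('      <CellData>')
  w('        <DataArray type="Int32" Name="region_id" format="ascii">')
  w('%s', paste(mesh$region_id, collapse = " "))
  w('        </DataArray>')
  for (nm in names(cell_data)) {
    w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
    w('%s', paste(format(cell_data[[nm]], digits = 10, trim = TRUE),
                  collapse = " "))
    w('        </DataArray>')
  }
  w('      </CellData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Export a mesh as Gmsh MSH (version 2.2, ASCII)
#'
#' Region ids become physical tags of 6-node second-order triangles (Gmsh
#' element type 9).
#'
#' @param mesh a `labeled_mesh`.
#' @param path output file (conventionally `.msh`).
#' @return invisibly, the path.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  w("$MeshFormat"); w("2.2 0 8"); w("$EndMeshFormat")
  w("$PhysicalNames"); w("%d", nrow(mesh$labels))
  for (i in seq_len(nrow(mesh$labels)))
    w('2 %d "%s"', mesh$labels$region_id[i], mesh$labels$label[i])
  w("$EndPhysicalNames")
  w("$Nodes"); w("%d", n)
  writeLines(paste(seq_len(n),
                   format(mesh$nodes[, 1], digits = 10, trim = TRUE),
                   format(mesh$nodes[, 2], digits = 10, trim = TRUE), "0"),
             con)
  w("$EndNodes")
  w("$Elements"); w("%d", m)
  ## gmsh type-9 node order matches corners then midside(1-2,2-3,3-1)
  writeLines(paste(seq_len(m), 9L, 2L, mesh$region_id, mesh$region_id,
                   mesh$tri[, 1], mesh$tri[, 2], mesh$tri[, 3],
                   mesh$tri[, 4], mesh$tri[, 5], mesh$tri[, 6]), con)
  w("$EndElements")
  invisible(path)
}

#' Write a disc summary as tidy CSV
#'
#' Columns: `bmi_class`, `traction_level`, `disc`, `mean_stress_MPa`,
#' `mean_strain`, `n_nodes`.
#'
#' @param summary a `disc_summary`.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_disc_summary <- function(summary, path) {
  cols <- c("bmi_class", "traction_level", "disc", "mean_stress_MPa",
            "mean_strain", "n_nodes")
  utils::write.csv(as.data.frame(summary)[, cols], path, row.names = FALSE)
  invisible(path)
}
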