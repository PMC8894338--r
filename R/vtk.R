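#' Write mesh and solution fields as a VTU file
#'
#' Emits an ASCII XML unstructured-grid (`.vtu`) file readable by ParaView
#' and other VTK-based viewers: the tetrahedral mesh, per-node fields
#' (scalars, or 3-vectors such as the displacement) and per-element fields
#' (such as the von Mises stress). The region tag is always included as a
#' cell field.
#'
#' @param mesh a [tet_mesh()].
#' @param node_fields named list; each entry a length-N vector or N x 3
#'   matrix.
#' @param cell_fields named list; each entry a length-M vector.
#' @param path output file path (conventionally `.vtu`).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, node_fields = list(), cell_fields = list(), path) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  for (nm in names(node_fields)) {
    len <- NROW(node_fields[[nm]])
    if (len != n) stop("node field '", nm, "' has length ", len,
                       " but the mesh has ", n, " nodes")
  }
  for (nm in names(cell_fields)) {
    len <- NROW(cell_fields[[nm]])
    if (len != m) stop("cell field '", nm, "' has length ", len,
                       " but the mesh has ", m, " elements")
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  num <- function(x) paste(sprintf("%.10g", x), collapse = " ")
  w('<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '  <UnstructuredGrid>',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m),
    '      <Points>',
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(paste(sprintf("%.10g %.10g %.10g", mesh$nodes[, 1], mesh$nodes[, 2],
                  mesh$nodes[, 3]), collapse = " "))
  w('        </DataArray>', '      </Points>', '      <Cells>',
    '        <DataArray type="Int64" Name="connectivity" format="ascii">')
  w(paste(t(mesh$tets) - 1L, collapse = " "))
  w('        </DataArray>',
    '        <DataArray type="Int64" Name="offsets" format="ascii">')
  w(paste(4L * seq_len(m), collapse = " "))
  w('        </DataArray>',
    '        <DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(10L, m), collapse = " "))
  w('        </DataArray>', '      </Cells>')

  w('      <PointData>')
  for (nm in names(node_fields)) {
    f <- node_fields[[nm]]
    if (is.matrix(f) && ncol(f) == 3L) {
      w(sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="3" format="ascii">', nm))
      w(paste(sprintf("%.10g %.10g %.10g", f[, 1], f[, 2], f[, 3]),
              collapse = " "))
    } else {
      w(sprintf('        <DataArray type="Float64" Name="%s" format="ascii">', nm))
      w(num(as.numeric(f)))
    }
    w('        </DataArray>')
  }
  w('      </PointData>')

  w('      <CellData>')
  region_id <- as.integer(factor(mesh$regions))
  w(sprintf('        <DataArray type="Int32" Name="region" format="ascii">'))
  w(paste(region_id, collapse = " "))
  w('        </DataArray>')
  for (nm in names(cell_fields)) {
    w(sprintf('        <DataArray type="Float64" Name="%s" format="ascii">', nm))
    w(num(as.numeric(cell_fields[[nm]])))
    w('        </DataArray>')
  }
  w('      </CellData>')
  w('    </Piece>', '  </UnstructuredGrid>', '</VTKFile>')
  invisible(path)
}

#' Export a surface as binary STL
#'
#' Writes either one facet group or the whole mesh boundary as a binary STL
#' surface, for quick inspection in mesh viewers or slicers.
#'
#' @param mesh a [tet_mesh()].
#' @param path output file path.
#' @param group facet-group name, or `NULL` for the full boundary.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, group = NULL) {
  tris <- if (is.null(group)) mesh_boundary_faces(mesh) else {
    if (!group %in% names(mesh$facet_groups)) {
      stop("unknown facet group '", group, "'")
    }
    mesh$facet_groups[[group]]
  }
  an <- facet_area_normals(mesh$nodes, tris)
  nn <- sqrt(rowSums(an^2))
  nn[nn == 0] <- 1
  an <- an / nn
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(as.integer(nrow(tris)), con, size = 4L, endian = "little")
  v1 <- mesh$nodes[tris[, 1], , drop = FALSE]
  v2 <- mesh$nodes[tris[, 2], , drop = FALSE]
  v3 <- mesh$nodes[tris[, 3], , drop = FALSE]
  block <- t(cbind(an, v1, v2, v3))
  for (i in seq_len(nrow(tris))) {
    writeBin(as.numeric(block[, i]), con, size = 4L, endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
  invisible(path)
}
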