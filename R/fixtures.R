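#' Unit-cube patch-test fixture
#'
#' Structured tetrahedral mesh of the cube `[0, 1]^3` (mm) with one region
#' tag `"cube"`, per-face facet groups (`"xmin"`, `"xmax"`, ..., `"zmax"`,
#' outward oriented) and node groups `"corners"` and `"edges"`. Used for
#' finite-element patch tests: P1 elements must reproduce any uniform-strain
#' state on it exactly.
#'
#' @param resolution target edge length in mm, at most 1.
#' @return A [tet_mesh()].
#' @export
build_unit_cube <- function(resolution = 0.25) {
  stopifnot(resolution > 0, resolution <= 1)
  n <- max(1L, ceiling(1 / resolution))
  g <- seq(0, 1, length.out = n + 1L)
  nx <- n + 1L
  pts2 <- cbind(rep(g, nx), rep(g, each = nx))
  tris <- quads_to_tris(grid_quads(nx, nx))
  ex <- extrude_triangulation(pts2, tris, g)
  tets <- prisms_to_tets(ex$prisms)
  nodes <- ex$nodes
  bf <- mesh_boundary_faces_raw(nodes, tets)
  face_of <- function(coord, val) {
    sel <- rowSums(matrix(abs(nodes[bf, coord] - val) < 1e-12, ncol = 3L)) == 3L
    bf[sel, , drop = FALSE]
  }
  facet_groups <- list(xmin = face_of(1, 0), xmax = face_of(1, 1),
                       ymin = face_of(2, 0), ymax = face_of(2, 1),
                       zmin = face_of(3, 0), zmax = face_of(3, 1))
  extremal <- abs(nodes - 0) < 1e-12 | abs(nodes - 1) < 1e-12
  node_groups <- list(corners = which(rowSums(extremal) == 3L),
                      edges = which(rowSums(extremal) >= 2L))
  tet_mesh(nodes, tets, rep("cube", nrow(tets)),
           facet_groups = facet_groups, node_groups = node_groups,
           repair = FALSE)
}

# subdivided icosahedron on the unit sphere; returns list(verts, faces)
# with outward-oriented (counter-clockwise from outside) triangles
icosphere <- function(level) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(level)) {
    nv <- nrow(v)
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    mid_id <- nv + as.integer(factor(ek, levels = unique(ek)))
    mids <- (v[edges[, 1], ] + v[edges[, 2], ]) / 2
    newv <- mids[!duplicated(ek), , drop = FALSE]
    newv <- newv / sqrt(rowSums(newv^2))
    v <- rbind(v, newv)
    m <- nrow(f)
    m12 <- mid_id[seq_len(m)]
    m23 <- mid_id[m + seq_len(m)]
    m31 <- mid_id[2L * m + seq_len(m)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  storage.mode(f) <- "integer"
  list(verts = v, faces = f)
}

#' Hollow-sphere verification mesh
#'
#' Tetrahedral mesh of a thick spherical shell, the classic Lame
#' verification geometry for internally pressurised solids. Built from a
#' subdivided icosahedron extruded radially; all shell nodes lie exactly on
#' their nominal radii. Facet groups `"inner_surface"` and
#' `"outer_surface"`; single region tag `"shell"`.
#'
#' @param inner_radius,outer_radius shell radii in mm, `0 < inner < outer`.
#' @param resolution target edge length in mm; controls both the icosphere
#'   subdivision level and the number of radial layers.
#' @return A [tet_mesh()].
#' @export
build_hollow_sphere <- function(inner_radius, outer_radius, resolution) {
  if (!(inner_radius > 0 && outer_radius > inner_radius)) {
    stop("radii must satisfy 0 < inner_radius < outer_radius")
  }
  stopifnot(resolution > 0)
  rmid <- (inner_radius + outer_radius) / 2
  level <- max(1L, ceiling(log2(1.05146 * rmid / resolution)))
  ico <- icosphere(level)
  nlay <- max(2L, round((outer_radius - inner_radius) / resolution))
  radii <- seq(inner_radius, outer_radius, length.out = nlay + 1L)
  nv <- nrow(ico$verts)
  nodes <- ico$verts[rep(seq_len(nv), nlay + 1L), ] * rep(radii, each = nv)
  prisms <- do.call(rbind, lapply(seq_len(nlay), function(l) {
    cbind(ico$faces + (l - 1L) * nv, ico$faces + l * nv)
  }))
  tets <- prisms_to_tets(prisms)
  bf <- mesh_boundary_faces_raw(nodes, tets)
  rad <- sqrt(rowSums(nodes^2))
  fr <- matrix(rad[bf], ncol = 3L)
  tol <- 1e-9 * outer_radius
  tet_mesh(nodes, tets, rep("shell", nrow(tets)),
           facet_groups = list(
             inner_surface = bf[rowSums(abs(fr - inner_radius) < tol) == 3L, ,
                                drop = FALSE],
             outer_surface = bf[rowSums(abs(fr - outer_radius) < tol) == 3L, ,
                                drop = FALSE]),
           repair = FALSE)
}
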