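#' Tagged tetrahedral mesh
#'
#' The central geometry container of the package: a linear (P1) tetrahedral
#' volume mesh in which every tetrahedron carries one named material-region
#' tag, plus named groups of oriented boundary triangles (e.g.
#' `"inner_surface"`, `"trephine_wall"`), named node sets (e.g.
#' `"fixed_edges"`) and named closed node cycles (e.g.
#' `"trephine_inner_loop"`). Coordinates are millimetres; together with MPa
#' for stresses this makes forces come out in newtons.
#'
#' Tetrahedra are stored with positive signed volume; `tet_mesh()` repairs
#' negatively oriented input tets by swapping their last two nodes and
#' reports how many were flipped. Node indices are 1-based throughout the
#' package; external formats that count from elsewhere are translated at the
#' I/O boundary.
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z in mm.
#' @param tets integer matrix, one row per tetrahedron, four node indices.
#' @param regions character vector, one region tag per tetrahedron.
#' @param facet_groups named list of integer matrices (rows = oriented
#'   surface triangles, outward normals with respect to the solid).
#' @param node_groups named list of integer vectors.
#' @param loops named list of integer vectors, each an ordered closed cycle
#'   (first node not repeated at the end).
#' @param repair flip negatively oriented tetrahedra instead of erroring.
#' @return An object of class `"tet_mesh"`.
#' @seealso [validate_mesh()], [read_gmsh()], [write_gmsh()]
#' @export
tet_mesh <- function(nodes, tets, regions,
                     facet_groups = list(), node_groups = list(),
                     loops = list(), repair = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3L) stop("`nodes` must have three columns (x, y, z in mm)")
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(tets) != 4L) stop("`tets` must have four columns")
  if (nrow(tets) == 0L) stop("no volume elements")
  regions <- as.character(regions)
  if (length(regions) != nrow(tets)) {
    stop("`regions` must supply exactly one tag per tetrahedron")
  }
  if (anyNA(regions) || any(!nzchar(regions))) stop("untagged region")
  if (min(tets) < 1L || max(tets) > nrow(nodes)) {
    stop("tetrahedron connectivity refers to nonexistent nodes")
  }
  v <- signed_tet_volumes(nodes, tets)
  neg <- which(v < 0)
  if (length(neg)) {
    if (!repair) stop(length(neg), " negatively oriented tetrahedra")
    tets[neg, c(3L, 4L)] <- tets[neg, c(4L, 3L)]
    message("tet_mesh: repaired orientation of ", length(neg), " tetrahedra")
  }
  mesh <- structure(
    list(nodes = nodes, tets = tets, regions = regions,
         facet_groups = normalize_facets(facet_groups),
         node_groups = lapply(node_groups, function(g) as.integer(g)),
         loops = lapply(loops, function(g) as.integer(g))),
    class = "tet_mesh")
  mesh
}

normalize_facets <- function(facet_groups) {
  lapply(facet_groups, function(f) {
    f <- as.matrix(f)
    storage.mode(f) <- "integer"
    if (nrow(f) > 0 && ncol(f) != 3L) stop("facet groups must be triangles")
    f
  })
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tetrahedra, regions: %s\n",
              nrow(x$nodes), nrow(x$tets),
              paste(sort(unique(x$regions)), collapse = ", ")))
  if (length(x$facet_groups)) {
    cat("  facet groups:",
        paste(sprintf("%s (%d)", names(x$facet_groups),
                      vapply(x$facet_groups, nrow, 1L)), collapse = ", "), "\n")
  }
  if (length(x$node_groups)) {
    cat("  node groups:",
        paste(sprintf("%s (%d)", names(x$node_groups),
                      lengths(x$node_groups)), collapse = ", "), "\n")
  }
  if (length(x$loops)) {
    cat("  loops:",
        paste(sprintf("%s (%d)", names(x$loops), lengths(x$loops)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# Signed volume of each tet: det[p2-p1, p3-p1, p4-p1] / 6, fully vectorised.
signed_tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
   b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
   b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

#' Per-tetrahedron and total mesh volume
#'
#' @param mesh a [tet_mesh()].
#' @return `tet_volumes()`: numeric vector of signed volumes (mm^3), positive
#'   for a valid mesh; `mesh_volume()`: their sum.
#' @export
tet_volumes <- function(mesh) signed_tet_volumes(mesh$nodes, mesh$tets)

#' @rdname tet_volumes
#' @export
mesh_volume <- function(mesh) sum(tet_volumes(mesh))

# rows of the vector cross product of matrices of row vectors
cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# area-weighted normals (norm = 2*area) of oriented triangles
facet_area_normals <- function(nodes, tris) {
  a <- nodes[tris[, 1], , drop = FALSE]
  cross3(nodes[tris[, 2], , drop = FALSE] - a,
         nodes[tris[, 3], , drop = FALSE] - a)
}

facet_areas <- function(nodes, tris) {
  n <- facet_area_normals(nodes, tris)
  sqrt(rowSums(n * n)) / 2
}

# The four faces of each tet, oriented with outward normal (opposite the
# remaining node). Local faces of positively oriented tet (1,2,3,4):
tet_face_local <- matrix(c(2L, 3L, 4L,
                           1L, 4L, 3L,
                           1L, 2L, 4L,
                           1L, 3L, 2L), ncol = 3, byrow = TRUE)

all_tet_faces <- function(tets) {
  m <- nrow(tets)
  faces <- matrix(0L, 4L * m, 3L)
  for (k in 1:4) {
    faces[seq_len(m) + (k - 1L) * m, ] <- tets[, tet_face_local[k, ], drop = FALSE]
  }
  faces
}

face_key <- function(faces) {
  s <- t(apply(faces, 1L, sort.int))
  paste(s[, 1], s[, 2], s[, 3], sep = "/")
}

# faster sorted-triple key without apply(): pairwise min/max network
face_key_fast <- function(faces) {
  a <- faces[, 1]; b <- faces[, 2]; c <- faces[, 3]
  lo <- pmin(a, b); hi <- pmax(a, b)
  mn <- pmin(lo, c)
  mx <- pmax(hi, c)
  md <- as.integer(a) + as.integer(b) + as.integer(c) - mn - mx
  paste(mn, md, mx, sep = "/")
}

#' Boundary triangles of a tetrahedral mesh
#'
#' Faces that belong to exactly one tetrahedron, oriented with the outward
#' normal of the solid.
#'
#' @param mesh a [tet_mesh()].
#' @return integer matrix of oriented boundary triangles.
#' @export
mesh_boundary_faces <- function(mesh) {
  faces <- all_tet_faces(mesh$tets)
  key <- face_key_fast(faces)
  tab <- table(key)
  faces[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

#' Validate a tetrahedral mesh
#'
#' Checks the structural invariants a mesh must satisfy before it can be
#' solved: strictly positive tet volumes, in-range group/loop indices,
#' declared surface facets actually on the boundary, non-empty region tags,
#' and loops that are closed, simple cycles of at least 8 distinct nodes.
#' Violations are reported, never raised.
#'
#' @param mesh a [tet_mesh()].
#' @param materials optional [material_table()]; when given, region tags
#'   missing from the table are reported too.
#' @return A tibble with columns `component`, `index`, `problem`; zero rows
#'   iff the mesh is solvable.
#' @export
validate_mesh <- function(mesh, materials = NULL) {
  out <- list()
  add <- function(component, index, problem) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      component = component, index = as.integer(index), problem = problem)
  }
  nn <- nrow(mesh$nodes)

  v <- tet_volumes(mesh)
  bad <- which(v <= 0)
  for (i in bad) add("tet", i, "non-positive volume")

  bfaces <- mesh_boundary_faces(mesh)
  bkey <- face_key_fast(bfaces)
  for (gname in names(mesh$facet_groups)) {
    f <- mesh$facet_groups[[gname]]
    if (nrow(f) == 0L) next
    if (min(f) < 1L || max(f) > nn) {
      add(paste0("facet_group:", gname), NA, "index out of range")
      next
    }
    on_boundary <- face_key_fast(f) %in% bkey
    for (i in which(!on_boundary)) {
      add(paste0("facet_group:", gname), i, "facet not on mesh boundary")
    }
  }
  for (gname in names(mesh$node_groups)) {
    g <- mesh$node_groups[[gname]]
    if (length(g) && (min(g) < 1L || max(g) > nn)) {
      add(paste0("node_group:", gname), NA, "index out of range")
    }
  }
  for (lname in names(mesh$loops)) {
    l <- mesh$loops[[lname]]
    if (length(l) && (min(l) < 1L || max(l) > nn)) {
      add(paste0("loop:", lname), NA, "index out of range")
      next
    }
    if (length(l) < 8L) add(paste0("loop:", lname), NA, "loop has fewer than 8 nodes")
    if (anyDuplicated(l)) add(paste0("loop:", lname), NA, "non-simple loop")
    if (length(l) >= 8L && !anyDuplicated(l) &&
        polyline_self_intersects(mesh$nodes[l, , drop = FALSE])) {
      add(paste0("loop:", lname), NA, "non-simple loop")
    }
  }
  if (!is.null(materials)) {
    missing <- setdiff(unique(mesh$regions), materials$region)
    for (tag in missing) add("region", NA, paste0("no material for tag '", tag, "'"))
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(component = character(), index = integer(), problem = character())
  }
}

# crude but deterministic planar self-intersection test: project the loop on
# its best-fit plane and test non-adjacent segment pairs. Loops here are
# small (tens of nodes), O(n^2) is fine.
polyline_self_intersects <- function(pts) {
  n <- nrow(pts)
  if (n < 4L) return(FALSE)
  ctr <- colMeans(pts)
  q <- sweep(pts, 2L, ctr)
  sv <- svd(q, nu = 0L, nv = 3L)
  uv <- q %*% sv$v[, 1:2]
  seg <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j > n) break
      if (segments_cross(uv[seg[i, 1], ], uv[seg[i, 2], ],
                         uv[seg[j, 1], ], uv[seg[j, 2], ])) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}
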