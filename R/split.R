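# Internal conforming subdivision utilities: triangular-prism columns are the
# common backbone of every generator in the package (flat slab, curved wall,
# icosphere shells). Prisms are split into 3 tets each with face diagonals
# chosen through the globally smallest node index of each quad face; both
# prisms sharing a quad face then agree on its diagonal, so the resulting
# tet mesh is conforming.

# orientation-preserving prism symmetries bringing local position k to 1
# (vertical pairs 1-4, 2-5, 3-6 are preserved)
prism_perm <- matrix(c(1L, 2L, 3L, 4L, 5L, 6L,
                       2L, 3L, 1L, 5L, 6L, 4L,
                       3L, 1L, 2L, 6L, 4L, 5L,
                       4L, 6L, 5L, 1L, 3L, 2L,
                       5L, 4L, 6L, 2L, 1L, 3L,
                       6L, 5L, 4L, 3L, 2L, 1L), nrow = 6L, byrow = TRUE)

# prisms: n x 6 matrix of global node ids, positively oriented (tet 1-2-3-4
# has positive volume). Returns 3n x 4 tet connectivity; tets i, n+i, 2n+i
# derive from prism i.
prisms_to_tets <- function(prisms) {
  n <- nrow(prisms)
  minpos <- max.col(-prisms, ties.method = "first")
  idx <- prism_perm[minpos, , drop = FALSE]
  L <- matrix(prisms[cbind(rep(seq_len(n), 6L), as.vector(idx))], n, 6L)
  # face (2,3,6,5): diagonal through its min vertex
  m2356 <- pmin(L[, 2], L[, 3], L[, 5], L[, 6])
  caseA <- m2356 == L[, 2] | m2356 == L[, 6]   # diagonal 2-6
  t1 <- cbind(L[, 1], L[, 2], L[, 3], ifelse(caseA, L[, 6], L[, 5]))
  t2 <- cbind(L[, 1],
              ifelse(caseA, L[, 2], L[, 5]),
              ifelse(caseA, L[, 6], L[, 3]),
              ifelse(caseA, L[, 5], L[, 6]))
  t3 <- cbind(L[, 1], L[, 5], L[, 6], L[, 4])
  tets <- rbind(t1, t2, t3)
  storage.mode(tets) <- "integer"
  tets
}

# Extrude a 2D triangulation through a stack of sheets into prisms.
# points2: n2 x 2, tris: m x 3 (counterclockwise), sheet_z: increasing z of
# each node sheet. Global node ids: (sheet-1)*n2 + node2d.
# Returns list(nodes, prisms, layer) where layer[i] gives the element layer
# (1 = bottom) of prism i.
extrude_triangulation <- function(points2, tris, sheet_z) {
  n2 <- nrow(points2)
  ns <- length(sheet_z)
  stopifnot(ns >= 2L, !is.unsorted(sheet_z, strictly = TRUE))
  nodes <- cbind(points2[rep(seq_len(n2), ns), , drop = FALSE],
                 rep(sheet_z, each = n2))
  m <- nrow(tris)
  prisms <- vector("list", ns - 1L)
  for (l in seq_len(ns - 1L)) {
    off_b <- (l - 1L) * n2
    off_t <- l * n2
    prisms[[l]] <- cbind(tris + off_b, tris + off_t)
  }
  list(nodes = nodes,
       prisms = do.call(rbind, prisms),
       layer = rep(seq_len(ns - 1L), each = m))
}

# split counterclockwise quads (n x 4) into triangles along the a-c diagonal
quads_to_tris <- function(quads) {
  rbind(quads[, c(1L, 2L, 3L), drop = FALSE],
        quads[, c(1L, 3L, 4L), drop = FALSE])
}

# structured quad connectivity of an (nx x ny)-node tensor grid, node ids
# column-major with x fastest: id(i, j) = (j-1)*nx + i
grid_quads <- function(nx, ny) {
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  a <- (j - 1L) * nx + i
  cbind(a, a + 1L, a + nx + 1L, a + nx)
}
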