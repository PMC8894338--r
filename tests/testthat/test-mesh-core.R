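test_that("tet volumes: analytic unit tet and renumbering invariance", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m <- tet_mesh(nodes, rbind(1:4), "A")
  expect_equal(tet_volumes(m), 1 / 6)

  cube <- coarse_cube()
  perm <- rev(seq_len(nrow(cube$nodes)))
  inv <- order(perm)
  m2 <- tet_mesh(cube$nodes[perm, ], matrix(inv[cube$tets], ncol = 4L),
                 cube$regions, repair = FALSE)
  expect_equal(mesh_volume(m2), mesh_volume(cube))
})

test_that("constructor repairs negatively oriented tets and flags bad input", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_message(m <- tet_mesh(nodes, rbind(c(1, 2, 4, 3)), "A"),
                 "repaired orientation of 1")
  expect_gt(tet_volumes(m), 0)

  expect_error(tet_mesh(nodes, matrix(integer(0), 0, 4), character(0)),
               "no volume elements")
  expect_error(tet_mesh(nodes, rbind(1:4), ""), "untagged region")
  expect_error(tet_mesh(nodes, rbind(c(1, 2, 3, 9)), "A"), "nonexistent")
})

test_that("validate_mesh reports inverted tets, bad groups and bad loops", {
  cube <- coarse_cube()
  expect_identical(nrow(validate_mesh(cube)), 0L)

  bad <- cube
  bad$tets[5L, c(3, 4)] <- bad$tets[5L, c(4, 3)]   # invert one tet
  rep1 <- validate_mesh(bad)
  expect_true(any(rep1$component == "tet" & rep1$index == 5L &
                  rep1$problem == "non-positive volume"))

  bad2 <- cube
  interior <- which(apply(cube$nodes, 1L, function(p) all(p > 0.2 & p < 0.8)))
  bad2$facet_groups$floating <- matrix(interior[1:3], 1L)
  expect_true(any(grepl("not on mesh boundary", validate_mesh(bad2)$problem)))

  bad3 <- cube
  ring <- which(abs(cube$nodes[, 3]) < 1e-12 & abs(cube$nodes[, 2]) < 1e-12)
  bad3$loops$short <- ring[1:4]
  expect_true(any(grepl("fewer than 8", validate_mesh(bad3)$problem)))
  bad3$loops$short <- c(ring[1:4], ring[1:4])      # repeated interior node
  expect_true(any(validate_mesh(bad3)$problem == "non-simple loop"))

  mats <- material_table("not_cube", 1, 0.3)
  expect_true(any(grepl("no material for tag 'cube'",
                        validate_mesh(cube, mats)$problem)))
})

test_that("boundary faces of the cube equal the union of its face groups", {
  cube <- coarse_cube()
  bf <- mesh_boundary_faces(cube)
  declared <- do.call(rbind, cube$facet_groups)
  key <- function(f) {
    s <- t(apply(f, 1L, sort.int))
    sort(paste(s[, 1], s[, 2], s[, 3]))
  }
  expect_identical(key(bf), key(declared))
  expect_identical(anyDuplicated(key(bf)), 0L)
})

test_that("gmsh 4.1 write/read round-trips coordinates, tags and groups", {
  m <- small_phantom("s21")
  path <- withr::local_tempfile(fileext = ".msh")
  write_gmsh(m, path)
  m2 <- read_gmsh(path)

  expect_identical(m2$nodes, m$nodes)
  a <- canon_tets(m$tets, m$regions)
  b <- canon_tets(m2$tets, m2$regions)
  expect_identical(b$tets, a$tets)
  expect_identical(b$regions, a$regions)
  expect_setequal(names(m2$facet_groups), names(m$facet_groups))
  expect_identical(m2$loops$trephine_inner_loop, m$loops$trephine_inner_loop)
  expect_identical(sort(m2$node_groups$fixed_edges),
                   sort(m$node_groups$fixed_edges))
  expect_identical(nrow(validate_mesh(m2)), 0L)
})

test_that("reader accepts the legacy 2.2 dialect", {
  path <- withr::local_tempfile(fileext = ".msh")
  writeLines(c(
    "$MeshFormat", "2.2 0 8", "$EndMeshFormat",
    "$PhysicalNames", "1", '3 7 "solid"', "$EndPhysicalNames",
    "$Nodes", "4",
    "1 0 0 0", "2 1 0 0", "3 0 1 0", "4 0 0 1",
    "$EndNodes",
    "$Elements", "1", "1 4 2 7 1 1 2 3 4", "$EndElements"), path)
  m <- read_gmsh(path)
  expect_identical(nrow(m$nodes), 4L)
  expect_identical(m$regions, "solid")
  expect_equal(tet_volumes(m), 1 / 6)
})

test_that("reader errors are specific", {
  p <- withr::local_tempfile(fileext = ".msh")
  writeLines(c("$MeshFormat", "3.0 0 8", "$EndMeshFormat"), p)
  expect_error(read_gmsh(p), "unsupported msh dialect")

  writeLines(c(
    "$MeshFormat", "2.2 0 8", "$EndMeshFormat",
    "$Nodes", "3", "1 0 0 0", "2 1 0 0", "3 0 1 0", "$EndNodes",
    "$Elements", "1", "1 2 1 5 1 2 3", "$EndElements"), p)
  expect_error(read_gmsh(p), "no volume elements")
})

test_that("writer refuses invalid meshes and warns on empty facet groups", {
  cube <- coarse_cube()
  bad <- cube
  bad$loops$broken <- bad$tets[1L, c(1, 2, 3, 1)]
  expect_error(write_gmsh(bad, withr::local_tempfile()), "refusing to write")

  m <- cube
  m$facet_groups$empty_group <- matrix(integer(0), 0L, 3L)
  path <- withr::local_tempfile(fileext = ".msh")
  expect_warning(write_gmsh(m, path), "empty facet group")
  m2 <- read_gmsh(path)
  expect_false("empty_group" %in% names(m2$facet_groups))
})

test_that("vtu export checks field sizes and writes both field kinds", {
  cube <- coarse_cube()
  path <- withr::local_tempfile(fileext = ".vtu")
  u <- matrix(0, nrow(cube$nodes), 3L)
  vm <- numeric(nrow(cube$tets))
  write_vtk(cube, node_fields = list(displacement = u),
            cell_fields = list(von_mises = vm), path = path)
  txt <- readLines(path)
  expect_true(any(grepl('Name="displacement"', txt)))
  expect_true(any(grepl('Name="von_mises"', txt)))
  expect_true(any(grepl("UnstructuredGrid", txt)))

  expect_error(
    write_vtk(cube, cell_fields = list(oops = vm[-1]), path = path),
    "cell field 'oops'")
})

test_that("stl export writes the expected number of boundary triangles", {
  cube <- coarse_cube()
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(cube, path)
  n_declared <- sum(vapply(cube$facet_groups, nrow, 1L))
  expect_identical(file.size(path), 84 + 50 * as.numeric(n_declared))
})
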