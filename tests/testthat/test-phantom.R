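test_that("phantom generation is deterministic and valid", {
  a <- build_wall_phantom(small_spec("s11"))
  b <- build_wall_phantom(small_spec("s11"))
  expect_identical(a, b)
  expect_identical(nrow(validate_mesh(a, default_materials())), 0L)

  plain <- small_phantom()
  expect_identical(nrow(validate_mesh(plain)), 0L)
  expect_false(any(grepl("trephine", names(plain$facet_groups))))
  expect_identical(length(plain$loops), 0L)
})

test_that("hole-free phantom is mirror-symmetric about the midline", {
  m <- small_phantom()
  n <- m$nodes
  mirrored <- cbind(-n[, 1], n[, 2], n[, 3])
  o1 <- do.call(order, as.data.frame(round(n, 9)))
  o2 <- do.call(order, as.data.frame(round(mirrored, 9)))
  expect_lt(max(abs(n[o1, ] - mirrored[o2, ])), 1e-9)
})

test_that("trephine loop sits exactly on the requested circle", {
  m <- small_phantom("s21")
  expect_true(all(c("trephine_inner_loop", "trephine_outer_loop") %in%
                  names(m$loops)))
  expect_true("trephine_wall" %in% names(m$facet_groups))
  expect_identical(length(m$loops$trephine_inner_loop), 32L)

  ref <- measure_loop(extract_trephine_loop(m, "trephine_inner_loop"))
  # inscribed regular 32-gon on a d = 2 cm circle
  expect_equal(ref$perimeter_cm, 32 * 2 * sin(pi / 32), tolerance = 1e-3)
  # the loop lives on a strongly curved wall (Rc = 100 mm here), so its
  # Newell area sits slightly below the developed-plane polygon area
  expect_equal(ref$area_cm2, 0.5 * 32 * sin(2 * pi / 32), tolerance = 3e-3)
})

test_that("mesh volume matches the closed-form slab-minus-polygon volume", {
  spec <- small_spec("s21")
  m <- build_wall_phantom(spec)
  t_total <- sum(spec$layer_thicknesses)
  hole_area <- 0.5 * spec$circle_nodes * sin(2 * pi / spec$circle_nodes) *
    (spec$hole_diameter / 2)^2
  expected <- spec$width * spec$height * t_total - hole_area * t_total
  expect_equal(mesh_volume(m), expected, tolerance = 0.01)

  plain <- small_phantom()
  expect_equal(mesh_volume(plain),
               spec$width * spec$height * t_total, tolerance = 0.01)
})

test_that("stoma grid follows the labelling scheme monotonically", {
  pos <- stoma_positions()
  expect_identical(nrow(pos), 17L)
  expect_identical(pos$label[1L], "s0")
  expect_identical(sum(pos$i == 1L), 6L)
  expect_identical(sum(pos$i == 2L), 6L)
  expect_identical(sum(pos$i == 3L), 4L)
  # lateral offset strictly grows with i, height strictly grows with j
  off <- tapply(abs(pos$x[pos$i > 0]), pos$i[pos$i > 0], unique)
  expect_true(all(diff(unlist(off)) > 0))
  for (ii in 1:3) {
    y <- pos$y[pos$i == ii][order(pos$j[pos$i == ii])]
    expect_true(all(diff(y) > 0))
  }
  expect_identical(pos$x[pos$label == "s0"], 0)
})

test_that("the stiff strip spans the full height and both halves", {
  m <- small_phantom()
  la <- m$tets[m$regions == "LA", , drop = FALSE]
  la_nodes <- unique(as.vector(la))
  expect_gt(max(m$nodes[la_nodes, 1]), 0)
  expect_lt(min(m$nodes[la_nodes, 1]), 0)
  expect_equal(range(m$nodes[la_nodes, 2]), c(0, 200))
  # the four strata all present outside the strip
  expect_setequal(unique(m$regions), c("EO", "IO", "RA", "TR", "LA"))
})

test_that("generator refuses impossible hole placements and resolutions", {
  expect_error(phantom_spec(width = 80, hole_position = "s31"),
               "too close to the fixed boundary")
  expect_error(phantom_spec(circle_nodes = 8), "at least 16")
  expect_error(phantom_spec(hole_position = "s99"), "unknown hole position")
})

test_that("seeded jitter is deterministic and leaves the rim untouched", {
  s1 <- small_spec("s21"); s1$seed <- 7L
  a <- build_wall_phantom(s1)
  b <- build_wall_phantom(s1)
  expect_identical(a, b)
  plainspec <- small_spec("s21")
  c0 <- build_wall_phantom(plainspec)
  expect_false(identical(a$nodes, c0$nodes))
  expect_identical(a$nodes[a$loops$trephine_inner_loop, ],
                   c0$nodes[c0$loops$trephine_inner_loop, ])
  expect_identical(nrow(validate_mesh(a)), 0L)
})

test_that("verification fixtures have the advertised geometry", {
  sph <- build_hollow_sphere(10, 20, 2.5)
  expect_equal(mesh_volume(sph), 4 * pi / 3 * (20^3 - 10^3), tolerance = 0.01)
  inner <- sph$facet_groups$inner_surface
  expect_equal(sum(wallfem:::facet_areas(sph$nodes, inner)), 4 * pi * 100,
               tolerance = 0.01)
  expect_identical(nrow(validate_mesh(sph)), 0L)
  expect_error(build_hollow_sphere(20, 10, 2), "radii")

  cube <- coarse_cube()
  expect_identical(mesh_volume(cube), 1)
  expect_identical(length(cube$facet_groups), 6L)
  for (g in cube$facet_groups) {
    expect_equal(sum(wallfem:::facet_areas(cube$nodes, g)), 1)
  }
  expect_identical(length(cube$node_groups$corners), 8L)
})
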