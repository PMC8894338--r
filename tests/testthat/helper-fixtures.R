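# shared lazily-built fixtures; building meshes is the expensive part of
# this suite, so anything used twice is cached here
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_spec <- function(hole = NULL) {
  phantom_spec(width = 150, height = 200, layer_thicknesses = c(3, 3, 3, 3),
               strip_width = 20, curvature_radius = 100, resolution = 12,
               circle_nodes = 32, rings = 4, hole_position = hole)
}

small_phantom <- function(hole = NULL) {
  key <- paste0("small_phantom_", hole %||% "none")
  fixture(key, function() build_wall_phantom(small_spec(hole)))
}

coarse_cube <- function() fixture("cube", function() build_unit_cube(0.25))

default_wall_solution <- function() {
  fixture("default_wall_solution", function() {
    mesh <- build_wall_phantom(phantom_spec())
    sol <- solve_displacements(mesh, default_materials(), load_case(0.02))
    list(mesh = mesh, sol = sol)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# closed regular polygon on a circle in 3D
circle_loop <- function(n, diameter = 20, center = c(0, 0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + diameter / 2 * cos(th),
        center[2] + diameter / 2 * sin(th),
        center[3])
}

# canonical form of a connectivity matrix for order-insensitive comparison
canon_tets <- function(tets, regions) {
  s <- t(apply(tets, 1L, sort.int))
  o <- do.call(order, c(as.data.frame(s), list(regions)))
  list(tets = s[o, , drop = FALSE], regions = regions[o])
}
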