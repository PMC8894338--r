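test_that("isotropic Hooke matrix: closed forms and positive definiteness", {
  D0 <- hooke_isotropic(1, 0)
  expect_equal(unname(diag(D0)), c(1, 1, 1, 0.5, 0.5, 0.5))
  expect_equal(D0[1, 2], 0)

  # rectus abdominis modulus: lambda = 0.3 MPa, mu = 0.2 MPa exactly
  D <- hooke_isotropic(0.52, 0.3)
  expect_equal(D[1, 2], 0.3)
  expect_equal(D[4, 4], 0.2)
  expect_equal(D[1, 1], 0.7)

  for (E in c(0.52, 1, 72)) {
    for (nu in c(0, 0.3, 0.49)) {
      expect_gt(min(eigen(hooke_isotropic(E, nu), symmetric = TRUE,
                          only.values = TRUE)$values), 0)
    }
  }
  expect_error(hooke_isotropic(1, 0.5), "incompressible")
})

test_that("stiffness operator annihilates rigid-body motions", {
  cube <- coarse_cube()
  mats <- material_table("cube", 1.03, 0.3)
  K <- assemble_stiffness(cube, mats)
  expect_lt(max(abs(K - Matrix::t(K))) / max(abs(K)), 1e-10)

  n <- nrow(cube$nodes)
  scale_K <- max(abs(K))
  for (tr in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    u <- as.vector(t(matrix(tr, n, 3, byrow = TRUE)))
    expect_lt(max(abs(K %*% u)), 1e-10 * scale_K)
  }
  om <- c(0.3, -0.2, 0.5)
  rot <- t(apply(cube$nodes, 1L, function(p) {
    c(om[2] * p[3] - om[3] * p[2],
      om[3] * p[1] - om[1] * p[3],
      om[1] * p[2] - om[2] * p[1])
  }))
  expect_lt(max(abs(K %*% as.vector(t(rot)))), 1e-8 * scale_K)
})

test_that("strain energy of a uniform state matches the closed form", {
  cube <- coarse_cube()
  E <- 0.65; nu <- 0.3
  mats <- material_table("cube", E, nu)
  K <- assemble_stiffness(cube, mats)
  eps <- c(0.01, -0.005, 0.002, 0.003, -0.001, 0.004)
  A <- rbind(c(eps[1], eps[4] / 2, eps[6] / 2),
             c(eps[4] / 2, eps[2], eps[5] / 2),
             c(eps[6] / 2, eps[5] / 2, eps[3]))
  u <- as.vector(t(cube$nodes %*% t(A)))
  D <- hooke_isotropic(E, nu)
  expected <- as.numeric(eps %*% D %*% eps) * mesh_volume(cube)
  expect_equal(as.numeric(u %*% (K %*% u)), expected, tolerance = 1e-8)
})

test_that("consistent pressure load: single facet, closed surface, linearity", {
  nodes <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0), c(0, 0, 1))
  m <- tet_mesh(nodes, rbind(1:4), "A")
  m$facet_groups$base <- rbind(c(1L, 3L, 2L))   # outward normal -z, area 3
  p <- 0.7
  f <- assemble_pressure_load(m, "base", p)
  fm <- matrix(f, ncol = 3L, byrow = TRUE)
  expect_equal(colSums(fm), c(0, 0, p * 3))           # pushes inward (+z)
  expect_equal(fm[1, ], c(0, 0, p))                   # A/3 per node
  expect_equal(assemble_pressure_load(m, "base", 2 * p), 2 * f)

  sph <- build_hollow_sphere(10, 20, 4)
  fs <- assemble_pressure_load(sph, "inner_surface", 0.02)
  area <- sum(wallfem:::facet_areas(sph$nodes, sph$facet_groups$inner_surface))
  fsm <- matrix(fs, ncol = 3L, byrow = TRUE)
  expect_lt(sqrt(sum(colSums(fsm)^2)), 1e-8 * 0.02 * area)

  expect_error(assemble_pressure_load(m, "nope", 1), "unknown facet group")
  m$facet_groups$base <- rbind(c(1L, 2L, 3L))   # inward-oriented facet
  expect_error(assemble_pressure_load(m, "base", 1),
               "inconsistent facet orientation")
})

test_that("missing material names the offending tag", {
  cube <- coarse_cube()
  expect_error(assemble_stiffness(cube, material_table("muscle", 1, 0.3)),
               "no material for tag 'cube'")
})

test_that("zero pressure and insufficient constraints behave as specified", {
  cube <- coarse_cube()
  cube$node_groups$fixed_edges <- cube$node_groups$corners
  mats <- material_table("cube", 1, 0.3)
  sol <- solve_displacements(cube, mats, load_case(0, group = "zmax"))
  expect_identical(max(abs(sol$u)), 0)
  expect_error(
    solve_displacements(cube, mats,
                        load_case(0.01, group = "zmax", fixed_group = NULL)),
    "insufficient constraints")
})

test_that("patch test: traction-loaded cube reproduces the uniform state", {
  res <- verify_patch_test(material_table("RA", 0.52, 0.3), resolution = 0.34)
  expect_lt(res$max_rel_error, 1e-8)
  expect_lt(res$stress_rel_error, 1e-8)
})

test_that("direct and iterative solvers agree", {
  cube <- coarse_cube()
  cube$node_groups$fixed_edges <- which(abs(cube$nodes[, 3]) < 1e-12)
  mats <- material_table("cube", 1, 0.3)
  lc <- load_case(0.01, group = "zmax")
  u1 <- solve_displacements(cube, mats, lc, method = "direct")
  u2 <- solve_displacements(cube, mats, lc, method = "cg", cg_tol = 1e-12)
  expect_lt(max(abs(u1$u - u2$u)), 1e-8 * max(abs(u1$u)))
  # determinism of the direct path
  u3 <- solve_displacements(cube, mats, lc, method = "direct")
  expect_identical(u1$u, u3$u)
})

test_that("strain/stress post-processing closed forms", {
  cube <- coarse_cube()
  mats <- material_table("cube", 2, 0.25)
  u_rigid <- matrix(rep(c(3, -1, 2), each = nrow(cube$nodes)), ncol = 3L)
  ss <- compute_strain_stress(cube, mats, u_rigid)
  expect_lt(max(abs(ss$strain)), 1e-12)
  expect_lt(max(ss$von_mises), 1e-12)

  # uniaxial stress state via prescribed linear displacement
  E <- 2; nu <- 0.25; s <- 0.1
  u_uni <- cbind(s / E * cube$nodes[, 1],
                 -nu * s / E * cube$nodes[, 2],
                 -nu * s / E * cube$nodes[, 3])
  ss2 <- compute_strain_stress(cube, mats, u_uni)
  expect_equal(max(abs(ss2$von_mises - s)), 0, tolerance = 1e-10)
  expect_equal(unname(colMeans(ss2$stress)), c(s, 0, 0, 0, 0, 0),
               tolerance = 1e-10)
})

test_that("von Mises closed forms and rotation invariance", {
  expect_identical(von_mises(diag(c(1, 0, 0))), 1)
  expect_identical(von_mises(diag(c(2, 2, 2))), 0)
  tau <- 0.37
  shear <- matrix(c(0, tau, 0, tau, 0, 0, 0, 0, 0), 3L)
  expect_equal(von_mises(shear), sqrt(3) * tau)

  expect_lt(verify_von_mises_invariance(n_tensors = 100)$max_deviation, 1e-10)
  expect_error(von_mises(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3L)),
               "symmetric")
})
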