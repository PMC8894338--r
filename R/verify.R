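#' Analytic verification suite
#'
#' Three classic solver verifications with closed-form oracles, returned as
#' tidy tibbles so they can be inspected, plotted or asserted on:
#'
#' * [verify_patch_test()] loads a unit cube with a uniform normal pressure
#'   on its top face, holds the bottom face flat and checks that the P1
#'   solution reproduces the homogeneous uniaxial-stress state (linear
#'   displacement, constant stress) to solver precision — separately for
#'   every material in the table.
#' * [verify_lame_sphere()] pressurises a hollow sphere internally and
#'   compares the inner-surface radial displacement with the Lame closed
#'   form `u(r) = p a^3 r / (E (b^3 - a^3)) ((1 - 2 nu) + (1 + nu) b^3 /
#'   (2 r^3))`, across a sequence of mesh resolutions.
#' * [verify_von_mises_invariance()] checks rotation invariance of the von
#'   Mises stress on random symmetric tensors.
#'
#' @name verification
NULL

#' @param materials a [material_table()]; one patch test per row.
#' @param resolution cube edge length (mm).
#' @param pressure applied pressure (MPa).
#' @return A tibble with one row per material: `region`, `E`, `nu`,
#'   `max_rel_error` (displacement, against the analytic uniform state) and
#'   `stress_rel_error` (element stresses against the constant oracle).
#' @rdname verification
#' @export
verify_patch_test <- function(materials = default_materials(),
                              resolution = 0.25, pressure = 0.02) {
  cube <- build_unit_cube(resolution)
  nd <- cube$nodes
  zmin_nodes <- which(abs(nd[, 3]) < 1e-12)
  origin <- which(rowSums(abs(nd)) < 1e-12)
  xaxis <- which(abs(nd[, 2]) < 1e-12 & abs(nd[, 3]) < 1e-12)
  con <- rbind(
    data.frame(node = zmin_nodes, dof = 3L, value = 0),
    data.frame(node = origin, dof = 1L, value = 0),
    data.frame(node = xaxis, dof = 2L, value = 0))
  lc <- load_case(pressure, group = "zmax", fixed_group = NULL)
  purrr::pmap_dfr(materials, function(region, E, nu) {
    mat <- material_table("cube", E, nu)
    sol <- solve_displacements(cube, mat, lc, constraints = con)
    # pressure presses down: sigma_zz = -p, lateral expansion nu p / E
    uex <- cbind(nu * pressure / E * nd[, 1],
                 nu * pressure / E * nd[, 2],
                 -pressure / E * nd[, 3])
    ss <- compute_strain_stress(cube, mat, sol)
    sex <- c(0, 0, -pressure, 0, 0, 0)
    tibble::tibble(
      region = region, E = E, nu = nu,
      max_rel_error = max(abs(sol$u - uex)) / max(abs(uex)),
      stress_rel_error = max(abs(sweep(ss$stress, 2L, sex))) / pressure)
  })
}

#' @param inner_radius,outer_radius,E,nu,pressure Lame problem data
#'   (mm, MPa).
#' @param resolutions decreasing target edge lengths (mm), one solve each.
#' @return A tibble with one row per resolution: node/element counts, the
#'   computed and analytic inner-surface radial displacement (mm) and
#'   `rel_error`.
#' @rdname verification
#' @export
verify_lame_sphere <- function(inner_radius = 10, outer_radius = 20,
                               E = 1, nu = 0.3, pressure = 0.02,
                               resolutions = c(5, 2.5, 1.25)) {
  a <- inner_radius; b <- outer_radius
  u_exact <- pressure * a^3 * a / (E * (b^3 - a^3)) *
    ((1 - 2 * nu) + (1 + nu) * b^3 / (2 * a^3))
  mat <- material_table("shell", E, nu)
  purrr::map_dfr(resolutions, function(res) {
    mesh <- build_hollow_sphere(a, b, res)
    sol <- solve_free_body(mesh, mat,
                           load_case(pressure, group = "inner_surface",
                                     fixed_group = NULL))
    nd <- mesh$nodes
    rad <- sqrt(rowSums(nd^2))
    inner <- which(abs(rad - a) < 1e-9 * b)
    ur <- rowSums(sol$u[inner, ] * nd[inner, ]) / rad[inner]
    tibble::tibble(resolution = res, nodes = nrow(nd), tets = nrow(mesh$tets),
                   u_inner = mean(ur), u_exact = u_exact,
                   rel_error = abs(mean(ur) - u_exact) / u_exact)
  })
}

# Equilibrated (net-zero) surface loads on an unconstrained body: pin six
# DOFs at three spread-out nodes to make the system definite, then project
# the best-fit rigid-body motion out of the solution.
solve_free_body <- function(mesh, materials, load) {
  nd <- mesh$nodes
  n1 <- which.max(nd[, 1])
  d2 <- rowSums(sweep(nd, 2L, nd[n1, ])^2)
  n2 <- which.max(d2)
  ax <- which.max(abs(nd[n2, ] - nd[n1, ]))
  perp <- setdiff(1:3, ax)
  e <- nd[n2, ] - nd[n1, ]
  cr <- cross3(matrix(e, nrow(nd), 3, byrow = TRUE), sweep(nd, 2L, nd[n1, ]))
  n3 <- which.max(rowSums(cr^2))
  nrm <- cr[n3, ]
  con <- data.frame(node = c(n1, n1, n1, n2, n2, n3),
                    dof = c(1L, 2L, 3L, perp, which.max(abs(nrm))),
                    value = 0)
  sol <- solve_displacements(mesh, materials, load, constraints = con)
  sol$u <- remove_rigid_motion(nd, sol$u)
  sol
}

# least-squares removal of t + omega x x from a displacement field
remove_rigid_motion <- function(nodes, u) {
  n <- nrow(nodes)
  A <- matrix(0, 3L * n, 6L)
  idx <- seq_len(n)
  A[3 * idx - 2, 1] <- 1; A[3 * idx - 1, 2] <- 1; A[3 * idx, 3] <- 1
  # omega x x = (w2 z3 - w3 z2, w3 z1 - w1 z3, w1 z2 - w2 z1)
  A[3 * idx - 2, 5] <- nodes[, 3]; A[3 * idx - 2, 6] <- -nodes[, 2]
  A[3 * idx - 1, 4] <- -nodes[, 3]; A[3 * idx - 1, 6] <- nodes[, 1]
  A[3 * idx, 4] <- nodes[, 2]; A[3 * idx, 5] <- -nodes[, 1]
  b <- as.vector(t(u))
  coef <- qr.coef(qr(A), b)
  matrix(b - A %*% coef, ncol = 3L, byrow = TRUE)
}

#' @param n_tensors,seed random symmetric tensors and rotations to sample.
#' @return A tibble with `max_deviation`: the largest absolute change of
#'   the von Mises stress under rotation.
#' @rdname verification
#' @export
verify_von_mises_invariance <- function(n_tensors = 50, seed = 1L) {
  set.seed(seed)
  dev <- replicate(n_tensors, {
    s <- matrix(stats::rnorm(9), 3L)
    s <- (s + t(s)) / 2
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
    abs(von_mises(q %*% s %*% t(q)) - von_mises(s))
  })
  tibble::tibble(n_tensors = n_tensors, max_deviation = max(dev))
}
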