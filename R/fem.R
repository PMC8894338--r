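#' Surface-pressure load case
#'
#' Describes one loading scenario: a uniform pressure (MPa) applied to a
#' named facet group, with a named node group held at zero displacement.
#' With mm/MPa/N units, an intraabdominal pressure of 20 kPa is
#' `pressure = 0.02`.
#'
#' @param pressure non-negative pressure magnitude in MPa.
#' @param group facet group carrying the pressure (default `"inner_surface"`).
#' @param fixed_group node group with zero prescribed displacement
#'   (default `"fixed_edges"`).
#' @return An object of class `"load_case"`.
#' @export
load_case <- function(pressure, group = "inner_surface",
                      fixed_group = "fixed_edges") {
  stopifnot(is.numeric(pressure), length(pressure) == 1L, pressure >= 0)
  structure(list(pressure = pressure, group = group, fixed_group = fixed_group),
            class = "load_case")
}

# P1 shape-function gradients and volumes, vectorised over all tets.
# Returns grad: m x 4 x 3 array (grad[, a, ] = grad of the hat function of
# local node a), vol: length-m vector.
shape_gradients <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - p1
  c_ <- nodes[tets[, 3], , drop = FALSE] - p1
  d <- nodes[tets[, 4], , drop = FALSE] - p1
  det <- b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
         b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
         b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])
  if (any(det <= 0)) stop("non-positive tet volume during assembly")
  m <- nrow(tets)
  grad <- array(0, c(m, 4L, 3L))
  # columns of J^{-1} for J = rbind(b, c, d); cofactor formulas
  grad[, 2L, 1L] <- (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) / det
  grad[, 2L, 2L] <- (c_[, 3] * d[, 1] - c_[, 1] * d[, 3]) / det
  grad[, 2L, 3L] <- (c_[, 1] * d[, 2] - c_[, 2] * d[, 1]) / det
  grad[, 3L, 1L] <- (d[, 2] * b[, 3] - d[, 3] * b[, 2]) / det
  grad[, 3L, 2L] <- (d[, 3] * b[, 1] - d[, 1] * b[, 3]) / det
  grad[, 3L, 3L] <- (d[, 1] * b[, 2] - d[, 2] * b[, 1]) / det
  grad[, 4L, 1L] <- (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) / det
  grad[, 4L, 2L] <- (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) / det
  grad[, 4L, 3L] <- (b[, 1] * c_[, 2] - b[, 2] * c_[, 1]) / det
  grad[, 1L, ] <- -(grad[, 2L, ] + grad[, 3L, ] + grad[, 4L, ])
  list(grad = grad, vol = det / 6)
}

region_lame <- function(mesh, materials) {
  idx <- match(mesh$regions, materials$region)
  if (anyNA(idx)) {
    stop("no material for tag '",
         mesh$regions[which(is.na(idx))[1L]], "'")
  }
  lc <- lame_constants(materials$E[idx], materials$nu[idx])
  lc
}

#' Assemble the global stiffness operator
#'
#' Builds the sparse symmetric stiffness matrix of P1 isotropic linear
#' elasticity on the mesh, 3 unknowns per node ordered
#' `(u_x1, u_y1, u_z1, u_x2, ...)`. Before constraints its kernel consists
#' of the six rigid-body modes.
#'
#' @param mesh a [tet_mesh()].
#' @param materials a [material_table()] covering all region tags.
#' @return A `dgCMatrix` of dimension `3 N x 3 N`.
#' @export
assemble_stiffness <- function(mesh, materials) {
  sg <- shape_gradients(mesh$nodes, mesh$tets)
  lc <- region_lame(mesh, materials)
  m <- nrow(mesh$tets)
  lamV <- lc$lambda * sg$vol
  muV <- lc$mu * sg$vol
  # per-pair 3x3 blocks: K_ab = V [ lam ga gb^T + mu gb ga^T + mu (ga.gb) I ]
  ii <- vector("list", 144L); jj <- vector("list", 144L); xx <- vector("list", 144L)
  k <- 0L
  for (a in 1:4) {
    ga <- sg$grad[, a, , drop = TRUE]
    if (m == 1L) ga <- matrix(ga, 1L)
    rowa <- 3L * (mesh$tets[, a] - 1L)
    for (b in 1:4) {
      gb <- sg$grad[, b, , drop = TRUE]
      if (m == 1L) gb <- matrix(gb, 1L)
      colb <- 3L * (mesh$tets[, b] - 1L)
      dot_ab <- muV * rowSums(ga * gb)
      for (i in 1:3) {
        for (j in 1:3) {
          k <- k + 1L
          val <- lamV * ga[, i] * gb[, j] + muV * gb[, i] * ga[, j]
          if (i == j) val <- val + dot_ab
          ii[[k]] <- rowa + i
          jj[[k]] <- colb + j
          xx[[k]] <- val
        }
      }
    }
  }
  Matrix::sparseMatrix(i = unlist(ii, use.names = FALSE),
                       j = unlist(jj, use.names = FALSE),
                       x = unlist(xx, use.names = FALSE),
                       dims = c(3L, 3L) * nrow(mesh$nodes))
}

# canonical rotation of a triangle cycle: smallest node first
canon_cycle <- function(tris) {
  shift <- max.col(-tris, ties.method = "first")
  n <- nrow(tris)
  idx <- cbind(shift, shift %% 3L + 1L, (shift + 1L) %% 3L + 1L)
  matrix(tris[cbind(rep(seq_len(n), 3L), as.vector(idx))], n, 3L)
}

# TRUE per facet if its stored orientation matches the solid-outward
# orientation derived from the tetrahedra
facets_outward <- function(mesh, facets) {
  bf <- mesh_boundary_faces(mesh)
  bc <- canon_cycle(bf)
  bkey <- paste(bc[, 1], bc[, 2], bc[, 3], sep = "/")
  fc <- canon_cycle(facets)
  fkey <- paste(fc[, 1], fc[, 2], fc[, 3], sep = "/")
  fkey %in% bkey
}

#' Consistent nodal forces of a uniform surface pressure
#'
#' Converts a uniform pressure on an oriented facet group into the
#' work-consistent P1 nodal force vector: each triangle of area `A`
#' contributes a force `p A` along its inward-pushing normal (the opposite
#' of the solid's outward normal), split equally over its three nodes.
#' The load acts on the reference configuration (dead load).
#'
#' @param mesh a [tet_mesh()].
#' @param group name of the facet group.
#' @param pressure pressure magnitude in MPa.
#' @return Numeric vector of length `3 N` (forces in N).
#' @export
assemble_pressure_load <- function(mesh, group, pressure) {
  if (!group %in% names(mesh$facet_groups)) {
    stop("unknown facet group '", group, "'; available: ",
         paste(names(mesh$facet_groups), collapse = ", "))
  }
  facets <- mesh$facet_groups[[group]]
  f <- numeric(3L * nrow(mesh$nodes))
  if (nrow(facets) == 0L || pressure == 0) return(f)
  if (!all(facets_outward(mesh, facets))) {
    stop("inconsistent facet orientation in group '", group, "'")
  }
  an <- facet_area_normals(mesh$nodes, facets)   # norm = 2 A, outward
  fc <- -pressure * an / 2                        # total facet force, inward
  for (a in 1:3) {
    for (c_ in 1:3) {
      idx <- 3L * (facets[, a] - 1L) + c_
      add <- fc[, c_] / 3
      agg <- rowsum(add, idx)
      f[as.integer(rownames(agg))] <- f[as.integer(rownames(agg))] + agg[, 1L]
    }
  }
  f
}

fixed_dof_indices <- function(mesh, load, constraints = NULL) {
  fixed <- integer(0)
  values <- numeric(0)
  if (!is.null(load$fixed_group)) {
    if (!load$fixed_group %in% names(mesh$node_groups)) {
      stop("unknown node group '", load$fixed_group, "'")
    }
    g <- mesh$node_groups[[load$fixed_group]]
    fixed <- as.vector(t(outer(3L * (g - 1L), 1:3, `+`)))
    values <- numeric(length(fixed))
  }
  if (!is.null(constraints)) {
    stopifnot(all(c("node", "dof") %in% names(constraints)))
    v <- if ("value" %in% names(constraints)) constraints$value else
      numeric(nrow(constraints))
    fixed <- c(fixed, 3L * (constraints$node - 1L) + constraints$dof)
    values <- c(values, v)
  }
  keep <- !duplicated(fixed)
  list(dofs = fixed[keep], values = values[keep])
}

#' Solve the constrained elastic equilibrium
#'
#' Assembles stiffness and pressure load, eliminates the fixed degrees of
#' freedom and solves `K u = f` with a sparse Cholesky factorisation
#' (default) or Jacobi-preconditioned conjugate gradients.
#'
#' @param mesh a [tet_mesh()].
#' @param materials a [material_table()].
#' @param load a [load_case()].
#' @param constraints optional data frame of extra homogeneous or
#'   inhomogeneous single-DOF constraints with columns `node`, `dof`
#'   (1 = x, 2 = y, 3 = z) and optionally `value` (mm).
#' @param method `"direct"` (deterministic, default) or `"cg"`.
#' @param cg_tol relative residual tolerance for the iterative solver.
#' @return An object of class `"displacement_field"`: list with `u`
#'   (N x 3 matrix, mm), `fixed_dofs`, `reactions` (N x 3, N, nonzero only
#'   on constrained DOFs), and `residual` (relative algebraic residual).
#' @export
solve_displacements <- function(mesh, materials, load, constraints = NULL,
                                method = c("direct", "cg"), cg_tol = 1e-10) {
  method <- match.arg(method)
  K <- assemble_stiffness(mesh, materials)
  f <- assemble_pressure_load(mesh, load$group, load$pressure)
  solve_linear_system(mesh, K, f, load, constraints, method, cg_tol)
}

# split out so the pipeline can reuse one factorisation-ready K per geometry
solve_linear_system <- function(mesh, K, f, load, constraints = NULL,
                                method = "direct", cg_tol = 1e-10) {
  ndof <- nrow(K)
  fx <- fixed_dof_indices(mesh, load, constraints)
  if (length(fx$dofs) == 0L) stop("insufficient constraints")
  free <- setdiff(seq_len(ndof), fx$dofs)
  u <- numeric(ndof)
  u[fx$dofs] <- fx$values
  rhs <- f[free]
  if (any(fx$values != 0)) {
    rhs <- rhs - as.numeric(K[free, fx$dofs, drop = FALSE] %*% fx$values)
  }
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  if (method == "direct") {
    sol <- tryCatch({
      ch <- Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE)
      Matrix::solve(ch, rhs, system = "A")
    }, error = function(e) stop("insufficient constraints: ",
                                conditionMessage(e)))
    u[free] <- as.numeric(sol)
  } else {
    u[free] <- cg_solve(Kff, rhs, tol = cg_tol)
  }
  r <- as.numeric(K %*% u - f)
  fn <- sqrt(sum(f^2))
  residual <- if (fn > 0) sqrt(sum(r[free]^2)) / fn else sqrt(sum(r[free]^2))
  reactions <- matrix(0, nrow(mesh$nodes), 3L)
  reactions[cbind((fx$dofs - 1L) %/% 3L + 1L, (fx$dofs - 1L) %% 3L + 1L)] <-
    r[fx$dofs]
  structure(list(u = matrix(u, ncol = 3L, byrow = TRUE),
                 fixed_dofs = fx$dofs,
                 reactions = reactions,
                 residual = residual),
            class = "displacement_field")
}

cg_solve <- function(A, b, tol = 1e-10, maxit = 20000L) {
  d <- Matrix::diag(A)
  d[d == 0] <- 1
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  b2 <- sqrt(sum(b^2))
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * b2) return(x)
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop("conjugate gradients did not converge: relative residual ",
       format(sqrt(sum(r^2)) / b2, digits = 3))
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(rowSums(x$u^2))
  cat(sprintf("<displacement_field> %d nodes, max |u| = %.4g mm, residual %.2e\n",
              nrow(x$u), max(mag), x$residual))
  invisible(x)
}

#' Element strain, stress and von Mises stress
#'
#' Differentiates the P1 displacement field (element-constant gradients),
#' forms the small-strain tensor `eps = sym(grad u)`, applies the isotropic
#' Hooke law region by region and evaluates the von Mises stress of each
#' element.
#'
#' @param mesh a [tet_mesh()].
#' @param materials a [material_table()].
#' @param u a [solve_displacements()] result or a plain N x 3 matrix.
#' @return An object of class `"stress_state"`: list with `strain`
#'   (m x 6 Voigt, engineering shears), `stress` (m x 6, MPa), `von_mises`
#'   (length m, MPa) and `regions`.
#' @export
compute_strain_stress <- function(mesh, materials, u) {
  if (inherits(u, "displacement_field")) u <- u$u
  u <- as.matrix(u)
  if (nrow(u) != nrow(mesh$nodes)) stop("displacement field size mismatch")
  sg <- shape_gradients(mesh$nodes, mesh$tets)
  m <- nrow(mesh$tets)
  H <- array(0, c(m, 3L, 3L))   # displacement gradient du_i/dx_j
  for (a in 1:4) {
    ua <- u[mesh$tets[, a], , drop = FALSE]
    for (i in 1:3) {
      for (j in 1:3) {
        H[, i, j] <- H[, i, j] + ua[, i] * sg$grad[, a, j]
      }
    }
  }
  eps <- cbind(H[, 1, 1], H[, 2, 2], H[, 3, 3],
               H[, 1, 2] + H[, 2, 1],
               H[, 2, 3] + H[, 3, 2],
               H[, 3, 1] + H[, 1, 3])
  colnames(eps) <- c("exx", "eyy", "ezz", "gxy", "gyz", "gzx")
  lc <- region_lame(mesh, materials)
  tr <- eps[, 1] + eps[, 2] + eps[, 3]
  stress <- cbind(lc$lambda * tr + 2 * lc$mu * eps[, 1],
                  lc$lambda * tr + 2 * lc$mu * eps[, 2],
                  lc$lambda * tr + 2 * lc$mu * eps[, 3],
                  lc$mu * eps[, 4], lc$mu * eps[, 5], lc$mu * eps[, 6])
  colnames(stress) <- c("sxx", "syy", "szz", "sxy", "syz", "szx")
  structure(list(strain = eps, stress = stress,
                 von_mises = von_mises_voigt(stress),
                 regions = mesh$regions),
            class = "stress_state")
}

#' @export
print.stress_state <- function(x, ...) {
  cat(sprintf("<stress_state> %d elements, max von Mises = %.4g MPa\n",
              length(x$von_mises), max(x$von_mises)))
  invisible(x)
}

von_mises_voigt <- function(s) {
  sqrt(pmax(0, 0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                      (s[, 3] - s[, 1])^2) +
              3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2)))
}

#' Von Mises stress of a symmetric stress tensor
#'
#' `sigma_v = sqrt(1/2 [(s11-s22)^2 + (s22-s33)^2 + (s33-s11)^2]
#'                 + 3 (s12^2 + s23^2 + s31^2))`,
#' a rotation-invariant scalar used as a rupture-risk proxy.
#'
#' @param stress a symmetric 3 x 3 matrix (MPa), or a matrix with 6 columns
#'   in Voigt order `(sxx, syy, szz, sxy, syz, szx)` for many tensors at
#'   once.
#' @return Non-negative scalar (or vector) in MPa.
#' @examples
#' von_mises(diag(c(1, 0, 0)))   # 1
#' von_mises(diag(c(2, 2, 2)))   # 0 (hydrostatic)
#' @export
von_mises <- function(stress) {
  if (is.matrix(stress) && ncol(stress) == 6L) return(von_mises_voigt(stress))
  stopifnot(is.matrix(stress), all(dim(stress) == c(3L, 3L)))
  if (max(abs(stress - t(stress))) > 1e-8 * max(1, max(abs(stress)))) {
    stop("stress tensor must be symmetric")
  }
  von_mises_voigt(matrix(c(stress[1, 1], stress[2, 2], stress[3, 3],
                           stress[1, 2], stress[2, 3], stress[3, 1]),
                         nrow = 1L))[1L]
}

# volume-weighted nodal average of an element field, for visualisation
nodal_average <- function(mesh, elem_field) {
  v <- tet_volumes(mesh)
  num <- numeric(nrow(mesh$nodes))
  den <- numeric(nrow(mesh$nodes))
  for (a in 1:4) {
    idx <- mesh$tets[, a]
    agg <- rowsum(cbind(elem_field * v, v), idx)
    at <- as.integer(rownames(agg))
    num[at] <- num[at] + agg[, 1L]
    den[at] <- den[at] + agg[, 2L]
  }
  den[den == 0] <- 1
  num / den
}
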