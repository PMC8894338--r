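#' Material tables for isotropic linear elasticity
#'
#' A material table maps each mesh region tag to the two constants of an
#' isotropic linear-elastic solid: Young's modulus `E` (MPa) and Poisson
#' ratio `nu`. [default_materials()] returns the abdominal-wall values used
#' throughout the package: experimentally derived moduli for the four muscle
#' layers (external oblique EO = 1, internal oblique IO = 0.65, rectus
#' abdominis RA = 0.52, transverse abdominis TR = 1.03 MPa) and a much
#' stiffer tendinous linea alba (LA = 72 MPa), all with Poisson ratio 0.3.
#'
#' @param region character vector of region tags.
#' @param E Young's moduli in MPa, recycled against `region`.
#' @param nu Poisson ratios in (0, 0.5), recycled against `region`.
#' @return A tibble with columns `region`, `E`, `nu` and class
#'   `"material_table"`.
#' @examples
#' default_materials()
#' material_table("steel_like", E = 200e3, nu = 0.3)
#' @export
material_table <- function(region, E, nu = 0.3) {
  tbl <- tibble::tibble(region = as.character(region),
                        E = as.double(E), nu = as.double(nu))
  if (anyDuplicated(tbl$region)) stop("duplicated region tag in material table")
  if (any(tbl$E <= 0)) stop("Young's modulus must be positive")
  if (any(tbl$nu <= 0 | tbl$nu >= 0.5)) stop("Poisson ratio must lie in (0, 0.5)")
  class(tbl) <- c("material_table", class(tbl))
  tbl
}

#' @rdname material_table
#' @export
default_materials <- function() {
  material_table(region = c("EO", "IO", "RA", "TR", "LA"),
                 E      = c(1, 0.65, 0.52, 1.03, 72),
                 nu     = 0.3)
}

#' Isotropic elasticity matrix in Voigt notation
#'
#' Returns the 6x6 stiffness relating engineering strain
#' `(exx, eyy, ezz, gxy, gyz, gzx)` to stress `(sxx, syy, szz, sxy, syz,
#' szx)` for an isotropic solid, built from the Lame constants
#' `lambda = E nu / ((1 + nu)(1 - 2 nu))` and `mu = E / (2 (1 + nu))`.
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio; the incompressible limit `nu -> 0.5` is refused.
#' @return 6x6 symmetric positive-definite matrix (MPa).
#' @examples
#' hooke_isotropic(0.52, 0.3)  # lambda = 0.3, mu = 0.2 exactly
#' @export
hooke_isotropic <- function(E, nu) {
  stopifnot(length(E) == 1L, length(nu) == 1L)
  if (E <= 0) stop("Young's modulus must be positive")
  if (abs(nu - 0.5) < 1e-6) stop("incompressible limit unsupported")
  if (nu < 0 || nu > 0.5) stop("Poisson ratio must lie in [0, 0.5)")
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(lam + 2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3][upper.tri(matrix(0, 3, 3))] <- lam
  D[1:3, 1:3][lower.tri(matrix(0, 3, 3))] <- lam
  D
}

lame_constants <- function(E, nu) {
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
       mu = E / (2 * (1 + nu)))
}
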