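#' Principal stretch triple under incompressibility
#'
#' Builds the full principal stretch triple from the circumferential and
#' axial stretches; the radial stretch follows from det F = 1. Signed values
#' are accepted (the everted cut-open state has negative radial and
#' circumferential entries in the deformation gradient); all constitutive
#' quantities depend only on even powers and the signed product, so the
#' incompressibility constraint is enforced on the signed triple.
#'
#' @param lam_th,lam_z Circumferential and axial principal stretches.
#' @return Tibble with columns `lam_r`, `lam_th`, `lam_z`.
#' @export
#' @examples
#' principal_stretches(1.2, 1.1)
principal_stretches <- function(lam_th, lam_z) {
  stopifnot(all(lam_th != 0), all(lam_z > 0))
  tibble(lam_r = 1 / (lam_th * lam_z), lam_th = lam_th, lam_z = lam_z)
}

#' Fourth pseudo-invariant of the fiber families
#'
#' `I4 = lam_th^2 cos^2(beta) + lam_z^2 sin^2(beta)` for two mechanically
#' equivalent collagen fiber families pitched at +/- `beta` from the
#' circumferential direction (so `I6 = I4`).
#'
#' @param lam_th,lam_z Principal stretches.
#' @param beta Fiber pitch angle in degrees, `0 <= beta < 90`.
#' @return Numeric vector of invariants.
#' @export
fiber_invariant <- function(lam_th, lam_z, beta) {
  stopifnot(all(beta >= 0), all(beta < 90))
  b <- beta * pi / 180
  lam_th^2 * cos(b)^2 + lam_z^2 * sin(b)^2
}

# cap on the fiber exponent: keeps the stress finite during root bracketing
# far outside the physical range without affecting converged solutions
.EXP_CAP <- 200

#' Isochoric HGO Cauchy stress components
#'
#' Deformation-dependent Cauchy stress of the Holzapfel--Gasser--Ogden
#' material: a neo-Hookean matrix, `Psi_iso = c (I1 - 3)`, giving diagonal
#' components `2 c lam_d^2`, plus two mechanically equivalent collagen fiber
#' families with `Psi_aniso = k1/(2 k2) (exp(k2 (I4-1)^2) + exp(k2 (I6-1)^2)
#' - 2)`. Fibers carry tension only: the anisotropic part vanishes for
#' `I4 < 1`. With `I6 = I4` the anisotropic components are
#' `4 k1 (I4 - 1) exp(k2 (I4-1)^2)` times `lam_th^2 cos^2(beta)`
#' (circumferential) and `lam_z^2 sin^2(beta)` (axial); the radial component
#' is identically zero. The reaction stress from incompressibility is not
#' included here; subtract it to obtain total stresses.
#'
#' @param stretches Tibble or list with `lam_r`, `lam_th`, `lam_z` (e.g. from
#'   [principal_stretches()]); vectors are recycled tidily.
#' @param c,k1 Stress-like material parameters \[kPa\].
#' @param k2 Dimensionless exponential stiffening parameter.
#' @param beta Fiber pitch angle \[degrees\].
#' @return Tibble with columns `iso_r`, `iso_th`, `iso_z`, `aniso_r`,
#'   `aniso_th`, `aniso_z`, `I4` (stresses in kPa).
#' @export
#' @examples
#' hgo_stress(principal_stretches(1, 1), c = 10, k1 = 5, k2 = 1, beta = 40)
hgo_stress <- function(stretches, c, k1, k2, beta) {
  stopifnot(all(c > 0), all(k1 >= 0), all(k2 > 0))
  lr <- stretches$lam_r
  lth <- stretches$lam_th
  lz <- stretches$lam_z
  I4 <- fiber_invariant(lth, lz, beta)
  b <- beta * pi / 180
  ex <- k2 * (I4 - 1)^2
  if (any(ex > .EXP_CAP & I4 >= 1)) {
    # converged states never reach this regime; flag it rather than overflow
    warning("fiber exponential capped: stretches far outside physical range",
            call. = FALSE)
    ex <- pmin(ex, .EXP_CAP)
  }
  fac <- ifelse(I4 >= 1, 4 * k1 * (I4 - 1) * exp(ex), 0)
  tibble(
    iso_r = 2 * c * lr^2,
    iso_th = 2 * c * lth^2,
    iso_z = 2 * c * lz^2,
    aniso_r = 0 * I4,
    aniso_th = fac * lth^2 * cos(b)^2,
    aniso_z = fac * lz^2 * sin(b)^2,
    I4 = I4
  )
}

# bare-metal kernel used inside quadratures (no tibble overhead)
.hgo <- function(lr, lth, lz, c, k1, k2, beta_rad) {
  I4 <- lth^2 * cos(beta_rad)^2 + lz^2 * sin(beta_rad)^2
  fac <- ifelse(I4 >= 1,
                4 * k1 * (I4 - 1) * exp(pmin(k2 * (I4 - 1)^2, .EXP_CAP)),
                0)
  list(
    iso_r = 2 * c * lr^2,
    iso_th = 2 * c * lth^2,
    iso_z = 2 * c * lz^2,
    aniso_th = fac * lth^2 * cos(beta_rad)^2,
    aniso_z = fac * lz^2 * sin(beta_rad)^2,
    I4 = I4
  )
}
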