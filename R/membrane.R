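#' Membrane equilibrium stresses
#'
#' Global equilibrium of a pressurized thin-walled cylinder from measured
#' geometry: circumferential `sigma_theta = (ri/h + alpha) P` (with
#' `alpha = 0.5` this is the mid-wall evaluation), axial
#' `sigma_z = (pi ri^2 P + Fred) / (pi h (2 ri + h))`, and radial stress
#' neglected (`sigma_r = 0`).
#'
#' @param ri,h Deformed inner radius and wall thickness \[mm\]; vectors allowed.
#' @param P Luminal pressure \[kPa\].
#' @param fred Reduced axial force in newtons (converted internally to
#'   kPa mm^2).
#' @param alpha Dimensionless evaluation-radius offset (default from
#'   [run_config()]).
#' @return Tibble with `sigma_theta_eq`, `sigma_z_eq`, `sigma_r_eq` \[kPa\].
#' @export
#' @examples
#' equilibrium_stresses(ri = 5, h = 1, P = 10, fred = 0) # sigma_theta = 55
equilibrium_stresses <- function(ri, h, P, fred, alpha = 0.5) {
  stopifnot(all(ri > 0), all(h > 0), all(P >= 0))
  fred_mm <- fred * 1000
  tibble(
    sigma_theta_eq = (ri / h + alpha) * P,
    sigma_z_eq = (pi * ri^2 * P + fred_mm) / (pi * h * (2 * ri + h)),
    sigma_r_eq = 0 * P
  )
}

#' Estimated reduced axial force
#'
#' The reduced axial force cannot be measured in vivo. It is estimated by
#' assuming the axial-to-circumferential stress ratio `gamma` at mean
#' arterial pressure: `Fred = P_map pi (gamma/2 (2 ri + h)^2 - ri^2)` with
#' the geometry taken at MAP.
#'
#' @param ri_map,h_map Inner radius and wall thickness at MAP \[mm\].
#' @param config A [run_config()] supplying `P_map` and `gamma`.
#' @return Estimated force in newtons.
#' @export
estimate_reduced_force <- function(ri_map, h_map, config = run_config()) {
  stopifnot(ri_map > 0, h_map > 0)
  config$P_map * pi *
    (config$gamma / 2 * (2 * ri_map + h_map)^2 - ri_map^2) / 1000
}

#' Membrane stretches from measured geometry
#'
#' Mid-wall stretches of the constitutive membrane model. The reference for
#' the membrane is the unloaded configuration with inner radius `Ri`; volume
#' conservation of the wall cross-section gives the unloaded outer radius
#' `Ro = sqrt(Ri^2 + lam h (2 ri + h))`, and the circumferential mid-wall
#' stretch is the ratio of deformed to unloaded mid-wall radius,
#' `lam_th = (2 ri + h) / (Ri + Ro)`. The axial stretch equals the in vivo
#' pre-stretch and the radial stretch follows from incompressibility.
#'
#' @param ri,h Measured deformed inner radius and thickness \[mm\].
#' @param Ri Unloaded inner radius \[mm\].
#' @param lam Axial stretch.
#' @return Tibble with `lam_th_m`, `lam_z_m`, `lam_r_m`.
#' @export
membrane_stretches <- function(ri, h, Ri, lam) {
  stopifnot(all(ri > 0), all(h > 0), Ri > 0, lam >= 1)
  Ro <- sqrt(Ri^2 + lam * h * (2 * ri + h))
  lam_th <- (2 * ri + h) / (Ri + Ro)
  tibble(lam_th_m = lam_th, lam_z_m = lam + 0 * lam_th,
         lam_r_m = 1 / (lam_th * lam))
}

#' Constitutive membrane stresses along a pressure--radius series
#'
#' Evaluates the constitutively determined membrane stresses at every level
#' of a measured (or simulated) series: the isochoric HGO components at the
#' membrane stretches, the reaction stress `p_mod = 2 c / (lam_th^2 lam^2)`
#' enforcing zero radial total stress, the total stresses, and the pointwise
#' load-bearing fractions (integration across a membrane is trivial, so the
#' fraction reduces to `aniso / (iso + aniso)`).
#'
#' @param series Tibble with columns `P`, `ri`, `h`.
#' @param params One row of [membrane_parameters()] (or equivalent list with
#'   `Ri`, `c`, `k1`, `k2`, `beta`, `lam`).
#' @return A tibble with one row per level: `P`, `ri`, `h`,
#'   `sigma_iso_theta`, `sigma_aniso_theta`, `sigma_total_theta`,
#'   `sigma_iso_z`, `sigma_aniso_z`, `sigma_total_z`, `reaction_p`,
#'   `psi_theta`, `psi_z`, `model = "membrane"`.
#' @export
membrane_stress_series <- function(series, params) {
  pp <- as_membrane_params(params)
  st <- membrane_stretches(series$ri, series$h, pp$Ri, pp$lam)
  s <- .hgo(st$lam_r_m, st$lam_th_m, st$lam_z_m,
            pp$c, pp$k1, pp$k2, pp$beta * pi / 180)
  p_mod <- s$iso_r # = 2 c lam_r^2, the radial isochoric component
  tibble(
    P = series$P, ri = series$ri, h = series$h,
    sigma_iso_theta = s$iso_th, sigma_aniso_theta = s$aniso_th,
    sigma_total_theta = s$iso_th + s$aniso_th - p_mod,
    sigma_iso_z = s$iso_z, sigma_aniso_z = s$aniso_z,
    sigma_total_z = s$iso_z + s$aniso_z - p_mod,
    reaction_p = p_mod,
    psi_theta = s$aniso_th / (s$iso_th + s$aniso_th),
    psi_z = s$aniso_z / (s$iso_z + s$aniso_z),
    model = "membrane"
  )
}

#' Membrane load-bearing fraction
#'
#' For a membrane the through-thickness integrals of the load-fraction
#' definition collapse to the pointwise ratio `aniso / (iso + aniso)`.
#'
#' @param stresses A row set of [membrane_stress_series()] output (needs
#'   `sigma_iso_*` and `sigma_aniso_*` columns).
#' @param direction `"theta"` or `"z"`.
#' @return Numeric vector of fractions.
#' @export
membrane_load_fraction <- function(stresses, direction = c("theta", "z")) {
  direction <- match.arg(direction)
  an <- stresses[[paste0("sigma_aniso_", direction)]]
  is <- stresses[[paste0("sigma_iso_", direction)]]
  den <- is + an
  if (any(abs(den) < .Machine$double.eps)) {
    stop("zero denominator in load fraction", call. = FALSE)
  }
  an / den
}

#' Self-consistent membrane pressure--radius series
#'
#' Generates the pressure--radius response of an artery that is *exactly* a
#' constitutive membrane with the given parameters: at every pressure level
#' the geometry `(ri, h)` solves the two-equation system "constitutive total
#' stress equals equilibrium stress" in both directions. The reduced axial
#' force entering the axial equilibrium stress is itself the gamma-ratio
#' estimate evaluated from the series at MAP, closed by a fixed point at the
#' MAP level first. Used as ground truth for parameter-recovery experiments.
#'
#' @inheritParams membrane_stress_series
#' @param config A [run_config()].
#' @param h_scale Initial guess for the wall thickness as a fraction of `Ri`.
#' @return Tibble of class `aorta_sweep` with columns `P`, `ri`, `h` and
#'   attribute `"fred_est"` (newtons).
#' @export
generate_membrane_series <- function(params, config = run_config(),
                                     h_scale = 0.15) {
  pp <- as_membrane_params(params)
  resid2 <- function(x, P, fred_mm) {
    ri <- x[1]; h <- x[2]
    if (ri <= 0 || h <= 0) return(c(1e8, 1e8))
    m <- membrane_stress_series(tibble(P = P, ri = ri, h = h), pp)
    eq <- equilibrium_stresses(ri, h, P, fred_mm / 1000, config$alpha)
    v <- c(m$sigma_total_theta - eq$sigma_theta_eq,
           m$sigma_total_z - eq$sigma_z_eq)
    ifelse(is.finite(v), v, 1e8)
  }
  newton2 <- function(fn, x0, tol = 1e-12, maxit = 60) {
    x <- x0
    for (it in seq_len(maxit)) {
      f0 <- fn(x)
      if (max(abs(f0)) < tol) break
      hstep <- pmax(abs(x), 1e-3) * 1e-7
      J <- cbind(
        (fn(x + c(hstep[1], 0)) - f0) / hstep[1],
        (fn(x + c(0, hstep[2])) - f0) / hstep[2]
      )
      dx <- tryCatch(solve(J, -f0), error = function(e) rep(0, 2))
      lam <- 1
      repeat {
        xn <- x + lam * dx
        if (xn[1] > 0 && xn[2] > 0 &&
            sum(fn(xn)^2) <= sum(f0^2) * (1 - 1e-4 * lam) + 1e-300) break
        lam <- lam / 2
        if (lam < 1e-6) break
      }
      x <- x + lam * dx
    }
    x
  }
  # MAP level with the force estimate substituted in (self-consistent close)
  x_map <- newton2(function(x) {
    fred_mm <- config$P_map * pi *
      (config$gamma / 2 * (2 * x[1] + x[2])^2 - x[1]^2)
    resid2(x, config$P_map, fred_mm)
  }, c(pp$Ri * 1.15, pp$Ri * h_scale))
  fred_mm <- config$P_map * pi *
    (config$gamma / 2 * (2 * x_map[1] + x_map[2])^2 - x_map[1]^2)
  P <- pressure_grid(config)
  ri <- h <- numeric(length(P))
  guess <- x_map
  for (j in order(abs(P - config$P_map))) {
    guess <- newton2(function(x) resid2(x, P[j], fred_mm), guess)
    ri[j] <- guess[1]
    h[j] <- guess[2]
  }
  out <- tibble(P = P, ri = ri, h = h)
  class(out) <- c("aorta_sweep", class(out))
  attr(out, "fred_est") <- fred_mm / 1000
  out
}
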