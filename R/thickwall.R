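#' Residual-stress parameter from the opening angle
#'
#' The circumferential stretch of the closing deformation is `k r / rho` with
#' `k = pi / (pi - Phi0)` (`Phi0` in radians). Under the default `"full"`
#' convention the tabulated angle is used directly in this formula; opening
#' angles above 180 degrees then give a negative k, which describes an
#' everted cut-open state (the sector bends past flat) and is handled
#' throughout by signed stretches. Under the `"half"` convention the
#' tabulated angle is interpreted as twice the angle of the formula,
#' equivalent to `k = 2 pi / (2 pi - Phi0)`.
#'
#' @param phi0 Opening angle in degrees, `0 <= phi0 < 360`.
#' @param convention `"full"` or `"half"`.
#' @return The scalar k. `k = 1` means no residual stress.
#' @export
#' @examples
#' opening_angle_parameter(0) # closed ring
#' opening_angle_parameter(96, "half") # 360/(360 - 96)
opening_angle_parameter <- function(phi0, convention = c("full", "half")) {
  convention <- match.arg(convention)
  stopifnot(phi0 >= 0, phi0 < 360)
  denom <- switch(convention,
    full = 180 - phi0,
    half = 360 - phi0
  )
  if (abs(denom) < sqrt(.Machine$double.eps)) {
    stop("opening angle ", phi0, " degrees is degenerate under the '",
         convention, "' convention (k is unbounded)", call. = FALSE)
  }
  switch(convention, full = 180 / denom, half = 360 / denom)
}

# integrand of the through-wall pressure quadrature, P = int (s_th - s_rr)/r dr,
# written in the reference (sector) coordinate rho; clamped so that root
# bracketing far outside the physical range stays finite
.press_integrand <- function(rho, ri, rho_i, k, lz, art) {
  r <- sqrt(ri^2 + (rho^2 - rho_i^2) / (k * lz))
  lth <- k * r / rho
  lr <- rho / (k * lz * r)
  s <- .hgo(lr, lth, lz, art$c, art$k1, art$k2, art$beta * pi / 180)
  v <- (s$iso_th + s$aniso_th - s$iso_r) / r * lr
  pmax(pmin(v, 1e9), -1e9)
}

# luminal pressure carried by the wall for inner radius ri and axial stretch lz
.wall_pressure <- function(ri, sector, lz, tol = 1e-10) {
  integrate(.press_integrand, sector$rho_i, sector$rho_o,
            ri = ri, rho_i = sector$rho_i, k = sector$k, lz = lz, art = sector,
            rel.tol = tol, stop.on.error = FALSE)$value
}

#' Stress-free sector of an in silico aorta
#'
#' The tabulated geometry (`R`, `H`) of an in silico aorta describes the
#' unloaded closed ring. This function recovers the cut-open, stress-free
#' sector consistent with it: the sector radii follow from incompressible
#' closing (at axial stretch 1) with the residual-stress parameter k, and the
#' inner sector radius is fixed by requiring the closed, axially unstretched
#' ring with inner radius `R` to be in equilibrium at zero pressure. For
#' everted sectors (k < 0) the sector radius paired with the lumen exceeds
#' the one paired with the outer surface.
#'
#' @param artery One row of [silico_aortas()] (or an equivalent list).
#' @param config A [run_config()].
#' @return The artery as a list of class `aorta_sector` with elements `k`,
#'   `rho_i`, `rho_o` added (sector radii in mm).
#' @export
#' @examples
#' sec <- stress_free_sector(silico_aortas()[15, ])
#' c(sec$k, sec$rho_i, sec$rho_o)
stress_free_sector <- function(artery, config = run_config()) {
  art <- as_artery(artery)
  if (inherits(art, "aorta_sector")) return(art)
  k <- opening_angle_parameter(art$phi0, config$opening_angle_convention)
  R_out <- art$R + art$H
  A <- k * (R_out^2 - art$R^2)
  resid <- function(rho_i) {
    sec <- c(art, list(k = k, rho_i = rho_i, rho_o = sqrt(rho_i^2 + A)))
    .wall_pressure(art$R, sec, lz = 1, tol = config$quadrature_tol)
  }
  if (k > 0) {
    lo <- art$R * sqrt(k) * 0.3
    hi <- max(R_out * sqrt(k) * 4, k * R_out * 1.5)
  } else {
    lo <- sqrt(-A) * (1 + 1e-9)
    hi <- abs(k) * R_out * 6
  }
  rho_i <- tryCatch(
    uniroot(resid, c(lo, hi), tol = config$root_tol)$root,
    error = function(e) {
      stop("cannot determine the stress-free sector for set ",
           art$set %||% "?", " (phi0 = ", art$phi0, " deg, k = ",
           signif(k, 5), "): ", conditionMessage(e), call. = FALSE)
    }
  )
  structure(c(art, list(k = k, rho_i = rho_i, rho_o = sqrt(rho_i^2 + A))),
            class = "aorta_sector")
}

#' Solve the extension--inflation problem at one pressure
#'
#' Finds the deformed inner radius at which the through-wall quadrature of
#' the radial equilibrium equation balances the luminal pressure, with the
#' axial stretch held at the artery's in vivo value. The bracket starts
#' around the unloaded radius (or a supplied guess) and expands
#' geometrically until the residual changes sign.
#'
#' @param artery One row of [silico_aortas()], or a precomputed
#'   [stress_free_sector()].
#' @param P Luminal pressure \[kPa\], `P >= 0`.
#' @param config A [run_config()].
#' @param ri_guess Optional starting value for the deformed inner radius
#'   (e.g. the solution at a neighbouring pressure).
#' @return A list with `P`, `ri`, `ro`, `h` \[mm\], `k`, `lam_z`.
#' @export
solve_inflation <- function(artery, P, config = run_config(), ri_guess = NULL) {
  sec <- stress_free_sector(artery, config)
  stopifnot(P >= 0)
  lz <- sec$lam
  g <- function(ri) .wall_pressure(ri, sec, lz, config$quadrature_tol) - P
  lo <- if (is.null(ri_guess)) sec$R * 0.35 else ri_guess * 0.9
  hi <- if (is.null(ri_guess)) sec$R * 0.8 else ri_guess * 1.02
  vlo <- g(lo)
  n_exp <- 0
  while ((!is.finite(vlo) || vlo > 0) && n_exp < 200) {
    lo <- lo * 0.9
    vlo <- g(lo)
    n_exp <- n_exp + 1
  }
  vhi <- g(hi)
  n_exp <- 0
  while ((!is.finite(vhi) || vhi < 0) && n_exp < 400) {
    hi <- hi * 1.04
    vhi <- g(hi)
    n_exp <- n_exp + 1
  }
  if (!is.finite(vlo) || !is.finite(vhi) || vlo > 0 || vhi < 0) {
    stop("no bracket for the inner radius (set ", sec$set %||% "?",
         ", P = ", P, " kPa, bracket [", signif(lo, 5), ", ", signif(hi, 5),
         "] mm)", call. = FALSE)
  }
  ri <- uniroot(g, c(lo, hi), f.lower = vlo, f.upper = vhi,
                tol = config$root_tol)$root
  ro <- sqrt(ri^2 + (sec$rho_o^2 - sec$rho_i^2) / (sec$k * lz))
  list(P = P, ri = ri, ro = ro, h = ro - ri, k = sec$k, lam_z = lz)
}

#' Pressure sweep of an in silico aorta
#'
#' Solves the extension--inflation problem at every pressure of the grid and
#' records the "measured" in vivo signal: pressure, deformed inner radius and
#' wall thickness.
#'
#' @inheritParams solve_inflation
#' @return A tibble of class `aorta_sweep` with columns `P` \[kPa\], `ri`,
#'   `h`, `ro` \[mm\]; the sector is attached as attribute `"sector"`.
#' @export
#' @examples
#' \donttest{
#' sw <- pressure_sweep(silico_aortas()[15, ], run_config(n_levels = 5))
#' sw
#' }
pressure_sweep <- function(artery, config = run_config()) {
  sec <- stress_free_sector(artery, config)
  P <- pressure_grid(config)
  ri <- ro <- numeric(length(P))
  guess <- NULL
  for (j in seq_along(P)) {
    st <- solve_inflation(sec, P[j], config, ri_guess = guess)
    ri[j] <- st$ri
    ro[j] <- st$ro
    guess <- st$ri
  }
  out <- tibble(P = P, ri = ri, h = ro - ri, ro = ro)
  class(out) <- c("aorta_sweep", class(out))
  attr(out, "sector") <- sec
  out
}

# Lobatto-clustered radial grid between the sector radii (works for everted
# sectors where rho_o < rho_i; the row order always runs lumen -> outer wall)
.sector_grid <- function(sector, n) {
  j <- seq(0, n - 1)
  mid <- (sector$rho_i + sector$rho_o) / 2
  half <- (sector$rho_o - sector$rho_i) / 2
  mid - half * cos(pi * j / (n - 1))
}

# cumulative Simpson quadrature of f over the (possibly non-uniform, possibly
# descending) nodes; f is evaluated at nodes and panel midpoints
.cumquad <- function(f, nodes) {
  mids <- (nodes[-1] + nodes[-length(nodes)]) / 2
  fn <- f(nodes)
  fm <- f(mids)
  d <- diff(nodes)
  c(0, cumsum(d / 6 * (fn[-length(fn)] + 4 * fm + fn[-1])))
}

#' Transmural stress profile of a solved state
#'
#' Evaluates the local stretches and all stress components across the wall
#' at one pressure: the isochoric (deformation-dependent) components, the
#' reaction stress p(r) obtained by integrating radial equilibrium from the
#' lumen, and the total stresses. Radial equilibrium implies sigma_rr = -P at
#' the lumen and 0 at the outer surface, which the returned profile satisfies
#' to quadrature accuracy.
#'
#' @inheritParams solve_inflation
#' @param state Optional result of [solve_inflation()] at `P` (computed if
#'   missing).
#' @return A tibble of class `aorta_profile` with columns `rho`, `r`,
#'   `lam_r`, `lam_th`, `lam_z`, `sigma_iso_theta`, `sigma_aniso_theta`,
#'   `sigma_total_theta`, `sigma_iso_z`, `sigma_aniso_z`, `sigma_total_z`,
#'   `reaction_p`, `sigma_rr` (stresses in kPa, radii in mm); attributes
#'   `"state"` and `"P"`.
#' @export
transmural_profile <- function(artery, P, config = run_config(), state = NULL) {
  sec <- stress_free_sector(artery, config)
  if (is.null(state)) state <- solve_inflation(sec, P, config)
  lz <- sec$lam
  rho <- .sector_grid(sec, config$profile_points)
  r <- sqrt(state$ri^2 + (rho^2 - sec$rho_i^2) / (sec$k * lz))
  lth <- sec$k * r / rho
  lr <- rho / (sec$k * lz * r)
  s <- .hgo(lr, lth, lz, sec$c, sec$k1, sec$k2, sec$beta * pi / 180)
  cum <- .cumquad(function(x) .press_integrand(x, state$ri, sec$rho_i,
                                               sec$k, lz, sec), rho)
  p <- state$P + s$iso_r - cum
  out <- tibble(
    rho = rho, r = r, lam_r = lr, lam_th = lth, lam_z = lz,
    sigma_iso_theta = s$iso_th, sigma_aniso_theta = s$aniso_th,
    sigma_total_theta = s$iso_th + s$aniso_th - p,
    sigma_iso_z = s$iso_z, sigma_aniso_z = s$aniso_z,
    sigma_total_z = s$iso_z + s$aniso_z - p,
    reaction_p = p,
    sigma_rr = s$iso_r - p
  )
  class(out) <- c("aorta_profile", class(out))
  attr(out, "state") <- state
  attr(out, "P") <- state$P
  out
}

#' Transmural stress gradient
#'
#' Total stress at the outer wall minus total stress at the inner wall, in
#' the requested direction, for one transmural profile. The operation is
#' pressure-agnostic; evaluate the profile at the pressure of interest.
#'
#' @param profile A [transmural_profile()].
#' @param direction `"theta"` or `"z"`.
#' @return Signed gradient in kPa.
#' @export
transmural_gradient <- function(profile, direction = c("theta", "z")) {
  direction <- match.arg(direction)
  col <- paste0("sigma_total_", direction)
  v <- profile[[col]]
  v[length(v)] - v[1]
}

#' Reduced axial force of a solved state
#'
#' The axial reaction force beyond the pressure-on-cap contribution that
#' maintains the axial pre-stretch:
#' `F_red = pi * int_ri^ro (2 sigma_zz - sigma_theta - sigma_rr) r dr`,
#' evaluated by adaptive quadrature in the reference coordinate. The reaction
#' stress cancels in the integrand, so only isochoric components enter.
#'
#' @inheritParams transmural_profile
#' @return Force in newtons (kPa mm^2 / 1000).
#' @export
reduced_axial_force <- function(artery, P, config = run_config(), state = NULL) {
  sec <- stress_free_sector(artery, config)
  if (is.null(state)) state <- solve_inflation(sec, P, config)
  lz <- sec$lam
  f <- function(rho) {
    r <- sqrt(state$ri^2 + (rho^2 - sec$rho_i^2) / (sec$k * lz))
    lth <- sec$k * r / rho
    lr <- rho / (sec$k * lz * r)
    s <- .hgo(lr, lth, lz, sec$c, sec$k1, sec$k2, sec$beta * pi / 180)
    (2 * (s$iso_z + s$aniso_z) - (s$iso_th + s$aniso_th) - s$iso_r) * r * lr
  }
  val <- integrate(f, sec$rho_i, sec$rho_o, rel.tol = config$quadrature_tol,
                   stop.on.error = FALSE)$value
  pi * val / 1000
}

#' Collagen load-bearing fraction of the thick-walled model
#'
#' Fraction of the directional wall stress carried by the collagen
#' (anisotropic) component: the through-thickness integral of the anisotropic
#' component divided by the integral of the isochoric total (isotropic +
#' anisotropic), both over the deformed wall on the same grid.
#'
#' @param profile A [transmural_profile()].
#' @param direction `"theta"` or `"z"`.
#' @return Dimensionless fraction in `[0, 1]`.
#' @export
silico_load_fraction <- function(profile, direction = c("theta", "z")) {
  direction <- match.arg(direction)
  an <- profile[[paste0("sigma_aniso_", direction)]]
  is <- profile[[paste0("sigma_iso_", direction)]]
  # dr = lam_r drho; spline-refined quadrature on the profile grid
  w <- profile$lam_r
  x <- profile$rho
  ord <- order(x)
  xf <- seq(x[ord][1], x[ord][length(x)], length.out = 8 * length(x))
  tr <- function(y) {
    yf <- stats::spline(x[ord], y[ord], xout = xf)$y
    v <- sum((yf[-1] + yf[-length(yf)]) / 2 * diff(xf))
    if (x[1] > x[length(x)]) -v else v
  }
  num <- tr(an * w)
  den <- tr((is + an) * w)
  if (abs(den) < .Machine$double.eps) {
    stop("degenerate material: zero total directional stress integral",
         call. = FALSE)
  }
  num / den
}

#' Mid-wall stress series of the in silico model
#'
#' Runs the pressure sweep and, at every level, evaluates the stress state at
#' the deformed mid-wall radius `ri + h/2` by local evaluation of the
#' constitutive law and of the reaction-stress integral (no grid
#' interpolation), together with the through-thickness load-bearing
#' fractions and the reduced axial force.
#'
#' @inheritParams pressure_sweep
#' @param sweep Optional precomputed [pressure_sweep()] for the same artery
#'   and config.
#' @return A tibble with one row per pressure level: `P`, `ri`, `h`,
#'   `sigma_iso_theta`, `sigma_aniso_theta`, `sigma_total_theta`,
#'   `sigma_iso_z`, `sigma_aniso_z`, `sigma_total_z`, `reaction_p`,
#'   `psi_theta`, `psi_z`, `fred` \[N\], `model = "thick_wall"`.
#' @export
midwall_stress_series <- function(artery, config = run_config(), sweep = NULL) {
  sec <- stress_free_sector(artery, config)
  if (is.null(sweep)) sweep <- pressure_sweep(sec, config)
  lz <- sec$lam
  beta_rad <- sec$beta * pi / 180
  one_level <- function(P, ri, h) {
    rm <- ri + h / 2
    rho_m <- sqrt(sec$rho_i^2 + sec$k * lz * (rm^2 - ri^2))
    lth_m <- sec$k * rm / rho_m
    lr_m <- rho_m / (sec$k * lz * rm)
    sm <- .hgo(lr_m, lth_m, lz, sec$c, sec$k1, sec$k2, beta_rad)
    p_m <- P + sm$iso_r -
      integrate(.press_integrand, sec$rho_i, rho_m,
                ri = ri, rho_i = sec$rho_i, k = sec$k, lz = lz, art = sec,
                rel.tol = config$quadrature_tol, stop.on.error = FALSE)$value
    prof <- transmural_profile(sec, P, config,
                               state = list(P = P, ri = ri,
                                            ro = ri + h, h = h,
                                            k = sec$k, lam_z = lz))
    tibble(
      P = P, ri = ri, h = h,
      sigma_iso_theta = sm$iso_th, sigma_aniso_theta = sm$aniso_th,
      sigma_total_theta = sm$iso_th + sm$aniso_th - p_m,
      sigma_iso_z = sm$iso_z, sigma_aniso_z = sm$aniso_z,
      sigma_total_z = sm$iso_z + sm$aniso_z - p_m,
      reaction_p = p_m,
      psi_theta = silico_load_fraction(prof, "theta"),
      psi_z = silico_load_fraction(prof, "z"),
      fred = reduced_axial_force(sec, P, config,
                                 state = list(P = P, ri = ri))
    )
  }
  out <- purrr::pmap_dfr(list(sweep$P, sweep$ri, sweep$h), one_level)
  out$model <- "thick_wall"
  out
}

#' Emulated ultrasound measurement noise
#'
#' Perturbs the inner-radius signal of a pressure--radius series with i.i.d.
#' zero-mean Gaussian noise and recomputes the wall thickness from
#' incompressibility of the wall cross-section relative to the unperturbed
#' reference (`h' (2 ri' + h') = h (2 ri + h)` per level). Pressures are
#' unchanged. The seed is required so that every noisy dataset is
#' reproducible.
#'
#' @param series A tibble with columns `P`, `ri`, `h`.
#' @param sd_radius Standard deviation of the radius noise \[mm\], `>= 0`.
#' @param seed Integer seed.
#' @return A tibble with the same columns, perturbed.
#' @export
add_measurement_noise <- function(series, sd_radius, seed) {
  stopifnot(is.numeric(sd_radius), length(sd_radius) == 1, sd_radius >= 0,
            !missing(seed))
  if (sd_radius == 0) return(series)
  area <- series$h * (2 * series$ri + series$h)
  ri_new <- series$ri +
    withr::with_seed(seed, rnorm(nrow(series), mean = 0, sd = sd_radius))
  out <- series
  out$ri <- ri_new
  out$h <- -ri_new + sqrt(ri_new^2 + area)
  if ("ro" %in% names(out)) out$ro <- out$ri + out$h
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
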