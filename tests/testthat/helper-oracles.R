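# Independent brute-force oracles: dense-grid trapezoid quadrature plus plain
# bisection, coded directly from the model equations without reusing the
# package's solver internals.

oracle_hgo <- function(lr, lth, lz, c, k1, k2, beta_deg) {
  b <- beta_deg * pi / 180
  I4 <- lth^2 * cos(b)^2 + lz^2 * sin(b)^2
  fac <- ifelse(I4 >= 1, 4 * k1 * (I4 - 1) * exp(k2 * (I4 - 1)^2), 0)
  list(
    s_rr = 2 * c * lr^2,
    s_th = 2 * c * lth^2 + fac * lth^2 * cos(b)^2,
    s_zz = 2 * c * lz^2 + fac * lz^2 * sin(b)^2,
    aniso_th = fac * lth^2 * cos(b)^2,
    aniso_z = fac * lz^2 * sin(b)^2
  )
}

# all wall fields on an n-point uniform reference grid for a given ri
oracle_fields <- function(sec, ri, lz, n = 20001) {
  rho <- seq(sec$rho_i, sec$rho_o, length.out = n)
  r <- sqrt(ri^2 + (rho^2 - sec$rho_i^2) / (sec$k * lz))
  lth <- sec$k * r / rho
  lr <- rho / (sec$k * lz * r)
  s <- oracle_hgo(lr, lth, lz, sec$c, sec$k1, sec$k2, sec$beta)
  list(rho = rho, r = r, lr = lr, lth = lth, s = s)
}

oracle_trap <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

oracle_pressure <- function(sec, ri, lz, n = 20001) {
  f <- oracle_fields(sec, ri, lz, n)
  oracle_trap(f$rho, (f$s$s_th - f$s$s_rr) / f$r * f$lr)
}

oracle_solve_ri <- function(sec, P, lz, lo, hi, n = 20001, tol = 1e-10) {
  flo <- oracle_pressure(sec, lo, lz, n) - P
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- oracle_pressure(sec, mid, lz, n) - P
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# reaction stress at radius r_eval by cumulative trapezoid
oracle_reaction <- function(sec, ri, lz, P, r_eval, n = 20001) {
  f <- oracle_fields(sec, ri, lz, n)
  g <- (f$s$s_th - f$s$s_rr) / f$r * f$lr
  cum <- c(0, cumsum((g[-1] + g[-length(g)]) / 2 * diff(f$rho)))
  rho_eval <- sqrt(sec$rho_i^2 + sec$k * lz * (r_eval^2 - ri^2))
  s_rr <- oracle_hgo(rho_eval / (sec$k * lz * r_eval),
                     sec$k * r_eval / rho_eval, lz,
                     sec$c, sec$k1, sec$k2, sec$beta)$s_rr
  P + s_rr - approx(f$rho, cum, rho_eval)$y
}

oracle_fred <- function(sec, ri, lz, n = 20001) {
  f <- oracle_fields(sec, ri, lz, n)
  integrand <- (2 * f$s$s_zz - f$s$s_th - f$s$s_rr) * f$r * f$lr
  pi * oracle_trap(f$rho, integrand) / 1000
}

oracle_fraction <- function(sec, ri, lz, direction = "theta", n = 20001) {
  f <- oracle_fields(sec, ri, lz, n)
  an <- if (direction == "theta") f$s$aniso_th else f$s$aniso_z
  tot <- if (direction == "theta") f$s$s_th else f$s$s_zz
  oracle_trap(f$rho, an * f$lr) / oracle_trap(f$rho, tot * f$lr)
}

# finite-difference oracle for the isochoric Cauchy stress: sigma_dd =
# lam_d dPsi/dlam_d on the unconstrained strain energy
oracle_fd_stress <- function(lr, lth, lz, c, k1, k2, beta_deg, step = 1e-6) {
  b <- beta_deg * pi / 180
  psi <- function(l1, l2, l3) {
    I1 <- l1^2 + l2^2 + l3^2
    I4 <- l2^2 * cos(b)^2 + l3^2 * sin(b)^2
    aniso <- if (I4 >= 1) k1 / (2 * k2) * (2 * exp(k2 * (I4 - 1)^2) - 2) else 0
    c * (I1 - 3) + aniso
  }
  d <- function(f, x, i) {
    xp <- x; xm <- x
    xp[i] <- x[i] + step
    xm[i] <- x[i] - step
    (f(xp[1], xp[2], xp[3]) - f(xm[1], xm[2], xm[3])) / (2 * step)
  }
  x <- c(lr, lth, lz)
  c(r = lr * d(psi, x, 1), theta = lth * d(psi, x, 2), z = lz * d(psi, x, 3))
}

# directly coded offset-corrected coefficient of determination
oracle_r_hat_sq <- function(pre, y) {
  d <- pre - y
  max(1 - sum((d - mean(d))^2) / sum((y - mean(y))^2), 0)
}
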