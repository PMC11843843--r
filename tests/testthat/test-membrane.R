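test_that("equilibrium stresses follow the thin-wall formulas", {
  eq <- equilibrium_stresses(ri = 5, h = 1, P = 10, fred = 0, alpha = 0.5)
  expect_equal(eq$sigma_theta_eq, 55)
  expect_equal(eq$sigma_r_eq, 0)
  eq0 <- equilibrium_stresses(ri = 6, h = 0.9, P = 0, fred = 0)
  expect_equal(unlist(eq0), c(sigma_theta_eq = 0, sigma_z_eq = 0,
                              sigma_r_eq = 0))
  expect_error(equilibrium_stresses(5, 0, 10, 0))
})

test_that("gamma-ratio closure holds as an algebraic identity", {
  cfg <- run_config()
  for (geo in list(c(6, 0.9), c(5.1, 1.3), c(8.7, 0.6))) {
    fred <- estimate_reduced_force(geo[1], geo[2], cfg)
    eq <- equilibrium_stresses(geo[1], geo[2], cfg$P_map, fred, cfg$alpha)
    expect_equal(eq$sigma_z_eq / eq$sigma_theta_eq, cfg$gamma,
                 tolerance = 1e-12)
  }
  # balanced ratio gives zero estimated force
  ri <- 6; gam <- run_config(gamma = 2 * ri^2 / (2 * ri + 0.8)^2)
  expect_equal(estimate_reduced_force(ri, 0.8, gam), 0, tolerance = 1e-12)
})

test_that("membrane stretches match the mid-wall-radius geometric oracle", {
  # identity: Ri chosen as the unloaded inner radius consistent with (ri, h)
  ri <- 6; h <- 0.9
  Ri <- uniroot(function(R) (2 * ri + h) - R - sqrt(R^2 + h * (2 * ri + h)),
                c(1, 10), tol = 1e-13)$root
  st <- membrane_stretches(ri, h, Ri, lam = 1)
  expect_equal(st$lam_th_m, 1, tolerance = 1e-10)
  # lam_z is always the prescribed axial stretch; lam_r from incompressibility
  st2 <- membrane_stretches(5.9, 0.7, 5.2, lam = 1.0918)
  expect_equal(st2$lam_z_m, 1.0918)
  expect_equal(st2$lam_r_m * st2$lam_th_m * st2$lam_z_m, 1)
  # geometric oracle: deformed over unloaded mid-wall radius
  Ro <- sqrt(5.2^2 + 1.0918 * 0.7 * (2 * 5.9 + 0.7))
  expect_equal(st2$lam_th_m, (5.9 + 0.7 / 2) / ((5.2 + Ro) / 2),
               tolerance = 1e-14)
})

test_that("membrane stresses close the radial direction exactly", {
  p15 <- membrane_parameters()[15, ]
  s <- membrane_stress_series(tibble::tibble(P = c(9.3, 13.3, 16),
                                             ri = c(6.4, 6.7, 6.9),
                                             h = c(0.75, 0.7, 0.67)), p15)
  st <- membrane_stretches(s$ri, s$h, p15$Ri, p15$lam)
  # p_mod equals the radial isochoric component: total radial stress is zero
  expect_equal(s$reaction_p, 2 * p15$c * st$lam_r_m^2, tolerance = 1e-14)
  # stress-free at identity; neo-Hookean closed form without fibers
  ri <- 6; h <- 0.9
  Ri <- uniroot(function(R) (2 * ri + h) - R - sqrt(R^2 + h * (2 * ri + h)),
                c(1, 10), tol = 1e-13)$root
  id <- membrane_stress_series(tibble::tibble(P = 0, ri = ri, h = h),
                               list(Ri = Ri, c = 10, k1 = 5, k2 = 1,
                                    beta = 40, lam = 1))
  expect_equal(id$sigma_total_theta, 0, tolerance = 1e-8)
  expect_equal(id$sigma_total_z, 0, tolerance = 1e-8)
  nh <- membrane_stress_series(tibble::tibble(P = 10, ri = 6.5, h = 0.8),
                               list(Ri = 5.5, c = 14, k1 = 1e-12, k2 = 1,
                                    beta = 40, lam = 1.1))
  stn <- membrane_stretches(6.5, 0.8, 5.5, 1.1)
  expect_equal(nh$sigma_total_theta,
               2 * 14 * (stn$lam_th_m^2 - stn$lam_th_m^-2 * 1.1^-2),
               tolerance = 1e-9)
})

test_that("membrane constitutive stresses match the energy oracle", {
  p15 <- membrane_parameters()[15, ]
  s <- membrane_stress_series(tibble::tibble(P = 16, ri = 6.9, h = 0.67), p15)
  st <- membrane_stretches(6.9, 0.67, p15$Ri, p15$lam)
  fd <- oracle_fd_stress(st$lam_r_m, st$lam_th_m, st$lam_z_m,
                         p15$c, p15$k1, p15$k2, p15$beta)
  expect_equal(s$sigma_total_theta, unname(fd["theta"] - fd["r"]),
               tolerance = 1e-6)
  expect_equal(s$sigma_total_z, unname(fd["z"] - fd["r"]),
               tolerance = 1e-6)
})

test_that("membrane load fractions are complementary, bounded, and grow with
          pressure under fiber recruitment", {
  s15 <- silico_series_for(15)
  mem <- membrane_stress_series(s15[c("P", "ri", "h")],
                                membrane_parameters()[15, ])
  psi <- membrane_load_fraction(mem, "theta")
  expect_equal(psi, mem$psi_theta)
  expect_true(all(psi >= 0 & psi <= 1))
  expect_true(all(diff(psi) > 0))
  expect_true(all(abs((1 - psi) - mem$sigma_iso_theta /
                        (mem$sigma_iso_theta + mem$sigma_aniso_theta)) < 1e-12))
  none <- membrane_stress_series(tibble::tibble(P = 10, ri = 6.5, h = 0.8),
                                 list(Ri = 5.5, c = 14, k1 = 1e-12, k2 = 1,
                                      beta = 40, lam = 1.1))
  expect_lt(membrane_load_fraction(none, "theta"), 1e-10)
})

test_that("the self-consistent membrane generator closes both equilibria", {
  p15 <- membrane_parameters()[15, ]
  ser <- membrane_truth_series(15)
  expect_equal(ser$P, pressure_grid(run_config()))
  obj <- stress_objective(p15[c("Ri", "c", "k1", "k2", "beta", "lam")],
                          ser, fred_est = attr(ser, "fred_est"))
  expect_lt(obj, 1e-10)
})

test_that("the membrane reaction stress is systematically underpredicted", {
  # with the artery's own parameters at mid-wall, the thin-wall reaction
  # stress lies below the thick-wall one at every pressure level
  for (id in c(15, 18, 4)) {
    art <- silico_aortas()[id, ]
    s <- silico_series_for(id)
    mem <- membrane_stress_series(
      s[c("P", "ri", "h")],
      list(Ri = art$R, c = art$c, k1 = art$k1, k2 = art$k2,
           beta = art$beta, lam = art$lam)
    )
    expect_true(all(mem$reaction_p - s$reaction_p <= 1e-6))
  }
})
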