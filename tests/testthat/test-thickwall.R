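test_that("opening-angle parameter follows both conventions", {
  expect_equal(opening_angle_parameter(0), 1)
  expect_equal(opening_angle_parameter(0, "half"), 1)
  expect_equal(opening_angle_parameter(96, "half"), 360 / 264)
  expect_equal(opening_angle_parameter(96, "full"), 180 / 84)
  # beyond 180 degrees the cut-open state is everted: k < 0
  expect_lt(opening_angle_parameter(252, "full"), 0)
  expect_error(opening_angle_parameter(180, "full"), "degenerate")
  expect_error(opening_angle_parameter(-3))
})

test_that("a closed, unstretched, unpressurized ring stays at its reference", {
  art <- list(set = 99L, R = 6, H = 1.2, phi0 = 0, c = 20, k1 = 15,
              k2 = 2, beta = 40, lam = 1)
  st <- solve_inflation(art, 0)
  expect_equal(st$ri, 6, tolerance = 1e-8)
  prof <- transmural_profile(art, 0, state = st)
  # at the identity the reaction stress equals the hydrostatic part 2c of
  # the neo-Hookean response, leaving every total stress component zero
  expect_lt(max(abs(prof$reaction_p - 2 * art$c)), 1e-6)
  expect_lt(max(abs(prof$sigma_total_theta)), 1e-6)
  expect_lt(max(abs(prof$sigma_total_z)), 1e-6)
  expect_lt(max(abs(prof$sigma_rr)), 1e-6)
  expect_equal(reduced_axial_force(art, 0, state = st), 0, tolerance = 1e-9)
})

test_that("stress-free sector equilibrates the unloaded ring, everted included", {
  cfg <- run_config()
  for (id in c(15, 1)) {
    art <- silico_aortas()[id, ]
    sec <- stress_free_sector(art, cfg)
    # the unloaded ring (P = 0, no axial stretch) carries no net pressure
    expect_lt(abs(aortamech:::.wall_pressure(art$R, sec, 1)), 1e-8)
  }
  sec1 <- stress_free_sector(silico_aortas()[1, ], cfg) # phi0 = 252 deg
  expect_lt(sec1$k, 0)
  expect_lt(sec1$rho_o, sec1$rho_i) # everted: lumen pairs with larger radius
})

test_that("solved states agree with the dense-trapezoid bisection oracle", {
  cfg <- run_config()
  for (id in c(15, 3, 19)) {
    art <- silico_aortas()[id, ]
    sec <- stress_free_sector(art, cfg)
    st <- solve_inflation(sec, 13.3, cfg)
    ri_o <- oracle_solve_ri(sec, 13.3, art$lam, lo = art$R * 0.5,
                            hi = st$ri * 1.3)
    expect_equal(st$ri, ri_o, tolerance = 1e-6)
    # reaction stress, axial force and load fractions at the oracle grid
    rm <- st$ri + st$h / 2
    p_pkg <- midwall_stress_series(
      sec, run_config(n_levels = 2, P_dbp = 13.3, P_map = 13.31, P_sbp = 13.32)
    )
    expect_equal(p_pkg$reaction_p[1],
                 oracle_reaction(sec, st$ri, art$lam, 13.3, rm),
                 tolerance = 1e-6)
    expect_equal(p_pkg$fred[1], oracle_fred(sec, st$ri, art$lam),
                 tolerance = 1e-6)
    prof <- transmural_profile(sec, 13.3, cfg, state = st)
    expect_equal(silico_load_fraction(prof, "theta"),
                 oracle_fraction(sec, st$ri, art$lam, "theta"),
                 tolerance = 1e-6)
    expect_equal(silico_load_fraction(prof, "z"),
                 oracle_fraction(sec, st$ri, art$lam, "z"),
                 tolerance = 1e-6)
  }
})

test_that("sweeps are monotone with incompressible thinning and exact BCs", {
  cfg <- run_config(n_levels = 11)
  for (id in c(15, 4)) {
    art <- silico_aortas()[id, ]
    sw <- pressure_sweep(art, cfg)
    expect_true(all(diff(sw$ri) > 0))
    expect_true(all(diff(sw$h) < 0))
    expect_true(all(sw$h > 0))
    for (P in c(9.3, 16)) {
      prof <- transmural_profile(art, P, cfg)
      tol <- 1e-6 * max(P, 1)
      expect_lt(abs(prof$sigma_rr[1] + P), tol)
      expect_lt(abs(prof$sigma_rr[nrow(prof)]), tol)
      expect_lt(max(abs(prof$lam_r * prof$lam_th * prof$lam_z - 1)), 1e-12)
      expect_true(all(diff(prof$r) > 0))
    }
  }
})

test_that("thin-wall limit reproduces the Laplace stress", {
  art <- list(set = 98L, R = 6, H = 6e-3, phi0 = 0, c = 20, k1 = 15,
              k2 = 2, beta = 40, lam = 1.1)
  cfg <- run_config(n_levels = 5)
  s <- midwall_stress_series(art, cfg)
  laplace <- (s$ri / s$h + 0.5) * s$P
  expect_true(all(abs(s$sigma_total_theta - laplace) / laplace < 0.005))
})

test_that("constant-strain sets are strain-uniform at MAP, unlike the
          high-gradient sets", {
  cfg <- run_config()
  prof18 <- transmural_profile(silico_aortas()[18, ], 13.3, cfg)
  prof4 <- transmural_profile(silico_aortas()[4, ], 13.3, cfg)
  spread <- function(p) diff(range(p$lam_th)) / mean(abs(p$lam_th))
  expect_lt(spread(prof18), 1e-3)
  expect_gt(spread(prof4), 0.05)
})

test_that("transmural gradient is the outer-minus-inner total stress", {
  art <- silico_aortas()[17, ]
  prof <- transmural_profile(art, 16)
  expect_equal(transmural_gradient(prof, "theta"),
               prof$sigma_total_theta[nrow(prof)] - prof$sigma_total_theta[1])
  # a stress-free profile has zero gradient
  art0 <- list(set = 97L, R = 6, H = 1, phi0 = 0, c = 20, k1 = 15, k2 = 2,
               beta = 40, lam = 1)
  expect_equal(transmural_gradient(transmural_profile(art0, 0), "theta"), 0,
               tolerance = 1e-8)
})

test_that("measurement noise is seeded, volume-preserving, and sized right", {
  sw <- membrane_truth_series(15)
  expect_identical(add_measurement_noise(sw, 0, seed = 1)$ri, sw$ri)
  n1 <- add_measurement_noise(sw, 0.05, seed = 42)
  n2 <- add_measurement_noise(sw, 0.05, seed = 42)
  expect_identical(n1$ri, n2$ri)
  expect_false(identical(n1$ri, add_measurement_noise(sw, 0.05, seed = 43)$ri))
  # wall cross-section preserved per level
  expect_equal(n1$h * (2 * n1$ri + n1$h), sw$h * (2 * sw$ri + sw$h),
               tolerance = 1e-12)
  # sample sd of the perturbation within 30% of the nominal sd at n = 101
  expect_lt(abs(sd(n1$ri - sw$ri) - 0.05) / 0.05, 0.3)
  expect_error(add_measurement_noise(sw, -0.1, seed = 1))
})
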