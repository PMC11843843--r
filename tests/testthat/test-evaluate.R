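test_that("signed maximum difference keeps sign and breaks ties upward", {
  expect_equal(delta_max(c(1, 2, 3), c(1, 2, 3)), 0)
  y <- c(10, 20, 30)
  expect_equal(delta_max(y + 3, y), 3)
  expect_equal(delta_max(y - 3, y), -3)
  # tie between -4 (index 1) and +4 (index 3): the later element wins
  expect_equal(delta_max(c(-4, 0, 4), c(0, 0, 0)), 4)
  expect_error(delta_max(numeric(0), numeric(0)))
})

test_that("offset-corrected R^2 is offset-invariant, clipped, and matches the
          direct formula", {
  y <- c(3, 5, 9, 11, 16)
  expect_equal(r_hat_squared(y + 7.3, y), 1)
  # uncorrelated prediction against a trend clips to zero
  expect_equal(r_hat_squared(c(5, -5, 5, -5, 5), 1:5), 0)
  expect_true(is.na(r_hat_squared(1:5, rep(2, 5))))
  set.seed(21)
  for (i in 1:20) {
    y <- rnorm(10)
    pre <- rnorm(10)
    expect_equal(r_hat_squared(pre, y), oracle_r_hat_sq(pre, y),
                 tolerance = 1e-12)
    shift <- runif(1, -100, 100)
    expect_equal(r_hat_squared(pre + shift, y), r_hat_squared(pre, y),
                 tolerance = 1e-12)
  }
})

test_that("group tests flag only a group different from both others", {
  expect_error(group_tests(1:3, c("a", "a", "b")))
  same <- group_tests(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_gt(same$kruskal_p, 0.05)
  expect_length(same$flagged, 0)
  sep <- group_tests(c(1:5, c(101, 103, 105, 107, 109),
                       c(102, 104, 106, 108, 110)),
                     rep(c("a", "b", "c"), each = 5))
  expect_lt(sep$kruskal_p, 0.05)
  expect_equal(sep$flagged, "a")
  expect_true(sep$flagged_p["a"] < 0.05 / 3)
})

test_that("correlation helper behaves on trivial inputs", {
  m <- tibble::tibble(set = 1:5, direction = "theta", component = "total",
                      delta_max = c(2, 4, 6, 8, 10), r_hat_sq = 1)
  g <- tibble::tibble(set = 1:5, gradient_theta = c(20, 40, 60, 80, 100),
                      gradient_z = 0)
  expect_equal(correlation_delta_gradient(m, g)$r, 1, tolerance = 1e-12)
  g2 <- g
  g2$gradient_theta <- rev(g$gradient_theta)
  expect_lt(correlation_delta_gradient(m, g2)$r, 0)
  expect_error(correlation_delta_gradient(m[1:2, ], g[1:2, ]))
})

test_that("a vanishing wall isolates the half-pressure reaction offset", {
  art <- list(set = 96L, R = 6, H = 6e-3, phi0 = 0, c = 20, k1 = 15,
              k2 = 2, beta = 40, lam = 1.1)
  cfg <- run_config(n_levels = 11)
  cmp <- compare_set(art, list(Ri = 6, c = 20, k1 = 15, k2 = 2, beta = 40,
                               lam = 1.1), cfg)
  get <- function(dir, comp) {
    cmp$delta_max[cmp$direction == dir & cmp$component == comp]
  }
  # the isochoric components and fractions coincide in the membrane limit
  # (sub-kPa against wall stresses of order P r/h ~ 1.6e4 kPa here)
  expect_lt(max(abs(c(get("theta", "iso"), get("theta", "aniso"),
                      get("z", "iso"), get("z", "aniso")))), 0.5)
  expect_lt(max(abs(c(get("theta", "fraction"), get("z", "fraction")))), 1e-3)
  # but the mid-wall reaction stress keeps half the luminal pressure that a
  # membrane cannot represent, shifting the totals by +P/2 at systole
  expect_equal(get("radial", "reaction"), -16 / 2, tolerance = 0.03)
  expect_equal(get("theta", "total"), 16 / 2, tolerance = 0.03)
  expect_equal(get("z", "total"), 16 / 2, tolerance = 0.03)
})

test_that("single-set groups give degenerate summaries", {
  art <- silico_aortas()[15, ]
  gt <- gradient_table(art, run_config(), pressure = 16)
  expect_equal(nrow(gt$per_set), 1)
  s <- gt$summary[gt$summary$direction == "theta", ]
  expect_equal(s$median, gt$per_set$gradient_theta)
  expect_equal(s$q1, s$q3)
})

test_that("plot helpers return ggplot objects", {
  sw <- membrane_truth_series(15)
  expect_s3_class(ggplot2::autoplot(sw), "ggplot")
  prof <- transmural_profile(silico_aortas()[15, ], 13.3)
  expect_s3_class(ggplot2::autoplot(prof, "theta"), "ggplot")
  cmp <- compare_set(silico_aortas()[15, ], membrane_parameters()[15, ],
                     silico = silico_series_for(15))
  expect_s3_class(plot_stress_comparison(cmp), "ggplot")
})
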