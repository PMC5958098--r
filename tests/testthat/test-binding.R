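test_that("fraction_bound solves the exact 1:1 binding quadratic", {
  # half saturation in the dilute-protein limit
  expect_equal(fraction_bound(6e-3, 0, 6e-3), 0.5, tolerance = 1e-12)
  expect_equal(fraction_bound(0, 1e-4, 6e-3), 0)
  # exact root against an independent bracketing-root oracle
  oracle <- function(L, P, K) {
    f <- function(X) X^2 - X * (L + P + K) + L * P
    X <- stats::uniroot(f, c(0, min(L, P)), tol = 1e-15)$root
    X / P
  }
  for (case in list(c(1e-3, 5e-5, 6e-3), c(5e-2, 1e-4, 5.9e-3),
                    c(2e-6, 1e-6, 3e-6))) {
    expect_equal(fraction_bound(case[1], case[2], case[3]),
                 oracle(case[1], case[2], case[3]), tolerance = 1e-10)
  }
  expect_error(fraction_bound(1e-3, 1e-4, 0), "positive")
})

test_that("fraction_bound is monotone in ligand and in affinity", {
  L <- 10^seq(-5, -1, length.out = 40)
  f <- fraction_bound(L, 5e-5, 6e-3)
  expect_true(all(diff(f) > 0))
  ks <- 10^seq(-4, -1, length.out = 20)
  fk <- vapply(ks, function(k) fraction_bound(1e-3, 5e-5, k), numeric(1))
  expect_true(all(diff(fk) < 0))
})

test_that("fit_kd recovers parameters and respects symmetries", {
  grid <- c(0.5, 1, 2, 4, 8, 16, 32, 64, 100) * 1e-3
  s <- simulate_titration(6e-3, 8.52, 8.87, 1.5e-4, grid, noise_sd = 0)
  fit <- fit_kd(s)
  expect_equal(fit$K_D, 6e-3, tolerance = 1e-6)
  expect_equal(fit$delta_free, 8.52, tolerance = 1e-6)
  expect_equal(fit$delta_bound, 8.87, tolerance = 1e-6)

  # sign symmetry: decreasing series gives the same K_D
  s_dn <- simulate_titration(6e-3, 8.87, 8.52, 1.5e-4, grid, noise_sd = 0)
  expect_equal(fit_kd(s_dn)$K_D, fit$K_D, tolerance = 1e-6)

  # scale equivariance: concentrations x c multiply K_D by c
  s_sc <- titration_series(s$L_tot * 10, s$delta_obs, s$P_tot * 10)
  expect_equal(fit_kd(s_sc)$K_D, 10 * fit$K_D, tolerance = 1e-5)
})

test_that("flat titrations are reported unidentifiable", {
  grid <- c(1, 2, 4, 8) * 1e-3
  flat <- titration_series(grid, rep(8.5, 4), 1e-4)
  expect_error(fit_kd(flat), "unidentifiable")
  expect_error(fit_kd(titration_series(grid[1:3], c(1, 2, 3), 1e-4)),
               "at least 4")
})

test_that("free-energy conversion matches RT ln(K1/K2)", {
  expect_equal(delta_delta_g(5e-3, 5e-3), 0)
  expect_equal(delta_delta_g(5.9e-3, 3e-6, 298.15), 4.49, tolerance = 0.01)
  expect_equal(delta_delta_g(1e-2, 1e-3, 298.15), 1.987e-3 * 298.15 * log(10),
               tolerance = 1e-12)
  # antisymmetry and additivity
  expect_equal(delta_delta_g(2e-3, 7e-6), -delta_delta_g(7e-6, 2e-3))
  expect_equal(delta_delta_g(1e-2, 1e-6),
               delta_delta_g(1e-2, 1e-4) + delta_delta_g(1e-4, 1e-6))
  expect_error(delta_delta_g(-1e-3, 1e-3), "positive")
})

test_that("populations normalise intensities (optionally per proton)", {
  expect_equal(population_from_intensities(c(3, 7)), c(0.3, 0.7))
  expect_equal(population_from_intensities(c(1, 1)), c(0.5, 0.5))
  expect_equal(population_from_intensities(5), 1)
  expect_equal(sum(population_from_intensities(runif(6))), 1)
  expect_equal(population_from_intensities(c(9, 1), protons = c(3, 1)),
               c(0.75, 0.25))
  expect_error(population_from_intensities(c(0, 0)), "zero")
})

test_that("STD difference isolates saturated-ligand peaks", {
  x <- seq(0, 10, length.out = 201)
  off <- exp(-((x - 3) / 0.2)^2) + exp(-((x - 7) / 0.2)^2)
  on <- off - 0.36 * exp(-((x - 3) / 0.2)^2) - 0.64 * exp(-((x - 7) / 0.2)^2)
  out <- std_difference(on, off)
  expect_equal(nrow(out$peaks), 2L)
  expect_equal(unname(out$populations), c(0.36, 0.64), tolerance = 1e-6)

  zero <- std_difference(off, off)
  expect_true(all(zero$difference == 0))
  expect_equal(nrow(zero$peaks), 0L)
  expect_error(std_difference(off, off[-1]), "equal length")
})
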