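test_that("current density is Ohm's law nodewise", {
  g <- build_grid(c(2e-3, 2e-3, 2e-3), 0.5e-3)
  E <- list(Ex = array(2.5e4, g$n), Ey = array(0, g$n), Ez = array(0, g$n),
            mag = array(2.5e4, g$n))
  J <- current_density(array(0.504, g$n), E)
  expect_equal(J$mag[1, 1, 1], 1.26e4, tolerance = 1e-12)
  J2 <- current_density(array(2 * 0.504, g$n), E)
  expect_equal(J2$mag, 2 * J$mag)
  Jz <- current_density(array(0.504, g$n),
                        list(Ex = array(0, g$n), Ey = array(0, g$n),
                             Ez = array(0, g$n), mag = array(0, g$n)))
  expect_true(all(Jz$mag == 0))
})

test_that("plate electrode current reproduces sigma*E*A in the uniform limit", {
  # full-cross-section plates 19 x 7 mm, 5 mm apart, 250 V/cm -> I = 1.6758 A
  fx <- plate_fixture(extent = c(5e-3, 19e-3, 7e-3), h = 0.5e-3,
                      sigma_val = 0.504)
  V <- 2.5e4 * 5e-3  # 125 V across the 5 mm gap
  sol <- solve_potential(fx$grid, fx$labels, fx$sigma, V, 0,
                         solver_settings(tol = 1e-10))
  Ia <- electrode_current(sol$phi, fx$sigma, fx$grid, fx$labels, "anode")
  Ic <- electrode_current(sol$phi, fx$sigma, fx$grid, fx$labels, "cathode")
  expect_equal(Ia, 0.504 * 2.5e4 * 19e-3 * 7e-3, tolerance = 1e-6)
  expect_lt(abs(Ia - Ic) / abs(Ia), 1e-2)
  # zero field -> zero current
  expect_equal(electrode_current(array(0, fx$grid$n), fx$sigma, fx$grid,
                                 fx$labels, "anode"), 0)
})

test_that("anode and cathode currents agree for needle pairs too", {
  fx <- needle_fixture()
  sig <- array(0.3, fx$grid$n)
  sol <- solve_potential(fx$grid, fx$labels, sig, 200, 0,
                         solver_settings(tol = 1e-9))
  Ia <- electrode_current(sol$phi, sig, fx$grid, fx$labels, "anode")
  Ic <- electrode_current(sol$phi, sig, fx$grid, fx$labels, "cathode")
  expect_gt(Ia, 0)
  expect_lt(abs(Ia - Ic) / abs(Ia), 1e-2)
  expect_error(electrode_current(sol$phi, sig, fx$grid,
                                 rasterize_electrodes(fx$grid, list()), "anode"),
               "lookup error")
})

test_that("charge accumulates trapezoidally and plateaus during OFF windows", {
  # 8 rectangular 1 A windows of 50 ms at 1 Hz, step edges as double samples
  t <- c(0); I <- c(0)
  for (k in 0:7) {
    t <- c(t, k, k + 0.05, k + 0.05, k + 1)
    I <- c(I, 1, 1, 0, 0)
  }
  Q <- accumulate_charge(t, I)
  expect_equal(Q[length(Q)], 0.4)
  # plateaus: Q identical at the start and end of every OFF interval
  expect_equal(Q[seq(4, 32, 4)], Q[seq(5, 33, 4)])
  expect_true(all(diff(Q) >= 0))

  expect_equal(accumulate_charge(c(0, 1, 2), c(0, 0, 0)), c(0, 0, 0))
  set.seed(2)
  Ir <- stats::runif(50)
  expect_true(all(diff(accumulate_charge(seq(0, 4.9, 0.1), Ir)) >= 0))
  expect_error(accumulate_charge(c(0, 1, 0.5), c(1, 1, 1)), "non-decreasing")
})

test_that("the threshold decays exponentially from E0 toward Einf with pulse number", {
  m <- threshold_model(E0 = 8e4, Einf = 2e4, tau = 6)
  expect_equal(threshold_at(m, 0), 8e4)
  expect_equal(threshold_at(m, 1e6), 2e4)
  ns <- 0:32
  expect_true(all(diff(threshold_at(m, ns)) < 0))
  expect_equal(threshold_at(m, 6), 2e4 + 6e4 * exp(-1))
  expect_error(threshold_model(E0 = 1e4, Einf = 2e4, tau = 6), "E0 >= Einf")
  expect_error(threshold_model(1e4, 1e3, tau = -1), "tau")
})

test_that("electroporated region matches an exhaustive nodewise comparison", {
  fx <- needle_fixture()  # 21^3 grid
  sig <- array(0.3, fx$grid$n)
  sol <- solve_potential(fx$grid, fx$labels, sig, 400, 0,
                         solver_settings(tol = 1e-8))
  E <- electric_field(sol$phi, fx$grid)
  thr <- 5e4
  reg <- electroporated_region(E$mag, thr, fx$grid, fx$labels)
  # brute-force oracle
  n <- fx$grid$n
  cnt <- 0L
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) for (k in seq_len(n[3])) {
    if (fx$labels$label[i, j, k] == 0L && E$mag[i, j, k] >= thr) {
      cnt <- cnt + 1L
      expect_true(reg$mask[i, j, k])
    }
  }
  expect_equal(sum(reg$mask), cnt)
  expect_equal(reg$volume, cnt * fx$grid$h^3)

  # trivial bounds
  uni <- array(600 * 100, fx$grid$n)
  all_t <- electroporated_region(uni, 500 * 100, fx$grid, fx$labels)
  expect_equal(all_t$volume, sum(fx$labels$label == 0L) * fx$grid$h^3)
  none <- electroporated_region(E$mag, 2 * max(E$mag), fx$grid, fx$labels)
  expect_equal(none$volume, 0)
})

test_that("threshold_from_area inverts the area of a level set", {
  g <- build_grid(c(8e-3, 8e-3, 2e-3), 0.25e-3)
  Emag <- make_synthetic_field("radial", g, list(c = 10))
  plane <- list(axis = 3, index = 5)
  # analytic: |E| = c/r >= level inside radius r* = c/level
  level_true <- 10 / 2e-3  # r* = 2 mm
  area_true <- pi * (2e-3)^2
  res <- threshold_from_area(Emag, area_true, g, plane)
  expect_equal(res$level, level_true, tolerance = 0.05)
  expect_equal(res$area, area_true, tolerance = 0.05)

  # identity: recovering the level of a measured mask area
  reg_area <- sum(slice_of(Emag, plane) >= 4000) * g$h^2
  back <- threshold_from_area(Emag, reg_area, g, plane)
  expect_equal(sum(slice_of(Emag, plane) >= back$level) * g$h^2, reg_area,
               tolerance = 1e-12)

  # monotonicity: larger target area -> smaller level
  r1 <- threshold_from_area(Emag, 5e-6, g, plane)
  r2 <- threshold_from_area(Emag, 2e-5, g, plane)
  expect_lt(r2$level, r1$level)
  expect_error(threshold_from_area(Emag, 1, g, plane), "range error")
})

test_that("threshold-decay fitting recovers parameters and flags degenerate input", {
  m <- threshold_model(E0 = 8e4, Einf = 2.2e4, tau = 5.5)
  ns <- seq(0, 32, 2)
  fit <- fit_threshold_decay(ns, threshold_at(m, ns))
  expect_true(fit$identifiable)
  expect_equal(fit$model$E0, m$E0, tolerance = 1e-6)
  expect_equal(fit$model$Einf, m$Einf, tolerance = 1e-6)
  expect_equal(fit$model$tau, m$tau, tolerance = 1e-6)
  expect_lt(fit$rms, 1e-6 * m$E0)

  cst <- fit_threshold_decay(c(1, 2, 3, 4), rep(5e4, 4))
  expect_false(cst$identifiable)
  expect_equal(cst$model$E0, 5e4)
})

test_that("damage is the union of irreversible field and thermal excess", {
  fx <- needle_fixture()
  n <- fx$grid$n
  set.seed(9)
  Emag <- array(stats::runif(prod(n), 0, 1e5), n)
  Tf <- array(stats::runif(prod(n), 36, 55), n)
  irrev <- threshold_model(E0 = 5e4)
  dm <- damage_region(Emag, irrev, n = 3, Tf, T_crit = 50, fx$grid, fx$labels)
  oracle <- (Emag >= 5e4 | Tf >= 50) & fx$labels$label == 0L
  expect_identical(dm$mask, oracle)
  expect_equal(dm$volume, sum(oracle) * fx$grid$h^3)

  # nothing above either threshold -> zero volume
  none <- damage_region(array(0, n), irrev, 1, array(37, n), 50, fx$grid, fx$labels)
  expect_equal(none$volume, 0)

  # reversible-only band: reversible minus damage = E_rev <= |E| < E_irr when cool
  rev <- electroporated_region(Emag, 2e4, fx$grid, fx$labels)
  cool <- damage_region(Emag, irrev, 1, array(37, n), 50, fx$grid, fx$labels)
  band <- rev$mask & !cool$mask
  expect_identical(band, (Emag >= 2e4 & Emag < 5e4) & fx$labels$label == 0L)
})
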