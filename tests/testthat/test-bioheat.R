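all_tissue <- function(extent = c(2e-3, 2e-3, 2e-3), h = 0.5e-3) {
  g <- build_grid(extent, h)
  list(grid = g, labels = classify_boundaries(g, rasterize_electrodes(g, list())))
}

adiabatic_params <- function(...) {
  physical_parameters(tissue = list(q_m = 0, rho = 1000, cp = 4000),
                      blood = list(omega = 0), ...)
}

test_that("temperature initializes uniformly at T_init", {
  fx <- all_tissue()
  p <- physical_parameters(env = list(T_init = 37))
  Tf <- initialize_temperature(fx$grid, p)
  expect_true(all(Tf == 37))
  expect_equal(mean(Tf), 37)
  p2 <- physical_parameters(env = list(T_init = 22.5))
  expect_true(all(initialize_temperature(fx$grid, p2) == 22.5))
})

test_that("equilibrium states stay put and uniform Joule heating matches the closed form", {
  fx <- all_tissue()
  # steady state: T = T0 = T_b, no sources
  p_eq <- physical_parameters(tissue = list(q_m = 0), blood = list(T_b = 37),
                              env = list(T_init = 37))
  T0 <- initialize_temperature(fx$grid, p_eq)
  st <- step_temperature(T0, fx$labels, fx$grid, p_eq, dt = 0.95, stage = "OFF")
  expect_lt(max(abs(st$T - 37)), 1e-12)

  # adiabatic uniform Joule: dT = sigma |E|^2 dt / (rho Cp)
  p <- adiabatic_params(env = list(T_init = 37))
  sig <- array(0.5, fx$grid$n); Em <- array(2.5e4, fx$grid$n)
  st2 <- step_temperature(T0, fx$labels, fx$grid, p, dt = 5e-5, stage = "ON",
                          sigma = sig, E_mag = Em,
                          settings = solver_settings(tol = 1e-14, omega = 1))
  expect_equal(unname(st2$T[2, 2, 2] - 37), 3.90625e-3, tolerance = 1e-10)
  expect_lt(diff(range(st2$T)), 1e-12)
})

test_that("perfusion-only cooling follows the lumped exponential with O(dt) accuracy", {
  fx <- all_tissue()
  p <- physical_parameters(tissue = list(q_m = 0, rho = 1000, cp = 4000),
                           blood = list(rho = 1060, omega = 1e-3, c = 3600, T_b = 37),
                           env = list(T_init = 42))
  rate <- 1060 * 1e-3 * 3600 / 4e6
  expect_equal(rate, 9.54e-4, tolerance = 1e-3)
  horizon <- 200
  run <- function(nsteps) {
    Tf <- initialize_temperature(fx$grid, p)
    for (i in seq_len(nsteps)) {
      Tf <- step_temperature(Tf, fx$labels, fx$grid, p, dt = horizon / nsteps,
                             stage = "OFF",
                             settings = solver_settings(tol = 1e-12, omega = 1))$T
    }
    Tf[2, 2, 2]
  }
  exact <- 37 + 5 * exp(-rate * horizon)
  e1 <- abs(run(8) - exact)
  e2 <- abs(run(16) - exact)
  expect_lt(e2, e1)                      # first-order convergence...
  expect_equal(e1 / e2, 2, tolerance = 0.15)  # ...halving dt halves the error
})

test_that("insulated OFF stages conserve total thermal energy", {
  fx <- all_tissue(extent = c(3e-3, 3e-3, 3e-3))
  p <- adiabatic_params(env = list(T_init = 37))
  set.seed(21)
  Tf <- 37 + array(stats::runif(prod(fx$grid$n)), fx$grid$n)
  e0 <- sum(Tf) * 1000 * 4000 * fx$grid$h^3
  st <- step_temperature(Tf, fx$labels, fx$grid, p, dt = 0.5, stage = "OFF",
                         settings = solver_settings(tol = 1e-12, omega = 1))
  e1 <- sum(st$T) * 1000 * 4000 * fx$grid$h^3
  expect_equal(e1, e0, tolerance = 1e-9)
})

test_that("a nonnegative Joule source never decreases any nodal temperature", {
  fx <- all_tissue()
  p <- adiabatic_params(env = list(T_init = 37))
  set.seed(5)
  for (rep in 1:5) {
    Tf <- 37 + array(stats::runif(prod(fx$grid$n), 0, 3), fx$grid$n)
    base <- step_temperature(Tf, fx$labels, fx$grid, p, dt = 1e-2, stage = "OFF",
                             settings = solver_settings(tol = 1e-12, omega = 1))$T
    src <- step_temperature(Tf, fx$labels, fx$grid, p, dt = 1e-2, stage = "ON",
                            sigma = array(stats::runif(prod(fx$grid$n), 0, 1), fx$grid$n),
                            E_mag = array(stats::runif(prod(fx$grid$n), 0, 2e4), fx$grid$n),
                            settings = solver_settings(tol = 1e-12, omega = 1))$T
    expect_true(all(src - base >= -1e-9))
  }
})

test_that("a slab with convective faces relaxes monotonically toward room temperature", {
  g <- build_grid(c(2e-3, 2e-3, 2e-3), 0.5e-3)
  # electrode block occupying the full top layer, fully exposed
  els <- list(
    electrode("plate", center = c(1e-3, 1e-3, 2e-3), polarity = "anode",
              size = c(2e-3, 2e-3, 0.25e-3), exposed_fraction = 1),
    electrode("plate", center = c(1e-3, 1e-3, 0), polarity = "cathode",
              size = c(2e-3, 2e-3, 0.25e-3), exposed_fraction = 1))
  lab <- classify_boundaries(g, rasterize_electrodes(g, els))
  p <- physical_parameters(tissue = list(q_m = 0), blood = list(omega = 0),
                           env = list(T_init = 37, T_room = 25, h = 50))
  Tf <- initialize_temperature(g, p)
  prev_max <- max(Tf)
  for (i in 1:5) {
    Tf <- step_temperature(Tf, lab, g, p, dt = 5, stage = "OFF")$T
    expect_lt(max(Tf), prev_max)
    expect_gte(min(Tf), 25)
    prev_max <- max(Tf)
  }
  expect_lt(max(Tf), 37)
})

test_that("transient diffusion matches the analytic cosine-mode decay within 1%", {
  # insulated 1D slab, initial cosine perturbation: the first Neumann
  # eigenmode decays as exp(-alpha (pi/L)^2 t). Grid nodes are the cell
  # centers of a slab of physical length L = n*h under the zero-flux
  # (omitted-face) discretization, so the mode is cos(pi (x + h/2) / L).
  h <- 1e-4
  g <- build_grid(c(40 * h, 8 * h, 8 * h), h)
  L <- g$n[1] * h
  lab <- classify_boundaries(g, rasterize_electrodes(g, list()))
  p <- physical_parameters(tissue = list(q_m = 0, rho = 1000, cp = 4000, kappa = 0.5),
                           blood = list(omega = 0), env = list(T_init = 37))
  alpha <- 0.5 / (1000 * 4000)
  x <- (seq_len(g$n[1]) - 1) * h
  mode <- cos(pi * (x + h / 2) / L)
  Tf <- array(0, g$n)
  for (i in seq_len(g$n[1])) Tf[i, , ] <- 37 + 2 * mode[i]
  t_end <- 40; nsteps <- 80
  for (s in seq_len(nsteps)) {
    Tf <- step_temperature(Tf, lab, g, p, dt = t_end / nsteps, stage = "OFF",
                           settings = solver_settings(tol = 1e-11, omega = 1))$T
  }
  exact <- 37 + 2 * mode * exp(-alpha * (pi / L)^2 * t_end)
  expect_lt(max(abs(sweep(Tf, 1, exact, "-"))) / 2, 0.01)
})
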