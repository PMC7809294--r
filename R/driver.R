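probe_index <- function(grid, p) {
  # nearest grid node to a probe coordinate
  as.integer(round(p / grid$h)) + 1L
}

#' Run a full staged electro-thermal simulation
#'
#' Orchestrates the staged ON/OFF loop over all pulse periods. After
#' initialization (`T = T_init` everywhere, `Phi = 0`, `sigma` from `T`),
#' every ON stage is subdivided into `thermal$dt_on_divisor` implicit steps;
#' at each step with a nonzero applied voltage the conductivity is updated
#' from the current temperature, the potential equation is re-solved
#' (warm-started from the previous solution), and `E`, `J` and the electrode
#' current are computed; at zero-voltage instants (OFF stages and H-FIRE
#' inter-phase delays) the potential solve is bypassed and the field is
#' identically zero. Temperature always advances; charge accumulates by
#' trapezoid. Each OFF stage is covered by a single unconditionally stable
#' implicit step. Field snapshots are recorded at the end of each ON and
#' OFF stage (cadence `"stage"`), and per-pulse electroporated/damage
#' volumes are evaluated on the end-of-ON field with the pulse-number-
#' dependent thresholds. The run is fully deterministic.
#'
#' @param config an `ep_config` from [build_config()] / [load_config()] /
#'   [scenario()].
#' @return An `ep_result` list: `series` (t, I, Q, probe temperatures),
#'   `pulses` (per-pulse threshold, electroporated and damage volumes, peak
#'   temperature), `snapshots`, `final` state fields, and a convergence
#'   `log`.
#' @export
run_simulation <- function(config) {
  grid <- config$grid
  labels <- classify_boundaries(grid, rasterize_electrodes(grid, config$electrodes))
  wave <- build_waveform(config$protocol)
  params <- config$params
  n_on <- max(1L, as.integer(config$thermal$dt_on_divisor))
  # the implicit thermal system is diagonally dominant (rho*Cp/dt term), so
  # plain Gauss-Seidel (omega = 1) converges fastest there
  tset <- solver_settings(tol = config$thermal$implicit_tol,
                          max_iter = config$thermal$implicit_max_iter,
                          omega = 1)

  T_field <- initialize_temperature(grid, params)
  phi <- array(0, grid$n)
  period <- 1 / config$protocol$frequency
  t_on <- config$protocol$t_on
  dt_on <- t_on / n_on
  probes <- config$probes
  probe_ix <- lapply(probes, probe_index, grid = grid)
  probe_names <- if (length(probes)) paste0("T", seq_along(probes)) else character()

  # rows: initial sample, then per pulse: one sample at the start of each ON
  # step (the step's current), the ON-stage end, a duplicate-time sample on
  # the OFF side of the current jump, and the OFF-stage end. Duplicate
  # timestamps carry step discontinuities without smearing the trapezoidal
  # charge integral.
  ns <- config$protocol$n_pulses * (n_on + 3L) + 1L
  t_s <- numeric(ns); I_s <- numeric(ns)
  P_s <- matrix(0, ns, length(probes))
  row <- 0L
  record <- function(t, I) {
    row <<- row + 1L
    t_s[row] <<- t; I_s[row] <<- I
    if (length(probes)) {
      P_s[row, ] <<- vapply(probe_ix, function(ix) T_field[ix[1], ix[2], ix[3]], 0)
    }
  }
  record(0, 0)

  pulses <- data.frame(pulse = seq_len(config$protocol$n_pulses),
                       threshold_V_per_m = NA_real_, ep_volume_m3 = NA_real_,
                       damage_volume_m3 = NA_real_, peak_T_C = NA_real_)
  snapshots <- list()
  iter_log <- list()
  E_pulse <- vector("list", config$protocol$n_pulses)
  keep_snaps <- identical(config$snapshot_cadence, "stage")

  sigma <- conductivity_from_temperature(T_field, params)
  E <- list(Ex = array(0, grid$n), Ey = array(0, grid$n),
            Ez = array(0, grid$n), mag = array(0, grid$n))
  v_prev <- 0
  phi_on <- array(0, grid$n); sigma_on <- sigma  # last energized solve
  joule_J <- 0  # cumulative Joule energy deposited in tissue (rectangle rule
                # per step, matching the source term of the implicit solver)
  tissue <- labels$label == 0L

  for (p in seq_len(config$protocol$n_pulses)) {
    t0 <- (p - 1) * period
    # field magnitude at the last energized instant of this pulse; the
    # trailing zero-voltage remainder of a burst window must not zero the
    # dose observables
    E_on_mag <- array(0, grid$n)
    for (s in seq_len(n_on)) {
      t_now <- t0 + (s - 1) * dt_on
      v <- voltage_at(wave, t_now)
      if (v != 0) {
        sigma <- conductivity_from_temperature(T_field, params)
        # the solve is linear in the applied voltage: rescaling the previous
        # solution gives a near-exact warm start across polarity flips
        phi0 <- if (v_prev != 0) phi * (v / v_prev) else phi
        sol <- solve_potential(grid, labels, sigma, v_anode = v,
                               v_cathode = 0, settings = config$solver,
                               phi0 = phi0)
        v_prev <- v
        phi <- sol$phi
        phi_on <- phi; sigma_on <- sigma
        E <- electric_field(phi, grid)
        E_on_mag <- E$mag
        I <- electrode_current(phi, sigma, grid, labels, "anode")
        iter_log[[length(iter_log) + 1L]] <- c(t = t_now, laplace = sol$iterations)
      } else {
        st <- off_stage_field(list(phi = phi), 0)
        phi <- st$phi; E <- st$E
        I <- 0
      }
      record(t_now, I)
      if (v != 0) joule_J <- joule_J + sum((sigma * E$mag^2)[tissue]) * grid$h^3 * dt_on
      ts <- step_temperature(T_field, labels, grid, params, dt_on, stage = "ON",
                             sigma = sigma, E_mag = E$mag, settings = tset)
      T_field <- ts$T
      if (s == n_on) {
        record(t0 + t_on, I)  # current holds to the end of the ON window
        record(t0 + t_on, 0)  # and drops at the ON/OFF transition
      }
    }
    # end-of-ON observables for this pulse
    thr <- threshold_at(config$reversible, p)
    ep <- electroporated_region(E_on_mag, thr, grid, labels)
    dm <- damage_region(E_on_mag, config$irreversible, p, T_field, config$t_crit,
                        grid, labels)
    pulses$threshold_V_per_m[p] <- thr
    pulses$ep_volume_m3[p] <- ep$volume
    pulses$damage_volume_m3[p] <- dm$volume
    pulses$peak_T_C[p] <- max(T_field)
    E_pulse[[p]] <- E_on_mag
    if (keep_snaps) {
      snapshots[[length(snapshots) + 1L]] <-
        list(name = sprintf("on-end-pulse-%03d", p), t = t0 + t_on,
             phi = phi, T = T_field, sigma = sigma)
    }
    # OFF stage: one implicit step, field bypassed
    dt_off <- period - t_on
    st <- off_stage_field(list(phi = phi), 0)
    phi <- st$phi; E <- st$E
    ts <- step_temperature(T_field, labels, grid, params, dt_off, stage = "OFF",
                           settings = tset)
    T_field <- ts$T
    record(t0 + period, 0)
    if (keep_snaps) {
      snapshots[[length(snapshots) + 1L]] <-
        list(name = sprintf("off-end-pulse-%03d", p), t = t0 + period,
             phi = phi, T = T_field, sigma = sigma)
    }
  }

  series <- data.frame(t_s = t_s[1:row], I_A = I_s[1:row],
                       Q_C = accumulate_charge(t_s[1:row], I_s[1:row]))
  if (length(probes)) {
    pt <- as.data.frame(P_s[1:row, , drop = FALSE])
    names(pt) <- probe_names
    series <- cbind(series, pt)
  }
  structure(list(series = series, pulses = pulses, snapshots = snapshots,
                 E_pulse = E_pulse,
                 final = list(T = T_field, phi = phi, sigma = sigma,
                              E_mag = E$mag, phi_on = phi_on,
                              sigma_on = sigma_on),
                 energy = list(joule_J = joule_J),
                 grid = grid, labels = labels, waveform = wave,
                 log = do.call(rbind, iter_log), config = config),
            class = "ep_result")
}

#' @export
print.ep_result <- function(x, ...) {
  cat(sprintf("<ep_result> %d pulses, %d samples, Q_final = %.4g C, peak T = %.2f C\n",
              nrow(x$pulses), nrow(x$series), max(x$series$Q_C),
              max(x$pulses$peak_T_C)))
  invisible(x)
}

#' Write a result bundle into a run directory
#'
#' Emits the CSV time series (`current.csv`, `charge.csv`, `probes.csv`,
#' `ep_volume.csv`), the VTK snapshots, the echoed configuration and a
#' per-solve iteration log, following the `config/`, `data/`, `log/` run
#' layout.
#'
#' @param result an `ep_result`.
#' @param run_dir a directory from [create_run_dir()].
#' @return `run_dir`, invisibly.
#' @export
write_result <- function(result, run_dir) {
  dat <- file.path(run_dir, "data")
  write_timeseries_csv(result$series[c("t_s", "I_A")], file.path(dat, "current.csv"))
  write_timeseries_csv(result$series[c("t_s", "Q_C")], file.path(dat, "charge.csv"))
  pcols <- setdiff(names(result$series), c("I_A", "Q_C"))
  write_timeseries_csv(result$series[pcols], file.path(dat, "probes.csv"))
  pv <- result$pulses
  ep <- data.frame(pulse = pv$pulse,
                   volume_mm3 = pv$ep_volume_m3 * 1e9,
                   threshold_V_per_cm = pv$threshold_V_per_m / 100,
                   damage_volume_mm3 = pv$damage_volume_m3 * 1e9)
  write_timeseries_csv(ep, file.path(dat, "ep_volume.csv"))
  for (sn in result$snapshots) {
    write_vtk(sn$T, result$grid, "T", file.path(dat, sprintf("T-%s.vtk", sn$name)))
    write_vtk(sn$phi, result$grid, "phi", file.path(dat, sprintf("phi-%s.vtk", sn$name)))
  }
  write_config(result$config, file.path(run_dir, "config", "config.yaml"))
  if (!is.null(result$log)) {
    lg <- as.data.frame(result$log)
    write_timeseries_csv(lg, file.path(run_dir, "log", "solver_iterations.csv"))
  }
  writeLines(sprintf("run completed at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             file.path(run_dir, "log", "run.log"))
  invisible(run_dir)
}

#' Pulse-number dose tuning
#'
#' Sweeps the pulse number and tabulates, for each candidate `n`, the
#' reversibly electroporated volume (end-of-ON field of pulse `n` against
#' the decayed threshold), the damage volume (irreversible field or thermal
#' excess) and the peak temperature reached by pulse `n`. Because all
#' per-pulse fields come from one simulation at `max(n_range)`, the sweep
#' costs a single run. The chosen dose is the smallest `n` whose reversible
#' volume is within a fraction `within` (default 1%) of the best feasible
#' volume, subject to the damage-volume and peak-temperature constraints.
#'
#' @param config an `ep_config`.
#' @param n_range integer vector of candidate pulse numbers.
#' @param max_damage_m3 damage-volume constraint (m^3), default `Inf`.
#' @param max_T_C peak-temperature constraint (degrees C), default `Inf`.
#' @param within slack fraction defining "as good as the maximum".
#' @param result optionally, a precomputed `ep_result` for this config at
#'   `>= max(n_range)` pulses (avoids re-running).
#' @return list with `table` (one row per n), `chosen` (selected n, or `NA`)
#'   and `feasible` (logical: any candidate met the constraints).
#' @export
tune_pulse_number <- function(config, n_range, max_damage_m3 = Inf, max_T_C = Inf,
                              within = 0.01, result = NULL) {
  n_range <- sort(unique(as.integer(n_range)))
  stopifnot(all(n_range >= 1))
  n_max <- max(n_range)
  if (is.null(result) || nrow(result$pulses) < n_max) {
    cfg <- config
    cfg$protocol$n_pulses <- n_max
    result <- run_simulation(cfg)
  }
  pv <- result$pulses
  tab <- data.frame(
    n = n_range,
    ep_volume_m3 = pv$ep_volume_m3[n_range],
    damage_volume_m3 = pv$damage_volume_m3[n_range],
    peak_T_C = cummax(pv$peak_T_C)[n_range]
  )
  tab$feasible <- tab$damage_volume_m3 <= max_damage_m3 & tab$peak_T_C <= max_T_C
  if (!any(tab$feasible)) {
    return(list(table = tab, chosen = NA_integer_, feasible = FALSE))
  }
  best <- max(tab$ep_volume_m3[tab$feasible])
  ok <- tab$feasible & tab$ep_volume_m3 >= (1 - within) * best
  list(table = tab, chosen = tab$n[which(ok)[1]], feasible = TRUE)
}
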