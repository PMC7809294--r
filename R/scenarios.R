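# Ready-to-run protocol presets transcribing the published case-study
# protocols (pulse counts, ON lengths, frequencies, V/D ratios, electrode
# geometries). Values not printed in the main protocol tables — domain sizes
# and detailed physiology — use documented placeholder defaults
# (source: default) that users should override for quantitative work.

scenario_names <- c("IRE-table1", "ECT-table1", "GET-table1",
                    "GET-needles-lackovic", "ECT-potato-4needle",
                    "HFIRE-well", "IRE-plates")

two_needles <- function(extent_mm, gap_mm, radius_mm = 0.5, length_mm = NULL,
                        exposed = 0.2) {
  # a facing anode/cathode needle pair along z, centered in the box,
  # separated gap_mm center-to-center along x, tips reaching mid-depth
  if (is.null(length_mm)) length_mm <- extent_mm[3] / 2
  ctr <- extent_mm / 2
  z_c <- extent_mm[3] - length_mm / 2  # inserted from the top face
  list(
    list(kind = "needle", polarity = "anode",
         center_mm = c(ctr[1] - gap_mm / 2, ctr[2], z_c),
         radius_mm = radius_mm, length_mm = length_mm, axis = c(0, 0, 1),
         exposed_fraction = exposed),
    list(kind = "needle", polarity = "cathode",
         center_mm = c(ctr[1] + gap_mm / 2, ctr[2], z_c),
         radius_mm = radius_mm, length_mm = length_mm, axis = c(0, 0, 1),
         exposed_fraction = exposed)
  )
}

two_plates <- function(extent_mm, gap_mm, size_mm) {
  ctr <- extent_mm / 2
  list(
    list(kind = "plate", polarity = "anode",
         center_mm = c(ctr[1] - gap_mm / 2 - size_mm[1] / 2, ctr[2], ctr[3]),
         size_mm = size_mm, exposed_fraction = 0.5),
    list(kind = "plate", polarity = "cathode",
         center_mm = c(ctr[1] + gap_mm / 2 + size_mm[1] / 2, ctr[2], ctr[3]),
         size_mm = size_mm, exposed_fraction = 0.5)
  )
}

potato_params <- function() {
  # vegetable tissue at room temperature: no perfusion, no metabolism
  list(tissue = list(sigma_b = 0.2, alpha = 0.015, T0 = 22, q_m = 0,
                     rho = 1050, cp = 3640, kappa = 0.56),
       blood = list(omega = 0),
       env = list(T_init = 22, T_room = 22))
}

scenario_specs <- function() {
  list(
    # 80 pulses, 100 us, 1 Hz, 1800 V/cm  (IRE protocol table)
    `IRE-table1` = list(
      domain = list(extent_mm = c(20, 20, 10), spacing_mm = 0.5),
      electrodes = two_needles(c(20, 20, 10), gap_mm = 10),
      protocol = list(n_pulses = 80, t_on_s = 1e-4, freq_hz = 1,
                      v_per_cm = 1800, gap_mm = 10),
      thresholds = list(irreversible = list(e_v_per_cm = 500))),
    # 8 pulses, 100 us, 10 Hz, 600 V/cm  (ECT protocol table)
    `ECT-table1` = list(
      domain = list(extent_mm = c(20, 20, 10), spacing_mm = 0.5),
      electrodes = two_needles(c(20, 20, 10), gap_mm = 8),
      protocol = list(n_pulses = 8, t_on_s = 1e-4, freq_hz = 10,
                      v_per_cm = 600, gap_mm = 8)),
    # 10 pulses, 20 ms, 1 Hz, 300 V/cm  (GET protocol table)
    `GET-table1` = list(
      domain = list(extent_mm = c(20, 20, 10), spacing_mm = 0.5),
      electrodes = two_needles(c(20, 20, 10), gap_mm = 8),
      protocol = list(n_pulses = 10, t_on_s = 0.02, freq_hz = 1,
                      v_per_cm = 300, gap_mm = 8)),
    # two-needle gene electrotransfer: 8 pulses of 50 ms, 1 Hz, 250 V/cm,
    # tissue conductivity 0.504 S/m; temperature probed at the electrode,
    # quarter gap and mid gap
    `GET-needles-lackovic` = list(
      domain = list(extent_mm = c(16, 16, 8), spacing_mm = 0.4),
      electrodes = two_needles(c(16, 16, 8), gap_mm = 8, radius_mm = 0.4),
      protocol = list(n_pulses = 8, t_on_s = 0.05, freq_hz = 1,
                      v_per_cm = 250, gap_mm = 8),
      params = list(tissue = list(sigma_b = 0.504)),
      output = list(probes_mm = list(c(4.6, 8, 5), c(6, 8, 5), c(8, 8, 5)))),
    # four-needle potato protocol: 4 pulses of 100 us, 1 Hz, 1500 V/cm
    `ECT-potato-4needle` = list(
      domain = list(extent_mm = c(20, 20, 8), spacing_mm = 0.5),
      electrodes = c(two_needles(c(20, 20, 8), gap_mm = 10),
                     lapply(two_needles(c(20, 20, 8), gap_mm = 10), function(e) {
                       e$center_mm <- e$center_mm[c(2, 1, 3)]  # rotated pair along y
                       e$polarity <- if (e$polarity == "anode") "cathode" else "anode"
                       e
                     })),
      protocol = list(n_pulses = 4, t_on_s = 1e-4, freq_hz = 1,
                      v_per_cm = 1500, gap_mm = 10),
      params = potato_params()),
    # H-FIRE well: 1 mm diameter needles 3 mm apart edge-to-edge, 900 V,
    # asymmetric 2/1/0.5 us bursts energized for 50 us, irreversible
    # threshold 500 V/cm
    `HFIRE-well` = list(
      domain = list(extent_mm = c(8, 8, 8), spacing_mm = 0.25),
      electrodes = two_needles(c(8, 8, 8), gap_mm = 4, radius_mm = 0.5,
                               length_mm = 4, exposed = 0.3),
      protocol = list(n_pulses = 1, t_on_s = 50e-6, freq_hz = 1,
                      v_per_cm = 2250, gap_mm = 4,  # 900 V across 4 mm c-to-c
                      waveform = "hfire-asymmetric",
                      hfire = list(pos_us = 2, delay_us = 1, neg_us = 0.5,
                                   energized_us = 50)),
      params = potato_params(),
      thresholds = list(irreversible = list(e_v_per_cm = 500))),
    # plate electrodes 19 x 7 x 1 mm separated 5 mm; 8 pulses of 50 ms,
    # 1 Hz, 250 V/cm
    `IRE-plates` = list(
      domain = list(extent_mm = c(7, 19, 7), spacing_mm = 0.5),
      electrodes = two_plates(c(7, 19, 7), gap_mm = 5, size_mm = c(1, 19, 7)),
      protocol = list(n_pulses = 8, t_on_s = 0.05, freq_hz = 1,
                      v_per_cm = 250, gap_mm = 5))
  )
}

#' Ready-to-run protocol presets
#'
#' Returns a complete, validated configuration for one of the shipped case
#' studies. Protocol parameters (pulse number, ON length, frequency, V/D
#' ratio, electrode dimensions and separations) are transcribed from the
#' published protocols; domain sizes and physiology not printed there use
#' documented defaults and can be overridden via `overrides`.
#'
#' @param name one of `r paste0('\x60', scenario_names, '\x60', collapse = ", ")`.
#' @param overrides optional nested list merged over the preset before
#'   validation (e.g. `list(domain = list(spacing_mm = 1))` to coarsen).
#' @return An `ep_config`.
#' @export
scenario <- function(name, overrides = NULL) {
  specs <- scenario_specs()
  if (!name %in% names(specs)) {
    stop(sprintf("lookup error: unknown scenario '%s'; valid names: %s",
                 name, paste(names(specs), collapse = ", ")), call. = FALSE)
  }
  raw <- specs[[name]]
  if (!is.null(overrides)) raw <- utils::modifyList(raw, overrides)
  build_config(raw)
}

#' List the available scenario presets
#' @return character vector of preset names.
#' @export
list_scenarios <- function() scenario_names

#' The H-FIRE well preset
#'
#' Convenience accessor for the bipolar-burst case study: a cubic well with
#' two 1 mm needles separated 3 mm edge-to-edge delivering 900 V in
#' asymmetric 2/1/0.5 microsecond bursts energized for 50 microseconds,
#' with the 500 V/cm irreversible threshold.
#'
#' @param overrides optional nested list of config overrides.
#' @return An `ep_config`.
#' @export
hfire_well_preset <- function(overrides = NULL) scenario("HFIRE-well", overrides)

#' Analytic synthetic fields for oracle tests
#'
#' Generates fields with known closed forms on a grid: `"uniform"` (constant
#' `value`), `"linear"` (`a * x`, gradient known exactly), `"radial"`
#' (`c / r` around an axis through the domain center, known level sets) and
#' `"two-slab"` (conductivity `sigma1` for `x` below the midplane, `sigma2`
#' above; known series-conductance solution between plates).
#'
#' @param kind one of `"uniform"`, `"linear"`, `"radial"`, `"two-slab"`.
#' @param grid an `ep_grid`.
#' @param params named list: `value`; `a`; `c` (and optional `eps` core
#'   radius); `sigma1`, `sigma2`.
#' @return a scalar array on the grid.
#' @export
make_synthetic_field <- function(kind = c("uniform", "linear", "radial", "two-slab"),
                                 grid, params = list()) {
  kind <- match.arg(kind)
  co <- coord_arrays(grid)
  switch(kind,
    uniform = array(params$value %||% 1, grid$n),
    linear = (params$a %||% 1) * co$x,
    radial = {
      cx <- grid$extent[1] / 2; cy <- grid$extent[2] / 2
      r <- sqrt((co$x - cx)^2 + (co$y - cy)^2)
      eps <- params$eps %||% (grid$h / 2)
      (params$c %||% 1) / pmax(r, eps)
    },
    `two-slab` = {
      s <- array(params$sigma1 %||% 1, grid$n)
      s[co$x > grid$extent[1] / 2 + 1e-15] <- params$sigma2 %||% 2
      s
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
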