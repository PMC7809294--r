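# Legacy ASCII VTK (STRUCTURED_POINTS) writer/reader and deterministic CSV
# time-series output, plus the YAML configuration loader.

num_fmt <- function(x) {
  # shortest decimal representation that round-trips a double
  vapply(x, function(v) {
    for (d in c(15L, 16L, 17L)) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, "")
}

#' Write a field snapshot as a legacy VTK file
#'
#' Legacy ASCII VTK, `DATASET STRUCTURED_POINTS`, with `DIMENSIONS nx ny nz`,
#' `SPACING h h h`, `ORIGIN 0 0 0` and one `POINT_DATA` attribute: `SCALARS`
#' (+ `LOOKUP_TABLE default`) for scalar fields or `VECTORS` for vector
#' fields. Values are written with x varying fastest (the R array layout),
#' which is the VTK point order. Readable by Paraview.
#'
#' @param field scalar array (grid dims), or for vectors a list of three
#'   arrays (components x, y, z).
#' @param grid an `ep_grid`.
#' @param name attribute name (e.g. `"phi"`, `"T"`, `"sigma"`, `"E"`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(field, grid, name, path) {
  n <- grid$n
  vector_field <- is.list(field)
  if (vector_field) {
    stopifnot(length(field) == 3L, all(dim(field[[1]]) == n))
    dat <- cbind(as.vector(field[[1]]), as.vector(field[[2]]), as.vector(field[[3]]))
    body <- c(sprintf("VECTORS %s double", name),
              apply(dat, 1, function(r) paste(num_fmt(r), collapse = " ")))
  } else {
    stopifnot(all(dim(field) == n))
    body <- c(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default",
              num_fmt(as.vector(field)))
  }
  lines <- c("# vtk DataFile Version 3.0",
             sprintf("epsim field %s", name),
             "ASCII",
             "DATASET STRUCTURED_POINTS",
             sprintf("DIMENSIONS %d %d %d", n[1], n[2], n[3]),
             sprintf("SPACING %s %s %s", num_fmt(grid$h), num_fmt(grid$h), num_fmt(grid$h)),
             "ORIGIN 0 0 0",
             sprintf("POINT_DATA %d", prod(n)),
             body)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a legacy VTK structured-points file written by [write_vtk()]
#'
#' @param path file path.
#' @return list with `dims`, `spacing`, `name`, and `field` (scalar array or
#'   list of three component arrays).
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(trimws(sub("DIMENSIONS", "", lines[grep("^DIMENSIONS", lines)])), " +")[[1]])
  spacing <- as.numeric(strsplit(trimws(sub("SPACING", "", lines[grep("^SPACING", lines)])), " +")[[1]])
  i_sc <- grep("^SCALARS", lines); i_vec <- grep("^VECTORS", lines)
  npts <- prod(dims)
  if (length(i_sc)) {
    name <- strsplit(lines[i_sc], " +")[[1]][2]
    vals <- as.numeric(lines[(i_sc + 2):(i_sc + 1 + npts)])
    field <- array(vals, dim = dims)
  } else {
    name <- strsplit(lines[i_vec], " +")[[1]][2]
    rows <- do.call(rbind, lapply(strsplit(lines[(i_vec + 1):(i_vec + npts)], " +"), as.numeric))
    field <- list(array(rows[, 1], dims), array(rows[, 2], dims), array(rows[, 3], dims))
  }
  list(dims = dims, spacing = spacing, name = name, field = field)
}

#' Write a time-series data frame as a deterministic CSV
#'
#' Header row, fixed column order as given, shortest round-trip decimal
#' floats, comma separator, LF line endings; identical input produces
#' byte-identical files.
#'
#' @param df a data frame (may have zero rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(df, path) {
  lines <- paste(names(df), collapse = ",")
  if (nrow(df)) {
    cols <- lapply(df, function(col) if (is.numeric(col)) num_fmt(col) else as.character(col))
    lines <- c(lines, do.call(paste, c(cols, sep = ",")))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

# ---------------------------------------------------------------------------
# configuration

config_defaults <- function() {
  list(
    domain = list(extent_mm = NULL, spacing_mm = NULL),
    electrodes = NULL,
    protocol = list(n_pulses = NULL, t_on_s = NULL, freq_hz = NULL,
                    v_per_cm = NULL, gap_mm = NULL, waveform = "monopolar",
                    hfire = list(pos_us = NULL, delay_us = NULL, neg_us = NULL,
                                 energized_us = NULL, neg_scale = 1)),
    params = list(tissue = list(), blood = list(), env = list(), electrode = list()),
    solver = list(tol = 1e-6, max_iter = 20000, omega = 1.8),
    thermal = list(dt_on_divisor = 1000, implicit_tol = 1e-8,
                   implicit_max_iter = 20000),
    thresholds = list(
      reversible = list(e0_v_per_cm = 800, einf_v_per_cm = 200, tau_pulses = 6),
      irreversible = list(e_v_per_cm = 500),
      t_crit_c = Inf),
    # probes_mm defaults to NULL (not an empty list) so a configured list of
    # unnamed probe points replaces it wholesale under modifyList
    output = list(snapshot_cadence = "stage", probes_mm = NULL)
  )
}

known_keys <- function(defaults, prefix = "") {
  out <- character()
  for (k in names(defaults)) {
    key <- paste0(prefix, k)
    out <- c(out, key)
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      out <- c(out, known_keys(defaults[[k]], paste0(key, ".")))
    }
  }
  out
}

#' Assemble and validate a simulation configuration
#'
#' Takes a nested configuration list (the same shape a YAML config file
#' parses to), fills documented defaults, converts every quantity to SI
#' (mm to m, microseconds to s, V/cm to V/m by x100), cross-validates it
#' (electrodes inside the domain, `t_on` shorter than the pulse period,
#' probes inside the domain) and reports every violation at once.
#'
#' @param raw nested named list of configuration values.
#' @return An `ep_config` object carrying the grid, electrodes, protocol,
#'   parameters, solver and threshold settings (all SI), plus the raw input.
#' @export
build_config <- function(raw) {
  defaults <- config_defaults()
  errs <- character()
  unknown <- setdiff(known_keys(raw), c(known_keys(defaults),
                                        "electrodes", "output.probes_mm",
                                        "params.tissue", "params.blood",
                                        "params.env", "params.electrode"))
  unknown <- unknown[!startsWith(unknown, "electrodes") &
                       !startsWith(unknown, "params.") &
                       !startsWith(unknown, "output.probes_mm")]
  if (length(unknown)) errs <- c(errs, paste("unknown key(s):", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, raw)
  need <- function(x, key) {
    if (is.null(x)) errs <<- c(errs, paste("missing required key:", key))
    x
  }
  need(cfg$domain$extent_mm, "domain.extent_mm")
  need(cfg$domain$spacing_mm, "domain.spacing_mm")
  need(cfg$protocol$n_pulses, "protocol.n_pulses")
  need(cfg$protocol$t_on_s, "protocol.t_on_s")
  need(cfg$protocol$freq_hz, "protocol.freq_hz")
  need(cfg$protocol$v_per_cm, "protocol.v_per_cm")
  need(cfg$protocol$gap_mm, "protocol.gap_mm")
  if (is.null(cfg$electrodes) || length(cfg$electrodes) == 0) {
    errs <- c(errs, "missing required key: electrodes (need >= 2)")
  }
  if (!is.null(cfg$protocol$t_on_s) && !is.null(cfg$protocol$freq_hz) &&
      cfg$protocol$t_on_s >= 1 / cfg$protocol$freq_hz) {
    errs <- c(errs, "protocol.t_on_s must be shorter than the period 1/freq_hz")
  }
  if (length(errs)) {
    stop(paste0("configuration error(s):\n  - ", paste(errs, collapse = "\n  - ")),
         call. = FALSE)
  }

  grid <- build_grid(cfg$domain$extent_mm * 1e-3, cfg$domain$spacing_mm * 1e-3)
  electrodes <- lapply(cfg$electrodes, function(e) {
    mat <- if (is.null(e$material)) list() else e$material
    mat <- utils::modifyList(list(kappa = 15, rho = 7900, cp = 500), mat)
    if (identical(e$kind, "needle")) {
      electrode("needle", center = unlist(e$center_mm) * 1e-3, polarity = e$polarity,
                radius = e$radius_mm * 1e-3, length = e$length_mm * 1e-3,
                axis = if (is.null(e$axis)) c(0, 0, 1) else unlist(e$axis),
                exposed_fraction = if (is.null(e$exposed_fraction)) 0 else e$exposed_fraction,
                material = mat)
    } else {
      electrode("plate", center = unlist(e$center_mm) * 1e-3, polarity = e$polarity,
                size = unlist(e$size_mm) * 1e-3,
                exposed_fraction = if (is.null(e$exposed_fraction)) 0 else e$exposed_fraction,
                material = mat)
    }
  })
  # cross-validation: embedded part inside the domain, probes inside domain
  for (i in seq_along(electrodes)) {
    ctr <- electrodes[[i]]$center
    if (any(ctr < -1e-12) || any(ctr > grid$extent + 1e-12)) {
      errs <- c(errs, sprintf("electrode %d center lies outside the domain", i))
    }
  }
  probes <- lapply(if (is.null(cfg$output$probes_mm)) list() else cfg$output$probes_mm,
                   function(p) unlist(p) * 1e-3)
  for (p in probes) {
    if (any(p < -1e-12) || any(p > grid$extent + 1e-12)) {
      errs <- c(errs, "probe point lies outside the domain")
    }
  }
  if (length(errs)) {
    stop(paste0("configuration error(s):\n  - ", paste(errs, collapse = "\n  - ")),
         call. = FALSE)
  }

  hf <- NULL
  if (cfg$protocol$waveform != "monopolar") {
    hf <- list(pos = cfg$protocol$hfire$pos_us * 1e-6,
               delay = cfg$protocol$hfire$delay_us * 1e-6,
               neg = cfg$protocol$hfire$neg_us * 1e-6,
               energized = cfg$protocol$hfire$energized_us * 1e-6,
               neg_scale = cfg$protocol$hfire$neg_scale)
  }
  protocol <- pulse_protocol(
    n_pulses = cfg$protocol$n_pulses, t_on = cfg$protocol$t_on_s,
    frequency = cfg$protocol$freq_hz,
    v_per_m = cfg$protocol$v_per_cm * 100,  # V/cm -> V/m
    gap = cfg$protocol$gap_mm * 1e-3,
    waveform = cfg$protocol$waveform, hfire = hf)
  params <- physical_parameters(tissue = cfg$params$tissue, blood = cfg$params$blood,
                                env = cfg$params$env, electrode = cfg$params$electrode)
  thr <- cfg$thresholds
  reversible <- threshold_model(E0 = thr$reversible$e0_v_per_cm * 100,
                                Einf = thr$reversible$einf_v_per_cm * 100,
                                tau = thr$reversible$tau_pulses)
  irreversible <- threshold_model(E0 = thr$irreversible$e_v_per_cm * 100)
  structure(list(
    grid = grid, electrodes = electrodes, protocol = protocol, params = params,
    solver = solver_settings(cfg$solver$tol, cfg$solver$max_iter, cfg$solver$omega),
    thermal = cfg$thermal,
    reversible = reversible, irreversible = irreversible,
    t_crit = thr$t_crit_c, probes = probes,
    snapshot_cadence = cfg$output$snapshot_cadence,
    raw = cfg), class = "ep_config")
}

#' Load a simulation configuration from a YAML file
#'
#' See [build_config()] for the schema, unit conversions and validation
#' behavior. Unknown keys are rejected; all schema violations are reported
#' in one error.
#'
#' @param path YAML configuration file.
#' @return An `ep_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("configuration error: no such file '%s'", path),
                               call. = FALSE)
  build_config(yaml::read_yaml(path))
}

#' Echo a validated configuration back to YAML
#'
#' Writes the fully-defaulted raw configuration (original units) so a run
#' can be reproduced from its run directory.
#'
#' @param config an `ep_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  raw <- config$raw
  raw$thresholds$t_crit_c <- if (is.infinite(raw$thresholds$t_crit_c)) ".inf" else raw$thresholds$t_crit_c
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

#' Create the next sequentially numbered run directory
#'
#' `simulation-000001`, `simulation-000002`, ... under `root`, each with
#' `config/`, `data/` and `log/` subdirectories.
#'
#' @param root parent directory (created if missing).
#' @return path of the new run directory.
#' @export
create_run_dir <- function(root = ".") {
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  existing <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  nums <- suppressWarnings(as.integer(sub("^simulation-", "", existing[grepl("^simulation-\\d{6}$", existing)])))
  nxt <- if (length(nums)) max(nums) + 1L else 1L
  run <- file.path(root, sprintf("simulation-%06d", nxt))
  for (d in c("config", "data", "log")) {
    dir.create(file.path(run, d), recursive = TRUE, showWarnings = FALSE)
  }
  run
}
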