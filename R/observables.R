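#' Current density from conductivity and field
#'
#' Ohm's law nodewise: `J = sigma * E`.
#'
#' @param sigma conductivity array (S/m).
#' @param E electric field list (`Ex`, `Ey`, `Ez`, `mag`) from
#'   [electric_field()].
#' @return list of arrays `Jx`, `Jy`, `Jz` (A/m^2) and magnitude `mag`.
#' @export
current_density <- function(sigma, E) {
  stopifnot(all(dim(sigma) == dim(E$Ex)))
  list(Jx = sigma * E$Ex, Jy = sigma * E$Ey, Jz = sigma * E$Ez,
       mag = sigma * E$mag)
}

#' Total current through an electrode's surface
#'
#' Discrete surface integral of the current over the voxel surface of the
#' chosen electrode's node set: every face between an electrode node and a
#' non-electrode neighbor contributes the stencil-consistent flux
#' `g * (Phi_electrode - Phi_neighbor)` with face conductance
#' `g = sigma_face * h` (harmonic-mean face conductivity). Because these
#' are exactly the fluxes of the converged 7-point stencil, the discrete
#' divergence theorem makes anode and cathode currents agree closely.
#' The returned current is positive when flowing from the anode into the
#' tissue, and positive into the cathode, so the two values agree in sign.
#'
#' @param phi converged potential array (V).
#' @param sigma conductivity array (S/m).
#' @param grid an `ep_grid`.
#' @param labels an `ep_labels`.
#' @param which `"anode"` or `"cathode"`.
#' @return total current (A).
#' @export
electrode_current <- function(phi, sigma, grid, labels, which = c("anode", "cathode")) {
  which <- match.arg(which)
  code <- if (which == "anode") 1L else 2L
  M <- labels$label == code
  if (!any(M)) stop(sprintf("lookup error: no %s nodes on the grid", which), call. = FALSE)
  a <- face_conductances(sigma, grid$h)
  n <- grid$n
  # finite-volume dual widths: nodes on a domain boundary represent half
  # cells, so faces through them carry half (edge) or quarter (corner) area;
  # this makes the 1D plate limit reproduce I = sigma*E*A exactly.
  half <- function(m) { f <- rep(1, m); f[c(1, m)] <- 0.5; f }
  Fx <- array(rep(half(n[1]), times = n[2] * n[3]), dim = n)
  Fy <- array(rep(rep(half(n[2]), each = n[1]), times = n[3]), dim = n)
  Fz <- array(rep(half(n[3]), each = n[1] * n[2]), dim = n)
  face_wt <- list(`1` = Fy * Fz, `2` = Fx * Fz, `3` = Fx * Fy)
  I <- 0
  # neighbor views padded so that faces leaving the domain never qualify
  # (mask padded TRUE, so excluded)
  pad_shift <- function(x, axis, dir, fill) {
    out <- array(fill, dim(x))
    if (axis == 1 && dir == -1) out[2:n[1], , ] <- x[1:(n[1] - 1), , ]
    if (axis == 1 && dir == +1) out[1:(n[1] - 1), , ] <- x[2:n[1], , ]
    if (axis == 2 && dir == -1) out[, 2:n[2], ] <- x[, 1:(n[2] - 1), ]
    if (axis == 2 && dir == +1) out[, 1:(n[2] - 1), ] <- x[, 2:n[2], ]
    if (axis == 3 && dir == -1) out[, , 2:n[3]] <- x[, , 1:(n[3] - 1)]
    if (axis == 3 && dir == +1) out[, , 1:(n[3] - 1)] <- x[, , 2:n[3]]
    out
  }
  faces <- list(list(a$aW, 1, -1), list(a$aE, 1, +1), list(a$aS, 2, -1),
                list(a$aN, 2, +1), list(a$aB, 3, -1), list(a$aT, 3, +1))
  for (f in faces) {
    nb_M <- pad_shift(M, f[[2]], f[[3]], TRUE)
    nb_phi <- pad_shift(phi, f[[2]], f[[3]], 0)
    wt <- face_wt[[as.character(f[[2]])]]
    sel <- M & !nb_M
    I <- I + sum((wt * f[[1]] * (phi - nb_phi))[sel])
  }
  if (which == "anode") I else -I
}

#' Cumulative delivered charge from a current series
#'
#' Trapezoidal cumulative integral `Q(t) = int_0^t I dt`, `Q(0) = 0`.
#' Current steps (pulse edges) are represented by two samples at the same
#' instant, one on each side of the jump; the zero-width interval adds no
#' charge, so OFF windows with `I = 0` at both ends stay exactly flat.
#'
#' @param t sample times (s), non-decreasing (equal times mark a jump).
#' @param I current samples (A), same length.
#' @return numeric vector `Q` (C).
#' @export
accumulate_charge <- function(t, I) {
  stopifnot(length(t) == length(I), length(t) >= 1)
  if (any(diff(t) < 0)) stop("state error: sample times must be non-decreasing",
                             call. = FALSE)
  if (length(t) == 1L) return(0)
  c(0, cumsum(diff(t) * (I[-1] + I[-length(I)]) / 2))
}

#' Exponential pulse-number decay model for the electroporation threshold
#'
#' The electric-field threshold above which tissue counts as electroporated
#' decays with the number of delivered pulses, from `E_0` before the first
#' pulse toward the asymptote `E_inf`, with decay constant `tau` (in
#' pulses): `E_thr(n) = E_inf + (E_0 - E_inf) * exp(-n / tau)`. A second
#' instance of the same type (typically with `E_0 = E_inf`) models the
#' irreversible-electroporation threshold.
#'
#' @param E0 threshold before the first pulse (V/m).
#' @param Einf asymptotic threshold (V/m), `0 < Einf <= E0`.
#' @param tau decay constant (pulses), > 0.
#' @return An `ep_threshold_model` object.
#' @export
threshold_model <- function(E0, Einf = E0, tau = 1) {
  if (!(E0 >= Einf && Einf > 0)) {
    stop("threshold model: need E0 >= Einf > 0", call. = FALSE)
  }
  if (tau <= 0) stop("threshold model: tau must be > 0", call. = FALSE)
  structure(list(E0 = E0, Einf = Einf, tau = tau), class = "ep_threshold_model")
}

#' Threshold value after n pulses
#'
#' @param model an [threshold_model()].
#' @param n pulse count(s), >= 0; vectorized.
#' @return threshold(s) (V/m).
#' @export
threshold_at <- function(model, n) {
  stopifnot(all(n >= 0))
  model$Einf + (model$E0 - model$Einf) * exp(-n / model$tau)
}

#' Electroporated region under a field threshold
#'
#' Tissue nodes whose field magnitude reaches the threshold
#' (boundary-inclusive comparison `|E| >= E_thr`). Volume is the labeled
#' node count times `h^3`; optionally also the area of the mask on a named
#' axis slice (count times `h^2`).
#'
#' @param E_mag field magnitude array (V/m).
#' @param E_thr threshold (V/m).
#' @param grid an `ep_grid`.
#' @param labels an `ep_labels` (electrode nodes never count).
#' @param plane optional list `list(axis =, index =)` selecting a slice for
#'   the area measure.
#' @return list with `mask` (logical array), `volume` (m^3) and, when a
#'   plane is given, `area` (m^2).
#' @export
electroporated_region <- function(E_mag, E_thr, grid, labels, plane = NULL) {
  mask <- (E_mag >= E_thr) & (labels$label == 0L)
  out <- list(mask = mask, volume = sum(mask) * grid$h^3)
  if (!is.null(plane)) {
    sl <- slice_array(mask, plane$axis, plane$index)
    out$area <- sum(sl) * grid$h^2
  }
  out
}

slice_array <- function(x, axis, index) {
  switch(as.character(axis),
         `1` = x[index, , ], `2` = x[, index, ], `3` = x[, , index],
         stop("plane axis must be 1, 2 or 3", call. = FALSE))
}

#' Field level whose slice isoline encloses a target area
#'
#' Inverts the area-vs-level step function on a grid slice: finds the field
#' level whose boundary-inclusive super-level set (`|E| >= level`) covers
#' the target area. This is how a threshold is extracted from an
#' experimentally measured electroporated area. Bisection over the level is
#' refined with the exact discrete inverse (the sorted slice values), since
#' the area is a staircase in the level; when no level lands within one
#' voxel-area of the target the nearest achievable level is returned and
#' flagged.
#'
#' @param E_mag field magnitude array (V/m).
#' @param target_area target area (m^2), in `(0, full slice area)`.
#' @param grid an `ep_grid`.
#' @param plane list `list(axis =, index =)` naming the slice.
#' @return list with `level` (V/m), `area` (achieved area, m^2) and
#'   `exact` (logical; `FALSE` flags an unreachable target).
#' @export
threshold_from_area <- function(E_mag, target_area, grid, plane) {
  vals <- sort(as.vector(slice_array(E_mag, plane$axis, plane$index)),
               decreasing = TRUE)
  h2 <- grid$h^2
  full <- length(vals) * h2
  if (target_area <= 0 || target_area >= full) {
    stop("range error: target area must lie strictly inside (0, slice area)",
         call. = FALSE)
  }
  k <- max(1L, min(length(vals), as.integer(round(target_area / h2))))
  level <- vals[k]
  achieved <- sum(vals >= level) * h2
  if (abs(achieved - target_area) > h2) {
    # ties collapsed several candidate areas; report nearest achievable
    cand_area <- vapply(unique(vals), function(v) sum(vals >= v) * h2, 0)
    j <- which.min(abs(cand_area - target_area))
    level <- unique(vals)[j]; achieved <- cand_area[j]
  }
  list(level = level, area = achieved,
       exact = abs(achieved - target_area) <= h2)
}

#' Fit the exponential threshold-decay model to (pulse, threshold) pairs
#'
#' Least-squares fit of `E_inf + (E_0 - E_inf) * exp(-n / tau)` by
#' Levenberg-Marquardt. Needs at least 3 distinct pulse numbers; constant
#' input returns `E_0 = E_inf = value` with `tau` flagged unidentifiable.
#'
#' @param n pulse numbers (>= 0, distinct).
#' @param E_thr observed thresholds (V/m).
#' @return list with `model` ([threshold_model()]), `rms` residual, and
#'   `identifiable` (FALSE for degenerate input).
#' @export
fit_threshold_decay <- function(n, E_thr) {
  stopifnot(length(n) == length(E_thr), length(n) >= 3, !anyDuplicated(n))
  if (diff(range(E_thr)) < 1e-12 * max(abs(E_thr), 1)) {
    return(list(model = threshold_model(E_thr[1], E_thr[1], tau = 1),
                rms = 0, identifiable = FALSE))
  }
  df <- data.frame(n = n, y = E_thr)
  start <- list(Einf = min(E_thr), dE = max(E_thr) - min(E_thr),
                tau = max(diff(range(n)) / 3, 0.5))
  fit <- minpack.lm::nlsLM(y ~ Einf + dE * exp(-n / tau), data = df,
                           start = start,
                           lower = c(Einf = 0, dE = 0, tau = 1e-9),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  list(model = threshold_model(E0 = unname(cf["Einf"] + cf["dE"]),
                               Einf = unname(cf["Einf"]),
                               tau = unname(cf["tau"])),
       rms = sqrt(mean(stats::residuals(fit)^2)),
       identifiable = TRUE)
}

#' Damaged-tissue region (irreversible field or temperature excess)
#'
#' Damage is the union of irreversible electroporation (`|E| >=`
#' irreversible threshold after `n` pulses) and thermal excess
#' (`T >= T_crit`), over tissue nodes.
#'
#' @param E_mag field magnitude array (V/m).
#' @param irreversible an [threshold_model()] for the lethal threshold.
#' @param n pulse count for the threshold evaluation.
#' @param T_field temperature array (degrees C).
#' @param T_crit critical temperature (degrees C); `Inf` disables thermal
#'   damage.
#' @param grid an `ep_grid`.
#' @param labels an `ep_labels`.
#' @return list with `mask` and `volume` (m^3).
#' @export
damage_region <- function(E_mag, irreversible, n, T_field, T_crit, grid, labels) {
  thr <- threshold_at(irreversible, n)
  mask <- ((E_mag >= thr) | (T_field >= T_crit)) & (labels$label == 0L)
  list(mask = mask, volume = sum(mask) * grid$h^3)
}
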