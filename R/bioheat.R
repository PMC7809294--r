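#' Physical parameters of tissue, blood, environment and electrodes
#'
#' Collects every constant of the coupled electro-thermal model: the linear
#' conductivity law (`sigma_b`, `alpha`, `T0`), tissue thermal properties
#' (`rho`, `cp`, `kappa`, metabolic heat `q_m`), the blood perfusion sink
#' (`rho`, `c`, perfusion rate `omega`, arterial temperature `T_b`), the
#' environment (heat-transfer coefficient `h`, room temperature `T_room`,
#' initial temperature `T_init`) and the electrode metal (`kappa`, `rho`,
#' `cp`; used for heat conduction through electrode nodes).
#'
#' @param tissue,blood,env,electrode named lists overriding individual
#'   defaults (SI units; temperatures in degrees C).
#' @return An `ep_params` object.
#' @export
physical_parameters <- function(tissue = list(), blood = list(), env = list(),
                                electrode = list()) {
  p <- list(
    tissue = utils::modifyList(list(
      sigma_b = 0.504,  # S/m
      alpha = 0.015,    # 1/C
      T0 = 37,          # C, reference of the conductivity law
      rho = 1060,       # kg/m^3
      cp = 3600,        # J/(kg K)
      kappa = 0.512,    # W/(m K)
      q_m = 420         # W/m^3
    ), tissue),
    blood = utils::modifyList(list(
      rho = 1060, c = 3600, omega = 1e-3, T_b = 37
    ), blood),
    env = utils::modifyList(list(
      h = 10, T_room = 25, T_init = 37
    ), env),
    electrode = utils::modifyList(list(
      kappa = 15, rho = 7900, cp = 500
    ), electrode)
  )
  with(p, {
    if (tissue$rho <= 0 || tissue$cp <= 0 || tissue$kappa <= 0 ||
        blood$rho <= 0 || blood$c <= 0 || electrode$kappa <= 0 ||
        electrode$rho <= 0 || electrode$cp <= 0) {
      stop("parameter error: densities, heat capacities and conductivities must be > 0",
           call. = FALSE)
    }
    if (blood$omega < 0 || tissue$q_m < 0 || env$h < 0) {
      stop("parameter error: omega, q_m and h must be >= 0", call. = FALSE)
    }
  })
  structure(p, class = "ep_params")
}

#' Initialize the temperature field
#'
#' Uniform initial temperature `T_init` everywhere (tissue and electrodes).
#'
#' @param grid an `ep_grid`.
#' @param params an [physical_parameters()].
#' @return temperature array (degrees C).
#' @export
initialize_temperature <- function(grid, params) {
  array(params$env$T_init, grid$n)
}

# Per-node material property arrays (tissue vs electrode nodes).
material_arrays <- function(labels, params) {
  el <- labels$label > 0L
  n <- dim(labels$label)
  kappa <- array(params$tissue$kappa, n); kappa[el] <- params$electrode$kappa
  rhocp <- array(params$tissue$rho * params$tissue$cp, n)
  rhocp[el] <- params$electrode$rho * params$electrode$cp
  perf <- array(params$blood$rho * params$blood$omega * params$blood$c, n)
  perf[el] <- 0
  qm <- array(params$tissue$q_m, n); qm[el] <- 0
  list(kappa = kappa, rhocp = rhocp, perf = perf, qm = qm)
}

# Add the convective (Robin) boundary terms to diag/b in place-by-return:
# for each electrode-air boundary face, flux h_conv * w * h^2 * (T - T_room).
robin_terms <- function(labels, grid, params, diag, b) {
  fc <- labels$faces
  if (is.null(fc)) return(list(diag = diag, b = b))
  h2 <- grid$h^2
  for (f in face_names) {
    w <- fc$robin[[f]]
    if (!any(w > 0)) next
    coef <- params$env$h * w * h2
    sl <- face_slice(grid$n, f)
    diag[sl$i, sl$j, sl$k] <- diag[sl$i, sl$j, sl$k] + coef
    b[sl$i, sl$j, sl$k] <- b[sl$i, sl$j, sl$k] + coef * params$env$T_room
  }
  list(diag = diag, b = b)
}

#' Advance the bioheat equation one implicit step
#'
#' One backward-Euler step of Pennes' bioheat equation
#' `rho Cp dT/dt = div(kappa grad T) - rho_b omega_b C_b (T - T_b)
#'  + sigma |grad Phi|^2 + q_m`:
#' 7-point diffusion with harmonic-mean face conductivities (mixing tissue
#' and electrode kappa at material interfaces), perfusion sink and metabolic
#' source in tissue nodes only, Joule source `sigma |E|^2` during ON stages
#' (zero inside electrodes and identically zero during OFF), convective
#' Robin condition on electrode-air boundary faces and zero flux on
#' tissue-air faces. The linear system is solved by the same red-black SOR
#' machinery as the potential equation; backward Euler is unconditionally
#' stable, which permits the long single OFF step.
#'
#' @param T_field current temperature array (degrees C).
#' @param labels an `ep_labels` with boundary faces classified.
#' @param grid an `ep_grid`.
#' @param params an [physical_parameters()].
#' @param dt time step (s).
#' @param stage `"ON"` or `"OFF"`.
#' @param sigma,E_mag conductivity (S/m) and field magnitude (V/m) arrays;
#'   required during ON, ignored during OFF.
#' @param settings inner-solver settings (default relative residual 1e-8).
#' @return list with `T` (new temperature array) and `iterations`.
#' @export
step_temperature <- function(T_field, labels, grid, params, dt,
                             stage = c("ON", "OFF"), sigma = NULL, E_mag = NULL,
                             settings = solver_settings(tol = 1e-8, omega = 1)) {
  stage <- match.arg(stage)
  if (dt <= 0) stop("state error: dt must be positive", call. = FALSE)
  mat <- material_arrays(labels, params)
  h3 <- grid$h^3
  a <- face_conductances(mat$kappa, grid$h)
  joule <- if (stage == "ON") {
    if (is.null(sigma) || is.null(E_mag)) {
      stop("state error: ON-stage temperature step needs sigma and E", call. = FALSE)
    }
    src <- sigma * E_mag^2
    src[labels$label > 0L] <- 0  # perfect conductors generate no Joule heat
    src
  } else {
    array(0, grid$n)
  }
  diag <- a$aW + a$aE + a$aS + a$aN + a$aB + a$aT +
    (mat$rhocp / dt + mat$perf) * h3
  b <- (mat$rhocp / dt * T_field + mat$perf * params$blood$T_b +
          joule + mat$qm) * h3
  rb <- robin_terms(labels, grid, params, diag, b)
  free <- array(TRUE, grid$n)
  sol <- relax_solve(a, rb$diag, rb$b, T_field, free, settings)
  if (!sol$converged) {
    stop(sprintf("solver error: bioheat relaxation stopped at residual %.3e after %d iterations",
                 sol$residual, sol$iterations), call. = FALSE)
  }
  list(T = sol$x, iterations = sol$iterations)
}
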