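#' Electrical conductivity from temperature
#'
#' The tissue conductivity follows a linear temperature law:
#' `sigma = sigma_b * (1 + alpha * (T - T0))`, with `sigma_b` the baseline
#' conductivity at the reference temperature `T0` and `alpha` the fractional
#' change per degree. This is the nonlinearity coupling the potential
#' equation to the bioheat equation.
#'
#' @param T_field temperature array (degrees C), any shape.
#' @param params an [physical_parameters()] object (uses `sigma_b`, `alpha`,
#'   `T0` of the tissue block).
#' @return conductivity array (S/m), same shape.
#' @export
conductivity_from_temperature <- function(T_field, params) {
  p <- params$tissue
  sig <- p$sigma_b * (1 + p$alpha * (T_field - p$T0))
  if (any(sig <= 0)) {
    bad <- T_field[which(sig <= 0)[1]]
    stop(sprintf("state error: non-physical conductivity <= 0 at T = %.3f C", bad),
         call. = FALSE)
  }
  sig
}

# Precompute the Laplace stencil for a conductivity field: face conductances
# (harmonic mean, zero-flux boundaries by omission) and diagonal.
laplace_stencil <- function(sigma, h) {
  a <- face_conductances(sigma, h)
  list(a = a, diag = a$aW + a$aE + a$aS + a$aN + a$aB + a$aT)
}

#' Solve the potential equation by relaxation
#'
#' Solves `div(sigma grad Phi) = 0` with a 7-point variable-coefficient
#' stencil (face conductivities are harmonic means of the adjacent nodal
#' values, which is flux-continuous across conductivity jumps), Dirichlet
#' values on electrode nodes, and zero-flux conditions on all tissue-air
#' boundary faces (mirror-node treatment, realized by omitting the outside
#' face). Red-black successive over-relaxation iterates until the relative
#' L2 residual falls below the tolerance.
#'
#' @param grid an `ep_grid`.
#' @param labels an `ep_labels` (needs at least one node of each polarity).
#' @param sigma conductivity array (S/m) on the grid.
#' @param v_anode,v_cathode imposed electrode potentials (V).
#' @param settings an [solver_settings()].
#' @param phi0 optional warm-start potential array (e.g. the previous ON
#'   step's solution); defaults to zero.
#' @return list with `phi` (V), `iterations`, `residual`.
#' @export
solve_potential <- function(grid, labels, sigma, v_anode, v_cathode,
                            settings = solver_settings(), phi0 = NULL) {
  if (any(sigma <= 0)) stop("state error: sigma must be positive", call. = FALSE)
  if (!any(labels$label == 1L) || !any(labels$label == 2L)) {
    stop("geometry error: potential solve needs both an anode and a cathode",
         call. = FALSE)
  }
  st <- laplace_stencil(sigma, grid$h)
  phi <- if (is.null(phi0)) array(0, grid$n) else phi0
  phi[labels$label == 1L] <- v_anode
  phi[labels$label == 2L] <- v_cathode
  free <- labels$label == 0L
  b <- array(0, grid$n)
  sol <- relax_solve(st$a, st$diag, b, phi, free, settings)
  if (!sol$converged) {
    stop(sprintf("solver error: potential relaxation stopped at residual %.3e after %d iterations",
                 sol$residual, sol$iterations), call. = FALSE)
  }
  list(phi = sol$x, iterations = sol$iterations, residual = sol$residual)
}

# one-axis gradient: central differences interior, second-order one-sided
# at the two boundary layers
grad_axis <- function(f, h, axis) {
  n <- dim(f)
  g <- array(0, n)
  idx <- function(i) switch(axis,
    `1` = f[i, , , drop = FALSE], `2` = f[, i, , drop = FALSE], `3` = f[, , i, drop = FALSE])
  asg <- function(i, val) {
    if (axis == 1) g[i, , ] <<- val else if (axis == 2) g[, i, ] <<- val else g[, , i] <<- val
  }
  m <- n[axis]
  asg(2:(m - 1), (idx(3:m) - idx(1:(m - 2))) / (2 * h))
  asg(1, (-3 * idx(1) + 4 * idx(2) - idx(3)) / (2 * h))
  asg(m, (3 * idx(m) - 4 * idx(m - 1) + idx(m - 2)) / (2 * h))
  g
}

#' Electric field from the potential
#'
#' `E = -grad(Phi)` by central differences in the interior and second-order
#' one-sided differences on the boundary layers (exact for linear
#' potentials, including at the boundary).
#'
#' @param phi potential array (V).
#' @param grid an `ep_grid`.
#' @return list of arrays `Ex`, `Ey`, `Ez` (V/m) and magnitude `mag`.
#' @export
electric_field <- function(phi, grid) {
  Ex <- -grad_axis(phi, grid$h, 1)
  Ey <- -grad_axis(phi, grid$h, 2)
  Ez <- -grad_axis(phi, grid$h, 3)
  list(Ex = Ex, Ey = Ey, Ez = Ez, mag = sqrt(Ex^2 + Ey^2 + Ez^2))
}

#' Zero the electric state during an OFF (or zero-voltage) stage
#'
#' During the OFF stage no voltage is applied, the field is zero, and the
#' potential solve is bypassed entirely: `Phi`, `E` and `J` are zeroed
#' without iterating, while temperature and conductivity are untouched.
#'
#' @param state a `FieldState`-style list holding at least `phi`, `E`, `J`.
#' @param applied_voltage the current segment's voltage; must be 0.
#' @return the state with `phi`, `E`, `J` identically zero.
#' @export
off_stage_field <- function(state, applied_voltage = 0) {
  if (applied_voltage != 0) {
    stop("logic error: OFF-stage bypass called while a nonzero voltage is applied",
         call. = FALSE)
  }
  z <- array(0, dim(state$phi))
  state$phi <- z
  state$E <- list(Ex = z, Ey = z, Ez = z, mag = z)
  state$J <- list(Jx = z, Jy = z, Jz = z, mag = z)
  state
}
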