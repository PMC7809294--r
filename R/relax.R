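# Shared red-black SOR relaxation core for the 7-point variable-coefficient
# stencils (Laplace and implicit bioheat). Coefficient arrays aW..aT hold the
# face conductances toward each neighbor (zero where the neighbor is outside
# the domain, which realizes the zero-flux mirror condition); `diag` is the
# full diagonal (sum of face conductances plus any reaction/ time terms).
# Fixed (Dirichlet) nodes keep the value passed in `x`.

#' Solver settings for the relaxation machinery
#'
#' @param tol relative L2 residual tolerance (dimensionless).
#' @param max_iter iteration cap (one iteration = one red + one black sweep).
#' @param omega SOR relaxation factor in (0, 2).
#' @return An `ep_solver_settings` list.
#' @export
solver_settings <- function(tol = 1e-6, max_iter = 20000L, omega = 1.8) {
  if (tol <= 0) stop("solver settings: tol must be > 0", call. = FALSE)
  if (max_iter < 1) stop("solver settings: max_iter must be >= 1", call. = FALSE)
  if (omega <= 0 || omega >= 2) stop("solver settings: omega must lie in (0, 2)", call. = FALSE)
  structure(list(tol = tol, max_iter = as.integer(max_iter), omega = omega),
            class = "ep_solver_settings")
}

# face conductance arrays from a node-valued coefficient field (sigma or kappa):
# harmonic mean across each face, scaled by h (conductance of a face of area
# h^2 at distance h). Returns aW,aE,aS,aN,aB,aT with zeros at missing faces.
face_conductances <- function(coef, h) {
  n <- dim(coef)
  hm <- function(a, b) 2 * a * b / (a + b)
  z <- array(0, n)
  aW <- z; aE <- z; aS <- z; aN <- z; aB <- z; aT <- z
  aW[2:n[1], , ] <- hm(coef[1:(n[1] - 1), , ], coef[2:n[1], , ]) * h
  aE[1:(n[1] - 1), , ] <- aW[2:n[1], , ]
  aS[, 2:n[2], ] <- hm(coef[, 1:(n[2] - 1), ], coef[, 2:n[2], ]) * h
  aN[, 1:(n[2] - 1), ] <- aS[, 2:n[2], ]
  aB[, , 2:n[3]] <- hm(coef[, , 1:(n[3] - 1)], coef[, , 2:n[3]]) * h
  aT[, , 1:(n[3] - 1)] <- aB[, , 2:n[3]]
  list(aW = aW, aE = aE, aS = aS, aN = aN, aB = aB, aT = aT)
}

# weighted neighbor sum S[i] = sum_f a_f x[neighbor_f]
neighbor_sum <- function(a, x) {
  n <- dim(x)
  S <- array(0, n)
  S[2:n[1], , ] <- S[2:n[1], , ] + a$aW[2:n[1], , ] * x[1:(n[1] - 1), , ]
  S[1:(n[1] - 1), , ] <- S[1:(n[1] - 1), , ] + a$aE[1:(n[1] - 1), , ] * x[2:n[1], , ]
  S[, 2:n[2], ] <- S[, 2:n[2], ] + a$aS[, 2:n[2], ] * x[, 1:(n[2] - 1), ]
  S[, 1:(n[2] - 1), ] <- S[, 1:(n[2] - 1), ] + a$aN[, 1:(n[2] - 1), ] * x[, 2:n[2], ]
  S[, , 2:n[3]] <- S[, , 2:n[3]] + a$aB[, , 2:n[3]] * x[, , 1:(n[3] - 1)]
  S[, , 1:(n[3] - 1)] <- S[, , 1:(n[3] - 1)] + a$aT[, , 1:(n[3] - 1)] * x[, , 2:n[3]]
  S
}

parity_mask <- function(n) {
  i <- array(rep(seq_len(n[1]), times = n[2] * n[3]), dim = n)
  j <- array(rep(rep(seq_len(n[2]), each = n[1]), times = n[3]), dim = n)
  k <- array(rep(seq_len(n[3]), each = n[1] * n[2]), dim = n)
  (i + j + k) %% 2 == 0
}

# Red-black SOR solve of diag*x - sum_f a_f x_nb = b on free nodes.
# Returns list(x, iterations, residual, converged).
relax_solve <- function(a, diag, b, x, free, settings, check_every = 4L) {
  red <- parity_mask(dim(x)) & free
  black <- !parity_mask(dim(x)) & free
  w <- settings$omega
  res <- Inf; it <- 0L
  repeat {
    it <- it + 1L
    S <- neighbor_sum(a, x)
    x[red] <- (1 - w) * x[red] + w * (S[red] + b[red]) / diag[red]
    S <- neighbor_sum(a, x)
    x[black] <- (1 - w) * x[black] + w * (S[black] + b[black]) / diag[black]
    if (it %% check_every == 0L || it >= settings$max_iter) {
      # relative L2 residual over free nodes
      S <- neighbor_sum(a, x)
      r <- b[free] + S[free] - diag[free] * x[free]
      den <- sqrt(sum((diag[free] * x[free])^2) + sum(b[free]^2))
      res <- if (den > 0) sqrt(sum(r^2)) / den else sqrt(sum(r^2))
      if (res <= settings$tol || it >= settings$max_iter) break
    }
  }
  list(x = x, iterations = it, residual = res, converged = res <= settings$tol)
}
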