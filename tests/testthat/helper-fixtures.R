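# Shared fixtures and independent oracles for the suite. All fixtures are
# built in code; no binary data.

# full-cross-section plate pair at the x ends of the box (one node layer
# each), so the interior problem is one-dimensional along x
plate_fixture <- function(extent = c(10e-3, 5e-3, 5e-3), h = 0.5e-3,
                          sigma_val = 0.5) {
  g <- build_grid(extent, h)
  thin <- h / 2  # covers exactly the boundary node layer
  els <- list(
    electrode("plate", center = c(0, extent[2] / 2, extent[3] / 2),
              polarity = "anode", size = c(thin, extent[2], extent[3])),
    electrode("plate", center = c(extent[1], extent[2] / 2, extent[3] / 2),
              polarity = "cathode", size = c(thin, extent[2], extent[3])))
  lab <- classify_boundaries(g, rasterize_electrodes(g, els))
  list(grid = g, labels = lab, sigma = array(sigma_val, g$n))
}

# a facing needle pair fixture for exhaustive-oracle tests
needle_fixture <- function(extent = c(8e-3, 8e-3, 8e-3), h = 0.4e-3) {
  g <- build_grid(extent, h)
  els <- list(
    electrode("needle", center = c(2.4e-3, 4e-3, 6e-3), polarity = "anode",
              radius = 0.5e-3, length = 4e-3),
    electrode("needle", center = c(5.6e-3, 4e-3, 6e-3), polarity = "cathode",
              radius = 0.5e-3, length = 4e-3))
  lab <- classify_boundaries(g, rasterize_electrodes(g, els))
  list(grid = g, labels = lab, electrodes = els)
}

# brute-force point-membership rasterization oracle (independent loop
# implementation, no vectorized reuse of the package's mask code)
brute_force_labels <- function(grid, electrodes) {
  lab <- array(0L, dim = grid$n)
  for (i in seq_len(grid$n[1])) for (j in seq_len(grid$n[2])) for (k in seq_len(grid$n[3])) {
    pt <- c(i - 1, j - 1, k - 1) * grid$h
    for (e in electrodes) {
      inside <- if (e$kind == "plate") {
        all(abs(pt - e$center) <= e$size / 2 + 1e-12)
      } else {
        d <- pt - e$center
        proj <- sum(d * e$axis)
        radial2 <- sum((d - proj * e$axis)^2)
        abs(proj) <= e$length / 2 + 1e-12 && radial2 <= (e$radius + 1e-12)^2
      }
      if (inside) lab[i, j, k] <- if (e$polarity == "anode") 1L else 2L
    }
  }
  lab
}

# dense direct solve of the identical 7-point stencil (independent route:
# assembles the full matrix and uses base::solve)
dense_potential <- function(grid, labels, sigma, v_anode, v_cathode) {
  n <- grid$n; N <- prod(n)
  idx <- function(i, j, k) i + (j - 1) * n[1] + (k - 1) * n[1] * n[2]
  hm <- function(a, b) 2 * a * b / (a + b)
  fixed <- labels$label != 0L
  phi_fix <- numeric(N)
  phi_fix[as.vector(labels$label) == 1L] <- v_anode
  phi_fix[as.vector(labels$label) == 2L] <- v_cathode
  free_ids <- which(!as.vector(fixed))
  pos <- match(seq_len(N), free_ids)
  A <- matrix(0, length(free_ids), length(free_ids))
  b <- numeric(length(free_ids))
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) for (k in seq_len(n[3])) {
    p <- idx(i, j, k)
    if (fixed[i, j, k]) next
    rp <- pos[p]
    nbrs <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                 c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (nb in nbrs) {
      if (any(nb < 1) || any(nb > n)) next
      g <- hm(sigma[i, j, k], sigma[nb[1], nb[2], nb[3]]) * grid$h
      q <- idx(nb[1], nb[2], nb[3])
      A[rp, rp] <- A[rp, rp] + g
      if (fixed[nb[1], nb[2], nb[3]]) {
        b[rp] <- b[rp] + g * phi_fix[q]
      } else {
        A[rp, pos[q]] <- A[rp, pos[q]] - g
      }
    }
  }
  phi <- phi_fix
  phi[free_ids] <- solve(A, b)
  array(phi, dim = n)
}

# resistor-chain closed form for the 1D series-slab problem on the same
# stencil: returns the exact discrete potential profile along x
series_chain_phi <- function(sigma_profile, v_anode, v_cathode) {
  hm <- function(a, b) 2 * a * b / (a + b)
  m <- length(sigma_profile)
  g_face <- hm(sigma_profile[-m], sigma_profile[-1])
  R <- cumsum(c(0, 1 / g_face))
  v_anode + (v_cathode - v_anode) * R / R[m]
}

# slice extraction mirroring the package's plane convention
slice_of <- function(x, plane) {
  switch(plane$axis, x[plane$index, , ], x[, plane$index, ], x[, , plane$index])
}

# minimal fast driver config on a small plate geometry
small_run_config <- function(n_pulses = 2, v_per_cm = 250, freq_hz = 1,
                             t_on_s = 0.05, divisor = 5, extent_mm = c(6, 4, 4),
                             spacing_mm = 1, extra = list()) {
  base <- list(
    domain = list(extent_mm = extent_mm, spacing_mm = spacing_mm),
    electrodes = list(
      list(kind = "plate", polarity = "anode",
           center_mm = c(0, extent_mm[2] / 2, extent_mm[3] / 2),
           size_mm = c(spacing_mm / 2, extent_mm[2], extent_mm[3])),
      list(kind = "plate", polarity = "cathode",
           center_mm = c(extent_mm[1], extent_mm[2] / 2, extent_mm[3] / 2),
           size_mm = c(spacing_mm / 2, extent_mm[2], extent_mm[3]))),
    protocol = list(n_pulses = n_pulses, t_on_s = t_on_s, freq_hz = freq_hz,
                    v_per_cm = v_per_cm, gap_mm = extent_mm[1]),
    thermal = list(dt_on_divisor = divisor),
    solver = list(tol = 1e-8)
  )
  build_config(utils::modifyList(base, extra))
}
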