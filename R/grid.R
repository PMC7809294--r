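#' Build a uniform 3D simulation grid
#'
#' The simulation domain is a rectangular box discretized as a node-centered
#' uniform lattice with a single spacing `h` on all three axes. Node
#' coordinates are `(i-1)*h` along each axis (0-based physical coordinates,
#' 1-based R indices). All geometry is in SI meters internally.
#'
#' @param extent numeric length-3, domain extent per axis in meters.
#' @param spacing numeric scalar, grid spacing `h` in meters; must divide
#'   every extent to within a relative tolerance of 1e-9.
#' @return An object of class `ep_grid`: list with `n` (node counts),
#'   `h` (spacing, m) and `extent` (m). Face area is `h^2`, node volume `h^3`.
#' @examples
#' g <- build_grid(extent = c(1, 1, 1) * 1e-3, spacing = 0.5e-3)
#' g$n  # 3 3 3
#' @export
build_grid <- function(extent, spacing) {
  if (length(extent) != 3L || !is.numeric(extent) || any(!is.finite(extent)) ||
      any(extent <= 0)) {
    stop("configuration error: `extent` must be 3 positive finite lengths (m)",
         call. = FALSE)
  }
  if (length(spacing) != 1L || !is.numeric(spacing) || !is.finite(spacing) ||
      spacing <= 0) {
    stop("configuration error: `spacing` must be a positive length (m)",
         call. = FALSE)
  }
  ratio <- extent / spacing
  bad <- abs(ratio - round(ratio)) > 1e-9 * pmax(ratio, 1)
  if (any(bad)) {
    stop(sprintf(
      "configuration error: spacing %.6g m does not divide the extent on axis %s",
      spacing, paste(c("x", "y", "z")[bad], collapse = ", ")), call. = FALSE)
  }
  n <- as.integer(round(ratio)) + 1L
  if (any(n < 3L)) {
    stop("configuration error: each axis needs at least 3 nodes (extent >= 2*spacing)",
         call. = FALSE)
  }
  structure(list(n = n, h = spacing, extent = (n - 1L) * spacing),
            class = "ep_grid")
}

#' @export
print.ep_grid <- function(x, ...) {
  cat(sprintf("<ep_grid> %d x %d x %d nodes, h = %g mm, extent = %s mm\n",
              x$n[1], x$n[2], x$n[3], x$h * 1e3,
              paste(signif(x$extent * 1e3, 6), collapse = " x ")))
  invisible(x)
}

#' Node coordinates of a grid axis
#'
#' @param grid an `ep_grid`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of node coordinates (m) along that axis.
#' @keywords internal
axis_coords <- function(grid, axis) {
  (seq_len(grid$n[axis]) - 1) * grid$h
}

#' Full coordinate arrays (nx x ny x nz) for each axis
#' @keywords internal
#' @noRd
coord_arrays <- function(grid) {
  n <- grid$n
  list(
    x = array(rep(axis_coords(grid, 1), times = n[2] * n[3]), dim = n),
    y = array(rep(rep(axis_coords(grid, 2), each = n[1]), times = n[3]), dim = n),
    z = array(rep(axis_coords(grid, 3), each = n[1] * n[2]), dim = n)
  )
}

#' Describe an electrode solid
#'
#' Electrodes are either needle cylinders (arbitrary axis direction) or
#' axis-aligned plate boxes, carrying a polarity, the fraction of the
#' electrode protruding into the air above the tissue, and the electrode
#' material's thermal properties (used in the bioheat conduction step;
#' electrodes are treated as perfect electric conductors).
#'
#' @param kind `"needle"` (cylinder) or `"plate"` (axis-aligned box).
#' @param center numeric length-3 center position (m).
#' @param polarity `"anode"` or `"cathode"`.
#' @param radius,length needle dimensions (m); `axis` is the cylinder axis
#'   direction (any nonzero 3-vector, normalized internally).
#' @param size plate box side lengths (m), length-3.
#' @param exposed_fraction fraction in `[0, 1]` of the electrode exposed to
#'   room air; gates and scales the convective cooling boundary condition on
#'   boundary faces over this electrode (0 = fully embedded, insulated).
#' @param material list with `kappa` (W/m/K), `rho` (kg/m^3), `cp` (J/kg/K)
#'   of the electrode metal.
#' @return An `ep_electrode` object.
#' @export
electrode <- function(kind = c("needle", "plate"), center, polarity = c("anode", "cathode"),
                      radius = NULL, length = NULL, axis = c(0, 0, 1),
                      size = NULL, exposed_fraction = 0,
                      material = list(kappa = 15, rho = 7900, cp = 500)) {
  kind <- match.arg(kind)
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(center), length(center) == 3L, all(is.finite(center)))
  if (!is.numeric(exposed_fraction) || exposed_fraction < 0 || exposed_fraction > 1) {
    stop("geometry error: exposed_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (kind == "needle") {
    if (is.null(radius) || is.null(length) || radius <= 0 || length <= 0) {
      stop("geometry error: needle electrodes need positive radius and length",
           call. = FALSE)
    }
    nrm <- sqrt(sum(axis^2))
    if (nrm == 0) stop("geometry error: needle axis must be nonzero", call. = FALSE)
    axis <- axis / nrm
  } else {
    if (is.null(size) || length(size) != 3L || any(size <= 0)) {
      stop("geometry error: plate electrodes need 3 positive side lengths",
           call. = FALSE)
    }
  }
  structure(list(kind = kind, center = as.numeric(center), polarity = polarity,
                 radius = radius, length = length, axis = axis, size = size,
                 exposed_fraction = exposed_fraction, material = material),
            class = "ep_electrode")
}

# Closed-solid membership of all grid nodes in one electrode (boundary inclusive).
electrode_mask <- function(grid, el, tol = 1e-12) {
  co <- coord_arrays(grid)
  dx <- co$x - el$center[1]
  dy <- co$y - el$center[2]
  dz <- co$z - el$center[3]
  if (el$kind == "plate") {
    (abs(dx) <= el$size[1] / 2 + tol) &
      (abs(dy) <= el$size[2] / 2 + tol) &
      (abs(dz) <= el$size[3] / 2 + tol)
  } else {
    ax <- el$axis
    proj <- dx * ax[1] + dy * ax[2] + dz * ax[3]
    r2 <- (dx - proj * ax[1])^2 + (dy - proj * ax[2])^2 + (dz - proj * ax[3])^2
    (abs(proj) <= el$length / 2 + tol) & (r2 <= (el$radius + tol)^2)
  }
}

#' Rasterize electrode solids onto the grid
#'
#' Labels every node `tissue` (0), `anode` (1) or `cathode` (2) by an exact
#' closed-solid membership test at the node coordinates (boundary inclusive;
#' no sub-voxel anti-aliasing). Deterministic by construction.
#'
#' @param grid an `ep_grid`.
#' @param electrodes list of [electrode()] objects (may be empty).
#' @return An `ep_labels` object: integer array `label` (dim = grid nodes),
#'   plus `electrodes` and per-electrode node index lists.
#' @export
rasterize_electrodes <- function(grid, electrodes) {
  lab <- array(0L, dim = grid$n)
  owner <- array(0L, dim = grid$n)
  if (length(electrodes) > 0) {
    pol <- vapply(electrodes, `[[`, "", "polarity")
    if (!any(pol == "anode") || !any(pol == "cathode")) {
      stop("geometry error: need at least one anode and one cathode", call. = FALSE)
    }
    for (e in seq_along(electrodes)) {
      m <- electrode_mask(grid, electrodes[[e]])
      if (!any(m)) {
        stop(sprintf("geometry error: electrode %d covers no grid node (outside domain?)", e),
             call. = FALSE)
      }
      clash <- m & owner > 0L
      if (any(clash)) {
        stop(sprintf("geometry error: electrodes %d and %d overlap at %d node(s)",
                     owner[which(clash)[1]], e, sum(clash)), call. = FALSE)
      }
      owner[m] <- e
      lab[m] <- if (pol[e] == "anode") 1L else 2L
    }
  }
  structure(list(label = lab, owner = owner, electrodes = electrodes,
                 grid = grid, faces = NULL), class = "ep_labels")
}

#' @export
print.ep_labels <- function(x, ...) {
  cat(sprintf("<ep_labels> %d tissue, %d anode, %d cathode nodes\n",
              sum(x$label == 0L), sum(x$label == 1L), sum(x$label == 2L)))
  if (!is.null(x$faces)) {
    cat(sprintf("  boundary faces: %d tissue-air, %d electrode-air\n",
                x$faces$n_tissue_air, x$faces$n_electrode_air))
  }
  invisible(x)
}

# The six domain boundary faces, each a matrix over the two in-face axes.
face_names <- c("x0", "x1", "y0", "y1", "z0", "z1")

# slice indices of the boundary node layer for a named face
face_slice <- function(n, face) {
  switch(face,
    x0 = list(i = 1L,    j = seq_len(n[2]), k = seq_len(n[3]), axes = c(2L, 3L)),
    x1 = list(i = n[1],  j = seq_len(n[2]), k = seq_len(n[3]), axes = c(2L, 3L)),
    y0 = list(i = seq_len(n[1]), j = 1L,    k = seq_len(n[3]), axes = c(1L, 3L)),
    y1 = list(i = seq_len(n[1]), j = n[2],  k = seq_len(n[3]), axes = c(1L, 3L)),
    z0 = list(i = seq_len(n[1]), j = seq_len(n[2]), k = 1L,    axes = c(1L, 2L)),
    z1 = list(i = seq_len(n[1]), j = seq_len(n[2]), k = n[3],  axes = c(1L, 2L))
  )
}

#' Classify domain boundary faces for the thermal boundary conditions
#'
#' Every face of the domain boundary is tagged `tissue-air` (zero heat flux)
#' or `electrode-air` (convective cooling toward room temperature). A
#' boundary face is `electrode-air` when the node behind it belongs to an
#' electrode with `exposed_fraction > 0`; the stored Robin weight equals that
#' fraction, so a fraction of 0 reduces exactly to the insulated case.
#'
#' @param grid an `ep_grid`.
#' @param labels an `ep_labels` from [rasterize_electrodes()].
#' @return The `ep_labels` with a filled `faces` component: per-face tag
#'   matrices, Robin weight matrices, and tag counts.
#' @export
classify_boundaries <- function(grid, labels) {
  stopifnot(inherits(labels, "ep_labels"))
  exf <- vapply(labels$electrodes, `[[`, 0, "exposed_fraction")
  tags <- list(); robin <- list()
  n_el <- 0L; n_ti <- 0L
  for (f in face_names) {
    sl <- face_slice(grid$n, f)
    own <- labels$owner[sl$i, sl$j, sl$k]
    w <- array(0, dim = dim(as.array(own)))
    if (length(exf)) {
      idx <- own > 0L
      w[idx] <- exf[own[idx]]
    }
    tg <- ifelse(w > 0, "electrode-air", "tissue-air")
    n_el <- n_el + sum(w > 0); n_ti <- n_ti + sum(w == 0)
    tags[[f]] <- tg; robin[[f]] <- w
  }
  labels$faces <- list(tag = tags, robin = robin,
                       n_electrode_air = n_el, n_tissue_air = n_ti)
  labels
}
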