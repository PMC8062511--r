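# Performance metrics of a deployed stent: mean stent diameter (MSD),
# circular cell diameter (CCD, vessel scaffolding), vessel prolapse,
# stent-to-artery ratio (SAR), normalized hoop force and radial strength.

# even-odd point-in-polygon test; pts n x 2, poly m x 2 (open loop)
.points_in_polygon <- function(pts, poly) {
  n <- nrow(pts)
  m <- nrow(poly)
  inside <- logical(n)
  j <- m
  xs <- poly[, 1]; ys <- poly[, 2]
  for (i in seq_len(m)) {
    cond <- ((ys[i] > pts[, 2]) != (ys[j] > pts[, 2]))
    xin <- (xs[j] - xs[i]) * (pts[, 2] - ys[i]) / (ys[j] - ys[i]) + xs[i]
    flip <- cond & (pts[, 1] < xin)
    inside <- xor(inside, flip)
    j <- i
  }
  inside
}

# minimum distance from each point to the polygon boundary
.dist_to_boundary <- function(pts, poly) {
  m <- nrow(poly)
  dmin <- rep(Inf, nrow(pts))
  j <- m
  for (i in seq_len(m)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    if (L2 < 1e-24) { j <- i; next }
    t <- pmin(pmax(((pts[, 1] - ax) * vx + (pts[, 2] - ay) * vy) / L2, 0), 1)
    dx <- pts[, 1] - (ax + t * vx); dy <- pts[, 2] - (ay + t * vy)
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
    j <- i
  }
  dmin
}

.polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Largest inscribed circle of a planar polygon
#'
#' Maximizes the distance to the polygon boundary over interior points:
#' a coarse interior grid seeds a shrinking pattern search (a local 5 x 5
#' candidate patch, halved whenever the center stays best) started from up
#' to five well-separated grid maxima, keeping the overall best. The
#' pattern search is derivative-free and robust to the flat plateaus of
#' the distance field (e.g. inside a rectangle, where one coordinate is
#' locally inactive); the multiple seeds cover the separate local maxima
#' a nonconvex polygon can have.
#'
#' @param poly An n x 2 matrix of polygon vertices (open loop).
#' @param n_grid Grid resolution per axis for the seeding stage.
#' @return A list with `center` (length-2) and `radius`; `radius = 0` for
#'   degenerate polygons with no interior grid point.
#' @export
inscribed_circle <- function(poly, n_grid = 24) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  gx <- seq(xr[1], xr[2], length.out = n_grid + 2)[-c(1, n_grid + 2)]
  gy <- seq(yr[1], yr[2], length.out = n_grid + 2)[-c(1, n_grid + 2)]
  pts <- as.matrix(expand.grid(x = gx, y = gy))
  inside <- .points_in_polygon(pts, poly)
  if (!any(inside)) return(list(center = c(NA, NA), radius = 0))
  pts <- pts[inside, , drop = FALSE]
  d <- .dist_to_boundary(pts, poly)
  scale <- max(diff(xr), diff(yr))
  spacing <- scale / (n_grid + 1)
  # the distance field of a nonconvex polygon has several local maxima:
  # refine from up to 3 well-separated seeds, advanced in lockstep so each
  # iteration costs one vectorized boundary-distance evaluation
  ord <- order(d, decreasing = TRUE)
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) >= 3) break
    if (length(sel) == 0 ||
        min((pts[sel, 1] - pts[i, 1])^2 + (pts[sel, 2] - pts[i, 2])^2) >
          (2.5 * spacing)^2) {
      sel <- c(sel, i)
    }
  }
  cur <- pts[sel, , drop = FALSE]
  cur_d <- d[sel]
  k <- length(sel)
  h <- rep(spacing, k)
  active <- rep(TRUE, k)
  h_min <- 1e-7 * scale
  off <- as.matrix(expand.grid(dx = -2:2, dy = -2:2)) / 2
  n_off <- nrow(off)
  while (any(active)) {
    ai <- which(active)
    cand <- cbind(rep(cur[ai, 1], each = n_off) +
                    rep(h[ai], each = n_off) * off[, 1],
                  rep(cur[ai, 2], each = n_off) +
                    rep(h[ai], each = n_off) * off[, 2])
    ok <- .points_in_polygon(cand, poly)
    dc <- rep(-Inf, nrow(cand))
    if (any(ok)) dc[ok] <- .dist_to_boundary(cand[ok, , drop = FALSE], poly)
    for (j in seq_along(ai)) {
      s <- ai[j]
      rows <- ((j - 1) * n_off + 1):(j * n_off)
      jb <- which.max(dc[rows])
      if (dc[rows][jb] > cur_d[s]) {
        cur[s, ] <- cand[rows[jb], ]
        cur_d[s] <- dc[rows][jb]
      } else {
        h[s] <- h[s] / 2
        if (h[s] <= h_min) active[s] <- FALSE
      }
    }
  }
  b <- which.max(cur_d)
  list(center = unname(cur[b, ]), radius = cur_d[b])
}

# unrolled planar cells of a deployed (or crimped) lattice: x = r_bar*theta,
# y = z, one matrix per cell, with metadata
.unrolled_cells <- function(lattice) {
  cells <- cell_polygons(lattice)
  lapply(cells, function(cl) {
    r_bar <- mean(cl$coords[, "r"])
    poly <- cbind(r_bar * cl$coords[, "theta"], cl$coords[, "z"])
    list(poly = poly, r_bar = r_bar,
         z_range = range(cl$coords[, "z"]),
         theta_mid = mean(cl$coords[, "theta"]) %% (2 * pi),
         area = .polygon_area(poly))
  })
}

# inscribed radii of all cells of a state, excluding (by default) cells
# overlying the side-branch ostium; degenerate cells are flagged
.state_cell_radii <- function(state, include_ostium = FALSE) {
  cells <- .unrolled_cells(state$lattice)
  keep <- rep(TRUE, length(cells))
  if (!include_ostium && !state$free && !is.null(state$ostium)) {
    for (k in seq_along(cells)) {
      zr <- cells[[k]]$z_range + state$position
      th <- cells[[k]]$theta_mid
      if (zr[2] > state$ostium$z_range[1] && zr[1] < state$ostium$z_range[2] &&
          abs(.wrap_dtheta(th - state$ostium$theta)) < state$ostium$half_arc) {
        keep[k] <- FALSE
      }
    }
  }
  cells <- cells[keep]
  rad <- vapply(cells, function(cl) inscribed_circle(cl$poly)$radius, 1)
  degenerate <- rad <= 1e-9 | vapply(cells, function(cl) cl$area, 1) <= 1e-12
  if (any(degenerate)) {
    warning(sprintf("%d degenerate cell(s) excluded", sum(degenerate)))
  }
  # the cell polygon runs through strut centerlines; the open cell between
  # strut edges is narrower by half the strut width on every side
  w <- state$lattice$design$strut_width
  list(radius = rad[!degenerate],
       open_radius = pmax(rad[!degenerate] - w / 2, 0),
       cells = cells[!degenerate],
       n_degenerate = sum(degenerate))
}

#' Mean inner stent diameter (MSD) of a deployed state
#'
#' @param state A `deployed_state`.
#' @return MSD in mm: the station mean of twice the inner stent radius.
#' @export
mean_stent_diameter <- function(state) {
  stopifnot(inherits(state, "deployed_state"))
  if (nrow(state$stations) == 0) stop("empty deployed state")
  mean(2 * state$stations$r_inner)
}

#' Circular cell diameter (CCD): vessel scaffolding of a deployed state
#'
#' Each deployed stent cell is unrolled onto the plane of its mean-radius
#' cylinder (cells are shallow relative to curvature at deployment
#' diameters) and the largest inscribed circle of the open cell is found:
#' the inscribed radius of the strut-centerline polygon minus half the
#' strut width (the distance from the circle to a strut edge is the
#' centerline distance minus half the width). CCD is the mean of the open
#' inscribed diameters over cells; smaller CCD means denser scaffolding.
#' Degenerate cells are excluded with a warning; cells over the
#' side-branch ostium are excluded by default.
#'
#' @param state A `deployed_state` (or a bare `stent_lattice`).
#' @param include_ostium Include cells overlying the ostium.
#' @param .cell_radii Precomputed `.state_cell_radii()` result (internal).
#' @return CCD in mm, with attribute `n_cells` and `n_degenerate`.
#' @export
circular_cell_diameter <- function(state, include_ostium = FALSE,
                                   .cell_radii = NULL) {
  if (inherits(state, "stent_lattice")) {
    state <- list(lattice = state, free = TRUE, ostium = NULL)
    class(state) <- "deployed_state"
  }
  stopifnot(inherits(state, "deployed_state"))
  cr <- if (is.null(.cell_radii)) {
    .state_cell_radii(state, include_ostium)
  } else .cell_radii
  if (length(cr$radius) == 0) stop("deployed lattice has no usable cells")
  out <- mean(2 * cr$open_radius)
  attr(out, "n_cells") <- length(cr$radius)
  attr(out, "n_degenerate") <- cr$n_degenerate
  out
}

#' Vessel prolapse of a deployed state
#'
#' The wall between struts sags into each open cell as an equilibrated
#' membrane: the sag of a membrane spanning a gap of half-width `a` under
#' transmural pressure `p` with tension `T` is `p a^2 / (2 T)`, and the
#' thin-wall equilibrium of the deployed wall gives `T = p r`, so the sag
#' depth is `sag_coefficient * a^2 / r` with the derived coefficient 1/2
#' (`a` the open-cell inscribed radius, `r` the cell's mean deployed
#' radius; see the methods vignette). Explicit per-cell sag depths may be
#' supplied instead. Per cross-section, prolapse follows the
#' centroid-distance definition: the mean radial distance to the strut
#' outer surfaces minus the radial distance to the deepest wall
#' protrusion. Sections where the wall is not pressed onto the stent
#' (malapposed: the undisturbed lumen lies outside the strut surface)
#' protrude nothing, because the wall between struts sits behind the
#' struts there; supplying explicit `sag_depths` bypasses this apposition
#' gate. The state value aggregates sections by their maximum (clinically
#' conservative default); the mean is attached as an attribute.
#'
#' @param state A `deployed_state`.
#' @param sag_coefficient Membrane sag coefficient; defaults to the solver
#'   config value (1/2 from the equilibrium derivation).
#' @param sag_depths Optional explicit per-cell sag depths in mm
#'   (overrides the membrane model).
#' @param aggregate `"max"` (default) or `"mean"` across cross-sections.
#' @param .cell_radii Precomputed `.state_cell_radii()` result (internal).
#' @return Prolapse in mm (non-negative), with attribute `per_station`.
#' @export
vessel_prolapse <- function(state, sag_coefficient = NULL, sag_depths = NULL,
                            aggregate = c("max", "mean"),
                            .cell_radii = NULL) {
  stopifnot(inherits(state, "deployed_state"))
  aggregate <- match.arg(aggregate)
  if (is.null(sag_coefficient)) {
    sag_coefficient <- if (!is.null(state$config)) {
      state$config$prolapse_sag_coefficient
    } else 0.5
  }
  cr <- if (is.null(.cell_radii)) {
    .state_cell_radii(state, include_ostium = FALSE)
  } else .cell_radii
  explicit_sag <- !is.null(sag_depths)
  if (!explicit_sag) {
    r_cell <- vapply(cr$cells, function(cl) cl$r_bar, 1)
    sag_depths <- sag_coefficient * cr$open_radius^2 / r_cell
  } else {
    stopifnot(length(sag_depths) == length(cr$radius))
  }
  st <- state$stations
  per_station <- numeric(nrow(st))
  lat <- state$lattice
  z_lo <- vapply(seq_len(nrow(st)), function(i) {
    min(lat$z[lat$ring == st$ring[i]])
  }, 1)
  z_hi <- vapply(seq_len(nrow(st)), function(i) {
    max(lat$z[lat$ring == st$ring[i]])
  }, 1)
  apposed <- if (explicit_sag) {
    rep(TRUE, nrow(st))
  } else if (!is.null(state$free) && state$free) {
    rep(FALSE, nrow(st))
  } else if (is.null(st$r_lumen0) || all(!is.finite(st$r_lumen0))) {
    rep(TRUE, nrow(st))
  } else {
    st$r_lumen0 <= st$r_outer + 1e-9
  }
  for (i in seq_len(nrow(st))) {
    r_out <- st$r_outer[i]
    if (!apposed[i]) { per_station[i] <- 0; next }
    hit <- vapply(cr$cells, function(cl) {
      cl$z_range[2] > z_lo[i] && cl$z_range[1] < z_hi[i]
    }, TRUE)
    if (!any(hit)) { per_station[i] <- 0; next }
    # radial distance from the lumen centroid to the deepest protrusion,
    # and the mean distance to the strut outer surfaces
    protrusion_radius <- r_out - max(sag_depths[hit])
    per_station[i] <- r_out - protrusion_radius
  }
  out <- if (aggregate == "max") max(per_station) else mean(per_station)
  attr(out, "per_station") <- per_station
  attr(out, "mean") <- mean(per_station)
  out
}

#' Stent-to-artery ratio (SAR) of a deployed state
#'
#' 100 times the strut outer surface area divided by the lumen surface
#' area between the stent end planes (the deployed lumen follows the
#' strut outer surface where the stent is apposed).
#'
#' @param state A `deployed_state`.
#' @return SAR in percent.
#' @export
stent_artery_ratio <- function(state) {
  stopifnot(inherits(state, "deployed_state"))
  strut_area <- strut_outer_surface_area(state$lattice, state$design)
  st <- state$stations
  pitch <- st$h_ring + state$design$link_gap
  pitch[length(pitch)] <- st$h_ring[length(pitch)]
  r_lum <- if (state$free) st$r_outer else pmax(st$r_lumen0, st$r_outer)
  lumen_area <- sum(2 * pi * r_lum * pitch)
  if (lumen_area <= 0) stop("zero lumen surface area")
  100 * strut_area / lumen_area
}

#' Normalized hoop force of a crimp test
#'
#' Hoop force is radial force / 2*pi; the normalized hoop force is the
#' maximum hoop force over the crimp curve divided by the nominal stent
#' length (N/mm).
#'
#' @param crimp A `crimp_result` from [radial_crimp()].
#' @param nominal_length Nominal stent length in mm.
#' @return Normalized hoop force in N/mm.
#' @export
normalized_hoop_force <- function(crimp, nominal_length) {
  stopifnot(inherits(crimp, "crimp_result"))
  if (nrow(crimp$curve) == 0) stop("empty crimp curve")
  if (nominal_length <= 0) stop("nominal length must be positive")
  max(crimp$curve$radial_force_N) / (2 * pi) / nominal_length
}

#' Radial strength of a deployed state
#'
#' Total outward radial contact force on the lumen wall divided by the
#' total stent (outer strut surface) area, in N/mm^2.
#'
#' @param state A `deployed_state` with contact forces.
#' @return Radial strength in N/mm^2 (0 for free expansion).
#' @export
radial_strength <- function(state) {
  stopifnot(inherits(state, "deployed_state"))
  area <- strut_outer_surface_area(state$lattice, state$design)
  if (area <= 0) stop("zero stent area")
  sum(state$stations$f_contact) / area
}

#' Full metrics report for one deployed state
#'
#' @param state A `deployed_state`.
#' @param crimp Optional `crimp_result` for the normalized hoop force.
#' @param metadata Optional named list appended as columns (design,
#'   diameter, plaque mode, seed, ...).
#' @return A one-row tibble (the `MetricsReport` row of a factorial cell).
#' @export
metrics_report <- function(state, crimp = NULL, metadata = list()) {
  cr <- .state_cell_radii(state, include_ostium = FALSE)
  ccd <- circular_cell_diameter(state, .cell_radii = cr)
  prol <- vessel_prolapse(state, .cell_radii = cr)
  n_cells <- attr(ccd, "n_cells")
  n_degenerate <- attr(ccd, "n_degenerate")
  row <- tibble::tibble(
    msd = mean_stent_diameter(state),
    ccd = as.numeric(ccd),
    prolapse = as.numeric(prol),
    prolapse_mean = attr(prol, "mean"),
    sar = stent_artery_ratio(state),
    hoop_force = if (is.null(crimp)) NA_real_ else {
      normalized_hoop_force(crimp, state$nominal_length)
    },
    radial_strength = radial_strength(state),
    n_cells = n_cells,
    n_degenerate_cells = n_degenerate,
    max_residual = max(state$stations$residual)
  )
  for (nm in names(metadata)) row[[nm]] <- metadata[[nm]]
  row
}
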