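# Seeded generator of left-main-bifurcation-like vessel geometries: a
# tapered main-branch lumen with a mid-segment eccentric stenosis, a
# side-branch ostium (absent wall over an arc), a normal-wall layer
# 0.1-0.25 mm thick, and plaque described either as one homogeneous
# stiffness category or as contiguous heterogeneous zones grouped from
# OCT-style morphometrics. This is the synthetic stand-in for the
# angiography + OCT reconstructions the study design assumes; it emulates
# their lumen scale, wall layering and plaque zoning, not their
# patient-specific shapes.

#' Generate a synthetic bifurcation vessel geometry
#'
#' Axial stations are spaced 0.2 mm (OCT-frame-like spacing). The lumen is
#' a linear taper from the proximal to the distal diameter with a Gaussian
#' mid-segment stenosis whose minimal lumen area is `(1 - severity)` times
#' the local reference area (exactly, by construction), and whose
#' eccentricity scales with the local stenosis depth. Per-seed jitter of
#' diameters, severity, stenosis position and wall thickness emulates the
#' between-patient variability of a small imaging cohort.
#'
#' @param proximal_diameter Proximal (left-main-like) lumen diameter, mm.
#'   The proximal reference mean diameter never exceeds 5.0 mm.
#' @param distal_diameter Distal main-branch lumen diameter, mm.
#' @param side_branch_diameter Side-branch diameter, mm (sets the ostium).
#' @param length Vessel length, mm.
#' @param spacing Station spacing, mm.
#' @param bifurcation_z Axial position of the side-branch ostium, mm.
#' @param stenosis_center Axial position of the stenosis, mm.
#' @param stenosis_sd Gaussian axial spread of the stenosis, mm.
#' @param severity Area stenosis severity in `[0, 0.9]`.
#' @param eccentricity Plaque eccentricity scale in `[0, 1]`.
#' @param wall_thickness_range Normal-wall thickness range, mm; must lie
#'   inside `[0.1, 0.25]`.
#' @param n_theta Number of circumferential sample arcs.
#' @param seed Integer seed; geometry is bitwise deterministic per seed.
#' @param jitter If `TRUE`, apply seeded patient-like parameter jitter.
#' @return An object of class `vessel_geometry`.
#' @export
generate_bifurcation <- function(proximal_diameter = 4.5,
                                 distal_diameter = 3.6,
                                 side_branch_diameter = 2.8,
                                 length = 30, spacing = 0.2,
                                 bifurcation_z = 10,
                                 stenosis_center = 18, stenosis_sd = 3,
                                 severity = 0.55, eccentricity = 0.5,
                                 wall_thickness_range = c(0.12, 0.22),
                                 n_theta = 24, seed = 1, jitter = TRUE) {
  stopifnot(proximal_diameter >= distal_diameter,
            severity >= 0, severity <= 0.9,
            eccentricity >= 0, eccentricity <= 1)
  if (wall_thickness_range[1] < 0.1 || wall_thickness_range[2] > 0.25) {
    stop("normal wall thickness range must lie within [0.1, 0.25] mm")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })

  if (jitter) {
    proximal_diameter <- min(proximal_diameter * stats::runif(1, 0.95, 1.05), 5.0)
    distal_diameter <- min(distal_diameter * stats::runif(1, 0.95, 1.05),
                           proximal_diameter)
    severity <- min(max(severity + stats::runif(1, -0.08, 0.08), 0), 0.9)
    stenosis_center <- stenosis_center + stats::runif(1, -1.5, 1.5)
    theta0 <- stats::runif(1, 0, 2 * pi)
    wall_phase <- stats::runif(1, 0, 2 * pi)
  } else {
    theta0 <- 0
    wall_phase <- 0
  }

  z <- seq(0, length, by = spacing)
  n_z <- length(z)
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta

  R_taper <- (proximal_diameter + (distal_diameter - proximal_diameter) *
                z / length) / 2
  g <- exp(-(z - stenosis_center)^2 / (2 * stenosis_sd^2))
  delta <- eccentricity * severity * g
  f_area <- 1 - severity * g

  cosm <- cos(outer(rep(1, n_z), theta) - theta0)
  lumen_r <- (R_taper * sqrt(f_area)) *
    (1 + delta * cosm) / sqrt(1 + delta^2 / 2)

  diseased <- g > 0.1
  plaque_t <- pmax(R_taper - lumen_r, 0) + 0.05 * g
  plaque_t[!diseased, ] <- 0

  t_mid <- mean(wall_thickness_range)
  t_amp <- diff(wall_thickness_range) / 2 * 0.8
  normal_t_z <- t_mid + t_amp * sin(2 * pi * z / length + wall_phase)
  normal_t <- matrix(rep(normal_t_z, n_theta), nrow = n_z)
  if (any(normal_t < 0.1 - 1e-12)) {
    stop("generated normal wall thinner than the 0.1 mm floor")
  }

  # side-branch ostium: wall absent over an arc around theta = pi
  wall_present <- matrix(TRUE, n_z, n_theta)
  rs <- side_branch_diameter / 2
  for (iz in seq_len(n_z)) {
    dz <- z[iz] - bifurcation_z
    if (abs(dz) < rs) {
      half_chord <- sqrt(rs^2 - dz^2)
      half_arc <- asin(pmin(1, half_chord / mean(lumen_r[iz, ])))
      d_ang <- abs(.wrap_dtheta(theta - pi))
      wall_present[iz, d_ang <= half_arc] <- FALSE
    }
  }

  prox_idx <- which(z <= 5)
  proximal_ref <- 2 * mean(lumen_r[prox_idx, ])

  v <- list(
    z = z, theta = theta, spacing = spacing,
    R_taper = R_taper, lumen_r = lumen_r,
    plaque_t = plaque_t, normal_t = normal_t,
    wall_present = wall_present, diseased = diseased,
    zone_id = matrix(0L, n_z, n_theta), zones = NULL,
    plaque_mode = "none",
    stenosis_center = stenosis_center, severity = severity,
    bifurcation_z = bifurcation_z,
    proximal_ref_diameter = proximal_ref,
    side_branch_diameter = side_branch_diameter,
    seed = seed
  )
  class(v) <- "vessel_geometry"
  v
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf(
    "<vessel_geometry> %.0f mm, %d stations, proximal ref %.2f mm, severity %.2f, plaque mode '%s'\n",
    max(x$z), length(x$z), x$proximal_ref_diameter, x$severity, x$plaque_mode))
  invisible(x)
}

#' Assign one homogeneous plaque stiffness category to the diseased extent
#'
#' All diseased stations receive a single plaque zone with the given
#' category; the normal-wall layer keeps the `normal_wall` material.
#'
#' @param vessel A [generate_bifurcation()] result.
#' @param category A plaque category label (see [plaque_categories()]).
#' @return The vessel with its zone map and zone table filled in.
#' @export
assign_homogeneous_plaque <- function(vessel, category) {
  stopifnot(inherits(vessel, "vessel_geometry"))
  category <- match.arg(category, plaque_categories())
  zid <- matrix(0L, length(vessel$z), length(vessel$theta))
  zid[vessel$plaque_t > 0] <- 1L
  dis <- which(vessel$diseased)
  vessel$zone_id <- zid
  vessel$zones <- tibble::tibble(
    zone = 1L, category = category,
    z_start = vessel$z[min(dis)], z_end = vessel$z[max(dis)],
    plaque_thickness = max(vessel$plaque_t),
    eccentricity = NA_real_, lipid_arc = NA_real_, calcium_arc = NA_real_,
    fibrosis_arc = NA_real_, cap_thickness = NA_real_, necrotic_core = NA
  )
  vessel$plaque_mode <- category
  vessel
}

# weighted morphometric distance used for zoning (thickness in mm,
# arcs in degrees)
.morph_distance <- function(a, b) {
  abs(a$plaque_thickness - b$plaque_thickness) / 0.5 +
    abs(a$lipid_arc - b$lipid_arc) / 180 +
    abs(a$calcium_arc - b$calcium_arc) / 180
}

# dominance rule: softest of the three tissue classes wins on the largest
# arc, with a thickness-based up/down shift
.zone_category <- function(lipid_arc, fibrosis_arc, calcium_arc,
                           plaque_thickness) {
  cats <- plaque_categories()
  dom <- which.max(c(lipid_arc, fibrosis_arc, calcium_arc))
  idx <- c(2L, 3L, 4L)[dom]           # soft / neutral / stiff
  if (plaque_thickness > 0.7) idx <- idx + 1L
  if (plaque_thickness < 0.25) idx <- idx - 1L
  cats[max(1L, min(5L, idx))]
}

#' Assign heterogeneous (patient-like) plaque stiffness zones
#'
#' OCT-style morphometrics (plaque thickness, eccentricity, lipid, calcium
#' and fibrosis arcs, cap thickness, necrotic core) are sampled on a coarse
#' axial grid (every 10th station, emulating every-10th-frame reading),
#' interpolated to all diseased stations, grouped into contiguous zones by
#' a weighted morphometric distance threshold, and each zone mapped to a
#' stiffness category by an arc-dominance rule (lipid-dominant zones to the
#' soft side, calcium-dominant to the stiff side, shifted by plaque
#' thickness). Deterministic per seed.
#'
#' @param vessel A [generate_bifurcation()] result.
#' @param seed Integer seed for the morphometric sampling.
#' @param similarity_threshold Zoning distance threshold (dimensionless).
#' @param coarse_every Coarse sampling stride in stations (default 10).
#' @return The vessel with zone map, zone table and morphometrics filled in.
#' @export
assign_heterogeneous_plaque <- function(vessel, seed = vessel$seed,
                                        similarity_threshold = 0.35,
                                        coarse_every = 10L) {
  stopifnot(inherits(vessel, "vessel_geometry"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed + 10000L)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })

  dis <- which(vessel$diseased)
  if (length(dis) == 0) stop("vessel has no diseased stations")
  coarse <- dis[seq(1, length(dis), by = coarse_every)]
  if (coarse[length(coarse)] != dis[length(dis)]) {
    coarse <- c(coarse, dis[length(dis)])
  }
  g <- exp(-(vessel$z - vessel$stenosis_center)^2 / 18)
  samp <- tibble::tibble(
    station = coarse,
    plaque_thickness = apply(vessel$plaque_t[coarse, , drop = FALSE], 1, max),
    eccentricity = apply(vessel$lumen_r[coarse, , drop = FALSE], 1,
                         function(r) (max(r) - min(r)) / (max(r) + min(r))),
    lipid_arc = g[coarse] * stats::runif(length(coarse), 60, 240),
    calcium_arc = g[coarse] * stats::runif(length(coarse), 0, 70),
    fibrosis_arc = g[coarse] * stats::runif(length(coarse), 20, 130),
    cap_thickness = stats::runif(length(coarse), 0.05, 0.2),
    necrotic_core = stats::runif(length(coarse)) < 0.4 * g[coarse]
  )
  # interpolate morphometrics to every diseased station
  interp <- function(y) stats::approx(coarse, y, xout = dis, rule = 2)$y
  fine <- tibble::tibble(
    station = dis,
    plaque_thickness = interp(samp$plaque_thickness),
    eccentricity = interp(samp$eccentricity),
    lipid_arc = interp(samp$lipid_arc),
    calcium_arc = interp(samp$calcium_arc),
    fibrosis_arc = interp(samp$fibrosis_arc),
    cap_thickness = interp(samp$cap_thickness),
    necrotic_core = interp(as.numeric(samp$necrotic_core)) > 0.5
  )

  # contiguous zoning by similarity to the running zone mean
  zone_of <- integer(length(dis))
  zone_of[1] <- 1L
  ref <- fine[1, ]
  n_in_zone <- 1
  for (k in 2:length(dis)) {
    cur <- fine[k, ]
    if (.morph_distance(cur, ref) > similarity_threshold) {
      zone_of[k] <- zone_of[k - 1] + 1L
      ref <- cur; n_in_zone <- 1
    } else {
      zone_of[k] <- zone_of[k - 1]
      n_in_zone <- n_in_zone + 1
      for (fld in c("plaque_thickness", "eccentricity", "lipid_arc",
                    "calcium_arc", "fibrosis_arc", "cap_thickness")) {
        ref[[fld]] <- ref[[fld]] + (cur[[fld]] - ref[[fld]]) / n_in_zone
      }
    }
  }

  zones <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(fine, zone = zone_of), .data$zone),
    z_start = vessel$z[min(.data$station)],
    z_end = vessel$z[max(.data$station)],
    plaque_thickness = mean(.data$plaque_thickness),
    eccentricity = mean(.data$eccentricity),
    lipid_arc = mean(.data$lipid_arc),
    calcium_arc = mean(.data$calcium_arc),
    fibrosis_arc = mean(.data$fibrosis_arc),
    cap_thickness = mean(.data$cap_thickness),
    necrotic_core = any(.data$necrotic_core),
    .groups = "drop"
  )
  zones$category <- mapply(.zone_category, zones$lipid_arc,
                           zones$fibrosis_arc, zones$calcium_arc,
                           zones$plaque_thickness)

  zid <- matrix(0L, length(vessel$z), length(vessel$theta))
  for (k in seq_along(dis)) {
    row <- dis[k]
    zid[row, vessel$plaque_t[row, ] > 0] <- zone_of[k]
  }
  vessel$zone_id <- zid
  vessel$zones <- zones
  vessel$plaque_mode <- "heterogeneous"
  vessel
}

#' Per-station pressure-displacement response of the vessel wall
#'
#' The wall at each station is treated as a laminated thin-walled cylinder:
#' the normal layer and the plaque layer share the hoop strain
#' \eqn{\varepsilon = u / \bar r}, and the resisting pressure is the
#' theta-average of \eqn{\sum_l \sigma_l(\varepsilon) t_l / \bar r} over
#' arcs where wall is present (the ostium contributes nothing). In the
#' thin linear-elastic limit this reduces to the closed form
#' \eqn{p = E t u / r^2}.
#'
#' @param vessel A vessel with plaque assigned (or none: wall only).
#' @param station Station index (1-based).
#' @param displacement Outward radial displacement u in mm (vectorized,
#'   non-negative).
#' @param materials Optional named list of materials overriding the default
#'   catalog (`normal_wall` plus plaque categories).
#' @return Resisting pressure in MPa, monotone non-decreasing in `u`.
#' @export
radial_response <- function(vessel, station, displacement, materials = NULL) {
  stopifnot(inherits(vessel, "vessel_geometry"))
  if (station < 1 || station > length(vessel$z)) {
    stop("station outside the vessel")
  }
  u <- as.numeric(displacement)
  if (any(u < 0)) stop("displacement must be non-negative (outward)")
  if (is.null(materials)) materials <- .default_wall_materials()
  agg <- .station_wall_aggregate(vessel, station)
  eps <- u / agg$r_bar
  p <- uniaxial_stress(materials$normal_wall, 1 + eps) * agg$t_normal / agg$r_bar
  for (cat in names(agg$t_plaque)) {
    tp <- agg$t_plaque[[cat]]
    if (tp > 0) {
      p <- p + plaque_stress(materials[[cat]], eps) * tp / agg$r_bar
    }
  }
  p
}

.default_wall_materials <- function() {
  mats <- lapply(plaque_categories(), material_catalog)
  names(mats) <- plaque_categories()
  mats$normal_wall <- material_catalog("normal_wall")
  mats
}

# theta-averaged layer composition at one station: mean lumen radius,
# present-arc normal thickness, and mean plaque thickness per category
.station_wall_aggregate <- function(vessel, station) {
  pres <- vessel$wall_present[station, ]
  n_th <- length(vessel$theta)
  r_bar <- mean(vessel$lumen_r[station, ])
  t_normal <- sum(vessel$normal_t[station, ] * pres) / n_th
  zid <- vessel$zone_id[station, ]
  t_plaque <- stats::setNames(as.list(rep(0, 5)), plaque_categories())
  if (any(zid > 0) && !is.null(vessel$zones)) {
    for (zk in unique(zid[zid > 0])) {
      cat <- vessel$zones$category[match(zk, vessel$zones$zone)]
      sel <- (zid == zk) & pres
      t_plaque[[cat]] <- t_plaque[[cat]] +
        sum(vessel$plaque_t[station, ] * sel) / n_th
    }
  }
  list(r_bar = r_bar, t_normal = t_normal, t_plaque = t_plaque)
}

#' Export the plaque zone map as CSV
#'
#' One row per (zone, station) arc with the zone morphometrics.
#'
#' @param vessel A vessel with plaque assigned.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_zone_map_csv <- function(vessel, path) {
  if (is.null(vessel$zones)) stop("vessel has no plaque zones assigned")
  readr::write_csv(vessel$zones, path)
  invisible(path)
}

#' Export the lumen surface as a legacy-VTK structured grid (ASCII)
#' @param vessel A [generate_bifurcation()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vessel_vtk <- function(vessel, path) {
  n_z <- length(vessel$z); n_t <- length(vessel$theta)
  pts <- matrix(0, n_z * n_t, 3)
  k <- 1
  for (iz in seq_len(n_z)) {
    for (it in seq_len(n_t)) {
      r <- vessel$lumen_r[iz, it]
      pts[k, ] <- c(r * cos(vessel$theta[it]), r * sin(vessel$theta[it]),
                    vessel$z[iz])
      k <- k + 1
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vessel lumen", "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", n_t, n_z),
               sprintf("POINTS %d float", nrow(pts))), con)
  utils::write.table(format(pts, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
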