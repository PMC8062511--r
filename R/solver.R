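# Reduced-order quasi-static deployment mechanics.
#
# The full 3-D explicit-dynamics contact problem is replaced by an
# axisymmetric per-station model: each zigzag ring is a chain of 2*peaks
# inextensible strut legs joined by elastoplastic hinges at the crowns.
# Opening a ring from radius r0 to r rotates every hinge by
# theta(r) = 2*(alpha(r) - alpha0) with sin(alpha) = chord(r)/L, and the
# outward radial force follows from the work balance
# F(r) = n_hinges * M(theta) * dtheta/dr. Balloon pressure, stent hinge
# resistance and the vessel's layered-wall response are balanced per
# station by monotone bisection at each pressure increment; hinge
# plasticity is committed by a 1-D return map after each increment.
# This model reproduces definitions and orderings, not the absolute
# newton/millimetre output of a full contact FEA.

.ATM_MPA <- 0.101325

#' Solver configuration
#'
#' @param pressure_atm Peak balloon inflation pressure in atmospheres
#'   (default 18).
#' @param target_diameter Balloon nominal (sizing) inner diameter in mm.
#' @param n_steps Pressure increments for each of inflation and deflation.
#' @param tol Equilibrium force tolerance in N.
#' @param friction Friction coefficient recorded for provenance; the
#'   reduced model has no axial contact sliding, so it is unused.
#' @param max_iter Maximum bisection iterations per increment.
#' @param balloon [balloon_material()] of the delivery balloon.
#' @param alloy [alloy_material()] of the stent.
#' @param balloon_nominal_pressure_atm Pressure at which the balloon
#'   reaches its nominal diameter.
#' @param rigid_vessel If `TRUE`, treat the vessel lumen as a rigid bound.
#' @param prolapse_sag_coefficient Coefficient of the membrane sag model
#'   for tissue prolapse into an open cell, `sag = c * a^2 / r` (1/2 from
#'   balancing transmural pressure against thin-wall hoop tension; see
#'   [vessel_prolapse()] and the methods vignette).
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(pressure_atm = 18, target_diameter = 4.5,
                          n_steps = 25, tol = 1e-6, friction = 0.2,
                          max_iter = 60,
                          balloon = material_catalog("balloon"),
                          alloy = material_catalog("pt_cr"),
                          balloon_nominal_pressure_atm = 10,
                          rigid_vessel = FALSE,
                          prolapse_sag_coefficient = 0.5) {
  stopifnot(pressure_atm > 0, tol > 0, n_steps >= 2)
  structure(list(pressure_atm = pressure_atm,
                 target_diameter = target_diameter,
                 n_steps = as.integer(n_steps), tol = tol,
                 friction = friction, max_iter = max_iter,
                 balloon = balloon, alloy = alloy,
                 balloon_nominal_pressure_atm = balloon_nominal_pressure_atm,
                 rigid_vessel = rigid_vessel,
                 prolapse_sag_coefficient = prolapse_sag_coefficient),
            class = "solver_config")
}

# ring geometry scalars for a design
.ring_geom <- function(design) {
  r0 <- (design$crimped_id + design$strut_thickness) / 2
  sinp <- sin(pi / (2 * design$peaks))
  h0 <- design$crown_height
  L <- sqrt(h0^2 + (2 * r0 * sinp)^2)
  list(p = design$peaks, n_h = 2L * design$peaks, L = L, sinp = sinp,
       r0 = r0, alpha0 = asin(2 * r0 * sinp / L),
       r_max = L / (2 * sinp))
}

# elastic/plastic hinge properties from the strut section and alloy
.hinge_props <- function(design, alloy) {
  t <- design$strut_thickness; w <- design$strut_width
  I <- t * w^3 / 12                       # in-surface bending
  list(k_m = alloy$elastic_modulus * I / .ring_geom(design)$L,
       M_y = alloy$yield_stress * t * w^2 / 6,
       H_m = hardening_modulus(alloy) * I / .ring_geom(design)$L)
}

.ring_alpha <- function(r, geom) {
  asin(pmin(2 * r * geom$sinp / geom$L, 1 - 1e-12))
}
.ring_theta <- function(r, geom) 2 * (.ring_alpha(r, geom) - geom$alpha0)
.ring_dtheta_dr <- function(r, geom) {
  4 * geom$sinp / (geom$L * cos(.ring_alpha(r, geom)))
}
.ring_height <- function(r, geom) geom$L * cos(.ring_alpha(r, geom))

# trial hinge moment for rotation theta given committed plastic state
# (theta_p, kappa); vectorized over rings
.hinge_moment <- function(theta, theta_p, kappa, props) {
  M_tr <- props$k_m * (theta - theta_p)
  M_yc <- props$M_y + props$H_m * kappa
  over <- abs(M_tr) - M_yc
  plastic <- over > 0
  dg <- ifelse(plastic, over / (props$k_m + props$H_m), 0)
  M <- ifelse(plastic, sign(M_tr) * (M_yc + props$H_m * dg), M_tr)
  list(M = M, dg = dg, sgn = sign(M_tr))
}

# commit the plastic update at rotation theta
.hinge_commit <- function(theta, theta_p, kappa, props) {
  hm <- .hinge_moment(theta, theta_p, kappa, props)
  list(theta_p = theta_p + hm$sgn * hm$dg, kappa = kappa + hm$dg)
}

# outward radial ring force (N) at radius r; positive resists expansion
.ring_force <- function(r, theta_p, kappa, geom, props) {
  th <- .ring_theta(r, geom)
  hm <- .hinge_moment(th, theta_p, kappa, props)
  geom$n_h * hm$M * .ring_dtheta_dr(r, geom)
}

#' Elastoplastic force path of one stent ring along a radius history
#'
#' Drives a single ring through the given sequence of centerline radii,
#' committing hinge plasticity at each step, and records rotation, moment,
#' radial force and equivalent external pressure. This is the mechanical
#' kernel shared by [stent_hoop_resistance()], [expand_stent()] and
#' [radial_crimp()], exposed for verification (work-balance and
#' reversibility checks).
#'
#' @param design A [stent_design()].
#' @param radii Sequence of centerline radii in mm.
#' @param alloy An [alloy_material()].
#' @return A tibble with columns `r`, `theta_h`, `moment`, `force_N`,
#'   `pressure_MPa`; the final hinge state is attached as attribute
#'   `hinge_state`.
#' @export
hoop_resistance_path <- function(design, radii,
                                 alloy = material_catalog("pt_cr")) {
  geom <- .ring_geom(design)
  props <- .hinge_props(design, alloy)
  if (any(radii >= geom$r_max)) {
    stop(sprintf("radius beyond the kinematic limit %.3f mm", geom$r_max))
  }
  theta_p <- 0; kappa <- 0
  n <- length(radii)
  th <- mom <- fr <- pr <- numeric(n)
  for (i in seq_len(n)) {
    r <- radii[i]
    th[i] <- .ring_theta(r, geom)
    hm <- .hinge_moment(th[i], theta_p, kappa, props)
    mom[i] <- hm$M
    fr[i] <- geom$n_h * hm$M * .ring_dtheta_dr(r, geom)
    pr[i] <- fr[i] / (2 * pi * r * .ring_height(r, geom))
    st <- .hinge_commit(th[i], theta_p, kappa, props)
    theta_p <- st$theta_p; kappa <- st$kappa
  }
  out <- tibble::tibble(r = radii, theta_h = th, moment = mom,
                        force_N = fr, pressure_MPa = pr)
  attr(out, "hinge_state") <- list(theta_p = theta_p, kappa = kappa)
  out
}

#' Equivalent external pressure holding a stent at a given diameter
#'
#' Loads the ring model monotonically from the crimped state to the target
#' inner diameter (hinges yielding along the way) and returns the
#' equivalent internal pressure that holds that diameter: zero at the
#' crimped reference, elastic at small openings, plastic beyond hinge
#' yield, continuous in diameter.
#'
#' @param lattice A [build_lattice()] result.
#' @param design The [stent_design()]; defaults to the lattice's own.
#' @param alloy An [alloy_material()].
#' @param inner_diameter Target inner diameter in mm.
#' @param n_steps Loading path increments.
#' @return Equivalent pressure in MPa.
#' @export
stent_hoop_resistance <- function(lattice, design = lattice$design,
                                  alloy = material_catalog("pt_cr"),
                                  inner_diameter, n_steps = 200) {
  geom <- .ring_geom(design)
  r_target <- inner_diameter / 2 + design$strut_thickness / 2
  if (inner_diameter < design$crimped_id - 1e-9 ||
      r_target >= geom$r_max) {
    stop(sprintf("inner diameter %.3f mm outside [%.3f, %.3f) mm",
                 inner_diameter, design$crimped_id,
                 max_expansion_diameter(design)))
  }
  if (r_target <= geom$r0 + 1e-12) return(0)
  path <- hoop_resistance_path(design,
                               seq(geom$r0, r_target, length.out = n_steps),
                               alloy)
  path$pressure_MPa[n_steps]
}

# balloon-limited centerline radius at pressure p (MPa): the balloon
# unfolds toward its nominal diameter and then grows semi-compliantly per
# its 900 MPa membrane
.balloon_radius <- function(p_mpa, config, design) {
  p_nom <- config$balloon_nominal_pressure_atm * .ATM_MPA
  r_nom <- config$target_diameter / 2 + design$strut_thickness / 2
  bal <- config$balloon
  if (p_mpa <= p_nom) {
    r_nom * p_mpa / p_nom
  } else {
    r_nom * (1 + (p_mpa - p_nom) * r_nom /
               (bal$elastic_modulus * bal$thickness))
  }
}

# per-ring wall composition (thin laminated cylinder) for the stations the
# stent occupies; NULL for free expansion
.vessel_rings <- function(vessel, design, position, materials) {
  g <- design$link_gap; h0 <- design$crown_height
  z_centers <- position + (seq_len(design$rings) - 1) * (h0 + g) + h0 / 2
  if (max(z_centers) + h0 / 2 > max(vessel$z) + 1e-9 || position < -1e-9) {
    stop("stent does not fit inside the vessel at this position")
  }
  idx <- vapply(z_centers, function(zc) which.min(abs(vessel$z - zc)), 1L)
  agg <- lapply(idx, function(i) .station_wall_aggregate(vessel, i))
  rs <- vessel$side_branch_diameter / 2
  i_bif <- which.min(abs(vessel$z - vessel$bifurcation_z))
  list(
    station = idx, z_center = z_centers,
    r_lumen = vapply(agg, function(a) a$r_bar, 1),
    t_normal = vapply(agg, function(a) a$t_normal, 1),
    t_plaque = do.call(rbind, lapply(agg, function(a) unlist(a$t_plaque))),
    materials = materials,
    position = position,
    ostium = list(
      z_range = vessel$bifurcation_z + c(-rs, rs),
      theta = pi,
      half_arc = asin(min(1, rs / mean(vessel$lumen_r[i_bif, ])))
    )
  )
}

# vessel reaction pressure per ring at outer radii r_out (vectorized)
.vessel_pressure <- function(r_out, vr) {
  if (is.null(vr)) return(rep(0, length(r_out)))
  u <- pmax(r_out - vr$r_lumen, 0)
  eps <- u / vr$r_lumen
  p <- uniaxial_stress(vr$materials$normal_wall, 1 + eps) *
    vr$t_normal / vr$r_lumen
  for (cat in plaque_categories()) {
    tp <- vr$t_plaque[, cat]
    if (any(tp > 0)) {
      p <- p + plaque_stress(vr$materials[[cat]], eps) * tp / vr$r_lumen
    }
  }
  p[u <= 0] <- 0
  p
}

# rebuild the lattice with per-ring centerline radii (axial positions
# re-accumulated from per-ring foreshortened crown heights)
.apply_ring_radii <- function(lattice, r_rings) {
  d <- lattice$design
  geom <- .ring_geom(d)
  h_new <- sqrt(pmax(lattice$leg_length^2 -
                       (2 * r_rings * geom$sinp)^2, 0))
  h_old <- lattice$crown_height
  z <- lattice$z; r <- lattice$r
  z_base_new <- 0
  for (k in seq_len(d$rings)) {
    idx <- which(lattice$ring == k)
    z_base_old <- (k - 1) * (h_old + d$link_gap)
    z[idx] <- z_base_new + (lattice$z[idx] - z_base_old) *
      (h_new[k] / h_old)
    r[idx] <- r_rings[k]
    z_base_new <- z_base_new + h_new[k] + d$link_gap
  }
  out <- lattice
  out$z <- z; out$r <- r
  out$crown_height <- mean(h_new)
  out$ring_heights <- h_new
  out
}

# one pressure increment: vectorized monotone bisection for the ring radii
.solve_increment <- function(p_b, r_prev, theta_p, kappa, geom, props,
                             vr, cap, config) {
  t_half <- 0  # forces balanced at the strut centerline radius
  f_of <- function(r) {
    p_b - .ring_force(r, theta_p, kappa, geom, props) /
      (2 * pi * r * .ring_height(r, geom)) -
      .vessel_pressure(r + t_half, vr)
  }
  n <- length(r_prev)
  lo <- rep(max(geom$r0 - 0.3, 0.05), n)
  hi <- rep(min(cap, geom$r_max * (1 - 1e-9)), n)
  if (!is.null(vr) && config$rigid_vessel) hi <- pmin(hi, vr$r_lumen)
  hi <- pmax(hi, lo + 1e-9)
  cap_r <- hi
  f_hi <- f_of(hi)
  at_cap <- f_hi >= 0
  f_lo <- f_of(lo)
  stuck_lo <- f_lo <= 0
  for (it in seq_len(config$max_iter)) {
    mid <- (lo + hi) / 2
    pos <- f_of(mid) > 0
    lo <- ifelse(pos, mid, lo)
    hi <- ifelse(pos, hi, mid)
    if (max(hi - lo) < 1e-11) break
  }
  r <- (lo + hi) / 2
  r[at_cap] <- cap_r[at_cap]
  r[stuck_lo & !at_cap] <- lo[stuck_lo & !at_cap]
  list(r = r, at_cap = at_cap)
}

# assemble a deployed_state from solved ring radii
.make_state <- function(lattice, design, geom, props, vr, config, r_rings,
                        theta_p, kappa, pressure_mpa, at_cap) {
  t_s <- design$strut_thickness
  h_ring <- .ring_height(r_rings, geom)
  p_contact <- .vessel_pressure(r_rings, vr)
  f_contact <- p_contact * 2 * pi * r_rings * h_ring
  p_stent <- .ring_force(r_rings, theta_p, kappa, geom, props) /
    (2 * pi * r_rings * h_ring)
  resid <- abs(pressure_mpa - p_stent - p_contact) *
    2 * pi * r_rings * h_ring
  resid[at_cap] <- 0
  st <- list(
    lattice = .apply_ring_radii(lattice, r_rings),
    design = design,
    stations = tibble::tibble(
      ring = seq_along(r_rings),
      z_center = if (is.null(vr)) NA_real_ else vr$z_center,
      r = r_rings, r_inner = r_rings - t_s / 2, r_outer = r_rings + t_s / 2,
      r_lumen0 = if (is.null(vr)) NA_real_ else vr$r_lumen,
      engagement = if (is.null(vr)) 0 else pmax(r_rings - vr$r_lumen, 0),
      p_contact = p_contact, f_contact = f_contact,
      h_ring = h_ring, residual = resid, at_cap = at_cap
    ),
    hinge_state = list(theta_p = theta_p, kappa = kappa),
    pressure_mpa = pressure_mpa,
    config = config, vessel_rings = vr,
    position = if (is.null(vr)) 0 else vr$position,
    ostium = if (is.null(vr)) NULL else vr$ostium,
    nominal_length = design$crimped_length,
    free = is.null(vr)
  )
  class(st) <- "deployed_state"
  st
}

#' @export
print.deployed_state <- function(x, ...) {
  cat(sprintf(
    "<deployed_state> %s at %.2f atm: mean inner diameter %.3f mm, max residual %.2e N\n",
    x$design$name, x$pressure_mpa / .ATM_MPA,
    mean(2 * x$stations$r_inner), max(x$stations$residual)))
  invisible(x)
}

#' Balloon-driven stent expansion (and optional deflation) in a vessel
#'
#' Ramps the balloon pressure from zero to the configured peak in equal
#' increments; at each increment every ring is brought to radial
#' equilibrium between balloon pressure, its own elastoplastic hinge
#' resistance and the vessel's layered-wall reaction, capped by the
#' balloon diameter (sized to the target, semi-compliant above nominal
#' pressure). With `deflate = TRUE` the pressure is then ramped back to
#' zero, leaving the recoiled equilibrium state.
#'
#' @param lattice A [build_lattice()] result (crimped).
#' @param design The [stent_design()]; defaults to the lattice's own.
#' @param vessel A [generate_bifurcation()] vessel (with plaque assigned),
#'   or `NULL` for free expansion.
#' @param config A [solver_config()].
#' @param materials Optional named material list overriding the default
#'   wall/plaque catalog.
#' @param position Axial position of the stent's proximal end in the
#'   vessel frame (mm); default centres the stent on the stenosis.
#' @param deflate If `TRUE` (default), deflate fully after inflation.
#' @return A `deployed_state`.
#' @export
expand_stent <- function(lattice, design = lattice$design, vessel = NULL,
                         config = solver_config(), materials = NULL,
                         position = NULL, deflate = TRUE) {
  stopifnot(inherits(lattice, "stent_lattice"))
  geom <- .ring_geom(design)
  props <- .hinge_props(design, config$alloy)
  vr <- NULL
  if (!is.null(vessel)) {
    if (design$crimped_length > max(vessel$z)) {
      stop("stent longer than the vessel")
    }
    if (is.null(position)) {
      position <- min(max(vessel$stenosis_center - design$crimped_length / 2, 0),
                      max(vessel$z) - design$crimped_length)
    }
    if (is.null(materials)) materials <- .default_wall_materials()
    vr <- .vessel_rings(vessel, design, position, materials)
  }

  n_r <- design$rings
  theta_p <- rep(0, n_r); kappa <- rep(0, n_r)
  r_rings <- rep(geom$r0, n_r)
  p_peak <- config$pressure_atm * .ATM_MPA
  p_seq <- seq(p_peak / config$n_steps, p_peak, length.out = config$n_steps)
  at_cap <- rep(FALSE, n_r)
  for (p_b in p_seq) {
    cap <- max(.balloon_radius(p_b, config, design), geom$r0 + 1e-9)
    sol <- .solve_increment(p_b, r_rings, theta_p, kappa, geom, props, vr,
                            cap, config)
    r_rings <- sol$r; at_cap <- sol$at_cap
    th <- .ring_theta(r_rings, geom)
    st <- .hinge_commit(th, theta_p, kappa, props)
    theta_p <- st$theta_p; kappa <- st$kappa
  }
  state <- .make_state(lattice, design, geom, props, vr, config, r_rings,
                       theta_p, kappa, p_peak, at_cap)
  if (deflate) state <- recoil(state) else state
}

#' Balloon deflation and elastic recoil of a deployed state
#'
#' Ramps the balloon pressure from the state's current value to zero in
#' the configured number of increments. At each increment every ring
#' seeks its stent-vessel equilibrium (no balloon push once contact with
#' the shrinking balloon is lost), floored by the balloon radius at the
#' current pressure: the still-inflated balloon props the stent until it
#' deflates out of the way. Radii are non-increasing and contact forces
#' stay non-negative.
#'
#' @param state A `deployed_state` from [expand_stent()] (typically with
#'   `deflate = FALSE`).
#' @param vessel Unused; the vessel reaction travels with the state.
#' @return The recoiled `deployed_state` at zero balloon pressure.
#' @export
recoil <- function(state, vessel = NULL) {
  stopifnot(inherits(state, "deployed_state"))
  if (state$pressure_mpa <= 0) return(state)
  design <- state$design
  geom <- .ring_geom(design)
  config <- state$config
  props <- .hinge_props(design, config$alloy)
  vr <- state$vessel_rings
  theta_p <- state$hinge_state$theta_p
  kappa <- state$hinge_state$kappa
  r_rings <- state$stations$r
  p_seq <- seq(state$pressure_mpa, 0,
               length.out = config$n_steps + 1)[-1]
  for (p_b in p_seq) {
    r_bal <- .balloon_radius(p_b, config, design)
    sol <- .solve_increment(0, r_rings, theta_p, kappa, geom, props, vr,
                            cap = Inf, config)
    # balloon props the stent from inside; deflation cannot expand it
    r_rings <- pmin(pmax(sol$r, r_bal), r_rings)
    th <- .ring_theta(r_rings, geom)
    st <- .hinge_commit(th, theta_p, kappa, props)
    theta_p <- st$theta_p; kappa <- st$kappa
  }
  .make_state(state$lattice, design, geom, props, vr, config, r_rings,
              theta_p, kappa, 0, rep(FALSE, length(r_rings)))
}

#' Simulated radial crimp test of a stent design
#'
#' Reproduces the bench radial-force protocol: the stent is expanded to
#' the given (outer) diameter, released to its free recoiled diameter,
#' then compressed by uniform inward radial displacement until the outer
#' diameter reaches `(1 - reduction)` times the expansion diameter,
#' recording the total resisting radial force at each step.
#'
#' @param design A [stent_design()].
#' @param diameter Expansion outer diameter in mm before crimping.
#' @param reduction Diameter reduction fraction in `(0, 0.5]` (default
#'   0.15, the onset of permanent compressive set in the bench protocol).
#' @param alloy An [alloy_material()].
#' @param n_steps Crimp displacement steps.
#' @return An object of class `crimp_result`: `curve` (tibble with
#'   `outer_diameter_mm` strictly decreasing and `radial_force_N`),
#'   `max_hoop_force` (max radial force / 2*pi, N), `reduction`, `design`,
#'   `start_diameter`.
#' @export
radial_crimp <- function(design, diameter = 4.5, reduction = 0.15,
                         alloy = material_catalog("pt_cr"),
                         n_steps = 60) {
  if (reduction <= 0 || reduction > 0.5) {
    stop("reduction must lie in (0, 0.5]")
  }
  geom <- .ring_geom(design)
  props <- .hinge_props(design, alloy)
  r_start <- diameter / 2 - design$strut_thickness / 2
  if (r_start >= geom$r_max) {
    stop(sprintf("expansion diameter beyond the kinematic limit %.3f mm",
                 2 * geom$r_max + design$strut_thickness))
  }
  # expand with plasticity
  path_up <- hoop_resistance_path(design,
                                  seq(geom$r0, r_start, length.out = 150),
                                  alloy)
  hs <- attr(path_up, "hinge_state")
  theta_p <- hs$theta_p; kappa <- hs$kappa
  # release to the free (zero-force) radius: theta = theta_p
  alpha_free <- theta_p / 2 + geom$alpha0
  r_free <- geom$L * sin(alpha_free) / (2 * geom$sinp)
  r_free <- min(r_free, r_start)
  # crimp to the target outer diameter
  r_target <- (1 - reduction) * diameter / 2 - design$strut_thickness / 2
  radii <- seq(r_free, r_target, length.out = n_steps)
  th <- .ring_theta(radii, geom)
  force <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    hm <- .hinge_moment(th[i], theta_p, kappa, props)
    # compressive resistance: the plates push inward, the stent pushes out
    force[i] <- -design$rings * geom$n_h * hm$M *
      .ring_dtheta_dr(radii[i], geom)
    st <- .hinge_commit(th[i], theta_p, kappa, props)
    theta_p <- st$theta_p; kappa <- st$kappa
  }
  force <- pmax(force, 0)
  curve <- tibble::tibble(
    outer_diameter_mm = 2 * radii + design$strut_thickness,
    radial_force_N = force
  )
  out <- list(curve = curve, max_hoop_force = max(force) / (2 * pi),
              reduction = reduction, design = design$name,
              start_diameter = diameter,
              final_outer_diameter = (1 - reduction) * diameter)
  class(out) <- "crimp_result"
  out
}

#' @export
print.crimp_result <- function(x, ...) {
  cat(sprintf(
    "<crimp_result> %s: %.2f -> %.3f mm (%.0f%% reduction), max hoop force %.3f N\n",
    x$design, x$start_diameter, x$final_outer_diameter,
    100 * x$reduction, x$max_hoop_force))
  invisible(x)
}
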