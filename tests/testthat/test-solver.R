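test_that("plastic-hinge work balance closes along a loading path", {
  d <- stent_catalog("MEGATRON_9")
  geom <- stentmech:::.ring_geom(d)
  radii <- seq(geom$r0, 4.5 / 2, length.out = 4000)
  path <- hoop_resistance_path(d, radii)
  # external work of the radial force equals hinge work n_h * int M dtheta
  trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  w_ext <- trapz(path$r, path$force_N)
  w_hinge <- geom$n_h * trapz(path$theta_h, path$moment)
  expect_lt(abs(w_ext - w_hinge) / abs(w_hinge), 1e-6)
})

test_that("a sub-yield excursion is elastically reversible", {
  d <- stent_catalog("MEGATRON_10")
  geom <- stentmech:::.ring_geom(d)
  props <- stentmech:::.hinge_props(d, material_catalog("pt_cr"))
  # pick a rotation well below hinge yield and invert for the radius
  th_y <- props$M_y / props$k_m
  alpha_t <- th_y / 8 / 2 + geom$alpha0
  r_t <- geom$L * sin(alpha_t) / (2 * geom$sinp)
  radii <- c(seq(geom$r0, r_t, length.out = 50),
             seq(r_t, geom$r0, length.out = 50))
  path <- hoop_resistance_path(d, radii)
  hs <- attr(path, "hinge_state")
  expect_equal(hs$theta_p, 0)
  expect_equal(hs$kappa, 0)
  expect_equal(path$force_N[length(radii)], 0, tolerance = 1e-9)
  # moments retrace: unloading moment equals loading moment at equal radius
  expect_equal(path$moment[1:50], rev(path$moment[51:100]), tolerance = 1e-9)
})

test_that("hoop resistance is continuous, zero at crimp and positive beyond", {
  lat <- build_lattice(stent_catalog("MEGATRON_12"))
  d <- lat$design
  expect_equal(stent_hoop_resistance(lat, inner_diameter = d$crimped_id), 0)
  dias <- seq(1.5, 4.8, by = 0.3)
  p <- vapply(dias, function(x) stent_hoop_resistance(lat, inner_diameter = x),
              1)
  expect_true(all(p > 0))
  # continuity in the target diameter
  expect_lt(abs(stent_hoop_resistance(lat, inner_diameter = 3.0) -
                  stent_hoop_resistance(lat, inner_diameter = 3.0 + 1e-4)),
            1e-3)
  # the radial force itself grows monotonically along a loading path
  # (the equivalent pressure need not: its 2*pi*r*h denominator grows too)
  geom <- stentmech:::.ring_geom(d)
  path <- hoop_resistance_path(d, seq(geom$r0 * 1.001, 2.25,
                                      length.out = 300))
  expect_true(all(diff(path$force_N) > 0))
  expect_error(stent_hoop_resistance(lat, inner_diameter = 0.5), "outside")
  expect_error(stent_hoop_resistance(lat, inner_diameter = 20), "outside")
})

test_that("free expansion reaches the balloon-capped uniform diameter", {
  lat <- build_lattice(stent_catalog("MEGATRON_9"))
  cfg <- solver_config(target_diameter = 4.5)
  st <- expand_stent(lat, vessel = NULL, config = cfg, deflate = FALSE)
  expect_s3_class(st, "deployed_state")
  expect_true(st$free)
  # all rings identical in a free axisymmetric expansion
  expect_lt(diff(range(st$stations$r)), 1e-9)
  expect_true(all(st$stations$f_contact == 0))
  expect_lt(max(st$stations$residual), 1e-6)
  # the semi-compliant balloon at 18 atm carries the stent past nominal
  expect_gt(mean_stent_diameter(st), 4.5)
})

test_that("free recoil loses diameter and ends in equilibrium", {
  lat <- build_lattice(stent_catalog("MEGATRON_9"))
  st <- expand_stent(lat, vessel = NULL,
                     config = solver_config(target_diameter = 4.5),
                     deflate = FALSE)
  rec <- recoil(st)
  expect_equal(rec$pressure_mpa, 0)
  expect_true(all(rec$stations$r <= st$stations$r + 1e-12))
  expect_lt(mean_stent_diameter(rec), mean_stent_diameter(st))
  expect_lt(max(rec$stations$residual), 1e-6)
  # plastic deployment: most of the expansion is retained
  expect_gt(mean_stent_diameter(rec), 0.8 * mean_stent_diameter(st))
})

test_that("deployment in a vessel equilibrates and respects the lumen reaction", {
  lat <- build_lattice(stent_catalog("MEGATRON_10"))
  vessel <- assign_homogeneous_plaque(generate_bifurcation(seed = 1),
                                      "neutral")
  st <- expand_stent(lat, vessel = vessel,
                     config = solver_config(target_diameter = 4.5))
  expect_equal(st$pressure_mpa, 0)
  expect_lt(max(st$stations$residual), 1e-6)
  expect_true(all(st$stations$f_contact >= 0))
  # somewhere the stent engages the wall
  expect_gt(sum(st$stations$f_contact), 0)
  # stiffer plaque resists more: smaller deployed diameter
  vs <- assign_homogeneous_plaque(generate_bifurcation(seed = 1),
                                  "very_stiff")
  st_stiff <- expand_stent(lat, vessel = vs,
                           config = solver_config(target_diameter = 4.5))
  expect_lt(mean_stent_diameter(st_stiff), mean_stent_diameter(st))
})

test_that("a rigid vessel bounds the stent at the lumen", {
  lat <- build_lattice(stent_catalog("MEGATRON_10"))
  vessel <- assign_homogeneous_plaque(generate_bifurcation(seed = 2),
                                      "neutral")
  cfg <- solver_config(target_diameter = 4.5, rigid_vessel = TRUE)
  st <- expand_stent(lat, vessel = vessel, config = cfg, deflate = FALSE)
  expect_true(all(st$stations$r <= st$vessel_rings$r_lumen + 1e-9))
})

test_that("expansion in a vessel is deterministic", {
  lat <- build_lattice(stent_catalog("SYNERGY"))
  vessel <- assign_heterogeneous_plaque(generate_bifurcation(seed = 3))
  a <- expand_stent(lat, vessel = vessel)
  b <- expand_stent(lat, vessel = vessel)
  expect_identical(a$stations, b$stations)
})

test_that("radial crimp produces a monotone, non-negative force curve", {
  crimp <- radial_crimp(stent_catalog("MEGATRON_9"), diameter = 4.5)
  expect_s3_class(crimp, "crimp_result")
  expect_true(all(diff(crimp$curve$outer_diameter_mm) < 0))
  expect_true(all(crimp$curve$radial_force_N >= 0))
  expect_equal(crimp$max_hoop_force,
               max(crimp$curve$radial_force_N) / (2 * pi))
  expect_equal(crimp$final_outer_diameter, 0.85 * 4.5)
  expect_error(radial_crimp(stent_catalog("MEGATRON_9"), reduction = 0.7),
               "reduction")
})

test_that("the crimp peak force is insensitive to deepening the reduction", {
  # the force peaks within the first 10% of diameter reduction, so deeper
  # crimps report the same maximum up to path-discretization error
  d <- stent_catalog("MEGATRON_12")
  f10 <- radial_crimp(d, diameter = 4.5, reduction = 0.10)$max_hoop_force
  f20 <- radial_crimp(d, diameter = 4.5, reduction = 0.20)$max_hoop_force
  expect_equal(f20, f10, tolerance = 1e-3)
})

test_that("solver error paths trigger on invalid geometry", {
  d <- stent_catalog("MEGATRON_9")
  geom <- stentmech:::.ring_geom(d)
  expect_error(hoop_resistance_path(d, c(geom$r0, geom$r_max + 1)),
               "kinematic limit")
  lat <- build_lattice(d)
  short_vessel <- generate_bifurcation(length = 10, stenosis_center = 5,
                                       bifurcation_z = 4, seed = 1)
  expect_error(expand_stent(lat, vessel = short_vessel),
               "longer than the vessel")
})
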