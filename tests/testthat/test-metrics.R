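test_that("inscribed circle of axis-aligned shapes matches closed forms", {
  sq <- cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1))
  ic <- inscribed_circle(sq)
  expect_equal(ic$radius, 1, tolerance = 1e-6)
  expect_equal(as.numeric(ic$center), c(0, 0), tolerance = 1e-4)
  # the inscribed diameter of a square cell equals its side
  expect_equal(2 * ic$radius, 2, tolerance = 1e-6)
  rect <- cbind(c(0, 4, 4, 0), c(0, 0, 2, 2))
  expect_equal(inscribed_circle(rect)$radius, 1, tolerance = 1e-6)
  # 3-4-5 right triangle: incircle radius (a + b - c) / 2 = 1 at (1, 1)
  tri <- cbind(c(0, 3, 0), c(0, 0, 4))
  ict <- inscribed_circle(tri)
  expect_equal(ict$radius, 1, tolerance = 1e-5)
  expect_equal(as.numeric(ict$center), c(1, 1), tolerance = 1e-3)
})

test_that("inscribed circle is invariant under rotation and translation", {
  set.seed(7)
  poly <- random_polygon(9)
  r0 <- inscribed_circle(poly)$radius
  a <- 0.83
  rot <- cbind(poly[, 1] * cos(a) - poly[, 2] * sin(a) + 5,
               poly[, 1] * sin(a) + poly[, 2] * cos(a) - 2)
  # pattern-search refinement is accurate to well below the 1 percent the
  # metric requires, but not to machine precision on oblique ridges
  expect_equal(inscribed_circle(rot)$radius, r0, tolerance = 1e-3)
})

test_that("inscribed circle matches the brute-force grid oracle on random polygons", {
  set.seed(123)
  for (k in 1:100) {
    poly <- random_polygon(sample(5:12, 1))
    r_fast <- inscribed_circle(poly)$radius
    r_grid <- grid_inscribed_radius(poly, n = 150)
    # the grid oracle under-estimates by at most one grid cell diagonal;
    # the pattern search can stall within ~1e-4 on shallow oblique ridges
    step <- max(diff(range(poly[, 1])), diff(range(poly[, 2]))) / 149
    expect_gte(r_fast, r_grid - 1e-3)
    expect_lte(r_fast - r_grid, 1.5 * step)
    expect_lt(abs(r_fast - r_grid) / r_grid, 0.01 + 2 * step / r_grid)
  }
})

test_that("degenerate polygons yield radius zero", {
  sliver <- cbind(c(0, 1, 2), c(0, 1e-12, 0))
  expect_equal(inscribed_circle(sliver)$radius, 0)
})

test_that("CCD of a free expanded lattice uses all cells and the open width", {
  lat <- expand_kinematics(build_lattice(stent_catalog("MEGATRON_9")), 4.5)
  ccd <- circular_cell_diameter(lat)
  expect_gt(as.numeric(ccd), 0)
  expect_identical(attr(ccd, "n_cells"),
                   as.integer(expected_cell_count(lat)))
  expect_identical(attr(ccd, "n_degenerate"), 0L)
  # the open-cell definition subtracts the strut width from the
  # centerline inscribed diameter
  cr <- stentmech:::.state_cell_radii(
    structure(list(lattice = lat, free = TRUE, ostium = NULL),
              class = "deployed_state"))
  expect_equal(as.numeric(ccd),
               mean(2 * pmax(cr$radius - lat$design$strut_width / 2, 0)))
})

test_that("thinner struts widen the open cell at equal centerline geometry", {
  base <- stent_catalog("MEGATRON_10")
  thin <- stent_design("thin", peaks = base$peaks, rings = base$rings,
                       links_total = base$links_total,
                       strut_thickness = base$strut_thickness,
                       strut_width = base$strut_width / 2,
                       crimped_length = base$crimped_length)
  ccd_base <- circular_cell_diameter(
    expand_kinematics(build_lattice(base), 4.5))
  ccd_thin <- circular_cell_diameter(
    expand_kinematics(build_lattice(thin), 4.5))
  expect_gt(as.numeric(ccd_thin), as.numeric(ccd_base))
})

test_that("cells over the side-branch ostium are excluded by default", {
  lat <- build_lattice(stent_catalog("MEGATRON_10"))
  vessel <- assign_homogeneous_plaque(generate_bifurcation(seed = 1),
                                      "neutral")
  st <- expand_stent(lat, vessel = vessel,
                     config = solver_config(target_diameter = 4.5))
  ccd_excl <- circular_cell_diameter(st)
  ccd_all <- circular_cell_diameter(st, include_ostium = TRUE)
  expect_gt(attr(ccd_all, "n_cells"), attr(ccd_excl, "n_cells"))
})

test_that("explicit sag depths pass through to the prolapse value exactly", {
  lat <- build_lattice(stent_catalog("MEGATRON_9"))
  st <- expand_stent(lat, vessel = NULL,
                     config = solver_config(target_diameter = 4.5))
  n <- attr(circular_cell_diameter(st), "n_cells")
  p <- vessel_prolapse(st, sag_depths = rep(0.07, n))
  expect_equal(as.numeric(p), 0.07)
  expect_equal(attr(p, "mean"), 0.07)
  # free expansion has no apposed wall: membrane-model prolapse is zero
  expect_equal(as.numeric(vessel_prolapse(st)), 0)
})

test_that("membrane prolapse scales with the sag coefficient", {
  lat <- build_lattice(stent_catalog("MEGATRON_10"))
  vessel <- assign_homogeneous_plaque(generate_bifurcation(seed = 2),
                                      "neutral")
  st <- expand_stent(lat, vessel = vessel,
                     config = solver_config(target_diameter = 4.5))
  p1 <- as.numeric(vessel_prolapse(st, sag_coefficient = 0.5))
  p2 <- as.numeric(vessel_prolapse(st, sag_coefficient = 1.0))
  expect_gt(p1, 0)
  expect_equal(p2, 2 * p1, tolerance = 1e-9)
  expect_gte(as.numeric(vessel_prolapse(st)),
             as.numeric(vessel_prolapse(st, aggregate = "mean")))
})

test_that("normalized hoop force reproduces hand arithmetic exactly", {
  crimp <- structure(
    list(curve = tibble::tibble(outer_diameter_mm = c(4.0, 3.9, 3.8),
                                radial_force_N = c(0.5, 2 * pi, 1.0)),
         max_hoop_force = 1, reduction = 0.15, design = "hand",
         start_diameter = 4.0, final_outer_diameter = 3.4),
    class = "crimp_result")
  # radial force 2*pi N over a 1 mm stent -> 1 N/mm
  expect_identical(normalized_hoop_force(crimp, 1), 1)
  expect_equal(normalized_hoop_force(crimp, 2), 0.5)
  expect_error(normalized_hoop_force(crimp, 0), "positive")
})

test_that("SAR divides strut area by the stented lumen surface", {
  lat <- build_lattice(stent_catalog("MEGATRON_9"))
  st <- expand_stent(lat, vessel = NULL,
                     config = solver_config(target_diameter = 4.5))
  sar <- stent_artery_ratio(st)
  strut_area <- strut_outer_surface_area(st$lattice)
  pitch <- st$stations$h_ring + st$design$link_gap
  pitch[length(pitch)] <- st$stations$h_ring[length(pitch)]
  lumen <- sum(2 * pi * st$stations$r_outer * pitch)
  expect_equal(sar, 100 * strut_area / lumen)
  expect_gt(sar, 0)
  expect_lt(sar, 100)
})

test_that("radial strength is total contact force per strut area", {
  lat <- build_lattice(stent_catalog("MEGATRON_12"))
  vessel <- assign_homogeneous_plaque(generate_bifurcation(seed = 1),
                                      "neutral")
  st <- expand_stent(lat, vessel = vessel,
                     config = solver_config(target_diameter = 4.5))
  expect_equal(radial_strength(st),
               sum(st$stations$f_contact) /
                 strut_outer_surface_area(st$lattice))
  expect_gt(radial_strength(st), 0)
})

test_that("metrics_report assembles one complete row", {
  d <- stent_catalog("SYNERGY")
  lat <- build_lattice(d)
  vessel <- assign_homogeneous_plaque(generate_bifurcation(seed = 1),
                                      "neutral")
  st <- expand_stent(lat, vessel = vessel,
                     config = solver_config(target_diameter = 4.5))
  crimp <- radial_crimp(d, diameter = 4.5)
  row <- metrics_report(st, crimp, metadata = list(design = d$name))
  expect_identical(nrow(row), 1L)
  expect_true(all(c("msd", "ccd", "prolapse", "prolapse_mean", "sar",
                    "hoop_force", "radial_strength", "n_cells",
                    "n_degenerate_cells", "max_residual", "design") %in%
                    names(row)))
  expect_identical(row$design, "SYNERGY")
  expect_false(any(is.na(row[c("msd", "ccd", "prolapse", "sar",
                               "hoop_force", "radial_strength")])))
  row_nocrimp <- metrics_report(st)
  expect_true(is.na(row_nocrimp$hoop_force))
  expect_equal(row$msd, mean_stent_diameter(st))
})
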