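test_that("catalog designs carry their printed platform characteristics", {
  specs <- list(
    MEGATRON_9 = list(peaks = 9L, links = 36L, t = 0.089, len = 19.74),
    MEGATRON_10 = list(peaks = 10L, links = 28L, t = 0.089, len = 20.62),
    MEGATRON_12 = list(peaks = 12L, links = 50L, t = 0.089, len = 20.05),
    SYNERGY = list(peaks = 10L, links = 36L, t = 0.081, len = 20.33)
  )
  for (nm in stent_catalog_names()) {
    d <- stent_catalog(nm)
    s <- specs[[nm]]
    expect_identical(d$peaks, s$peaks)
    expect_identical(d$links_total, s$links)
    expect_equal(d$strut_thickness, s$t)
    expect_equal(d$crimped_length, s$len)
    expect_equal(d$crimped_id, 0.84)
    expect_equal(d$crimped_od, d$crimped_id + 2 * d$strut_thickness)
    expect_equal(sum(d$links_per_pair), d$links_total)
    expect_true(all(d$links_per_pair <= d$peaks))
    # ring decomposition reassembles the crimped length exactly
    expect_equal(d$rings * d$crown_height + (d$rings - 1) * d$link_gap,
                 d$crimped_length)
    expect_true(d$crown_height > 1.0 && d$crown_height < 1.4)
  }
  expect_error(stent_catalog("NONSENSE"), "unknown")
})

test_that("catalog kinematics stay below the 45-degree half-angle over 3.5-5.0 mm", {
  for (nm in stent_catalog_names()) {
    d <- stent_catalog(nm)
    geom <- stentmech:::.ring_geom(d)
    r_top <- 5.0 / 2 + d$strut_thickness / 2
    expect_lt(stentmech:::.ring_alpha(r_top, geom), pi / 4)
  }
})

test_that("lattice node and edge counts follow the construction", {
  for (nm in stent_catalog_names()) {
    d <- stent_catalog(nm)
    lat <- build_lattice(d)
    expect_identical(length(lat$theta), as.integer(d$rings * 2 * d$peaks))
    expect_identical(nrow(lat$edges),
                     as.integer(d$rings * 2 * d$peaks + d$links_total))
    expect_true(stentmech:::.lattice_connected(lat))
  }
})

test_that("strut segments all have the leg length, links the link gap", {
  d <- stent_catalog("MEGATRON_9")
  lat <- build_lattice(d)
  len <- segment_lengths(lat)
  expect_equal(len[lat$edge_type == "strut"],
               rep(lat$leg_length, sum(lat$edge_type == "strut")))
  expect_equal(len[lat$edge_type == "link"],
               rep(d$link_gap, d$links_total))
})

test_that("cell count matches the Euler face oracle on all catalog lattices", {
  for (nm in stent_catalog_names()) {
    lat <- build_lattice(stent_catalog(nm))
    cells <- cell_polygons(lat)
    expect_identical(length(cells), as.integer(expected_cell_count(lat)))
  }
})

test_that("cell count matches the Euler oracle on random small designs", {
  set.seed(42)
  for (rep in 1:6) {
    p <- sample(3:7, 1)
    R <- sample(2:5, 1)
    links <- sample(seq(R - 1, (R - 1) * p), 1)
    d <- stent_design(sprintf("rand_%d", rep), peaks = p, rings = R,
                      links_total = links, strut_thickness = 0.08,
                      crimped_length = R * 1.2 + (R - 1) * 0.3)
    lat <- build_lattice(d)
    expect_identical(length(cell_polygons(lat)),
                     as.integer(expected_cell_count(lat)))
  }
})

test_that("face cache distinguishes designs that differ only in links", {
  a <- stent_design("cache_probe", peaks = 6, rings = 4, links_total = 12,
                    strut_thickness = 0.08, crimped_length = 5.1)
  b <- stent_design("cache_probe", peaks = 6, rings = 4, links_total = 6,
                    strut_thickness = 0.08, crimped_length = 5.1)
  ca <- cell_polygons(build_lattice(a))
  cb <- cell_polygons(build_lattice(b))
  expect_identical(length(ca), as.integer(expected_cell_count(build_lattice(a))))
  expect_identical(length(cb), as.integer(expected_cell_count(build_lattice(b))))
  expect_false(length(ca) == length(cb))
})

test_that("kinematic expansion preserves strut leg lengths", {
  d <- stent_catalog("MEGATRON_10")
  lat <- build_lattice(d)
  ex <- expand_kinematics(lat, 4.5)
  len <- segment_lengths(ex)
  strut <- lat$edge_type == "strut"
  expect_equal(len[strut], rep(lat$leg_length, sum(strut)), tolerance = 1e-9)
  expect_equal(unique(ex$r), 4.5 / 2 + d$strut_thickness / 2)
  # foreshortening: the expanded stent is axially shorter
  expect_lt(lattice_length(ex), lattice_length(lat))
})

test_that("expansion beyond the kinematic limit errors", {
  d <- stent_catalog("MEGATRON_9")
  lat <- build_lattice(d)
  d_max <- max_expansion_diameter(d)
  expect_error(expand_kinematics(lat, d_max + 0.5), "unreachable")
  expect_error(expand_kinematics(lat, 0.5), "below the crimped")
  # just under the limit still works
  ex <- expand_kinematics(lat, d_max - 0.01)
  expect_s3_class(ex, "stent_lattice")
})

test_that("strut outer surface area is total segment length times width", {
  d <- stent_catalog("SYNERGY")
  lat <- build_lattice(d)
  expect_equal(strut_outer_surface_area(lat),
               sum(segment_lengths(lat)) * d$strut_width)
})

test_that("design config round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_design_config(path)
  back <- read_design_config(path)
  for (nm in stent_catalog_names()) {
    orig <- stent_catalog(nm)
    expect_equal(back[[nm]]$peaks, orig$peaks)
    expect_equal(back[[nm]]$rings, orig$rings)
    expect_equal(back[[nm]]$links_per_pair, orig$links_per_pair)
    expect_equal(back[[nm]]$crown_height, orig$crown_height)
  }
})

test_that("lattice VTK export writes a well-formed line mesh", {
  path <- withr::local_tempfile(fileext = ".vtk")
  lat <- build_lattice(stent_catalog("MEGATRON_9"))
  write_lattice_vtk(lat, path)
  lines <- readLines(path)
  expect_identical(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl(sprintf("^POINTS %d float", length(lat$theta)), lines)))
  expect_true(any(grepl(sprintf("^LINES %d", nrow(lat$edges)), lines)))
})

test_that("design constructor rejects impossible parameter combinations", {
  expect_error(stent_design("x", peaks = 4, rings = 3, links_total = 20,
                            strut_thickness = 0.08, crimped_length = 5),
               "exceed peaks")
  expect_error(stent_design("x", peaks = 6, rings = 10, links_total = 9,
                            strut_thickness = 0.08, crimped_length = 2),
               "too short")
})
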