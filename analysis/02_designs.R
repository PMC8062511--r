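#!/usr/bin/env Rscript
# Export the stent design catalog: YAML config, crimped lattice VTK line
# meshes and a per-design geometry summary (cells, strut area, limits).

suppressPackageStartupMessages({
  library(stentmech)
  library(tibble)
})

out_dir <- file.path("analysis", "results", "designs")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

write_design_config(file.path(out_dir, "design_catalog.yaml"))

rows <- lapply(stent_catalog_names(), function(nm) {
  d <- stent_catalog(nm)
  lat <- build_lattice(d)
  write_lattice_vtk(lat, file.path(out_dir, sprintf("%s_crimped.vtk", nm)))
  write_lattice_vtk(expand_kinematics(lat, 4.5),
                    file.path(out_dir, sprintf("%s_expanded_4.5.vtk", nm)))
  tibble(
    design = nm, peaks = d$peaks, rings = d$rings,
    links_total = d$links_total,
    strut_thickness_um = 1000 * d$strut_thickness,
    crimped_length_mm = d$crimped_length,
    crown_height_mm = d$crown_height,
    n_cells = expected_cell_count(lat),
    strut_area_mm2 = strut_outer_surface_area(lat),
    max_expansion_diameter_mm = max_expansion_diameter(d)
  )
})
summary <- do.call(rbind, rows)
readr::write_csv(summary, file.path(out_dir, "design_summary.csv"))
print(as.data.frame(summary))
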