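#!/usr/bin/env Rscript
# Simulated bench crimp protocol: radial force-diameter curves and
# normalized hoop force for each design and sizing diameter.

suppressPackageStartupMessages({
  library(stentmech)
  library(dplyr)
})

out_dir <- file.path("analysis", "results", "crimp")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (nm in stent_catalog_names()) {
  des <- stent_catalog(nm)
  for (dia in c(3.5, 4.5, 5.0)) {
    crimp <- radial_crimp(des, diameter = dia)
    curve <- dplyr::mutate(crimp$curve, design = nm, diameter = dia)
    readr::write_csv(curve,
                     file.path(out_dir,
                               sprintf("curve_%s_%.1f.csv", nm, dia)))
    rows[[length(rows) + 1]] <- tibble::tibble(
      design = nm, diameter = dia,
      max_hoop_force_N = crimp$max_hoop_force,
      normalized_hoop_force_N_mm =
        normalized_hoop_force(crimp, des$crimped_length)
    )
  }
}
summary <- dplyr::bind_rows(rows)
readr::write_csv(summary, file.path(out_dir, "hoop_force_summary.csv"))
print(as.data.frame(summary))
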