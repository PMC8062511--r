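# Parametric description of ring-and-link stent designs and the catalog of
# the four platforms compared in the study-style factorial (9/10/12-peak
# MEGATRON-style designs and a SYNERGY-style design).

#' Parametric stent design
#'
#' Describes a ring-and-link stent: zigzag rings of `peaks` crowns joined by
#' axial links. The printed platform characteristics (peaks, crimped length,
#' total links, strut thickness, crimped inner diameter 0.84 mm) pin down
#' most of the geometry; ring count, link gap and strut width are package
#' defaults where the platform documentation does not state them.
#'
#' @param name Design name.
#' @param peaks Peaks (crowns) per ring, >= 3.
#' @param rings Number of rings, >= 2.
#' @param links_total Total number of axial links over all ring pairs.
#' @param strut_thickness Strut (radial) thickness in mm.
#' @param crimped_length Overall crimped stent length in mm.
#' @param strut_width Strut in-surface width in mm; defaults to the
#'   thickness (square cross-section).
#' @param crimped_id Crimped inner diameter in mm (default 0.84).
#' @param link_gap Axial link length between adjacent rings in mm.
#' @return An object of class `stent_design`. Derived fields: crimped outer
#'   diameter `crimped_od = crimped_id + 2 * strut_thickness`, crown height
#'   `crown_height` (axial ring extent such that rings plus link gaps add to
#'   the crimped length), and `links_per_pair` (round-robin distribution of
#'   `links_total` over the `rings - 1` ring pairs).
#' @export
stent_design <- function(name, peaks, rings, links_total, strut_thickness,
                         crimped_length, strut_width = strut_thickness,
                         crimped_id = 0.84, link_gap = 0.3) {
  stopifnot(peaks >= 3, rings >= 2, links_total >= rings - 1,
            strut_thickness > 0, strut_width > 0, crimped_id > 0,
            crimped_length > 0, link_gap >= 0)
  n_pairs <- rings - 1
  base <- links_total %/% n_pairs
  extra <- links_total %% n_pairs
  links_per_pair <- rep(base, n_pairs)
  if (extra > 0) links_per_pair[seq_len(extra)] <- base + 1
  if (any(links_per_pair > peaks)) {
    stop("links per ring pair cannot exceed peaks per ring")
  }
  crown_height <- (crimped_length - n_pairs * link_gap) / rings
  if (crown_height <= 0) stop("crimped length too short for this ring count")
  d <- list(
    name = name, peaks = as.integer(peaks), rings = as.integer(rings),
    links_total = as.integer(links_total), links_per_pair = links_per_pair,
    strut_thickness = strut_thickness, strut_width = strut_width,
    crimped_id = crimped_id, crimped_od = crimped_id + 2 * strut_thickness,
    crimped_length = crimped_length, link_gap = link_gap,
    crown_height = crown_height
  )
  class(d) <- "stent_design"
  d
}

#' @export
print.stent_design <- function(x, ...) {
  cat(sprintf(
    "<stent_design> %s: %d peaks x %d rings, %d links, strut %.0f um, crimped %.2f mm (ID %.2f / OD %.2f mm)\n",
    x$name, x$peaks, x$rings, x$links_total, x$strut_thickness * 1000,
    x$crimped_length, x$crimped_id, x$crimped_od))
  invisible(x)
}

#' Catalog of the four stent designs under comparison
#'
#' Peaks, crimped length, total links and strut thickness follow the printed
#' platform characteristics; ring counts are package defaults chosen so the
#' crimped length decomposes into rings plus 0.3 mm link gaps with crown
#' heights in the 1.0-1.4 mm range typical of coronary platforms (shorter
#' crowns and more rings for the denser 12-peak design), subject to the
#' kinematic validity constraint of the hinge model: the strut half-angle
#' stays below 45 degrees across the studied deployment diameters (3.5-5.0
#' mm), where the straight-leg kinematics remain a faithful proxy for real
#' crown bending (real platforms foreshorten by only a few percent).
#'
#' @param name One of `"MEGATRON_9"`, `"MEGATRON_10"`, `"MEGATRON_12"`,
#'   `"SYNERGY"`.
#' @return A [stent_design()].
#' @export
stent_catalog <- function(name) {
  switch(name,
    MEGATRON_9 = stent_design("MEGATRON_9", peaks = 9, rings = 12,
                              links_total = 36, strut_thickness = 0.089,
                              crimped_length = 19.74),
    MEGATRON_10 = stent_design("MEGATRON_10", peaks = 10, rings = 14,
                               links_total = 28, strut_thickness = 0.089,
                               crimped_length = 20.62),
    MEGATRON_12 = stent_design("MEGATRON_12", peaks = 12, rings = 15,
                               links_total = 50, strut_thickness = 0.089,
                               crimped_length = 20.05),
    SYNERGY = stent_design("SYNERGY", peaks = 10, rings = 13,
                           links_total = 36, strut_thickness = 0.081,
                           crimped_length = 20.33),
    stop(sprintf("unknown stent design '%s'", name))
  )
}

#' Names of the catalog stent designs
#' @return Character vector.
#' @export
stent_catalog_names <- function() {
  c("MEGATRON_9", "MEGATRON_10", "MEGATRON_12", "SYNERGY")
}

#' Write the stent design catalog as a YAML config
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design_config <- function(path) {
  cfg <- lapply(stent_catalog_names(), function(nm) {
    d <- stent_catalog(nm)
    d[c("name", "peaks", "rings", "links_total", "strut_thickness",
        "strut_width", "crimped_id", "crimped_length", "link_gap")]
  })
  names(cfg) <- stent_catalog_names()
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a stent design config written by [write_design_config()]
#' @param path Config file path.
#' @return Named list of [stent_design()] objects.
#' @export
read_design_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(p) {
    stent_design(p$name, p$peaks, p$rings, p$links_total, p$strut_thickness,
                 p$crimped_length, strut_width = p$strut_width,
                 crimped_id = p$crimped_id, link_gap = p$link_gap)
  })
}
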