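# Session-cached default factorial cohort so that the ordinal acceptance
# block and any summary checks share one run.
.cohort_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.cohort_cache$tab)) {
    .cohort_cache$tab <- run_factorial(factorial_design())
  }
  .cohort_cache$tab
}

# numerical derivative of the uniaxial strain-energy path, for constitutive
# cross-checks
numeric_uniaxial_stress <- function(model, lam, h = 1e-6) {
  u <- function(l) strain_energy(model, c(l, 1 / sqrt(l), 1 / sqrt(l)))
  (u(lam + h) - u(lam - h)) / (2 * h)
}

# brute-force grid oracle for the largest inscribed circle of a polygon
grid_inscribed_radius <- function(poly, n = 200) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  gx <- seq(xr[1], xr[2], length.out = n)
  gy <- seq(yr[1], yr[2], length.out = n)
  pts <- as.matrix(expand.grid(x = gx, y = gy))
  inside <- stentmech:::.points_in_polygon(pts, poly)
  if (!any(inside)) return(0)
  max(stentmech:::.dist_to_boundary(pts[inside, , drop = FALSE], poly))
}

# random simply-connected test polygon: a star-shaped polygon around the
# origin with random radii
random_polygon <- function(n_vertices = 8, r_min = 0.5, r_max = 2) {
  th <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- stats::runif(n_vertices, r_min, r_max)
  cbind(r * cos(th), r * sin(th))
}
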