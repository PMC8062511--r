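# Constitutive models: polynomial hyperelasticity for wall/plaque, 1-D
# elastoplastic hardening for the Pt-Cr stent alloy, linear membrane for the
# semi-compliant balloon. All stresses are nominal (force per undeformed
# area), in MPa; strains are engineering (lambda - 1); incompressibility is
# assumed exactly, so the strain-energy function carries no volumetric term.

#' Polynomial hyperelastic material model
#'
#' Constructs an incompressible polynomial hyperelastic model with strain
#' energy density
#' \deqn{U = \sum_{i+j=1}^{N} C_{ij} (I_1 - 3)^i (I_2 - 3)^j}
#' where \eqn{I_1 = \lambda_1^2 + \lambda_2^2 + \lambda_3^2} and
#' \eqn{I_2 = \lambda_1^{-2} + \lambda_2^{-2} + \lambda_3^{-2}} are the
#' isochoric invariants of the Cauchy-Green tensor. The reduced polynomial
#' form used for arterial tissue keeps only the \eqn{(I_1-3)^i} terms
#' (all \eqn{j = 0}).
#'
#' @param coefficients Named numeric vector of coefficients in MPa. Names
#'   follow the `"C<i><j>"` convention, e.g. `c(C10 = 0.05, C20 = 0.3)`.
#' @return An object of class `hyperelastic_model` with fields
#'   `i`, `j`, `c` (one row per term) and `order` (\eqn{N = \max(i+j)}).
#' @examples
#' m <- hyperelastic_model(c(C10 = 0.5, C20 = 0.1))
#' strain_energy(m, c(1, 1, 1)) # exactly 0
#' @export
hyperelastic_model <- function(coefficients) {
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1)
  nm <- names(coefficients)
  if (is.null(nm) || any(!grepl("^C[0-9][0-9]$", nm))) {
    stop("coefficients must be named like 'C10', 'C01', 'C20', ...")
  }
  i <- as.integer(substr(nm, 2, 2))
  j <- as.integer(substr(nm, 3, 3))
  if (any(i + j < 1)) stop("coefficient exponents must satisfy i + j >= 1")
  m <- list(
    i = i, j = j, c = unname(as.numeric(coefficients)),
    order = max(i + j), incompressible = TRUE
  )
  class(m) <- "hyperelastic_model"
  m
}

#' @export
print.hyperelastic_model <- function(x, ...) {
  cat(sprintf("<hyperelastic_model> order N = %d, %d term(s)\n", x$order, length(x$c)))
  for (k in seq_along(x$c)) {
    cat(sprintf("  C%d%d = %g MPa\n", x$i[k], x$j[k], x$c[k]))
  }
  invisible(x)
}

# (I1 - 3) and (I2 - 3) from principal stretches; lam is a length-3 vector
# or an n x 3 matrix.
.invariant_deviations <- function(lam) {
  if (is.null(dim(lam))) lam <- matrix(lam, ncol = 3, byrow = TRUE)
  if (ncol(lam) != 3) stop("stretches must have three components")
  if (any(lam <= 0)) stop("principal stretches must be strictly positive")
  list(A = rowSums(lam^2) - 3, B = rowSums(lam^-2) - 3)
}

# x^k with the 0^0 = 1 convention needed at the identity configuration.
.pow0 <- function(x, k) if (k == 0) rep(1, length(x)) else x^k

#' Strain energy density of a hyperelastic model
#'
#' @param model A [hyperelastic_model()].
#' @param stretches Principal stretches: a length-3 vector or an n x 3 matrix.
#' @return Energy density in MPa (one value per row of `stretches`).
#' @export
strain_energy <- function(model, stretches) {
  stopifnot(inherits(model, "hyperelastic_model"))
  inv <- .invariant_deviations(stretches)
  u <- numeric(length(inv$A))
  for (k in seq_along(model$c)) {
    u <- u + model$c[k] * .pow0(inv$A, model$i[k]) * .pow0(inv$B, model$j[k])
  }
  u
}

#' Uniaxial nominal stress of an incompressible hyperelastic model
#'
#' Evaluates the analytic derivative \eqn{dU/d\lambda} along the
#' incompressible uniaxial path \eqn{\lambda_2 = \lambda_3 = \lambda^{-1/2}},
#' which is the nominal (first Piola-Kirchhoff) stress conjugate to the
#' axial stretch.
#'
#' @param model A [hyperelastic_model()].
#' @param stretch Axial stretch \eqn{\lambda > 0} (vectorized).
#' @return Nominal stress in MPa.
#' @export
uniaxial_stress <- function(model, stretch) {
  stopifnot(inherits(model, "hyperelastic_model"))
  lam <- as.numeric(stretch)
  if (any(lam <= 0)) stop("stretch must be strictly positive")
  A <- lam^2 + 2 / lam - 3          # I1 - 3 on the uniaxial path
  B <- lam^-2 + 2 * lam - 3         # I2 - 3 on the uniaxial path
  dA <- 2 * lam - 2 / lam^2
  dB <- -2 / lam^3 + 2
  s <- numeric(length(lam))
  for (k in seq_along(model$c)) {
    i <- model$i[k]; j <- model$j[k]; cc <- model$c[k]
    if (i >= 1) s <- s + cc * i * .pow0(A, i - 1) * .pow0(B, j) * dA
    if (j >= 1) s <- s + cc * j * .pow0(A, i) * .pow0(B, j - 1) * dB
  }
  s
}

#' Tangent stiffness of the uniaxial stress-strain curve
#'
#' Central-difference slope of [uniaxial_stress()] with respect to
#' engineering strain, used for the plaque category ordering checks.
#'
#' @param model A [hyperelastic_model()] (or a [plaque_material()], whose
#'   base model is used).
#' @param strain Engineering strain (vectorized).
#' @param h Step size for the central difference.
#' @return Tangent modulus in MPa.
#' @export
tangent_stiffness <- function(model, strain, h = 1e-6) {
  if (inherits(model, "plaque_material")) model <- model$model
  lam <- 1 + as.numeric(strain)
  (uniaxial_stress(model, lam + h) - uniaxial_stress(model, lam - h)) / (2 * h)
}

#' Plaque material: hyperelastic base with a plastic plateau
#'
#' Atherosclerotic plaque is modelled as hyperelastic up to a plasticity
#' onset at 34% engineering strain, beyond which the nominal stress holds a
#' perfectly-plastic plateau at the onset stress (the simplest continuous
#' post-yield extension).
#'
#' @param model A [hyperelastic_model()] for the pre-yield branch.
#' @param category Stiffness category label, one of `"very_soft"`, `"soft"`,
#'   `"neutral"`, `"stiff"`, `"very_stiff"`.
#' @param yield_strain Plasticity onset engineering strain (default 0.34).
#' @return An object of class `plaque_material`.
#' @export
plaque_material <- function(model, category, yield_strain = 0.34) {
  stopifnot(inherits(model, "hyperelastic_model"))
  category <- match.arg(category, plaque_categories())
  stopifnot(yield_strain > 0)
  structure(list(model = model, category = category, yield_strain = yield_strain),
            class = "plaque_material")
}

#' The five homogeneous plaque stiffness category labels, softest first
#' @return Character vector of category labels.
#' @export
plaque_categories <- function() {
  c("very_soft", "soft", "neutral", "stiff", "very_stiff")
}

#' Nominal stress of a plaque material at a given engineering strain
#'
#' Hyperelastic below the 34% plasticity onset, perfectly-plastic plateau
#' above it; continuous at the onset.
#'
#' @param material A [plaque_material()].
#' @param strain Engineering strain, must be non-negative (vectorized).
#' @return Nominal stress in MPa.
#' @export
plaque_stress <- function(material, strain) {
  stopifnot(inherits(material, "plaque_material"))
  strain <- as.numeric(strain)
  if (any(strain < 0)) stop("strain must be non-negative")
  capped <- pmin(strain, material$yield_strain)
  uniaxial_stress(material$model, 1 + capped)
}

#' Stent alloy: 1-D elastoplastic hardening law
#'
#' The platinum-chromium stent alloy is reduced to a one-dimensional
#' elastoplastic law (elastic modulus, yield stress, piecewise-linear
#' isotropic hardening), because the reduced-order solver tracks only the
#' bending fibre strain of strut hinges and never develops multiaxial
#' stress states.
#'
#' @param elastic_modulus Elastic modulus in MPa.
#' @param yield_stress Initial yield stress in MPa.
#' @param hardening A data frame with columns `plastic_strain` and `stress`
#'   (MPa), stresses non-decreasing, starting at `(0, yield_stress)`.
#' @return An object of class `alloy_material`.
#' @export
alloy_material <- function(elastic_modulus, yield_stress, hardening = NULL) {
  stopifnot(elastic_modulus > 0, yield_stress > 0)
  if (is.null(hardening)) {
    hardening <- data.frame(plastic_strain = c(0, 0.4),
                            stress = c(yield_stress, yield_stress))
  }
  stopifnot(is.data.frame(hardening),
            all(c("plastic_strain", "stress") %in% names(hardening)))
  if (is.unsorted(hardening$stress)) stop("hardening stresses must be non-decreasing")
  if (abs(hardening$stress[1] - yield_stress) > 1e-9) {
    stop("hardening curve must start at the yield stress")
  }
  structure(list(elastic_modulus = elastic_modulus, yield_stress = yield_stress,
                 hardening = hardening),
            class = "alloy_material")
}

#' Mean hardening modulus of an alloy (secant slope of the hardening curve)
#' @param alloy An [alloy_material()].
#' @return Hardening modulus in MPa (0 for perfectly plastic).
#' @export
hardening_modulus <- function(alloy) {
  stopifnot(inherits(alloy, "alloy_material"))
  h <- alloy$hardening
  n <- nrow(h)
  if (n < 2 || h$plastic_strain[n] <= 0) return(0)
  (h$stress[n] - h$stress[1]) / (h$plastic_strain[n] - h$plastic_strain[1])
}

#' Semi-compliant balloon membrane material
#'
#' @param elastic_modulus Membrane elastic modulus in MPa (default 900).
#' @param thickness Membrane thickness in mm.
#' @return An object of class `balloon_material` with a linear
#'   stress-strain response.
#' @export
balloon_material <- function(elastic_modulus = 900, thickness = 0.05) {
  stopifnot(elastic_modulus > 0, thickness > 0)
  structure(list(elastic_modulus = elastic_modulus, thickness = thickness),
            class = "balloon_material")
}

#' Fit a reduced polynomial hyperelastic model to uniaxial data
#'
#' Least-squares fit of the reduced polynomial coefficients
#' \eqn{C_{i0}, i = 1..N} to `(stretch, nominal stress)` pairs along the
#' incompressible uniaxial path. The stress is linear in the coefficients,
#' so the fit is an ordinary linear least-squares solve.
#'
#' @param stretch Numeric vector of stretches (> 0, spanning values > 1).
#' @param stress Numeric vector of nominal stresses (MPa), same length.
#' @param order Polynomial order \eqn{N}.
#' @return A [hyperelastic_model()] with attribute `residual_norm` (the
#'   Euclidean norm of the stress residuals).
#' @export
fit_reduced_polynomial <- function(stretch, stress, order) {
  stopifnot(length(stretch) == length(stress), order >= 1)
  if (any(stretch <= 0)) stop("stretches must be strictly positive")
  if (length(unique(stretch)) < order + 1) {
    stop("need at least order + 1 distinct stretches to fit")
  }
  lam <- as.numeric(stretch)
  A <- lam^2 + 2 / lam - 3
  dA <- 2 * lam - 2 / lam^2
  X <- sapply(seq_len(order), function(i) i * .pow0(A, i - 1) * dA)
  X <- matrix(X, ncol = order)
  qrX <- qr(X)
  if (qrX$rank < order) stop("rank-deficient fit: data do not span the basis")
  coef <- qr.coef(qrX, stress)
  res <- stress - X %*% coef
  cf <- stats::setNames(as.numeric(coef), sprintf("C%d0", seq_len(order)))
  out <- hyperelastic_model(cf)
  attr(out, "residual_norm") <- sqrt(sum(res^2))
  out
}

# ---------------------------------------------------------------------------
# Default material catalog.
#
# The plaque categories share one base reduced-polynomial shape, scaled by a
# per-category multiplier; proportional scaling makes the tangent-stiffness
# ordering very_soft < soft < neutral < stiff < very_stiff hold at every
# strain by construction. All values are documented synthetic defaults
# shaped to the literature character of the tissues (lipid pools in the low
# kPa stiffness range, calcific plaque in the MPa range), not vendor or
# study-specific coefficients.
.plaque_base_coefficients <- c(C10 = 0.04, C20 = 0.60)
.plaque_multipliers <- c(
  very_soft = 0.08, soft = 0.35, neutral = 1.0, stiff = 4.0, very_stiff = 16.0
)
.normal_wall_coefficients <- c(
  C10 = 0.02, C20 = 0.09, C30 = 0.35, C40 = 0, C50 = 0, C60 = 1.5
)

#' Default material catalog
#'
#' Returns the package's default material parameter set for a category
#' label. Plaque categories (`very_soft` .. `very_stiff`) return a
#' [plaque_material()]; `normal_wall` returns the sixth-order reduced
#' polynomial wall model; `pt_cr` returns the stent alloy; `balloon`
#' returns the 900 MPa semi-compliant balloon membrane.
#'
#' All catalog values are documented package defaults (the study that
#' motivates them reports its coefficients only in an unavailable
#' supplement); they are constructed so that the plaque stiffness ordering
#' holds at every strain, and are overridable by constructing materials
#' directly.
#'
#' @param category One of `"very_soft"`, `"soft"`, `"neutral"`, `"stiff"`,
#'   `"very_stiff"`, `"normal_wall"`, `"pt_cr"`, `"balloon"`.
#' @return A material object of the class matching the category.
#' @export
material_catalog <- function(category) {
  stopifnot(is.character(category), length(category) == 1)
  if (category %in% plaque_categories()) {
    mult <- .plaque_multipliers[[category]]
    return(plaque_material(hyperelastic_model(.plaque_base_coefficients * mult),
                           category = category))
  }
  switch(category,
    normal_wall = hyperelastic_model(.normal_wall_coefficients),
    pt_cr = alloy_material(
      elastic_modulus = 203000, yield_stress = 480,
      hardening = data.frame(plastic_strain = c(0, 0.05, 0.2, 0.4),
                             stress = c(480, 600, 850, 1000))
    ),
    balloon = balloon_material(elastic_modulus = 900, thickness = 0.05),
    stop(sprintf("unknown material category '%s'", category))
  )
}

#' Serialize the material catalog to a YAML config file
#'
#' Writes the default catalog (category, order, coefficients, plasticity
#' onset) as structured text, so runs can be driven from an editable config.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_material_config <- function(path) {
  plq <- lapply(plaque_categories(), function(cat) {
    m <- material_catalog(cat)
    list(order = m$model$order,
         coefficients = as.list(stats::setNames(m$model$c,
                                                sprintf("C%d%d", m$model$i, m$model$j))),
         yield_strain = m$yield_strain)
  })
  names(plq) <- plaque_categories()
  wall <- material_catalog("normal_wall")
  alloy <- material_catalog("pt_cr")
  cfg <- list(
    plaque = plq,
    normal_wall = list(order = wall$order,
                       coefficients = as.list(stats::setNames(wall$c,
                                                              sprintf("C%d%d", wall$i, wall$j)))),
    pt_cr = list(elastic_modulus = alloy$elastic_modulus,
                 yield_stress = alloy$yield_stress,
                 hardening = list(plastic_strain = alloy$hardening$plastic_strain,
                                  stress = alloy$hardening$stress)),
    balloon = list(elastic_modulus = material_catalog("balloon")$elastic_modulus,
                   thickness = material_catalog("balloon")$thickness)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a material config written by [write_material_config()]
#'
#' @param path Config file path.
#' @return A named list of material objects (plaque categories, `normal_wall`,
#'   `pt_cr`, `balloon`).
#' @export
read_material_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  for (cat in names(cfg$plaque)) {
    p <- cfg$plaque[[cat]]
    out[[cat]] <- plaque_material(hyperelastic_model(unlist(p$coefficients)),
                                  category = cat, yield_strain = p$yield_strain)
  }
  out$normal_wall <- hyperelastic_model(unlist(cfg$normal_wall$coefficients))
  out$pt_cr <- alloy_material(cfg$pt_cr$elastic_modulus, cfg$pt_cr$yield_stress,
                              data.frame(plastic_strain = cfg$pt_cr$hardening$plastic_strain,
                                         stress = cfg$pt_cr$hardening$stress))
  out$balloon <- balloon_material(cfg$balloon$elastic_modulus, cfg$balloon$thickness)
  out
}

#' Export a uniaxial stress-stretch curve as CSV
#'
#' @param model A [hyperelastic_model()] or [plaque_material()].
#' @param path Output CSV path (columns `stretch`, `nominal_stress_MPa`).
#' @param stretches Stretch grid to evaluate.
#' @return `path`, invisibly.
#' @export
export_stress_strain_csv <- function(model, path,
                                     stretches = seq(1, 1.5, by = 0.01)) {
  stress <- if (inherits(model, "plaque_material")) {
    plaque_stress(model, stretches - 1)
  } else {
    uniaxial_stress(model, stretches)
  }
  readr::write_csv(tibble::tibble(stretch = stretches,
                                  nominal_stress_MPa = stress), path)
  invisible(path)
}
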