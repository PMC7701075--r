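## Cylinder hydrodynamics: frictional ratio, equivalent sphere, forward and
## inverse sedimentation-coefficient model for rigid circular cylinders.
## Internal computations are SI (m, s, kg m^-3, Pa s); exported interfaces
## speak nm and Svedberg (1 S = 1e-13 s), the field's units.

#' @useDynLib fibrilhydro, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

SVEDBERG <- 1e-13   # s
AVOGADRO <- 6.02214076e23
BOLTZMANN <- 1.380649e-23

#' Solvent conditions
#'
#' Density and viscosity of the aqueous phase entering the sedimentation
#' model. Defaults are water at 20 degrees C; dilute HCl at pH 2 is
#' indistinguishable at the precision of the model.
#'
#' @param density Solvent density in kg m^-3.
#' @param viscosity Dynamic viscosity in Pa s.
#' @param temperature Temperature in degrees C (informational; used only
#'   where thermal energy enters, e.g. diffusion coefficients).
#' @return An object of class `solvent_conditions`.
#' @export
#' @examples
#' solvent_conditions()
solvent_conditions <- function(density = 998.2, viscosity = 1.002e-3,
                               temperature = 20) {
  stopifnot(is.numeric(density), density > 0,
            is.numeric(viscosity), viscosity > 0)
  structure(list(density = density, viscosity = viscosity,
                 temperature = temperature),
            class = "solvent_conditions")
}

#' Fibril material properties
#'
#' Effective (hydrated, in-solution) density of the sedimenting fibril. The
#' default base density 1331.6 kg m^-3 is the inverse partial specific volume
#' of beta-lactoglobulin; the default densification factor 1.02 reflects the
#' ~2 % tighter packing of cross-beta fibril cores relative to the native
#' protein.
#'
#' @param base_density Density of the monomeric building block, kg m^-3.
#' @param densification Multiplicative densification factor (dimensionless).
#' @return An object of class `fibril_material` with an `effective_density`
#'   field equal to `base_density * densification`.
#' @export
#' @examples
#' fibril_material()$effective_density  # 1358.2 kg m^-3
fibril_material <- function(base_density = 1331.6, densification = 1.02) {
  stopifnot(is.numeric(base_density), base_density > 0,
            is.numeric(densification), densification > 0)
  structure(list(base_density = base_density,
                 densification = densification,
                 effective_density = base_density * densification),
            class = "fibril_material")
}

#' Cylinder geometry
#'
#' A rigid circular cylinder standing in for a fragmented fibril. The
#' cross-sectional diameter is called the height `h` (the quantity AFM
#' measures); the aspect ratio `q = l / h` and its logarithm `k = ln q` are
#' derived, never stored independently.
#'
#' @param length Cylinder length in metres.
#' @param height Cylinder diameter in metres.
#' @return An object of class `cylinder_geometry`.
#' @export
#' @examples
#' cylinder_geometry(500e-9, 4.7e-9)
cylinder_geometry <- function(length, height) {
  stopifnot(is.numeric(length), is.numeric(height))
  if (!all(is.finite(length)) || !all(is.finite(height)) ||
      any(length <= 0) || any(height <= 0))
    stop("cylinder length and height must be finite and > 0")
  q <- length / height
  if (any(q < 1))
    stop("aspect ratio q = length/height must be >= 1 (rods, not disks)")
  structure(list(length = length, height = height,
                 aspect_ratio = q, k = log(q)),
            class = "cylinder_geometry")
}

#' @export
print.cylinder_geometry <- function(x, ...) {
  cat(sprintf("cylinder: l = %.4g nm, h = %.4g nm, q = %.4g\n",
              x$length * 1e9, x$height * 1e9, x$aspect_ratio))
  invisible(x)
}

#' Frictional ratio of a circular cylinder
#'
#' Translational frictional ratio f/f0 of a rigid circular cylinder relative
#' to the equal-volume sphere, as a 7th-order polynomial in `k = ln(q)`
#' (Hansen's numerical solution for cylinders):
#' `f/f0 = 1.0304 + 0.0193 k + 0.06229 k^2 + 0.00476 k^3 + 0.00166 k^4 +
#' 2.66e-6 k^7`.
#'
#' @param q Aspect ratio length/diameter, dimensionless, `>= 1`. Vectorized.
#' @return Frictional ratio f/f0 (dimensionless, `>= 1.0304`).
#' @export
#' @examples
#' friction_ratio(1)      # 1.0304, the sphere-limit anchor
#' friction_ratio(100)    # approx 3.8
friction_ratio <- function(q) {
  if (!is.numeric(q) || !all(is.finite(q)))
    stop("aspect ratio q must be finite numeric")
  if (any(q < 1))
    stop("friction_ratio is only validated for rods (q >= 1), got q < 1")
  k <- log(q)
  1.0304 + 0.0193 * k + 0.06229 * k^2 + 0.00476 * k^3 +
    0.00166 * k^4 + 2.66e-6 * k^7
}

#' Equivalent-sphere diameter of a cylinder
#'
#' Diameter of the sphere with the same volume as the cylinder
#' (`pi h^2 l / 4 = pi d^3 / 6`), i.e. `d_eq = (3 h^2 l / 2)^(1/3)`,
#' equivalently `(3 h^3 q / 2)^(1/3)`.
#'
#' @param geom A [cylinder_geometry()] object, or a length in metres when
#'   `height` is given.
#' @param height Cylinder diameter in metres (only when `geom` is numeric).
#' @return Equivalent-sphere diameter in metres.
#' @export
#' @examples
#' equivalent_sphere_diameter(cylinder_geometry(500e-9, 4.7e-9)) * 1e9  # ~25.5 nm
equivalent_sphere_diameter <- function(geom, height = NULL) {
  if (is.numeric(geom)) geom <- cylinder_geometry(geom, height)
  (3 * geom$height^2 * geom$length / 2)^(1 / 3)
}

#' Sedimentation coefficient of a rigid cylinder
#'
#' Forward hydrodynamic model: `s = d_eq^2 (rho_Feff - rho_S) / (18 eta
#' f/f0)`, with the equivalent-sphere diameter from
#' [equivalent_sphere_diameter()] and the frictional ratio from
#' [friction_ratio()]. Strictly increasing in length at fixed height.
#'
#' @param length Fibril length in nm (vectorized).
#' @param height Fibril height (cylinder diameter) in nm.
#' @param material A [fibril_material()].
#' @param solvent A [solvent_conditions()].
#' @param unit `"S"` (Svedberg, default) or `"s"` (seconds).
#' @return Sedimentation coefficient, in Svedberg unless `unit = "s"`.
#'   Exactly 0 (with a warning) at neutral buoyancy.
#' @export
#' @examples
#' sedimentation_coefficient(500, 4.7)  # ~33.5 S
sedimentation_coefficient <- function(length, height,
                                      material = fibril_material(),
                                      solvent = solvent_conditions(),
                                      unit = c("S", "s")) {
  unit <- match.arg(unit)
  geom <- cylinder_geometry(length * 1e-9, height * 1e-9)
  drho <- material$effective_density - solvent$density
  if (drho == 0) {
    warning("neutral buoyancy: effective density equals solvent density, s = 0")
    return(if (length(geom$length) > 1) rep(0, length(geom$length)) else 0)
  }
  deq <- equivalent_sphere_diameter(geom)
  s <- deq^2 * drho / (18 * solvent$viscosity * friction_ratio(geom$aspect_ratio))
  if (unit == "S") s / SVEDBERG else s
}

#' Fibril length from a sedimentation coefficient
#'
#' Inverse of [sedimentation_coefficient()] at fixed height: the unique rod
#' length whose cylinder model sediments at `s`, found by bracketed root
#' search on the (monotone) forward model. The bracket starts at
#' `q in [1, 1e6]` and is expanded if needed; convergence tolerance is
#' 1e-12 relative on s.
#'
#' @param s Sedimentation coefficient in Svedberg (vectorized).
#' @param height Fibril height in nm.
#' @inheritParams sedimentation_coefficient
#' @return Fibril length in nm.
#' @export
#' @examples
#' length_from_s(33.5, 4.7)  # ~500 nm
length_from_s <- function(s, height, material = fibril_material(),
                          solvent = solvent_conditions()) {
  stopifnot(is.numeric(s), all(is.finite(s)))
  if (any(s <= 0)) stop("s must be > 0")
  s_min <- sedimentation_coefficient(height, height, material, solvent)
  if (any(s < s_min * (1 - 1e-12)))
    stop(sprintf(paste0("s = %.4g S below the q = 1 limit (%.4g S) at height ",
                        "%.4g nm: no rod solution"), min(s), s_min, height))
  vapply(s, function(si) {
    if (si <= s_min) return(height)
    lo <- height
    hi <- height * 1e6
    f <- function(l) sedimentation_coefficient(l, height, material, solvent) - si
    while (f(hi) < 0) {
      lo <- hi
      hi <- hi * 10
      if (hi > height * 1e12) stop("no bracket found for s = ", si, " S")
    }
    stats::uniroot(f, c(lo, hi), tol = 1e-12 * si * height)$root
  }, numeric(1))
}

#' Molar mass of a cylindrical fibril
#'
#' `M = rho * (pi/4) h^2 l * N_A`. Used to justify neglecting diffusion for
#' fibril-sized species: a 500 nm fibril with a 10 nm circular cross-section
#' at protein density is ~31 MDa.
#'
#' @param length Fibril length in nm (vectorized).
#' @param height Fibril height (diameter) in nm.
#' @param density Particle density in kg m^-3 (defaults to the inverse
#'   partial specific volume of beta-lactoglobulin).
#' @return Molar mass in Da.
#' @export
#' @examples
#' cylinder_molar_mass(500, 10) / 1e6  # ~31.5 MDa
#' cylinder_molar_mass(500, 5) / 1e6   # ~7.9 MDa
cylinder_molar_mass <- function(length, height, density = 1331.6) {
  stopifnot(is.numeric(length), is.numeric(height), density > 0,
            all(length >= 0), all(height > 0))
  volume <- pi / 4 * (height * 1e-9)^2 * (length * 1e-9)
  density * volume * AVOGADRO * 1e3   # kg/mol -> g/mol = Da
}
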