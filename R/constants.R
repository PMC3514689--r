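#' Volume-conductor and source-model constants
#'
#' Bundles the physical constants of the line-source SFP model: the radial
#' conductivity and anisotropy of the extracellular volume conductor, the
#' gain converting the diameter-scaled second spatial derivative of the
#' intracellular action potential (IAP) into source current, and the IAP
#' shape parameters.
#'
#' The IAP is a Rosenfalck-type waveform
#' \deqn{e(z) = A\,(\lambda z)^3 e^{-\lambda z} + B, \quad z \ge 0}
#' with axial coordinate `z` in mm, so that its depolarization peak sits at
#' `z = 3 / lambda` with the fixed peak value `A 27 e^{-3} + B` (about
#' 39 mV above zero for the defaults) regardless of the axial scale.
#'
#' The default `iap_scale_per_mm` (1.8 per mm) and `K` (5) are calibrated so
#' that the simulated negative-peak duration spans 0.4--1.4 ms across the
#' reference grid of fiber diameters 25--90 um and radial distances
#' 50--500 um, the published operating range of the method; `K = 5` is also
#' the standard axial-to-radial conductivity ratio for skeletal muscle.
#' The default `current_scale` is calibrated once so that the simulated SFP
#' for a 55 um fiber at 80 um radial distance has a peak-to-peak amplitude
#' of 1.357 mV at the default internal sampling step (0.002 ms); only the
#' product `current_scale / sigma_r` affects amplitudes.
#'
#' @param sigma_r Radial conductivity of the extracellular medium (S/m).
#' @param K Anisotropy factor multiplying \eqn{r^2} inside the weight
#'   function; depends on the ratio of axial to radial conductivity.
#' @param current_scale Gain applied to `diameter_um^2` times the second
#'   spatial derivative of the IAP (calibrated amplitude units).
#' @param iap_amplitude_mv IAP shape amplitude `A` (mV).
#' @param iap_resting_mv IAP resting level `B` (mV).
#' @param iap_scale_per_mm IAP axial scale `lambda` (1/mm); larger values
#'   compress the depolarization zone.
#' @param z_cap_mm Axial truncation of the convolution domain (mm).
#'
#' @return An object of class `sfp_constants` (a named list).
#' @seealso [simulate_sfp()], [fiber_scenario()]
#' @examples
#' cst <- model_constants()
#' cst$K
#' @export
model_constants <- function(sigma_r = 0.1,
                            K = 5,
                            current_scale = sfp_calibrated_current_scale,
                            iap_amplitude_mv = 96,
                            iap_resting_mv = -90,
                            iap_scale_per_mm = 1.8,
                            z_cap_mm = 50) {
  stopifnot(length(sigma_r) == 1L, length(K) == 1L, length(current_scale) == 1L)
  if (!is.finite(sigma_r) || sigma_r <= 0)
    stop("'sigma_r' must be a positive conductivity (S/m)", call. = FALSE)
  if (!is.finite(K) || K <= 0)
    stop("'K' must be a positive anisotropy factor", call. = FALSE)
  if (!is.finite(current_scale) || current_scale <= 0)
    stop("'current_scale' must be positive", call. = FALSE)
  if (!is.finite(iap_scale_per_mm) || iap_scale_per_mm <= 0)
    stop("'iap_scale_per_mm' must be positive", call. = FALSE)
  if (!is.finite(z_cap_mm) || z_cap_mm <= 0)
    stop("'z_cap_mm' must be positive", call. = FALSE)
  structure(
    list(sigma_r = sigma_r,
         K = K,
         current_scale = current_scale,
         iap_amplitude_mv = iap_amplitude_mv,
         iap_resting_mv = iap_resting_mv,
         iap_scale_per_mm = iap_scale_per_mm,
         z_cap_mm = z_cap_mm),
    class = "sfp_constants")
}

#' @export
print.sfp_constants <- function(x, ...) {
  cat("SFP model constants\n")
  cat(sprintf("  sigma_r        : %g S/m\n", x$sigma_r))
  cat(sprintf("  K (anisotropy) : %g\n", x$K))
  cat(sprintf("  current_scale  : %g\n", x$current_scale))
  cat(sprintf("  IAP            : %g*(%g z)^3 exp(-%g z) %+g mV (z in mm)\n",
              x$iap_amplitude_mv, x$iap_scale_per_mm, x$iap_scale_per_mm,
              x$iap_resting_mv))
  cat(sprintf("  z cap          : %g mm\n", x$z_cap_mm))
  invisible(x)
}

#' Physical scenario of one simulated fiber
#'
#' A fiber diameter and the radial (perpendicular) distance from the fiber
#' axis to the point recording electrode.  Diameters outside the reference
#' simulation range 25--90 um raise a warning (not an error); the electrode
#' cannot sit inside the fiber, so `radial_um` must be at least the fiber
#' radius.
#'
#' @param diameter_um Fiber diameter (um).
#' @param radial_um Radial fiber-to-electrode distance (um).
#' @return An object of class `sfp_scenario`.
#' @examples
#' fiber_scenario(55, 80)
#' @export
fiber_scenario <- function(diameter_um, radial_um) {
  stopifnot(length(diameter_um) == 1L, length(radial_um) == 1L)
  if (!is.finite(diameter_um) || diameter_um <= 0)
    stop("'diameter_um' must be positive", call. = FALSE)
  if (!is.finite(radial_um) || radial_um < diameter_um / 2)
    stop("'radial_um' must be at least the fiber radius (diameter_um / 2): ",
         "the electrode cannot be inside the fiber", call. = FALSE)
  if (diameter_um < 25 || diameter_um > 90)
    warning("diameter ", diameter_um,
            " um is outside the reference simulation range 25-90 um",
            call. = FALSE)
  structure(list(diameter_um = diameter_um, radial_um = radial_um),
            class = "sfp_scenario")
}

#' @export
print.sfp_scenario <- function(x, ...) {
  cat(sprintf("Fiber scenario: diameter %g um, radial distance %g um (v = %g m/s)\n",
              x$diameter_um, x$radial_um, conduction_velocity(x$diameter_um)))
  invisible(x)
}

#' Muscle fiber conduction velocity from diameter
#'
#' Linear diameter-velocity relation
#' \deqn{v = 2.2 + 0.05\,(d - 25)}
#' with `d` in um and `v` in m/s (equivalently mm/ms), anchored at 2.2 m/s
#' for a 25 um fiber.
#'
#' @param diameter_um Fiber diameter(s), um; must be positive.
#' @return Conduction velocity in m/s.
#' @examples
#' conduction_velocity(c(25, 55, 90))
#' @export
conduction_velocity <- function(diameter_um) {
  if (length(diameter_um) == 0L || !all(is.finite(diameter_um)) ||
      any(diameter_um <= 0))
    stop("'diameter_um' must be positive and finite", call. = FALSE)
  2.2 + 0.05 * (diameter_um - 25)
}
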