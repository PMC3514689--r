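#' Simulate a grid of scenarios and extract their features
#'
#' Runs the forward simulator over a diameter-by-distance grid and
#' measures the feature pair of each waveform.  The defaults reproduce the
#' reference fitting grid: diameters 25--90 um in 5 um steps crossed with
#' radial distances 50--500 um in 25 um steps (266 scenarios).
#'
#' @param diameters_um Vector of fiber diameters (um).
#' @param radii_um Vector of radial distances (um).
#' @param constants A [model_constants()] object.
#' @param dt_ms Internal sampling interval (ms).
#' @return A data frame with columns `diameter_um`, `radial_um`,
#'   `amplitude_mv`, `tz_ms`.
#' @examples
#' \donttest{
#' g <- simulate_feature_grid(c(30, 60, 90), c(50, 200, 400))
#' }
#' @export
simulate_feature_grid <- function(diameters_um = seq(25, 90, by = 5),
                                  radii_um = seq(50, 500, by = 25),
                                  constants = model_constants(),
                                  dt_ms = 0.002) {
  grid <- expand.grid(diameter_um = diameters_um, radial_um = radii_um,
                      KEEP.OUT.ATTRS = FALSE)
  fe <- mapply(function(d, r) {
    w <- simulate_sfp(fiber_scenario(d, r), constants, dt_ms = dt_ms)
    c(measure_amplitude(w), as.numeric(measure_negative_peak_duration(w)))
  }, grid$diameter_um, grid$radial_um)
  grid$amplitude_mv <- fe[1, ]
  grid$tz_ms <- fe[2, ]
  grid
}

# least-squares fit of one bi-quadratic surface tz ~ sum c_jk x^(k-1) y^(j-1).
# x is centered for conditioning; the shift is folded back into the
# returned raw-x coefficients.
fit_one_surface <- function(x, y, tz) {
  mu <- mean(x)
  xc <- x - mu
  design <- outer(seq_along(x), 1:9, function(i, m) {
    j <- (m - 1) %/% 3 + 1
    k <- (m - 1) %% 3 + 1
    xc[i]^(k - 1) * y[i]^(j - 1)
  })
  qrd <- qr(design, LAPACK = TRUE)
  if (qr(design)$rank < 9L)
    stop("singular fit: the feature grid does not span the 9-term ",
         "bi-quadratic basis (need >= 3 distinct log-amplitudes and >= 3 ",
         "distinct y values with full rank)", call. = FALSE)
  b <- qr.solve(qrd, tz)
  bm <- matrix(b, nrow = 3, byrow = TRUE)   # [j, k] in centered x
  # de-center: c1 + c2 (x - mu) + c3 (x - mu)^2 -> raw-x coefficients
  raw <- cbind(bm[, 1] - bm[, 2] * mu + bm[, 3] * mu^2,
               bm[, 2] - 2 * bm[, 3] * mu,
               bm[, 3])
  fitted <- design %*% b
  list(c_jk = raw, residuals = tz - as.numeric(fitted))
}

#' Fit the bi-quadratic surfaces to a feature grid
#'
#' Standard linear least squares of the negative-peak duration on the
#' 9-term basis \eqn{x^p y^q,\ p,q \in \{0,1,2\}} with
#' `x = log10(amplitude)` and `y` the diameter (surface 1) or radial
#' distance (surface 2).  Residual diagnostics (mean absolute and RMS `tz`
#' residual per surface) are stored in the returned model.
#'
#' @param feature_grid Data frame with columns `diameter_um`, `radial_um`,
#'   `amplitude_mv`, `tz_ms` (at least 9 rows spanning both axes), as
#'   produced by [simulate_feature_grid()].
#' @return An [biquadratic_model()] with `source = "refit"`.
#' @examples
#' \donttest{
#' g <- simulate_feature_grid(seq(25, 90, 15), seq(50, 500, 100))
#' m <- fit_surfaces(g)
#' }
#' @export
fit_surfaces <- function(feature_grid) {
  need <- c("diameter_um", "radial_um", "amplitude_mv", "tz_ms")
  if (!all(need %in% names(feature_grid)))
    stop("'feature_grid' must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(feature_grid) < 9L)
    stop("at least 9 feature tuples are required to fit the 9-term basis",
         call. = FALSE)
  if (any(feature_grid$amplitude_mv <= 0) || any(feature_grid$tz_ms <= 0))
    stop("amplitudes and durations must be positive", call. = FALSE)
  x <- log10(feature_grid$amplitude_mv)
  f1 <- fit_one_surface(x, feature_grid$diameter_um, feature_grid$tz_ms)
  f2 <- fit_one_surface(x, feature_grid$radial_um, feature_grid$tz_ms)
  cc <- array(NA_real_, dim = c(2, 3, 3))
  cc[1, , ] <- f1$c_jk
  cc[2, , ] <- f2$c_jk
  biquadratic_model(
    cc,
    valid_d_range = range(feature_grid$diameter_um),
    valid_r_range = range(feature_grid$radial_um),
    residuals = list(
      mean_abs = c(mean(abs(f1$residuals)), mean(abs(f2$residuals))),
      rms = c(sqrt(mean(f1$residuals^2)), sqrt(mean(f2$residuals^2)))),
    source = "refit")
}

#' Round-trip inversion error over a scenario grid
#'
#' For every scenario: simulate the SFP, measure `(a, tz)`, invert both
#' surfaces, and record the estimation errors against the simulated ground
#' truth.  Solver failures are recorded per scenario (flag column) rather
#' than aborting; summary statistics are computed over the solved
#' scenarios.
#'
#' @param model An [biquadratic_model()] used for the inversion.
#' @param scenario_grid Data frame with columns `diameter_um`, `radial_um`;
#'   if it already carries `amplitude_mv` and `tz_ms` columns (e.g. from
#'   [simulate_feature_grid()]) the simulation step is skipped.
#' @param constants,dt_ms Forward-model settings used when simulating.
#' @return A list of class `sfp_error_report`: `per_scenario` (data frame
#'   with errors and flags), `rms_d_um`, `rms_r_um`, `max_abs_d_um`,
#'   `max_abs_r_um`, `n_failed_d`, `n_failed_r`.
#' @examples
#' \donttest{
#' g <- simulate_feature_grid(seq(25, 90, 15), seq(50, 500, 100))
#' rep <- evaluate_inversion_error(fit_surfaces(g), g)
#' rep$rms_d_um
#' }
#' @export
evaluate_inversion_error <- function(model, scenario_grid,
                                     constants = model_constants(),
                                     dt_ms = 0.002) {
  stopifnot(inherits(model, "sfp_biquadratic"))
  if (!all(c("amplitude_mv", "tz_ms") %in% names(scenario_grid)))
    scenario_grid <- simulate_feature_grid(
      diameters_um = unique(scenario_grid$diameter_um),
      radii_um = unique(scenario_grid$radial_um),
      constants = constants, dt_ms = dt_ms)
  inv <- invert_features(model, scenario_grid$amplitude_mv,
                         scenario_grid$tz_ms)
  per <- data.frame(scenario_grid,
                    d_est_um = inv$diameter_um,
                    r_est_um = inv$radial_um,
                    d_error_um = inv$diameter_um - scenario_grid$diameter_um,
                    r_error_um = inv$radial_um - scenario_grid$radial_um,
                    flag = inv$flag)
  structure(list(
    per_scenario = per,
    rms_d_um = sqrt(mean(per$d_error_um^2, na.rm = TRUE)),
    rms_r_um = sqrt(mean(per$r_error_um^2, na.rm = TRUE)),
    max_abs_d_um = max(abs(per$d_error_um), na.rm = TRUE),
    max_abs_r_um = max(abs(per$r_error_um), na.rm = TRUE),
    n_failed_d = sum(is.na(per$d_error_um)),
    n_failed_r = sum(is.na(per$r_error_um)),
    n = nrow(per)),
    class = "sfp_error_report")
}

#' @export
print.sfp_error_report <- function(x, ...) {
  cat(sprintf("Inversion error over %d scenarios\n", x$n))
  cat(sprintf("  diameter: RMS %.3g um, max |err| %.3g um (%d unsolved)\n",
              x$rms_d_um, x$max_abs_d_um, x$n_failed_d))
  cat(sprintf("  distance: RMS %.3g um, max |err| %.3g um (%d unsolved)\n",
              x$rms_r_um, x$max_abs_r_um, x$n_failed_r))
  invisible(x)
}
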