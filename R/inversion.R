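#' Bi-quadratic feature-surface model
#'
#' The negative-peak duration is modelled as two bi-quadratic surfaces of
#' the log-amplitude `x = log10(a / 1 mV)` and a geometric variable `y`:
#' \deqn{t_z = F_i(x, y) = e_{i,1} + y (e_{i,2} + y e_{i,3}),\qquad
#'       e_{i,j} = c_{i,j,1} + x (c_{i,j,2} + x c_{i,j,3})}
#' with `y` the fiber diameter `d` (um) for surface `i = 1` and the radial
#' electrode distance `r` (um) for `i = 2`.  Because each surface is
#' quadratic in `y`, it can be solved in closed form for the diameter or
#' the distance given a measured feature pair `(a, tz)`.
#'
#' Amplitudes are in mV by construction of the coefficient sets; inputs in
#' uV must be converted by the caller.
#'
#' @param coefficients Numeric array of dimension `c(2, 3, 3)` holding
#'   `c[i, j, k]`.
#' @param valid_d_range,valid_r_range Nominal geometric ranges (um) over
#'   which the surfaces were fitted.
#' @param residuals Optional fit diagnostics (stored by [fit_surfaces()]).
#' @param source Character tag, e.g. `"published"` or `"refit"`.
#' @return An object of class `sfp_biquadratic`.
#' @seealso [published_coefficients()], [fit_surfaces()], [solve_diameter()]
#' @export
biquadratic_model <- function(coefficients,
                              valid_d_range = c(25, 90),
                              valid_r_range = c(50, 500),
                              residuals = NULL,
                              source = "custom") {
  coefficients <- as.array(coefficients)
  if (!identical(dim(coefficients), c(2L, 3L, 3L)) ||
      !all(is.finite(coefficients)))
    stop("'coefficients' must be a finite numeric array of dimension 2 x 3 x 3 ",
         "(18 coefficients, both surfaces)", call. = FALSE)
  dimnames(coefficients) <- list(i = c("1", "2"), j = as.character(1:3),
                                 k = as.character(1:3))
  structure(list(c = coefficients,
                 amplitude_unit = "mV",
                 valid_d_range = valid_d_range,
                 valid_r_range = valid_r_range,
                 residuals = residuals,
                 source = source),
            class = "sfp_biquadratic")
}

#' @export
print.sfp_biquadratic <- function(x, ...) {
  cat(sprintf("Bi-quadratic SFP feature model (%s)\n", x$source))
  cat(sprintf("  valid d range: %g-%g um, valid r range: %g-%g um\n",
              x$valid_d_range[1], x$valid_d_range[2],
              x$valid_r_range[1], x$valid_r_range[2]))
  if (!is.null(x$residuals))
    cat(sprintf("  tz residuals: mean|res| F1 = %.3g, F2 = %.3g ms; RMS F1 = %.3g, F2 = %.3g ms\n",
                x$residuals$mean_abs[1], x$residuals$mean_abs[2],
                x$residuals$rms[1], x$residuals$rms[2]))
  invisible(x)
}

#' Published coefficient set
#'
#' The 18 printed coefficients of the two bi-quadratic surfaces, exactly as
#' published (4 significant figures, E-notation).  Surface 1 maps
#' `(log10 a, d)` to `tz`; surface 2 maps `(log10 a, r)` to `tz`.  The same
#' values are bundled as a plain-text JSON file in
#' `system.file("extdata", "published_coefficients.json", package = "sfpdiam")`.
#'
#' @return An [biquadratic_model()] with `source = "published"`.
#' @examples
#' m <- published_coefficients()
#' m$c["1", "1", "1"]   # 9.5100e-01
#' @export
published_coefficients <- function() {
  cc <- array(NA_real_, dim = c(2, 3, 3))
  # c[1, j, k]: surface tz = F1(log10 a, d)
  cc[1, 1, ] <- c(9.5100e-01, -2.2321e-01, 2.0358e-01)
  cc[1, 2, ] <- c(-7.3845e-03, 3.4212e-04, -1.6564e-03)
  cc[1, 3, ] <- c(2.5574e-05, -3.3074e-06, 6.4493e-06)
  # c[2, j, k]: surface tz = F2(log10 a, r)
  cc[2, 1, ] <- c(8.3844e-01, -5.1557e-01, 8.8151e-02)
  cc[2, 2, ] <- c(-2.4920e-03, -1.9468e-04, 3.2125e-04)
  cc[2, 3, ] <- c(3.4911e-06, 1.9169e-06, 3.2255e-07)
  biquadratic_model(cc, residuals = list(
    # published mean errors of the tz fit for the two surfaces (ms)
    mean_abs = c(5e-3, 3e-3), rms = c(NA_real_, NA_real_)),
    source = "published")
}

# quadratic-in-x coefficients e_{i,1..3} at a given log-amplitude
surface_e <- function(model, which_i, x) {
  cc <- model$c
  vapply(1:3, function(j)
    cc[which_i, j, 1] + x * (cc[which_i, j, 2] + x * cc[which_i, j, 3]),
    numeric(length(x)))
}

#' Evaluate a feature surface
#'
#' Computes the modelled negative-peak duration `tz = F_i(log10(a), y)`.
#'
#' @param model An [biquadratic_model()].
#' @param which_i Surface index: 1 (y = diameter) or 2 (y = radial
#'   distance).
#' @param amplitude_mv Peak-to-peak amplitude (mV), positive.
#' @param y Geometric variable (um): diameter for surface 1, radial
#'   distance for surface 2.
#' @return Modelled `tz` (ms); vectorized over `amplitude_mv` and `y`.
#' @examples
#' evaluate_surface(published_coefficients(), 1, 1.357, 55.7)  # ~0.593
#' @export
evaluate_surface <- function(model, which_i, amplitude_mv, y) {
  stopifnot(inherits(model, "sfp_biquadratic"), which_i %in% c(1, 2))
  if (any(!is.finite(amplitude_mv)) || any(amplitude_mv <= 0))
    stop("'amplitude_mv' must be positive (amplitude in mV)", call. = FALSE)
  x <- log10(amplitude_mv)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  e <- surface_e(model, which_i, x)
  e <- matrix(e, nrow = n)
  e[, 1] + y * (e[, 2] + y * e[, 3])
}

# closed-form solve of e3 y^2 + e2 y + (e1 - tz) = 0 with root selection.
# nominal: the fitted physiological range; margin extends it before a hard
# out-of-range error.
solve_surface <- function(model, which_i, amplitude_mv, tz_ms,
                          nominal, margin = 40) {
  if (!is.finite(amplitude_mv) || amplitude_mv <= 0)
    stop("'amplitude_mv' must be positive (amplitude in mV)", call. = FALSE)
  if (!is.finite(tz_ms) || tz_ms <= 0)
    stop("'tz_ms' must be positive", call. = FALSE)
  x <- log10(amplitude_mv)
  e <- as.numeric(surface_e(model, which_i, x))
  c0 <- e[1] - tz_ms
  what <- if (which_i == 1) "diameter" else "radial distance"
  if (abs(e[3]) < .Machine$double.eps * max(1, abs(e[2]))) {
    # degenerate quadratic: linear solution
    if (abs(e[2]) < .Machine$double.eps)
      stop("surface is constant in y; no ", what, " solution", call. = FALSE)
    roots <- (tz_ms - e[1]) / e[2]
    disc <- NA_real_
  } else {
    disc <- e[2]^2 - 4 * e[3] * c0
    if (disc < 0)
      stop(sprintf("no real %s solution: negative discriminant (%.3g) at a = %g mV, tz = %g ms",
                   what, disc, amplitude_mv, tz_ms), call. = FALSE)
    roots <- (-e[2] + c(-1, 1) * sqrt(disc)) / (2 * e[3])
  }
  admissible <- c(nominal[1] - margin, nominal[2] + margin)
  ok <- roots >= admissible[1] & roots <= admissible[2]
  if (!any(ok))
    stop(sprintf("both %s roots (%.4g, %.4g um) fall outside the admissible range [%g, %g] um",
                 what, roots[1], roots[length(roots)],
                 admissible[1], admissible[2]), call. = FALSE)
  cand <- roots[ok]
  ambiguous <- FALSE
  if (length(cand) > 1L) {
    in_nom <- cand >= nominal[1] & cand <= nominal[2]
    if (sum(in_nom) == 1L) {
      cand <- cand[in_nom]
    } else {
      ambiguous <- TRUE
      cand <- cand[which.min(abs(cand - mean(nominal)))]
    }
  }
  list(value = cand,
       roots = roots,
       discriminant = disc,
       e = e,
       in_range = cand >= nominal[1] && cand <= nominal[2],
       ambiguous = ambiguous)
}

#' Solve a feature pair for fiber diameter or radial distance
#'
#' Closed-form inversion of the bi-quadratic surfaces: given a measured
#' amplitude and negative-peak duration, solves the quadratic
#' \eqn{e_{i,3} y^2 + e_{i,2} y + (e_{i,1} - t_z) = 0} for `y`.  The root
#' inside the admissible physiological range is selected; if both roots are
#' admissible the one nearer the nominal range midpoint is chosen and the
#' result is flagged ambiguous.  The admissible range is the nominal fitted
#' range widened by `margin` on each side (estimates slightly beyond the
#' fitted grid remain usable, with `in_range = FALSE`).
#'
#' @param model An [biquadratic_model()].
#' @param amplitude_mv Measured peak-to-peak amplitude (mV), positive.
#' @param tz_ms Measured negative-peak duration (ms), positive.
#' @param margin Soft margin (um) beyond the nominal range before a hard
#'   out-of-range error.
#' @return A list of class `sfp_solve`: `value` (um), `roots` (both
#'   quadratic roots), `discriminant`, `e` (the quadratic coefficients
#'   used), `in_range`, `ambiguous`.
#' @examples
#' m <- published_coefficients()
#' solve_diameter(m, 1.357, 0.593)$value   # 55.7 um
#' solve_radius(m, 1.357, 0.593)$value     # 80.9 um
#' @export
solve_diameter <- function(model, amplitude_mv, tz_ms, margin = 40) {
  stopifnot(inherits(model, "sfp_biquadratic"))
  out <- solve_surface(model, 1L, amplitude_mv, tz_ms,
                       nominal = model$valid_d_range, margin = margin)
  structure(c(out, list(quantity = "diameter_um")), class = "sfp_solve")
}

#' @rdname solve_diameter
#' @export
solve_radius <- function(model, amplitude_mv, tz_ms, margin = 40) {
  stopifnot(inherits(model, "sfp_biquadratic"))
  out <- solve_surface(model, 2L, amplitude_mv, tz_ms,
                       nominal = model$valid_r_range, margin = margin)
  structure(c(out, list(quantity = "radial_um")), class = "sfp_solve")
}

#' @export
print.sfp_solve <- function(x, ...) {
  cat(sprintf("%s = %.4g um (roots %.4g / %.4g, discriminant %.3g)%s%s\n",
              x$quantity, x$value, x$roots[1], x$roots[length(x$roots)],
              x$discriminant,
              if (!x$in_range) " [outside nominal range]" else "",
              if (x$ambiguous) " [ambiguous root choice]" else ""))
  invisible(x)
}

#' Batch inversion of feature pairs
#'
#' Vectorized inversion of many `(amplitude, tz)` pairs.  Solver failures
#' (negative discriminant, out-of-range roots) are flagged per row instead
#' of aborting.
#'
#' @inheritParams solve_diameter
#' @param amplitude_mv,tz_ms Numeric vectors of equal length.
#' @return A data frame with columns `amplitude_mv`, `tz_ms`,
#'   `diameter_um`, `radial_um`, `d_in_range`, `r_in_range`, `flag`
#'   (empty string when both solves succeed).
#' @examples
#' invert_features(published_coefficients(), c(1.357, 0.7), c(0.593, 0.6))
#' @export
invert_features <- function(model, amplitude_mv, tz_ms, margin = 40) {
  stopifnot(inherits(model, "sfp_biquadratic"),
            length(amplitude_mv) == length(tz_ms))
  n <- length(amplitude_mv)
  out <- data.frame(amplitude_mv = amplitude_mv, tz_ms = tz_ms,
                    diameter_um = NA_real_, radial_um = NA_real_,
                    d_in_range = NA, r_in_range = NA,
                    flag = character(n))
  for (i in seq_len(n)) {
    flags <- character(0)
    sd <- tryCatch(solve_diameter(model, amplitude_mv[i], tz_ms[i], margin),
                   error = function(e) e)
    if (inherits(sd, "error")) {
      flags <- c(flags, paste0("d: ", conditionMessage(sd)))
    } else {
      out$diameter_um[i] <- sd$value
      out$d_in_range[i] <- sd$in_range
    }
    sr <- tryCatch(solve_radius(model, amplitude_mv[i], tz_ms[i], margin),
                   error = function(e) e)
    if (inherits(sr, "error")) {
      flags <- c(flags, paste0("r: ", conditionMessage(sr)))
    } else {
      out$radial_um[i] <- sr$value
      out$r_in_range[i] <- sr$in_range
    }
    out$flag[i] <- paste(flags, collapse = "; ")
  }
  out
}

#' Sensitivity of the inversion to measurement errors
#'
#' Re-solves the inversion at the four signed single-axis perturbations of
#' the base feature pair (`a +/- delta_a`, `tz +/- delta_tz`) and reports
#' the resulting changes in estimated diameter and radial distance.  The
#' defaults are the assumed measurement errors of a clinical recording:
#' +/-20 uV for amplitude and +/-0.04 ms for duration (one sample at
#' 25 kHz).
#'
#' @inheritParams solve_diameter
#' @param delta_a_mv Amplitude perturbation (mV).
#' @param delta_tz_ms Duration perturbation (ms).
#' @return A list of class `sfp_sensitivity`: `base` (the unperturbed
#'   solution), `table` (per-perturbation changes; `NA` where a perturbed
#'   point is unsolvable, with the failure message in `note`),
#'   `max_dd_amplitude`, `max_dd_duration`, `max_dr_amplitude`,
#'   `max_dr_duration` (um).
#' @examples
#' s <- sensitivity(published_coefficients(), 1.357, 0.593)
#' s$max_dd_duration   # ~8-9 um
#' s$max_dd_amplitude  # < 0.3 um
#' @export
sensitivity <- function(model, amplitude_mv, tz_ms,
                        delta_a_mv = 0.020, delta_tz_ms = 0.04, margin = 40) {
  stopifnot(inherits(model, "sfp_biquadratic"))
  base_d <- solve_diameter(model, amplitude_mv, tz_ms, margin)
  base_r <- solve_radius(model, amplitude_mv, tz_ms, margin)
  pert <- data.frame(
    da = c(delta_a_mv, -delta_a_mv, 0, 0),
    dtz = c(0, 0, delta_tz_ms, -delta_tz_ms))
  pert$delta_d <- NA_real_
  pert$delta_r <- NA_real_
  pert$note <- ""
  for (i in seq_len(nrow(pert))) {
    a <- amplitude_mv + pert$da[i]
    tz <- tz_ms + pert$dtz[i]
    sd <- tryCatch(solve_diameter(model, a, tz, margin), error = function(e) e)
    sr <- tryCatch(solve_radius(model, a, tz, margin), error = function(e) e)
    if (inherits(sd, "error"))
      pert$note[i] <- paste0("d: ", conditionMessage(sd))
    else pert$delta_d[i] <- sd$value - base_d$value
    if (inherits(sr, "error"))
      pert$note[i] <- paste(pert$note[i], "r:", conditionMessage(sr))
    else pert$delta_r[i] <- sr$value - base_r$value
  }
  safe_max <- function(v) if (all(is.na(v))) NA_real_ else max(abs(v),
                                                               na.rm = TRUE)
  amp_rows <- 1:2   # rows 3:4 perturb the duration
  structure(list(
    base = list(diameter_um = base_d$value, radial_um = base_r$value,
                amplitude_mv = amplitude_mv, tz_ms = tz_ms),
    table = pert,
    max_dd_amplitude = safe_max(pert$delta_d[amp_rows]),
    max_dd_duration = safe_max(pert$delta_d[-amp_rows]),
    max_dr_amplitude = safe_max(pert$delta_r[amp_rows]),
    max_dr_duration = safe_max(pert$delta_r[-amp_rows])),
    class = "sfp_sensitivity")
}

#' @export
print.sfp_sensitivity <- function(x, ...) {
  cat(sprintf("Sensitivity at a = %g mV, tz = %g ms (d = %.4g um, r = %.4g um)\n",
              x$base$amplitude_mv, x$base$tz_ms,
              x$base$diameter_um, x$base$radial_um))
  cat(sprintf("  max |delta d|: %.3g um (amplitude), %.3g um (duration)\n",
              x$max_dd_amplitude, x$max_dd_duration))
  cat(sprintf("  max |delta r|: %.3g um (amplitude), %.3g um (duration)\n",
              x$max_dr_amplitude, x$max_dr_duration))
  invisible(x)
}

#' Read and write bi-quadratic models as JSON
#'
#' Stores the 18 coefficients as explicit `(i, j, k, value)` triplets
#' (value both as full-precision float and as E-notation string), the
#' nominal ranges and fit diagnostics.
#'
#' @param model An [biquadratic_model()].
#' @param path File path.
#' @return `read_model_json` returns an `sfp_biquadratic`; the writer
#'   returns the path invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "sfp_biquadratic"))
  idx <- expand.grid(i = 1:2, j = 1:3, k = 1:3)
  triplets <- lapply(seq_len(nrow(idx)), function(n) {
    v <- model$c[idx$i[n], idx$j[n], idx$k[n]]
    list(i = idx$i[n], j = idx$j[n], k = idx$k[n],
         value = v, printed = sprintf("%.4E", v))
  })
  payload <- list(model = "biquadratic tz surfaces",
                  amplitude_unit = model$amplitude_unit,
                  valid_d_range = model$valid_d_range,
                  valid_r_range = model$valid_r_range,
                  source = model$source,
                  residuals = model$residuals,
                  coefficients = triplets)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cc <- array(NA_real_, dim = c(2, 3, 3))
  co <- obj$coefficients
  for (n in seq_len(nrow(co)))
    cc[co$i[n], co$j[n], co$k[n]] <- co$value[n]
  res <- obj$residuals
  if (!is.null(res)) res <- lapply(res, as.numeric)
  biquadratic_model(cc,
                    valid_d_range = as.numeric(obj$valid_d_range),
                    valid_r_range = as.numeric(obj$valid_r_range),
                    residuals = res,
                    source = obj$source %||% "file")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
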