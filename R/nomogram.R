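#' Iso-feature curves in the diameter-distance plane
#'
#' An iso-duration curve collects, for each diameter on a grid, the radial
#' distance at which the negative-peak duration equals a fixed level; an
#' iso-amplitude curve does the same for the peak-to-peak amplitude.  The
#' two families together form the graphical estimation tool: the
#' intersection of the measured amplitude's curve with the measured
#' duration's curve reads off the fiber diameter and radial distance.
#'
#' With `source = "simulator"` (the default, ground truth) each point is
#' found by 1-D root bracketing on the monotone radial profile of the
#' feature at fixed diameter.  A fitted or published [biquadratic_model()]
#' may be passed instead, in which case the curve is generated in closed
#' form from the parametric representation (solve both surfaces over a
#' sweep of the complementary feature) -- much faster, but only as accurate
#' as the surface fit.
#'
#' @param source `"simulator"` or an [biquadratic_model()].
#' @param level_ms Duration level (ms) for [iso_duration_curve()].
#' @param level_mv Amplitude level (mV) for [iso_amplitude_curve()].
#' @param diameters_um Diameter grid over which the curve is traced
#'   (simulator source).
#' @param r_range_um Radial search interval (um).
#' @param tol_um Root tolerance in `r` (um), simulator source.
#' @param constants,dt_ms Forward-model settings (simulator source).
#' @param sweep_n Number of sweep points (model source).
#' @return A list of class `sfp_isocurve`: `kind`, `level`, `points` (data
#'   frame `diameter_um`, `radial_um`, ordered by diameter).  Diameters
#'   with no in-range solution are omitted; an entirely empty curve is
#'   returned with a warning.
#' @examples
#' m <- published_coefficients()
#' curve_a <- iso_amplitude_curve(m, 0.7)
#' curve_tz <- iso_duration_curve(m, 0.6)
#' curve_intersection(curve_a, curve_tz)
#' @export
iso_duration_curve <- function(source = "simulator", level_ms,
                               diameters_um = seq(25, 90, by = 1),
                               r_range_um = c(50, 500), tol_um = 0.1,
                               constants = model_constants(), dt_ms = 0.002,
                               sweep_n = 200) {
  iso_curve_impl(source, "constant_duration", level_ms, diameters_um,
                 r_range_um, tol_um, constants, dt_ms, sweep_n)
}

#' @rdname iso_duration_curve
#' @export
iso_amplitude_curve <- function(source = "simulator", level_mv,
                                diameters_um = seq(25, 90, by = 1),
                                r_range_um = c(50, 500), tol_um = 0.1,
                                constants = model_constants(), dt_ms = 0.002,
                                sweep_n = 200) {
  iso_curve_impl(source, "constant_amplitude", level_mv, diameters_um,
                 r_range_um, tol_um, constants, dt_ms, sweep_n)
}

iso_curve_impl <- function(source, kind, level, diameters_um, r_range_um,
                           tol_um, constants, dt_ms, sweep_n) {
  if (!is.finite(level) || level <= 0)
    stop("'level' must be positive", call. = FALSE)
  pts <- if (inherits(source, "sfp_biquadratic"))
    iso_curve_from_model(source, kind, level, diameters_um, r_range_um,
                         sweep_n)
  else if (identical(source, "simulator"))
    iso_curve_from_simulator(kind, level, diameters_um, r_range_um, tol_um,
                             constants, dt_ms)
  else stop("'source' must be \"simulator\" or a biquadratic model",
            call. = FALSE)
  if (nrow(pts) == 0L)
    warning(sprintf("empty %s curve at level %g: no in-range solutions",
                    kind, level), call. = FALSE)
  structure(list(kind = kind, level = level, points = pts),
            class = "sfp_isocurve")
}

iso_curve_from_simulator <- function(kind, level, diameters_um, r_range_um,
                                     tol_um, constants, dt_ms) {
  feature_at <- function(d, r) {
    w <- simulate_sfp(fiber_scenario(d, r), constants, dt_ms = dt_ms)
    if (kind == "constant_duration")
      as.numeric(measure_negative_peak_duration(w))
    else measure_amplitude(w)
  }
  rows <- lapply(diameters_um, function(d) {
    lo <- max(r_range_um[1], d / 2)
    f_lo <- feature_at(d, lo) - level
    f_hi <- feature_at(d, r_range_um[2]) - level
    if (sign(f_lo) == sign(f_hi)) return(NULL)   # level unreachable at this d
    root <- stats::uniroot(function(r) feature_at(d, r) - level,
                           lower = lo, upper = r_range_um[2],
                           f.lower = f_lo, f.upper = f_hi,
                           tol = tol_um)$root
    data.frame(diameter_um = d, radial_um = root)
  })
  pts <- do.call(rbind, rows)
  if (is.null(pts))
    pts <- data.frame(diameter_um = numeric(0), radial_um = numeric(0))
  row.names(pts) <- NULL
  pts
}

# parametric generation from the fitted surfaces: fix one feature at the
# level, sweep the other, solve both quadratics -> (d(s), r(s))
iso_curve_from_model <- function(model, kind, level, diameters_um,
                                 r_range_um, sweep_n) {
  if (kind == "constant_duration") {
    sweep <- 10^seq(log10(0.03), log10(8), length.out = sweep_n)  # amplitude mV
    a <- sweep; tz <- rep(level, sweep_n)
  } else {
    sweep <- seq(0.2, 2.0, length.out = sweep_n)                   # tz ms
    a <- rep(level, sweep_n); tz <- sweep
  }
  inv <- invert_features(model, a, tz)
  ok <- !is.na(inv$diameter_um) & !is.na(inv$radial_um) &
    inv$diameter_um >= min(diameters_um) &
    inv$diameter_um <= max(diameters_um) &
    inv$radial_um >= r_range_um[1] & inv$radial_um <= r_range_um[2]
  pts <- data.frame(diameter_um = inv$diameter_um[ok],
                    radial_um = inv$radial_um[ok])
  # beyond the data support of the fit, a quadratic branch can fold back;
  # on the physical branch d and r move together along the sweep, so keep
  # the longest run of co-monotone steps
  if (nrow(pts) > 2L) {
    good <- diff(pts$diameter_um) * diff(pts$radial_um) > -1e-12
    runs <- rle(good)
    ends <- cumsum(runs$lengths)
    best <- which(runs$values)[which.max(runs$lengths[runs$values])]
    if (length(best) == 1L) {
      keep <- seq(ends[best] - runs$lengths[best] + 1L, ends[best] + 1L)
      pts <- pts[keep, , drop = FALSE]
    }
  }
  pts <- pts[order(pts$diameter_um), , drop = FALSE]
  row.names(pts) <- NULL
  pts
}

#' @export
print.sfp_isocurve <- function(x, ...) {
  unit <- if (x$kind == "constant_duration") "ms" else "mV"
  cat(sprintf("%s curve at %g %s: %d points", x$kind, x$level, unit,
              nrow(x$points)))
  if (nrow(x$points) > 0L)
    cat(sprintf(" (d %g-%g um, r %.4g-%.4g um)",
                min(x$points$diameter_um), max(x$points$diameter_um),
                min(x$points$radial_um), max(x$points$radial_um)))
  cat("\n")
  invisible(x)
}

#' Intersection of two iso-feature curves
#'
#' Locates the crossing of an iso-amplitude and an iso-duration polyline in
#' the (diameter, distance) plane by segment-segment intersection over
#' their common diameter span.
#'
#' @param curve_a,curve_b Two [iso_duration_curve()] /
#'   [iso_amplitude_curve()] objects of different kind or level.
#' @return A list with `diameter_um` and `radial_um` of the crossing.
#'   Errors if the curves are identical (degenerate) or do not cross in
#'   the common domain.
#' @examples
#' m <- published_coefficients()
#' curve_intersection(iso_amplitude_curve(m, 0.7), iso_duration_curve(m, 0.6))
#' @export
curve_intersection <- function(curve_a, curve_b) {
  stopifnot(inherits(curve_a, "sfp_isocurve"),
            inherits(curve_b, "sfp_isocurve"))
  if (curve_a$kind == curve_b$kind && isTRUE(all.equal(curve_a$level,
                                                       curve_b$level)))
    stop("degenerate intersection: the two curves are identical",
         call. = FALSE)
  pa <- curve_a$points
  pb <- curve_b$points
  if (nrow(pa) < 2L || nrow(pb) < 2L)
    stop("curves must each have at least two points to intersect",
         call. = FALSE)
  # difference of the two curves' r(d) profiles on the common d span
  dmin <- max(min(pa$diameter_um), min(pb$diameter_um))
  dmax <- min(max(pa$diameter_um), max(pb$diameter_um))
  if (dmin >= dmax)
    stop("no intersection: the curves do not overlap in diameter",
         call. = FALSE)
  dd <- seq(dmin, dmax, length.out = 512)
  ra <- stats::approx(pa$diameter_um, pa$radial_um, dd)$y
  rb <- stats::approx(pb$diameter_um, pb$radial_um, dd)$y
  diffr <- ra - rb
  if (all(abs(diffr) < 1e-9))
    stop("degenerate intersection: the two curves coincide", call. = FALSE)
  sgn <- sign(diffr)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(flips) == 0L) {
    if (any(diffr == 0)) {
      i <- which(diffr == 0)[1]
      return(list(diameter_um = dd[i], radial_um = ra[i]))
    }
    stop("no intersection of the two curves inside the common domain",
         call. = FALSE)
  }
  i <- flips[1]
  w <- diffr[i] / (diffr[i] - diffr[i + 1])
  list(diameter_um = dd[i] + w * (dd[i + 1] - dd[i]),
       radial_um = ra[i] + w * (ra[i + 1] - ra[i]))
}

#' Plot a nomogram of iso-amplitude and iso-duration curves
#'
#' Draws the two curve families in the (distance, diameter) plane: solid
#' lines for constant duration, dashed lines for constant amplitude, with
#' level labels at the curve ends.
#'
#' @param duration_curves,amplitude_curves Lists of [sfp_isocurve][iso_duration_curve] objects.
#' @param mark Optional point `c(diameter_um, radial_um)` to highlight.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_nomogram <- function(duration_curves, amplitude_curves, mark = NULL,
                          ...) {
  all_pts <- do.call(rbind, lapply(c(duration_curves, amplitude_curves),
                                   function(cv) cv$points))
  graphics::plot(NA, xlim = range(all_pts$radial_um),
                 ylim = range(all_pts$diameter_um),
                 xlab = "radial distance r (um)",
                 ylab = "fiber diameter d (um)", ...)
  for (cv in duration_curves)
    if (nrow(cv$points) > 1) {
      graphics::lines(cv$points$radial_um, cv$points$diameter_um, lty = 1)
      graphics::text(utils::tail(cv$points$radial_um, 1),
                     utils::tail(cv$points$diameter_um, 1),
                     sprintf("%g ms", cv$level), pos = 4, cex = 0.7)
    }
  for (cv in amplitude_curves)
    if (nrow(cv$points) > 1) {
      graphics::lines(cv$points$radial_um, cv$points$diameter_um, lty = 2)
      graphics::text(utils::tail(cv$points$radial_um, 1),
                     utils::tail(cv$points$diameter_um, 1),
                     sprintf("%g mV", cv$level), pos = 4, cex = 0.7)
    }
  if (!is.null(mark))
    graphics::points(mark[2], mark[1], pch = 19, col = "red")
  invisible(NULL)
}

#' Export iso-curves as a CSV table
#'
#' @param curves List of iso-curves.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  rows <- do.call(rbind, lapply(curves, function(cv) {
    if (nrow(cv$points) == 0L) return(NULL)
    data.frame(kind = cv$kind, level = cv$level, cv$points)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
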