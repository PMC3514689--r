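test_that("published coefficient set matches the printed table", {
  m <- published_coefficients()
  expect_identical(dim(m$c), c(2L, 3L, 3L))
  expect_true(all(is.finite(m$c)))
  expect_equal(m$c[1, 1, 1], 9.5100e-01)
  expect_equal(m$c[1, 2, 1], -7.3845e-03)
  expect_equal(m$c[2, 3, 3], 3.2255e-07)
  expect_equal(m$c[2, 1, 2], -5.1557e-01)
  expect_identical(m$amplitude_unit, "mV")
})

test_that("bundled coefficient file carries the same model", {
  path <- system.file("extdata", "published_coefficients.json",
                      package = "sfpdiam")
  expect_true(nzchar(path))
  m <- read_model_json(path)
  expect_equal(unname(m$c), unname(published_coefficients()$c))
})

test_that("surface evaluation composes the nested quadratics", {
  m0 <- one_coef_model(1, 1, 1, 0.5)
  expect_equal(evaluate_surface(m0, 1, 0.3, 40), 0.5)
  expect_equal(evaluate_surface(m0, 1, 4.2, 90), 0.5)
  my <- one_coef_model(1, 2, 1, 1)        # tz = y
  expect_equal(evaluate_surface(my, 1, 2.5, 77), 77)
  expect_error(evaluate_surface(m0, 1, -1, 40), "positive")
  expect_error(evaluate_surface(m0, 1, 0, 40), "positive")
})

test_that("worked-example inversion recovers the printed estimates", {
  m <- published_coefficients()
  sd <- solve_diameter(m, 1.357, 0.593)
  sr <- solve_radius(m, 1.357, 0.593)
  expect_equal(round(sd$value, 1), 55.7)
  expect_equal(round(sr$value, 1), 80.9)
  expect_true(sd$in_range)
  expect_true(sr$in_range)
  expect_false(sd$ambiguous)
  # rejected roots sit far outside physiology
  expect_equal(max(sd$roots), 236.1, tolerance = 1e-3)
  expect_equal(max(sr$roots), 588.9, tolerance = 1e-3)
  # re-substituting the selected root reproduces the measured duration
  expect_lt(abs(evaluate_surface(m, 1, 1.357, sd$value) - 0.593), 1e-9)
  expect_lt(abs(evaluate_surface(m, 2, 1.357, sr$value) - 0.593), 1e-9)
})

test_that("solver agrees with an independent polynomial root finder", {
  m <- published_coefficients()
  for (a in c(0.1, 0.5, 1.357, 3)) {
    for (tz in c(0.5, 0.7, 0.9)) {
      x <- log10(a)
      e <- vapply(1:3, function(j)
        m$c[1, j, 1] + x * (m$c[1, j, 2] + x * m$c[1, j, 3]), numeric(1))
      roots <- suppressWarnings(polyroot(c(e[1] - tz, e[2], e[3])))
      real_roots <- sort(Re(roots[abs(Im(roots)) < 1e-8]))
      sol <- tryCatch(solve_diameter(m, a, tz), error = function(e) NULL)
      if (!is.null(sol))
        expect_true(min(abs(sol$value - real_roots)) < 1e-8)
    }
  }
})

test_that("degenerate quadratics fall back to the linear solution", {
  cc <- array(0, dim = c(2, 3, 3))
  cc[1, 1, 1] <- 0.9
  cc[1, 2, 1] <- -5e-3            # tz = 0.9 - 5e-3 * y, no quadratic term
  cc[2, 1, 1] <- 0.9
  cc[2, 2, 1] <- -1e-3
  m <- biquadratic_model(cc)
  sol <- solve_diameter(m, 1, 0.6)
  expect_equal(sol$value, (0.6 - 0.9) / -5e-3)
  expect_true(is.na(sol$discriminant))
})

test_that("unsolvable feature pairs raise informative errors", {
  m <- published_coefficients()
  expect_error(solve_diameter(m, 1.357, 0.1), "discriminant")
  expect_error(solve_diameter(m, 1.357, 0.95, margin = 0), "outside")
  expect_error(solve_diameter(m, -1, 0.6), "positive")
  expect_error(solve_diameter(m, 1, -0.6), "positive")
})

test_that("ambiguous in-range root pairs are flagged and resolved to the midpoint side", {
  s <- 1e-4   # tz = 0.5 + s * (y - 40)(y - 70): roots 40 and 70 at tz = 0.5
  cc <- array(0, dim = c(2, 3, 3))
  cc[1, 1, 1] <- 0.5 + s * 2800
  cc[1, 2, 1] <- -s * 110
  cc[1, 3, 1] <- s
  cc[2, 1, 1] <- 1; cc[2, 2, 1] <- -1e-3
  m <- biquadratic_model(cc)
  sol <- solve_diameter(m, 1, 0.5)
  expect_true(sol$ambiguous)
  expect_equal(sort(sol$roots), c(40, 70), tolerance = 1e-9)
  expect_equal(sol$value, 70)   # nearer the 25-90 midpoint (57.5)
})

test_that("inversion round-trips on data generated from the surfaces", {
  m <- published_coefficients()
  for (r_true in c(60, 150, 300, 450)) {
    tz <- evaluate_surface(m, 2, 0.8, r_true)
    sol <- solve_radius(m, 0.8, tz)
    # the generating radius is always one of the quadratic roots; where the
    # surface folds (both roots physiological) the solve is flagged
    # ambiguous and may legitimately return the other branch
    expect_lt(min(abs(sol$roots - r_true)), 1e-6)
    if (!sol$ambiguous)
      expect_equal(sol$value, r_true, tolerance = 1e-6 / r_true)
  }
  for (d_true in c(30, 55, 75, 90)) {
    tz <- evaluate_surface(m, 1, 1.2, d_true)
    expect_equal(solve_diameter(m, 1.2, tz)$value, d_true,
                 tolerance = 1e-6 / d_true)
  }
})

test_that("exactly one admissible root arises from in-range feature pairs", {
  m <- published_coefficients()
  amps <- 10^seq(log10(0.05), log10(5), length.out = 9)
  for (a in amps) {
    for (d in seq(25, 90, by = 5)) {
      tz <- evaluate_surface(m, 1, a, d)
      if (tz <= 0) next
      sol <- solve_diameter(m, a, tz)
      # small slack: the generating diameter at the grid edge is itself a
      # root, recovered only to machine precision
      in_nominal <- sol$roots >= 25 - 1e-6 & sol$roots <= 90 + 1e-6
      expect_equal(sum(in_nominal), 1L)
      expect_false(sol$ambiguous)
    }
  }
})

test_that("least-squares refit recovers an exact generating model", {
  gen <- published_coefficients()
  grid <- expand.grid(amplitude_mv = c(0.1, 0.4, 0.9, 2, 4),
                      diameter_um = seq(25, 90, by = 13))
  grid$radial_um <- seq(50, 500, length.out = nrow(grid))
  grid$tz_ms <- evaluate_surface(gen, 1, grid$amplitude_mv, grid$diameter_um)
  fit <- fit_surfaces(grid)
  expect_equal(unname(fit$c[1, , ]), unname(gen$c[1, , ]),
               tolerance = 1e-10)
  # residual diagnostics recorded, and exact for exact data
  expect_lt(fit$residuals$rms[1], 1e-12)
  # refitting data generated from the fitted model reproduces it
  grid2 <- grid
  grid2$tz_ms <- evaluate_surface(fit, 1, grid2$amplitude_mv,
                                  grid2$diameter_um)
  fit2 <- fit_surfaces(grid2)
  expect_equal(fit2$c[1, , ], fit$c[1, , ], tolerance = 1e-10)
})

test_that("under-determined or rank-deficient fits are rejected", {
  g <- data.frame(diameter_um = seq(30, 65, by = 5),
                  radial_um = seq(50, 400, by = 50),
                  amplitude_mv = seq(0.2, 3, length.out = 8),
                  tz_ms = seq(0.5, 1.2, length.out = 8))
  expect_error(fit_surfaces(g), "at least 9")
  g2 <- data.frame(diameter_um = rep(55, 12),
                   radial_um = rep(c(100, 200, 300), 4),
                   amplitude_mv = rep(c(0.3, 0.7, 1.5, 3), each = 3),
                   tz_ms = seq(0.4, 1.3, length.out = 12))
  expect_error(fit_surfaces(g2), "singular")
})

test_that("batch inversion flags unsolvable rows instead of aborting", {
  m <- published_coefficients()
  res <- invert_features(m, c(1.357, 1.357), c(0.593, 0.01))
  expect_equal(res$diameter_um[1], 55.68, tolerance = 1e-3)
  expect_equal(res$radial_um[1], 80.87, tolerance = 1e-3)
  expect_identical(res$flag[1], "")
  expect_true(is.na(res$diameter_um[2]))
  expect_match(res$flag[2], "discriminant")
})

test_that("measurement-error sensitivity reproduces the published asymmetry", {
  m <- published_coefficients()
  s <- sensitivity(m, 1.357, 0.593)
  expect_equal(s$base$diameter_um, 55.68, tolerance = 1e-3)
  # duration errors dominate amplitude errors for the diameter
  expect_lt(s$max_dd_amplitude, 0.3)
  expect_gt(s$max_dd_duration, 7)
  # null perturbation changes nothing
  s0 <- sensitivity(m, 1.357, 0.593, delta_a_mv = 0, delta_tz_ms = 0)
  expect_equal(s0$max_dd_duration, 0)
  expect_equal(s0$max_dr_amplitude, 0)
  # the asymmetry holds across the operating range
  for (d in c(35, 55, 80)) {
    for (a in c(0.3, 1, 3)) {
      tz <- evaluate_surface(m, 1, a, d)
      sp <- tryCatch(sensitivity(m, a, tz), error = function(e) NULL)
      if (!is.null(sp) && is.finite(sp$max_dd_amplitude) &&
          is.finite(sp$max_dd_duration))
        expect_gt(sp$max_dd_duration, sp$max_dd_amplitude)
    }
  }
})

test_that("models serialize to JSON and back", {
  f <- withr::local_tempfile(fileext = ".json")
  g <- reference_grid()
  m <- fit_surfaces(g)
  write_model_json(m, f)
  m2 <- read_model_json(f)
  expect_equal(unname(m2$c), unname(m$c))
  expect_equal(m2$valid_d_range, m$valid_d_range)
  expect_equal(m2$residuals$mean_abs, m$residuals$mean_abs)
})
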