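# Shared fixtures built in code.

# Simple triphasic toy waveform with known feature values:
# crosses zero at 1.0 ms, dips to -1 mV, returns to zero at 1.6 ms.
toy_triphasic <- function() {
  sfp_waveform(0.9, 0.1, c(0.2, 0, -0.7, -1, -0.9, -0.7, -0.3, 0, 0.1))
}

# The reference fitting grid (266 scenarios) is expensive; simulate it once
# per test run and reuse across acceptance and property tests.
.grid_cache <- new.env(parent = emptyenv())
reference_grid <- function() {
  if (is.null(.grid_cache$grid))
    .grid_cache$grid <- simulate_feature_grid()
  .grid_cache$grid
}

reference_model <- function() {
  if (is.null(.grid_cache$model))
    .grid_cache$model <- fit_surfaces(reference_grid())
  .grid_cache$model
}

reference_report <- function() {
  if (is.null(.grid_cache$report))
    .grid_cache$report <- evaluate_inversion_error(reference_model(),
                                                   reference_grid())
  .grid_cache$report
}

# A bi-quadratic model with a single non-zero coefficient
one_coef_model <- function(i, j, k, value) {
  cc <- array(0, dim = c(2, 3, 3))
  cc[i, j, k] <- value
  # keep the other surface solvable to avoid distracting errors
  cc[3 - i, 1, 1] <- 1
  cc[3 - i, 2, 1] <- 1e-3
  biquadratic_model(cc)
}
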