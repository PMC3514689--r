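#' Uniformly sampled extracellular waveform
#'
#' Container for a uniformly sampled extracellular potential: first-sample
#' time, sampling interval and voltage samples, with optional provenance
#' (the simulated scenario and model constants).  Voltages are stored
#' physically: the negative peak is a minimum in mV.  Any negative-up EMG
#' display convention is applied only in [plot.sfp_waveform()].
#'
#' @param t0_ms Time of the first sample (ms).
#' @param dt_ms Sampling interval (ms), positive.
#' @param samples_mv Voltage samples (mV); at least 3.
#' @param scenario,constants Optional provenance attached by the simulator.
#' @return An object of class `sfp_waveform`.
#' @examples
#' w <- sfp_waveform(0, 0.1, c(0, 1, -2, 0.5, 0))
#' measure_amplitude(w)
#' @export
sfp_waveform <- function(t0_ms, dt_ms, samples_mv,
                         scenario = NULL, constants = NULL) {
  if (!is.numeric(samples_mv) || length(samples_mv) < 3L)
    stop("'samples_mv' must be a numeric vector with at least 3 samples",
         call. = FALSE)
  if (!is.finite(dt_ms) || dt_ms <= 0)
    stop("'dt_ms' must be positive", call. = FALSE)
  structure(list(t0_ms = t0_ms, dt_ms = dt_ms,
                 samples_mv = as.numeric(samples_mv),
                 scenario = scenario, constants = constants),
            class = "sfp_waveform")
}

#' Sample times of a waveform
#' @param waveform An [sfp_waveform()].
#' @return Numeric vector of sample times (ms).
#' @export
waveform_times <- function(waveform) {
  stopifnot(inherits(waveform, "sfp_waveform"))
  waveform$t0_ms + waveform$dt_ms * (seq_along(waveform$samples_mv) - 1L)
}

#' @export
print.sfp_waveform <- function(x, ...) {
  cat(sprintf("SFP waveform: %d samples, dt = %g ms (%g kHz), span %.3f..%.3f ms\n",
              length(x$samples_mv), x$dt_ms, 1 / x$dt_ms,
              x$t0_ms, max(waveform_times(x))))
  if (!is.null(x$scenario))
    cat(sprintf("  scenario: d = %g um, r = %g um\n",
                x$scenario$diameter_um, x$scenario$radial_um))
  cat(sprintf("  range: %+.4f .. %+.4f mV\n",
              min(x$samples_mv), max(x$samples_mv)))
  invisible(x)
}

#' @export
as.data.frame.sfp_waveform <- function(x, ...) {
  data.frame(time_ms = waveform_times(x), voltage_mv = x$samples_mv)
}

#' @param x An `sfp_waveform`.
#' @param negative_up Plot with the EMG display convention (negative peak
#'   upward)?  Display only; stored voltages are physical.
#' @param ... Passed to [graphics::plot()].
#' @rdname sfp_waveform
#' @export
plot.sfp_waveform <- function(x, negative_up = FALSE, ...) {
  y <- if (negative_up) -x$samples_mv else x$samples_mv
  graphics::plot(waveform_times(x), y, type = "l",
                 xlab = "time (ms)",
                 ylab = if (negative_up) "-voltage (mV)" else "voltage (mV)",
                 ...)
  graphics::abline(h = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Resample a waveform to a coarser clinical sampling rate
#'
#' Decimates by an integer factor, e.g. from the internal 0.002 ms step to
#' the 0.04 ms step of a 25 kHz clinical acquisition.  The target interval
#' must be an integer multiple of the current one.
#'
#' @param waveform An [sfp_waveform()].
#' @param dt_ms Target sampling interval (ms); default 0.04 (25 kHz).
#' @return A decimated `sfp_waveform`.
#' @examples
#' w <- simulate_sfp(fiber_scenario(55, 80))
#' w25 <- decimate_waveform(w)
#' w25$dt_ms
#' @export
decimate_waveform <- function(waveform, dt_ms = 0.04) {
  stopifnot(inherits(waveform, "sfp_waveform"))
  k <- dt_ms / waveform$dt_ms
  if (abs(k - round(k)) > 1e-8 || k < 1)
    stop("'dt_ms' must be an integer multiple of the waveform's interval",
         call. = FALSE)
  k <- as.integer(round(k))
  idx <- seq(1L, length(waveform$samples_mv), by = k)
  sfp_waveform(waveform$t0_ms, waveform$dt_ms * k,
               waveform$samples_mv[idx],
               scenario = waveform$scenario, constants = waveform$constants)
}

#' Read and write waveforms as CSV or JSON
#'
#' The CSV form is a two-column table `time_ms, voltage_mv` with one header
#' line.  The JSON form stores `t0_ms`, `dt_ms` and `samples_mv` together
#' with provenance metadata (scenario, model constants and package
#' version).  CSV input need not be uniformly sampled on read, but is
#' checked for a constant step.
#'
#' @param waveform An [sfp_waveform()].
#' @param path File path.
#' @return `read_waveform_*` return an `sfp_waveform`; writers return the
#'   path invisibly.
#' @examples
#' w <- sfp_waveform(0, 0.1, c(0.2, 1, -2, 0.5, -0.1))
#' f <- tempfile(fileext = ".csv")
#' write_waveform_csv(w, f)
#' w2 <- read_waveform_csv(f)
#' @export
write_waveform_csv <- function(waveform, path) {
  stopifnot(inherits(waveform, "sfp_waveform"))
  utils::write.csv(as.data.frame(waveform), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "voltage_mv") %in% names(df)))
    stop("waveform CSV must have columns 'time_ms' and 'voltage_mv'",
         call. = FALSE)
  dts <- diff(df$time_ms)
  if (length(dts) < 2L || max(dts) - min(dts) > 1e-6 * max(abs(dts)))
    stop("waveform CSV is not uniformly sampled", call. = FALSE)
  sfp_waveform(df$time_ms[1], mean(dts), df$voltage_mv)
}

#' @rdname write_waveform_csv
#' @export
write_waveform_json <- function(waveform, path) {
  stopifnot(inherits(waveform, "sfp_waveform"))
  payload <- list(
    t0_ms = waveform$t0_ms,
    dt_ms = waveform$dt_ms,
    samples_mv = waveform$samples_mv,
    provenance = list(
      scenario = if (!is.null(waveform$scenario))
        unclass(waveform$scenario),
      constants = if (!is.null(waveform$constants))
        unclass(waveform$constants),
      package = paste0("sfpdiam ", utils::packageVersion("sfpdiam"))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sfp_waveform(obj$t0_ms, obj$dt_ms, obj$samples_mv)
}
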