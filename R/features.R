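#' Peak-to-peak amplitude of a waveform
#'
#' The amplitude is measured from the maximum positive to the maximum
#' negative peak, i.e. `max - min` of the samples, in mV.
#'
#' @param waveform An [sfp_waveform()].
#' @return Peak-to-peak amplitude (mV), non-negative.
#' @examples
#' measure_amplitude(sfp_waveform(0, 0.1, c(0, 0.357, -1, 0)))
#' @export
measure_amplitude <- function(waveform) {
  if (!inherits(waveform, "sfp_waveform"))
    stop("'waveform' must be an sfp_waveform", call. = FALSE)
  max(waveform$samples_mv) - min(waveform$samples_mv)
}

#' Negative-peak duration between zero-crossings
#'
#' Identifies the negative lobe containing the waveform's global minimum
#' and returns the time between the zero-crossing entering that lobe and
#' the zero-crossing leaving it.  Crossings are located by linear
#' interpolation between the two bracketing samples, so durations are not
#' quantized to the sampling interval.  Zero volts is the baseline; an
#' optional mean-of-leading-samples correction is provided for imported
#' recordings with a DC offset (off by default, as simulated waveforms have
#' a clean baseline).
#'
#' When the waveform carries more than two zero-crossings (polyphasic
#' shapes), the lobe containing the global minimum is used and the returned
#' value carries the attribute `polyphasic = TRUE`.
#'
#' @param waveform An [sfp_waveform()].
#' @param baseline_correct Subtract the mean of the leading samples before
#'   locating crossings?
#' @param baseline_fraction Fraction of leading samples used for the
#'   baseline estimate.
#' @return Negative-peak duration (ms).
#' @examples
#' # crosses zero at 1.0 ms, dips to -1 mV, returns to zero at 1.6 ms
#' w <- sfp_waveform(0.9, 0.1, c(0.2, 0, -0.7, -1, -0.9, -0.7, -0.3, 0, 0.1))
#' measure_negative_peak_duration(w)  # 0.6 ms
#' @export
measure_negative_peak_duration <- function(waveform,
                                           baseline_correct = FALSE,
                                           baseline_fraction = 0.1) {
  if (!inherits(waveform, "sfp_waveform"))
    stop("'waveform' must be an sfp_waveform", call. = FALSE)
  y <- waveform$samples_mv
  if (baseline_correct) {
    n0 <- max(1L, floor(length(y) * baseline_fraction))
    y <- y - mean(y[seq_len(n0)])
  }
  t <- waveform_times(waveform)
  imin <- which.min(y)
  if (y[imin] >= 0)
    stop("waveform has no negative lobe; negative-peak duration undefined",
         call. = FALSE)
  # indices i where a zero level is crossed between samples i and i+1
  s <- y[-1] * y[-length(y)]
  cross_idx <- which(s < 0 | (y[-length(y)] != 0 & y[-1] == 0))
  entries <- cross_idx[cross_idx < imin]
  exits <- cross_idx[cross_idx >= imin]
  if (length(entries) == 0L || length(exits) == 0L)
    stop("no zero-crossings bound the negative lobe; ",
         "negative-peak duration undefined (monophasic waveform?)",
         call. = FALSE)
  interp <- function(i)
    t[i] + waveform$dt_ms * (0 - y[i]) / (y[i + 1L] - y[i])
  tz <- interp(min(exits)) - interp(max(entries))
  if (length(cross_idx) > 2L) attr(tz, "polyphasic") <- TRUE
  tz
}

#' Measure both SFP features of a waveform
#'
#' Convenience wrapper returning the feature pair used throughout the
#' package: peak-to-peak amplitude `a` (mV) and negative-peak duration
#' `tz` (ms), plus the number of zero-crossings and a polyphasic flag.
#'
#' @inheritParams measure_negative_peak_duration
#' @return A list of class `sfp_features` with elements `amplitude_mv`,
#'   `tz_ms`, `n_zero_crossings`, `polyphasic`.
#' @examples
#' sfp_features(simulate_sfp(fiber_scenario(55, 80)))
#' @export
sfp_features <- function(waveform, baseline_correct = FALSE,
                         baseline_fraction = 0.1) {
  tz <- measure_negative_peak_duration(waveform, baseline_correct,
                                       baseline_fraction)
  y <- waveform$samples_mv
  ncross <- sum(y[-1] * y[-length(y)] < 0)
  structure(list(amplitude_mv = measure_amplitude(waveform),
                 tz_ms = as.numeric(tz),
                 n_zero_crossings = ncross,
                 polyphasic = isTRUE(attr(tz, "polyphasic"))),
            class = "sfp_features")
}

#' @export
print.sfp_features <- function(x, ...) {
  cat(sprintf("SFP features: amplitude = %.4g mV, negative-peak duration = %.4g ms%s\n",
              x$amplitude_mv, x$tz_ms,
              if (x$polyphasic) " [polyphasic]" else ""))
  invisible(x)
}
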