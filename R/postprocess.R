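#' Low-pass filter specification
#'
#' Hard spectral truncation: every discrete Fourier bin whose frequency
#' exceeds the cutoff is zeroed. The default 150 Hz preserves the
#' physiological content of light-adapted waveforms (a-/b-waves and OPs up
#' to ~150 Hz) while removing high-frequency generator artifacts.
#'
#' @param cutoff Cutoff frequency, Hz (> 0; must be below the Nyquist
#'   frequency of any waveform it is applied to).
#' @return An object of class `lowpass_spec`.
#' @export
lowpass_spec <- function(cutoff = 150) {
  if (!is_scalar_num(cutoff) || cutoff <= 0)
    abort_validation("cutoff must be a positive number")
  structure(list(cutoff = cutoff, mode = "hard-zero"), class = "lowpass_spec")
}

#' Fourier low-pass smoothing of a waveform
#'
#' Real FFT, hard-zero of all bins above the cutoff, inverse transform.
#' Length, sampling rate and metadata are preserved; the output is real.
#' The operation is linear, idempotent, and never increases signal energy
#' (Parseval).
#'
#' @param w An [erg_waveform].
#' @param spec A [lowpass_spec] (or a plain cutoff in Hz).
#' @return The filtered [erg_waveform].
#' @export
fourier_lowpass <- function(w, spec = lowpass_spec()) {
  if (is.numeric(spec)) spec <- lowpass_spec(spec)
  if (!inherits(w, "erg_waveform")) abort_validation("w must be an erg_waveform")
  if (spec$cutoff >= w$fs / 2)
    abort_validation("cutoff must be below the Nyquist frequency fs/2")
  n <- length(w$samples)
  X <- stats::fft(w$samples)
  freq <- (0:(n - 1)) * w$fs / n
  freq <- pmin(freq, w$fs - freq)          # fold negative-frequency bins
  X[freq > spec$cutoff] <- 0 + 0i
  w$samples <- Re(stats::fft(X, inverse = TRUE)) / n
  w
}

#' Apply a low-pass to every waveform of a dataset
#'
#' @param dataset An [erg_dataset].
#' @param spec A [lowpass_spec].
#' @param provenance_only Restrict filtering to records of this provenance
#'   (default `"synthetic"`, the generated records the smoothing step is
#'   designed for); `NULL` filters everything.
#' @return The dataset with filtered records.
#' @export
lowpass_dataset <- function(dataset, spec = lowpass_spec(),
                            provenance_only = "synthetic") {
  out <- lapply(dataset, function(w) {
    if (is.null(provenance_only) || w$provenance %in% provenance_only)
      fourier_lowpass(w, spec) else w
  })
  erg_dataset(out)
}
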