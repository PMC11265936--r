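#' Construct a single ERG waveform record
#'
#' The atom flowing through every stage of the package: one fixed-length
#' full-field ERG trace (microvolts against time from flash onset) together
#' with its acquisition and label metadata.
#'
#' @param samples Numeric vector of amplitudes in microvolts; all finite,
#'   length at least 2.
#' @param fs Sampling rate in samples per second.
#' @param stimulus `"LA3"` (light-adapted 3 cd s m-2 single flash) or
#'   `"FLICKER30"` (30 Hz steady-state flicker).
#' @param subject_id Opaque subject identifier; replicates and fellow eyes of
#'   one subject share it.
#' @param eye `"left"` or `"right"`.
#' @param sex `"male"` or `"female"` (the classification label).
#' @param provenance `"real"` for recorded/simulated study data,
#'   `"synthetic"` for generator output.
#' @param replicate_index 1-based replicate counter within a subject/eye.
#' @return An object of class `erg_waveform`.
#' @export
erg_waveform <- function(samples, fs, stimulus, subject_id, eye, sex,
                         provenance = "real", replicate_index = 1L) {
  samples <- as.double(samples)
  if (length(samples) < 2L) abort_validation("waveform needs at least 2 samples")
  if (!all(is.finite(samples))) abort_validation("waveform samples must be finite")
  if (!is_scalar_num(fs) || fs <= 0) abort_validation("fs must be a positive number")
  stimulus <- match.arg(stimulus, c("LA3", "FLICKER30"))
  eye <- match.arg(eye, c("left", "right"))
  sex <- match.arg(sex, c("male", "female"))
  provenance <- match.arg(provenance, c("real", "synthetic"))
  structure(
    list(samples = samples, fs = as.double(fs), stimulus = stimulus,
         subject_id = as.character(subject_id), eye = eye, sex = sex,
         provenance = provenance,
         replicate_index = as.integer(replicate_index)),
    class = "erg_waveform")
}

#' @export
print.erg_waveform <- function(x, ...) {
  cat(sprintf("<erg_waveform> %s %s %s/%s rep %d (%s): %d samples @ %g Hz, range [%.2f, %.2f] uV\n",
              x$stimulus, x$subject_id, x$eye, x$sex, x$replicate_index,
              x$provenance, length(x$samples), x$fs,
              min(x$samples), max(x$samples)))
  invisible(x)
}

# Time grid (seconds from flash onset) for a waveform.
wave_time <- function(w) (seq_along(w$samples) - 1) / w$fs

#' Bundle waveforms into a dataset
#'
#' A dataset is an ordered collection of [erg_waveform] records. Within one
#' dataset all records of a given stimulus must share length and sampling
#' rate.
#'
#' @param waveforms A list of `erg_waveform` objects.
#' @return An object of class `erg_dataset`.
#' @export
erg_dataset <- function(waveforms = list()) {
  if (inherits(waveforms, "erg_waveform")) waveforms <- list(waveforms)
  ok <- vapply(waveforms, inherits, logical(1), what = "erg_waveform")
  if (!all(ok)) abort_validation("all elements must be erg_waveform objects")
  x <- structure(waveforms, class = "erg_dataset")
  validate_dataset(x)
  x
}

validate_dataset <- function(x) {
  if (length(x) == 0L) return(invisible(x))
  meta <- waveform_meta(x)
  for (st in unique(meta$stimulus)) {
    sub <- meta[meta$stimulus == st, ]
    if (length(unique(sub$n_samples)) != 1L)
      abort_validation(sprintf("records of stimulus %s differ in length", st))
    if (length(unique(sub$fs)) != 1L)
      abort_validation(sprintf("records of stimulus %s differ in fs", st))
  }
  invisible(x)
}

#' Metadata of every record in a dataset
#'
#' @param dataset An [erg_dataset].
#' @return A data frame with one row per waveform (no samples).
#' @export
waveform_meta <- function(dataset) {
  data.frame(
    subject_id = vapply(dataset, `[[`, character(1), "subject_id"),
    eye = vapply(dataset, `[[`, character(1), "eye"),
    sex = vapply(dataset, `[[`, character(1), "sex"),
    stimulus = vapply(dataset, `[[`, character(1), "stimulus"),
    provenance = vapply(dataset, `[[`, character(1), "provenance"),
    replicate_index = vapply(dataset, `[[`, integer(1), "replicate_index"),
    fs = vapply(dataset, `[[`, double(1), "fs"),
    n_samples = vapply(dataset, function(w) length(w$samples), integer(1)),
    stringsAsFactors = FALSE)
}

#' @export
`[.erg_dataset` <- function(x, i) {
  structure(unclass(x)[i], class = "erg_dataset")
}

#' @export
c.erg_dataset <- function(...) {
  parts <- lapply(list(...), unclass)
  erg_dataset(do.call(c, parts))
}

#' @export
print.erg_dataset <- function(x, ...) {
  cat(sprintf("<erg_dataset> %d waveforms\n", length(x)))
  if (length(x)) {
    m <- waveform_meta(x)
    print(table(stimulus = m$stimulus, sex = m$sex, provenance = m$provenance))
  }
  invisible(x)
}

#' @export
summary.erg_dataset <- function(object, ...) {
  m <- waveform_meta(object)
  cat(sprintf("erg_dataset: %d waveforms, %d subjects\n",
              nrow(m), length(unique(m$subject_id))))
  for (st in unique(m$stimulus)) {
    sub <- m[m$stimulus == st, ]
    cat(sprintf("  %s: n=%d (%d male / %d female; %d left / %d right), %d samples @ %g Hz\n",
                st, nrow(sub), sum(sub$sex == "male"), sum(sub$sex == "female"),
                sum(sub$eye == "left"), sum(sub$eye == "right"),
                sub$n_samples[1], sub$fs[1]))
  }
  invisible(m)
}

#' Long-format view of a dataset
#'
#' One row per sample, matching the on-disk CSV dialect of
#' [write_dataset()].
#'
#' @param x An [erg_dataset].
#' @param ... Unused.
#' @return A data frame with columns `subject_id, eye, sex, stimulus,
#'   provenance, replicate_index, fs, sample_index, amplitude_uv`.
#' @export
as.data.frame.erg_dataset <- function(x, ...) {
  if (length(x) == 0L)
    return(data.frame(subject_id = character(), eye = character(),
                      sex = character(), stimulus = character(),
                      provenance = character(), replicate_index = integer(),
                      fs = double(), sample_index = integer(),
                      amplitude_uv = double(), stringsAsFactors = FALSE))
  parts <- lapply(x, function(w) {
    n <- length(w$samples)
    data.frame(subject_id = rep(w$subject_id, n), eye = rep(w$eye, n),
               sex = rep(w$sex, n), stimulus = rep(w$stimulus, n),
               provenance = rep(w$provenance, n),
               replicate_index = rep(w$replicate_index, n),
               fs = rep(w$fs, n), sample_index = 0:(n - 1L),
               amplitude_uv = w$samples, stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

# Filter helper used throughout the pipeline.
subset_dataset <- function(dataset, stimulus = NULL, sex = NULL,
                           provenance = NULL, subject_id = NULL) {
  keep <- rep(TRUE, length(dataset))
  m <- waveform_meta(dataset)
  if (!is.null(stimulus)) keep <- keep & m$stimulus %in% stimulus
  if (!is.null(sex)) keep <- keep & m$sex %in% sex
  if (!is.null(provenance)) keep <- keep & m$provenance %in% provenance
  if (!is.null(subject_id)) keep <- keep & m$subject_id %in% subject_id
  dataset[keep]
}
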