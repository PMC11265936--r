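#' Time-domain feature extraction from LA3 waveforms
#'
#' Locates the a-wave trough and b-wave peak by windowed extremum search,
#' the convention used clinically for light-adapted ERGs: `ta` is the time of
#' the global minimum inside the a-wave search window, `tb` the time of the
#' global maximum inside the b-wave window restricted to `t > ta`, `la` the
#' magnitude of the trough relative to the pre-stimulus baseline (mean of
#' the initial reference segment), and `lb` the trough-to-peak b-wave
#' amplitude (a `baseline_to_peak` alternative is selectable). Ties in
#' extremum location resolve to the earliest sample.
#'
#' @param w An [erg_waveform] with `stimulus == "LA3"`.
#' @param a_window Two-element numeric, a-wave search interval in seconds.
#' @param b_window Two-element numeric, b-wave search interval in seconds.
#' @param baseline_window Length (seconds) of the initial reference segment
#'   whose mean defines the baseline.
#' @param lb_mode `"trough_to_peak"` (default, the standard convention) or
#'   `"baseline_to_peak"`.
#' @return A one-row data frame with columns `ta_s, la_uv, tb_s, lb_uv`.
#' @export
extract_la3_features <- function(w, a_window = c(0.005, 0.025),
                                 b_window = c(0.015, 0.060),
                                 baseline_window = 0.005,
                                 lb_mode = c("trough_to_peak", "baseline_to_peak")) {
  lb_mode <- match.arg(lb_mode)
  if (!inherits(w, "erg_waveform") || w$stimulus != "LA3")
    abort_validation("w must be an LA3 erg_waveform")
  if (length(a_window) != 2L || length(b_window) != 2L ||
      a_window[1] >= a_window[2] || b_window[1] >= b_window[2])
    abort_validation("windows must be increasing 2-element intervals")
  if (a_window[1] > b_window[1])
    abort_validation("a_window must start no later than b_window")
  t <- wave_time(w)
  if (b_window[2] > max(t) + 1 / w$fs)
    abort_validation("b_window extends beyond the record")
  y <- w$samples
  if (diff(range(y)) == 0) abort_extraction("flat signal: no extrema")
  baseline <- mean(y[t < baseline_window])

  ia <- which(t >= a_window[1] & t <= a_window[2])
  if (length(ia) < 3L) abort_extraction("a-window contains too few samples")
  seg <- y[ia]
  k <- which.min(seg)  # which.min -> earliest tie
  if (k == 1L || k == length(seg))
    abort_extraction("no trough inside the a-window (monotone segment)")
  trough_idx <- ia[k]
  ta <- t[trough_idx]
  trough_val <- y[trough_idx]

  ib <- which(t >= b_window[1] & t <= b_window[2] & t > ta)
  if (length(ib) < 3L) abort_extraction("b-window contains too few samples after the trough")
  seg <- y[ib]
  k <- which.max(seg)
  if (k == length(seg))
    abort_extraction("no peak inside the b-window (monotone segment)")
  peak_idx <- ib[k]
  tb <- t[peak_idx]
  peak_val <- y[peak_idx]

  la <- abs(baseline - trough_val)
  lb <- if (lb_mode == "trough_to_peak") peak_val - trough_val
        else peak_val - baseline
  data.frame(ta_s = ta, la_uv = la, tb_s = tb, lb_uv = lb)
}

#' Time-domain features of a 30 Hz flicker waveform
#'
#' The steady-state train is cut into 1/30 s cycles aligned to stimulus
#' onset; the first cycle is discarded. `lb` is the mean peak-to-adjacent-
#' trough amplitude over the steady-state cycles (trough = minimum within
#' three-quarters of a period after each peak, so the true trough stays
#' inside the search window despite sample quantization of the peak time)
#' and `tb` the time from cycle onset to the peak of the first steady-state
#' cycle.
#'
#' @param w An [erg_waveform] with `stimulus == "FLICKER30"` covering at
#'   least 2 full cycles.
#' @return A one-row data frame with columns `ta_s, la_uv` (NA for flicker)
#'   and `tb_s, lb_uv`.
#' @export
extract_flicker_features <- function(w) {
  if (!inherits(w, "erg_waveform") || w$stimulus != "FLICKER30")
    abort_validation("w must be a FLICKER30 erg_waveform")
  t <- wave_time(w)
  period <- 1 / 30
  n_cycles <- floor((max(t) + 1 / w$fs) / period)
  if (n_cycles < 2L) abort_extraction("fewer than 2 full flicker cycles")
  if (diff(range(w$samples)) == 0) abort_extraction("flat signal: no cycles detectable")
  y <- w$samples
  peaks <- troughs <- numeric(0)
  tb <- NA_real_
  for (cyc in 1:(n_cycles - 1L)) {       # discard cycle 0 (onset transient)
    on <- cyc * period
    idx <- which(t >= on & t < on + period)
    if (length(idx) < 4L) next
    k <- idx[which.max(y[idx])]
    t_peak <- t[k]
    jdx <- which(t > t_peak & t <= t_peak + 0.75 * period)
    if (length(jdx) == 0L) next
    j <- jdx[which.min(y[jdx])]
    peaks <- c(peaks, y[k]); troughs <- c(troughs, y[j])
    if (is.na(tb)) tb <- t_peak - on
  }
  if (length(peaks) < 1L || is.na(tb))
    abort_extraction("fewer than 2 detected cycles")
  data.frame(ta_s = NA_real_, la_uv = NA_real_, tb_s = tb,
             lb_uv = mean(peaks - troughs))
}

#' Extract features for every waveform of a dataset
#'
#' One row per waveform; records whose extraction fails (flat or monotone
#' segments) are excluded and logged, with the exclusion log attached as
#' attribute `"exclusions"`.
#'
#' @param dataset A nonempty [erg_dataset], all records of one stimulus.
#' @param ... Passed to the stimulus-appropriate extractor
#'   ([extract_la3_features()] arguments for LA3).
#' @param quiet Suppress the exclusion-count message.
#' @return A data frame with metadata columns (`subject_id, eye, sex,
#'   stimulus, provenance, replicate_index`) and `ta_s, la_uv, tb_s, lb_uv`.
#' @export
feature_table <- function(dataset, ..., quiet = FALSE) {
  if (!inherits(dataset, "erg_dataset") || length(dataset) == 0L)
    abort_validation("dataset must be a nonempty erg_dataset")
  m <- waveform_meta(dataset)
  if (length(unique(m$stimulus)) != 1L)
    abort_validation("feature_table requires a single-stimulus dataset")
  st <- m$stimulus[1]
  rows <- vector("list", length(dataset))
  excl <- list()
  for (i in seq_along(dataset)) {
    w <- dataset[[i]]
    res <- tryCatch(
      if (st == "LA3") extract_la3_features(w, ...) else extract_flicker_features(w),
      ergsynth_extraction_error = function(e) conditionMessage(e))
    if (is.character(res)) {
      excl[[length(excl) + 1L]] <- data.frame(
        subject_id = w$subject_id, eye = w$eye, sex = w$sex,
        provenance = w$provenance, replicate_index = w$replicate_index,
        reason = res, stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- cbind(m[i, c("subject_id", "eye", "sex", "stimulus",
                                "provenance", "replicate_index")],
                         res, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    abort_extraction("feature extraction failed for every record")
  rownames(out) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject_id = character(), eye = character(), sex = character(),
               provenance = character(), replicate_index = integer(),
               reason = character(), stringsAsFactors = FALSE)
  if (!quiet && nrow(exclusions) > 0L)
    message(sprintf("feature_table: excluded %d of %d records",
                    nrow(exclusions), length(dataset)))
  attr(out, "exclusions") <- exclusions
  out
}

# Feature columns used for classification, by stimulus.
stimulus_features <- function(stimulus) {
  if (stimulus == "LA3") c("ta_s", "la_uv", "tb_s", "lb_uv")
  else c("tb_s", "lb_uv")
}
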