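#' Write a waveform dataset to CSV
#'
#' Long-format dialect, one row per sample, header exactly
#' `subject_id,eye,sex,stimulus,provenance,replicate_index,fs,sample_index,amplitude_uv`.
#' Amplitudes are serialized with 17 significant digits so that
#' `read_dataset(write_dataset(d))` reproduces every value exactly.
#'
#' @param dataset A nonempty [erg_dataset].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  if (!inherits(dataset, "erg_dataset")) abort_validation("dataset must be an erg_dataset")
  if (length(dataset) == 0L) abort_validation("refusing to write an empty dataset")
  validate_dataset(dataset)
  df <- as.data.frame(dataset)
  df$amplitude_uv <- sprintf("%.17g", df$amplitude_uv)
  df$fs <- sprintf("%.17g", df$fs)
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

erg_csv_columns <- c("subject_id", "eye", "sex", "stimulus", "provenance",
                     "replicate_index", "fs", "sample_index", "amplitude_uv")

#' Read a waveform dataset from CSV
#'
#' Strictly validates the dialect written by [write_dataset()]: every record
#' (keyed by subject, eye, sex, stimulus, provenance, replicate) must carry a
#' contiguous 0-based `sample_index` run, a constant `fs`, finite
#' amplitudes, and per-stimulus constant record length. Violations raise a
#' parse error naming the offending record.
#'
#' @param path CSV file path.
#' @return An [erg_dataset].
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("no such file: %s", path))
  header <- names(data.table::fread(path, nrows = 0L))
  missing <- setdiff(erg_csv_columns, header)
  if (length(missing))
    abort_parse(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  df <- data.table::fread(path, colClasses = list(
    character = c("subject_id", "eye", "sex", "stimulus", "provenance"),
    integer = c("replicate_index", "sample_index"),
    double = c("fs", "amplitude_uv")), data.table = FALSE)
  if (nrow(df) == 0L) abort_parse("file contains no data rows")
  if (anyNA(df$amplitude_uv) || any(!is.finite(df$amplitude_uv)))
    abort_parse("non-finite or missing amplitude_uv values")
  key <- interaction(df$subject_id, df$eye, df$sex, df$stimulus,
                     df$provenance, df$replicate_index, drop = TRUE)
  waves <- vector("list", nlevels(key))
  for (i in seq_len(nlevels(key))) {
    rec <- df[key == levels(key)[i], , drop = FALSE]
    label <- sprintf("%s/%s/%s rep %d", rec$subject_id[1], rec$eye[1],
                     rec$stimulus[1], rec$replicate_index[1])
    if (length(unique(rec$fs)) != 1L)
      abort_parse(sprintf("mixed fs within record %s", label))
    rec <- rec[order(rec$sample_index), , drop = FALSE]
    if (anyDuplicated(rec$sample_index))
      abort_parse(sprintf("duplicate sample_index in record %s", label))
    if (!identical(rec$sample_index, 0:(nrow(rec) - 1L)))
      abort_parse(sprintf("sample_index not a contiguous 0-based run in record %s", label))
    waves[[i]] <- erg_waveform(rec$amplitude_uv, rec$fs[1], rec$stimulus[1],
                               rec$subject_id[1], rec$eye[1], rec$sex[1],
                               rec$provenance[1], rec$replicate_index[1])
  }
  tryCatch(erg_dataset(waves),
           ergsynth_validation_error = function(e) abort_parse(conditionMessage(e)))
}

#' Write a feature table to CSV
#'
#' @param features A feature table from [feature_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  if (!is.data.frame(features) || nrow(features) == 0L)
    abort_validation("features must be a nonempty data frame")
  data.table::fwrite(features, path)
  invisible(path)
}
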