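# Internal helpers: classed conditions, seeded evaluation, deterministic
# child seeds, canonical table hashing.

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ergsynth_error")))
}

abort_validation <- function(msg) abort(msg, "ergsynth_validation_error")
abort_parse      <- function(msg) abort(msg, "ergsynth_parse_error")
abort_extraction <- function(msg) abort(msg, "ergsynth_extraction_error")
abort_undefined  <- function(msg) abort(msg, "ergsynth_undefined_metric")

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# One root seed fans out to named per-stage streams. Polynomial string hash,
# exact in double precision (intermediates stay < 2^53), result < 2^31.
child_seed <- function(root, purpose) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(purpose))
  h <- as.double(abs(root) %% 2147483647)
  for (k in utf8ToInt(purpose)) h <- (h * 131 + k) %% 2147483629
  as.integer(h %% 2147483647)
}

# md5 of a canonical CSV rendering; numerics rounded to 12 significant
# digits so the hash is stable across serialization paths.
hash_table <- function(df) {
  stopifnot(is.data.frame(df))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  df <- df[do.call(order, unname(as.list(df))), , drop = FALSE]
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.csv(df, f, row.names = FALSE)
  unname(tools::md5sum(f))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
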