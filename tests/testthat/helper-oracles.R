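# Independent oracles and shared fixtures for the suite.

# Dense-grid search over the continuous LA3 kernel: trough/peak times and
# values found at dt resolution, independent of the sampled extraction path.
# The baseline follows the package's convention (mean of the kernel at the
# first 5 ms reference instants) since it is a definition, not a search.
la3_grid_oracle <- function(params, duration = 0.25, dt = 1e-5,
                            a_window = c(0.005, 0.025),
                            b_window = c(0.015, 0.060), fs = 1000) {
  t <- seq(0, duration, by = dt)
  y <- la3_model(t, params)
  ia <- which(t >= a_window[1] & t <= a_window[2])
  k <- ia[which.min(y[ia])]
  ta <- t[k]; trough <- y[k]
  ib <- which(t >= b_window[1] & t <= b_window[2] & t > ta)
  j <- ib[which.max(y[ib])]
  tb <- t[j]; peak <- y[j]
  baseline <- mean(la3_model((0:4) / fs, params))
  list(ta = ta, tb = tb, trough = trough, peak = peak,
       la = abs(baseline - trough), lb = peak - trough)
}

# Random valid noiseless LA3 parameterization for recovery tests. Extrema
# stay inside the default search windows, and the b-lobe is kept separated
# from the a-lobe (relative to its width) so the trough is not swamped —
# without a visible a-wave the trough is undefined for any extractor.
random_recovery_params <- function() {
  a_time <- stats::runif(1, 0.012, 0.020)
  b_time <- stats::runif(1, a_time + 0.017, 0.055)
  la3_params(a_amp = stats::runif(1, 8, 20),
             a_time = a_time,
             a_width = stats::runif(1, 0.004, 0.006),
             b_amp = stats::runif(1, 15, 40),
             b_time = b_time,
             b_width = stats::runif(1, 0.006, min(0.012, (b_time - a_time) / 2.8)),
             op_amp = 0, noise_sd = 0)
}

# Sample a noiseless kernel as an erg_waveform.
kernel_waveform <- function(params, fs = 1000, duration = 0.25, sex = "female") {
  t <- (0:(round(duration * fs) - 1)) / fs
  erg_waveform(la3_model(t, params), fs, "LA3", "oracle", "left", sex)
}

# Brute-force per-element confusion tally.
brute_confusion <- function(y_true, y_pred, positive) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == positive && y_pred[i] == positive) tp <- tp + 1L
    else if (y_true[i] != positive && y_pred[i] != positive) tn <- tn + 1L
    else if (y_true[i] != positive && y_pred[i] == positive) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Memoized expensive fixtures, built once per test run.
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

cached_fixture <- function(seed = 101) {
  cached(paste0("fixture", seed), make_study_fixture(seed = seed))
}

cached_la3 <- function(seed = 101) {
  fx <- cached_fixture(seed)
  fx[waveform_meta(fx)$stimulus == "LA3"]
}

# A quickly trained CGAN for structural tests (not quality assertions).
cached_tiny_gan <- function() {
  cached("tiny_gan", {
    d <- simulate_la3(n_per_class = c(male = 12, female = 12), seed = 7)
    erg_cgan(d, gan_config(epochs = 40), seed = 7)
  })
}
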