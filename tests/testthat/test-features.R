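test_that("extraction recovers kernel extrema against the dense-grid oracle", {
  set.seed(42)
  for (i in 1:20) {
    p <- random_recovery_params()
    w <- kernel_waveform(p)
    ft <- extract_la3_features(w)
    oracle <- la3_grid_oracle(p)
    expect_lte(abs(ft$ta_s - oracle$ta), 1 / w$fs)
    expect_lte(abs(ft$tb_s - oracle$tb), 1 / w$fs)
    expect_lt(abs(ft$la_uv - oracle$la) / oracle$la, 0.01)
    expect_lt(abs(ft$lb_uv - oracle$lb) / oracle$lb, 0.01)
  }
})

test_that("degenerate and malformed inputs are rejected", {
  w <- kernel_waveform(la3_params(noise_sd = 0))
  flat <- w; flat$samples <- rep(0, 250)
  expect_error(extract_la3_features(flat), class = "ergsynth_extraction_error")
  ramp <- w; ramp$samples <- seq(0, 1, length.out = 250)  # monotone: no trough
  expect_error(extract_la3_features(ramp), class = "ergsynth_extraction_error")
  fl <- simulate_flicker30(n_per_class = c(male = 1), seed = 1)[[1]]
  expect_error(extract_la3_features(fl), class = "ergsynth_validation_error")
})

test_that("amplitudes scale linearly and times are scale-invariant and shift-equivariant", {
  p <- la3_params(noise_sd = 0)
  w <- kernel_waveform(p)
  f1 <- extract_la3_features(w)
  w2 <- w; w2$samples <- 2 * w$samples
  f2 <- extract_la3_features(w2)
  expect_equal(f2$la_uv, 2 * f1$la_uv)
  expect_equal(f2$lb_uv, 2 * f1$lb_uv)
  expect_identical(f2$ta_s, f1$ta_s)
  expect_identical(f2$tb_s, f1$tb_s)

  k <- 3L
  w3 <- w; w3$samples <- c(rep(w$samples[1], k), head(w$samples, -k))
  f3 <- extract_la3_features(w3)
  expect_equal(f3$ta_s, f1$ta_s + k / w$fs)
  expect_equal(f3$tb_s, f1$tb_s + k / w$fs)
})

test_that("lb convention switch measures baseline-to-peak instead of trough-to-peak", {
  w <- kernel_waveform(la3_params(noise_sd = 0))
  tp <- extract_la3_features(w, lb_mode = "trough_to_peak")
  bp <- extract_la3_features(w, lb_mode = "baseline_to_peak")
  expect_lt(bp$lb_uv, tp$lb_uv)
  expect_equal(tp$lb_uv - bp$lb_uv, tp$la_uv, tolerance = 1e-9)
})

test_that("b-wave latency stays accurate under recording-level noise", {
  p <- la3_params(noise_sd = 2)
  d <- simulate_la3(p, n_per_class = c(male = 100), seed = 21)
  oracle <- la3_grid_oracle(la3_params(noise_sd = 0))
  errs <- vapply(d, function(w) abs(extract_la3_features(w)$tb_s - oracle$tb),
                 double(1))
  expect_lte(median(errs), 0.002)
})

test_that("flicker features follow the sinusoid oracle and phase translation", {
  p <- flicker_params(amp = 6, harmonic_amps = numeric(0), noise_sd = 0)
  w <- simulate_flicker30(p, n_per_class = c(male = 1), seed = 1)[[1]]
  ft <- extract_flicker_features(w)
  quant <- 2 * p$amp * (1 - cos(pi * 30 / w$fs)) + 1e-9
  expect_lt(abs(ft$lb_uv - 2 * p$amp), quant)

  dphi <- -pi / 3                          # delays the waveform
  p2 <- flicker_params(amp = 6, phase = dphi, harmonic_amps = numeric(0),
                       noise_sd = 0)
  w2 <- simulate_flicker30(p2, n_per_class = c(male = 1), seed = 1)[[1]]
  ft2 <- extract_flicker_features(w2)
  shift <- (-dphi) / (2 * pi * 30)
  dt <- (ft2$tb_s - ft$tb_s) %% (1 / 30)
  expect_lt(min(abs(dt - shift), abs(dt - shift - 1 / 30)), 1.5 / w$fs)

  # harmonics: dense-grid oracle applying the same peak-to-adjacent-trough
  # definition to the continuous model
  p3 <- flicker_params(amp = 6, harmonic_amps = c(2, 1), noise_sd = 0)
  w3 <- simulate_flicker30(p3, n_per_class = c(male = 1), seed = 1)[[1]]
  tt <- seq(1 / 30, 2 / 30, by = 1e-6)
  y <- flicker_model(tt, p3)
  t_pk <- tt[which.max(y)]
  jj <- seq(t_pk, t_pk + 0.75 / 30, by = 1e-6)
  oracle_lb <- max(y) - min(flicker_model(jj, p3))
  ft3 <- extract_flicker_features(w3)
  expect_equal(ft3$lb_uv, oracle_lb, tolerance = 0.02)

  short <- w
  short$samples <- short$samples[1:40]     # just over one cycle
  expect_error(extract_flicker_features(short),
               class = "ergsynth_extraction_error")
})

test_that("feature_table covers the fixture, excludes failures, enforces contracts", {
  la3 <- cached_la3(101)
  ft <- feature_table(la3, quiet = TRUE)
  expect_gte(nrow(ft), ceiling(0.95 * length(la3)))
  expect_equal(nrow(ft) + nrow(attr(ft, "exclusions")), length(la3))

  one <- feature_table(la3[1], quiet = TRUE)
  expect_equal(nrow(one), 1L)

  mixed <- c(la3[1:2], simulate_flicker30(n_per_class = c(male = 1), seed = 1))
  expect_error(feature_table(mixed), class = "ergsynth_validation_error")
  expect_error(feature_table(erg_dataset()), class = "ergsynth_validation_error")

  # a flat record is excluded and logged with its reason
  bad <- la3[1:5]
  flat <- bad[[3]]; flat$samples <- rep(1, length(flat$samples))
  bad <- erg_dataset(c(unclass(bad[1:2]), list(flat), unclass(bad[4:5])))
  expect_message(ft2 <- feature_table(bad), "excluded 1 of 5")
  expect_equal(nrow(ft2), 4L)
  expect_match(attr(ft2, "exclusions")$reason, "flat")
})
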