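test_that("LA3 kernel has the defined trough, baseline and stationary points", {
  p <- la3_params(a_amp = 10, a_time = 0.015, a_width = 0.001,
                  b_amp = 25, b_time = 0.060, b_width = 0.002,
                  op_amp = 0, noise_sd = 0)
  # narrow, well-separated lobes: value at a_time is the trough depth
  expect_equal(la3_model(p$a_time, p), -p$a_amp, tolerance = 1e-6)
  # far from both lobes the kernel sits on the zero baseline
  expect_lt(abs(la3_model(0, p)), 1e-10)

  # dense-grid global minimum matches the analytic stationary point of the
  # two-Gaussian sum (root of the derivative, found independently)
  p2 <- la3_params(a_amp = 10, a_time = 0.015, a_width = 0.004,
                   b_amp = 25, b_time = 0.032, b_width = 0.008,
                   op_amp = 0, noise_sd = 0)
  tg <- seq(0, 0.25, by = 1e-6)
  t_grid <- tg[which.min(la3_model(tg, p2))]
  dfun <- function(t) {
    with(p2, a_amp * (t - a_time) / a_width^2 * exp(-(t - a_time)^2 / (2 * a_width^2)) +
           -b_amp * (t - b_time) / b_width^2 * exp(-(t - b_time)^2 / (2 * b_width^2)))
  }
  t_analytic <- uniroot(dfun, c(0.005, 0.025), tol = 1e-10)$root
  expect_lt(abs(t_grid - t_analytic), 2e-6)   # grid resolution
})

test_that("parameter validation rejects inverted wave order and bad widths", {
  expect_error(la3_params(a_time = 0.04, b_time = 0.03),
               class = "ergsynth_validation_error")
  expect_error(la3_params(a_width = 0), class = "ergsynth_validation_error")
  expect_error(la3_params(noise_sd = -1), class = "ergsynth_validation_error")
  expect_error(flicker_params(fundamental = 25), class = "ergsynth_validation_error")
  expect_error(simulate_la3(la3_params(b_time = 0.3), duration = 0.25),
               class = "ergsynth_validation_error")
})

test_that("zero-noise simulation reproduces the sampled kernel; seeds reproduce", {
  p <- la3_params(noise_sd = 0)
  d <- simulate_la3(p, n_per_class = c(male = 3, female = 2), seed = 4)
  t <- (0:249) / 1000
  kern <- la3_model(t, p)
  for (w in d) expect_equal(w$samples, kern)

  d1 <- simulate_la3(seed = 9); d2 <- simulate_la3(seed = 9)
  expect_identical(lapply(d1, `[[`, "samples"), lapply(d2, `[[`, "samples"))
  d3 <- simulate_la3(seed = 10)
  expect_false(identical(d1[[1]]$samples, d3[[1]]$samples))
})

test_that("additive noise has the configured per-sample spread", {
  p <- la3_params(noise_sd = 1)
  d <- simulate_la3(p, n_per_class = c(male = 200, female = 0), seed = 12)
  X <- t(vapply(d, `[[`, double(250), "samples"))
  sds <- apply(X, 2, sd)
  for (i in c(1, 60, 125, 190, 250))
    expect_lt(abs(sds[i] - 1), 0.15)
})

test_that("sex effect machinery: identity is a no-op, shifts apply to the target only", {
  p <- la3_params()
  expect_identical(apply_sex_effect(p, identity_sex_effect(), "male"), p)
  eff <- sex_effect("male", scale = list(b_amp = 0.9), offset = list(b_time = 0.0015))
  pm <- apply_sex_effect(p, eff, "male")
  expect_equal(pm$b_amp, p$b_amp * 0.9)
  expect_equal(pm$b_time, p$b_time + 0.0015)
  expect_identical(apply_sex_effect(p, eff, "female"), p)
  expect_error(apply_sex_effect(p, sex_effect("male", scale = list(zz = 2)), "male"),
               class = "ergsynth_validation_error")
})

test_that("noiseless flicker is a pure tone with the expected spectrum and swing", {
  p <- flicker_params(amp = 7, harmonic_amps = numeric(0), noise_sd = 0)
  d <- simulate_flicker30(p, n_per_class = c(male = 1, female = 0),
                          duration = 0.30, seed = 1)
  y <- d[[1]]$samples                      # 9 full cycles in 300 samples
  mag <- Mod(fft(y))[1:150]
  expect_equal(which.max(mag), 10L)        # bin 9 (0-based) = 30 Hz
  expect_gt(mag[10] / sum(mag[-10]), 1e6)

  # dense-grid oracle: continuous peak-to-trough is exactly 2*amp; the
  # sampled swing matches within one sample-quantization step
  swing <- diff(range(y))
  quant <- 2 * p$amp * (1 - cos(pi * 30 / 1000))
  expect_lt(abs(swing - 2 * p$amp), quant + 1e-9)

  z <- simulate_flicker30(flicker_params(amp = 0, harmonic_amps = numeric(0),
                                         noise_sd = 0),
                          n_per_class = c(male = 1), seed = 1)
  expect_true(all(z[[1]]$samples == 0))
})

test_that("study fixture reproduces the published composition for every seed", {
  for (s in c(101, 202)) {
    fx <- if (s == 101) cached_fixture(101) else make_study_fixture(seed = s)
    m <- waveform_meta(fx)
    la3 <- m[m$stimulus == "LA3", ]
    fl <- m[m$stimulus == "FLICKER30", ]
    expect_equal(nrow(la3), 170)
    expect_equal(sum(la3$sex == "male"), 60)
    expect_equal(sum(la3$sex == "female"), 110)
    expect_equal(sum(la3$eye == "left"), 85)
    expect_equal(sum(la3$eye == "right"), 85)
    expect_equal(nrow(fl), 67)
    expect_equal(sum(fl$sex == "male"), 18)
    expect_equal(sum(fl$sex == "female"), 49)
    expect_equal(sum(fl$eye == "left"), 33)
    expect_equal(sum(fl$eye == "right"), 34)
  }
})

test_that("fixtures are seed-deterministic; different seeds differ only in samples", {
  a <- make_study_fixture(seed = 5)
  b <- make_study_fixture(seed = 5)
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
  c_ <- make_study_fixture(seed = 6)
  expect_identical(waveform_meta(a), waveform_meta(c_))
  expect_false(identical(a[[1]]$samples, c_[[1]]$samples))
})

test_that("noiseless LA3 kernel energy above 300 Hz is negligible", {
  p <- la3_params(noise_sd = 0)
  y <- la3_model((0:249) / 1000, p)
  mag2 <- Mod(fft(y))^2
  freq <- (0:249) * 1000 / 250
  freq <- pmin(freq, 1000 - freq)
  expect_lt(sum(mag2[freq > 300]) / sum(mag2), 0.01)
})

test_that("a stronger b-wave class effect raises the extracted lb of that class", {
  base <- make_study_fixture(effect_la3 = identity_sex_effect(), seed = 33)
  boosted <- make_study_fixture(
    effect_la3 = sex_effect("male", scale = list(b_amp = 1.3)), seed = 33)
  lb_of <- function(fx) {
    la3 <- fx[waveform_meta(fx)$stimulus == "LA3"]
    ft <- feature_table(la3, quiet = TRUE)
    mean(ft$lb_uv[ft$sex == "male"])
  }
  expect_gt(lb_of(boosted), lb_of(base))
})
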