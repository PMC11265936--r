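test_that("one-epoch training returns a handle with a finite loss log", {
  d <- simulate_la3(n_per_class = c(male = 4, female = 4),
                    duration = 0.05, seed = 2)
  g <- erg_cgan(d, gan_config(epochs = 1, batch_size = 4), seed = 3)
  expect_s3_class(g, "erg_cgan")
  expect_equal(nrow(g$log), 1L)
  expect_true(all(is.finite(unlist(g$log))))
  expect_equal(g$signal_length, 50L)
})

test_that("training and sampling are seed-deterministic", {
  d <- simulate_la3(n_per_class = c(male = 6, female = 6),
                    duration = 0.05, seed = 2)
  cfg <- gan_config(epochs = 3, batch_size = 4)
  g1 <- erg_cgan(d, cfg, seed = 11)
  g2 <- erg_cgan(d, cfg, seed = 11)
  expect_identical(g1$log, g2$log)
  expect_identical(g1$generator, g2$generator)

  s1 <- generate_waveforms(g1, "male", 5, seed = 4)
  s2 <- generate_waveforms(g1, "male", 5, seed = 4)
  expect_identical(lapply(s1, `[[`, "samples"), lapply(s2, `[[`, "samples"))
  s3 <- generate_waveforms(g1, "male", 5, seed = 5)
  expect_false(identical(s1[[1]]$samples, s3[[1]]$samples))
})

test_that("generated batches have the requested cardinality, shape and labels", {
  g <- cached_tiny_gan()
  s <- generate_waveforms(g, "male", 5, seed = 1)
  expect_length(s, 5L)
  m <- waveform_meta(s)
  expect_true(all(m$n_samples == g$signal_length))
  expect_true(all(m$sex == "male"))
  expect_true(all(m$provenance == "synthetic"))
  expect_true(all(vapply(s, function(w) all(is.finite(w$samples)), logical(1))))
  expect_error(generate_waveforms(g, "child", 5), class = "ergsynth_validation_error")
  # simulate() method delegates
  s2 <- simulate(g, nsim = 5, seed = 1, label = "male")
  expect_identical(lapply(s2, `[[`, "samples"), lapply(s, `[[`, "samples"))
})

test_that("augmentation arithmetic: parity and fractional policies", {
  d <- simulate_la3(n_per_class = c(male = 24, female = 48), seed = 6)
  g <- cached_tiny_gan()
  par <- balance_with_synthetic(d, g, augmentation_policy(balance_to_parity = TRUE),
                                seed = 1)
  m <- waveform_meta(par)
  expect_equal(sum(m$sex == "male"), 48L)
  expect_equal(sum(m$sex == "female"), 48L)
  expect_equal(sum(m$provenance == "synthetic"), 24L)

  frac <- balance_with_synthetic(d, g, augmentation_policy(synth_fraction = 0.2),
                                 seed = 1, initial_size = 170)
  expect_equal(length(frac), length(d) + 34L)

  # conservation: every real record passes through untouched
  expect_identical(lapply(frac[seq_along(d)], `[[`, "samples"),
                   lapply(d, `[[`, "samples"))
  expect_error(augmentation_policy(synth_fraction = 0),
               class = "ergsynth_validation_error")
})

test_that("checkpoints round-trip with an auditable sidecar", {
  g <- cached_tiny_gan()
  f <- withr::local_tempfile(fileext = ".rds")
  write_cgan(g, f)
  expect_true(file.exists(paste0(f, ".json")))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$signal_length, g$signal_length)
  g2 <- read_cgan(f)
  expect_identical(generate_waveforms(g2, "male", 3, seed = 2)[[1]]$samples,
                   generate_waveforms(g, "male", 3, seed = 2)[[1]]$samples)
})

test_that("a trained generator emits mostly plausible light-adapted morphology", {
  train <- simulate_la3(n_per_class = c(male = 100, female = 100), seed = 17)
  g <- cached("gate_gan", erg_cgan(train, gan_config(epochs = 300), seed = 17))
  expect_true(all(is.finite(unlist(g$log))))
  rng <- max(vapply(train, function(w) max(w$samples), double(1))) -
    min(vapply(train, function(w) min(w$samples), double(1)))
  s <- generate_waveforms(g, "male", 100, seed = 18)
  expect_gte(mean(plausibility_gate(s, rng)), 0.70)
})

test_that("generated male waveforms land nearer the male than the female feature mean", {
  # class-conditioning sanity at desk scale: majority vote over 3 seeds
  wins <- 0L
  for (s in 1:3) {
    train <- simulate_la3(effect = default_sex_effect_la3(),
                          n_per_class = c(male = 50, female = 50),
                          seed = 30 + s)
    g <- erg_cgan(train, gan_config(epochs = 300), seed = 30 + s)
    synth <- generate_waveforms(g, "male", 40, seed = 40 + s)
    synth <- lowpass_dataset(synth)
    real_ft <- feature_table(train, quiet = TRUE)
    syn_ft <- feature_table(synth, quiet = TRUE)
    lb_m <- mean(real_ft$lb_uv[real_ft$sex == "male"])
    lb_f <- mean(real_ft$lb_uv[real_ft$sex == "female"])
    lb_s <- mean(syn_ft$lb_uv)
    if (abs(lb_s - lb_m) < abs(lb_s - lb_f)) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
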