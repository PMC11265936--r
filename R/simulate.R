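#' Parameters of the light-adapted single-flash (LA3) waveform model
#'
#' The noiseless LA3 kernel is a sum of a negative Gaussian lobe (the a-wave
#' trough, cone hyperpolarization), a positive Gaussian lobe (the b-wave
#' peak, bipolar/amacrine origin) and a Gaussian-windowed sinusoid placed on
#' the ascending limb (the oscillatory potentials, OPs). Defaults are
#' plausible pediatric light-adapted magnitudes.
#'
#' @param a_amp a-wave trough depth, microvolts (> 0).
#' @param a_time a-wave time-to-trough, seconds.
#' @param a_width Gaussian width of the trough, seconds.
#' @param b_amp b-wave peak height, microvolts (> 0).
#' @param b_time b-wave time-to-peak, seconds; must exceed `a_time`.
#' @param b_width Gaussian width of the peak, seconds.
#' @param op_amp OP envelope amplitude, microvolts (>= 0; 0 disables OPs).
#' @param op_freq OP carrier frequency, Hz.
#' @param op_center,op_width Centre and width (seconds) of the OP envelope,
#'   normally on the ascending limb between `a_time` and `b_time`.
#' @param noise_sd Additive white-noise standard deviation, microvolts.
#' @param baseline_drift Amplitude (microvolts) of a slow random-phase
#'   sinusoidal offset added per record; 0 disables drift.
#' @return An object of class `la3_params`.
#' @export
la3_params <- function(a_amp = 10, a_time = 0.015, a_width = 0.004,
                       b_amp = 25, b_time = 0.032, b_width = 0.008,
                       op_amp = 3, op_freq = 120, op_center = 0.024,
                       op_width = 0.006, noise_sd = 2, baseline_drift = 0) {
  p <- structure(list(a_amp = a_amp, a_time = a_time, a_width = a_width,
                      b_amp = b_amp, b_time = b_time, b_width = b_width,
                      op_amp = op_amp, op_freq = op_freq,
                      op_center = op_center, op_width = op_width,
                      noise_sd = noise_sd, baseline_drift = baseline_drift),
                 class = "la3_params")
  validate_la3_params(p)
  p
}

validate_la3_params <- function(p) {
  for (f in names(p))
    if (!is_scalar_num(p[[f]])) abort_validation(sprintf("%s must be a finite scalar", f))
  if (p$a_amp <= 0 || p$b_amp <= 0) abort_validation("a_amp and b_amp must be > 0")
  if (p$a_time <= 0 || p$a_time >= p$b_time)
    abort_validation("need 0 < a_time < b_time (a-wave precedes b-wave)")
  if (p$a_width <= 0 || p$b_width <= 0 || p$op_width <= 0)
    abort_validation("all widths must be > 0")
  if (p$op_amp < 0 || p$noise_sd < 0)
    abort_validation("op_amp and noise_sd must be >= 0")
  if (p$op_freq <= 0) abort_validation("op_freq must be > 0")
  invisible(p)
}

#' Parameters of the 30 Hz flicker waveform model
#'
#' A steady-state cone-driven response: a 30 Hz fundamental plus optional
#' low-order harmonics. The fundamental frequency is fixed at 30 Hz by the
#' stimulus.
#'
#' @param amp Fundamental amplitude, microvolts (> 0).
#' @param phase Phase of the fundamental, radians (harmonics are phase-locked
#'   so that changing `phase` translates the waveform in time).
#' @param fundamental Fundamental frequency; must be 30.
#' @param harmonic_amps Amplitudes (microvolts, >= 0) of the 2nd, 3rd, ...
#'   harmonics.
#' @param noise_sd Additive white-noise standard deviation, microvolts.
#' @return An object of class `flicker_params`.
#' @export
flicker_params <- function(amp = 8, phase = 0, fundamental = 30,
                           harmonic_amps = c(2, 1), noise_sd = 2) {
  p <- structure(list(amp = amp, phase = phase, fundamental = fundamental,
                      harmonic_amps = as.double(harmonic_amps),
                      noise_sd = noise_sd),
                 class = "flicker_params")
  validate_flicker_params(p)
  p
}

validate_flicker_params <- function(p) {
  if (!is_scalar_num(p$amp) || p$amp < 0) abort_validation("amp must be >= 0")
  if (!is_scalar_num(p$phase)) abort_validation("phase must be a finite scalar")
  if (!is_scalar_num(p$fundamental) || p$fundamental != 30)
    abort_validation("fundamental must be exactly 30 Hz")
  if (any(!is.finite(p$harmonic_amps)) || any(p$harmonic_amps < 0))
    abort_validation("harmonic_amps must be finite and >= 0")
  if (!is_scalar_num(p$noise_sd) || p$noise_sd < 0)
    abort_validation("noise_sd must be >= 0")
  invisible(p)
}

#' Class effect on waveform-model parameters
#'
#' Describes how one class (by default male, the study's minority) differs
#' from the base parameterization: multiplicative scales and additive
#' offsets applied per parameter field. The identity effect (no scales, no
#' offsets) leaves parameters unchanged.
#'
#' @param target The class the effect applies to (`"male"` or `"female"`).
#' @param scale Named list of multiplicative factors, e.g.
#'   `list(b_amp = 0.9)`.
#' @param offset Named list of additive shifts in the field's own units,
#'   e.g. `list(b_time = 0.0015)`.
#' @return An object of class `sex_effect`.
#' @export
sex_effect <- function(target = "male", scale = list(), offset = list()) {
  target <- match.arg(target, c("male", "female"))
  for (v in c(scale, offset))
    if (!is_scalar_num(v)) abort_validation("sex_effect entries must be finite scalars")
  structure(list(target = target, scale = scale, offset = offset),
            class = "sex_effect")
}

#' @rdname sex_effect
#' @export
identity_sex_effect <- function() sex_effect()

#' Default class effects used by the study-emulation fixture
#'
#' A modest, detectable male shift: b-wave amplitude scaled by 0.9 and
#' b-wave time-to-peak delayed 1.5 ms for LA3; flicker fundamental amplitude
#' scaled by 0.9. These are stand-ins — the magnitude of the real
#' male/female ERG difference is not quantified by the reference ranges that
#' motivate it.
#'
#' @return A `sex_effect`.
#' @export
default_sex_effect_la3 <- function() {
  sex_effect("male", scale = list(b_amp = 0.9), offset = list(b_time = 0.0015))
}

#' @rdname default_sex_effect_la3
#' @export
default_sex_effect_flicker <- function() {
  sex_effect("male", scale = list(amp = 0.9))
}

#' Apply a class effect to model parameters
#'
#' @param params An `la3_params` or `flicker_params` object.
#' @param effect A [sex_effect].
#' @param sex The class of the record being generated; the effect applies
#'   only when `sex == effect$target`.
#' @return Parameters of the same class, revalidated.
#' @export
apply_sex_effect <- function(params, effect, sex) {
  stopifnot(inherits(effect, "sex_effect"))
  if (sex != effect$target) return(params)
  for (f in names(effect$scale)) {
    if (is.null(params[[f]])) abort_validation(sprintf("unknown parameter field '%s' in sex_effect", f))
    params[[f]] <- params[[f]] * effect$scale[[f]]
  }
  for (f in names(effect$offset)) {
    if (is.null(params[[f]])) abort_validation(sprintf("unknown parameter field '%s' in sex_effect", f))
    params[[f]] <- params[[f]] + effect$offset[[f]]
  }
  if (inherits(params, "la3_params")) validate_la3_params(params)
  else validate_flicker_params(params)
  params
}

#' Noiseless LA3 kernel
#'
#' Deterministic continuous-time model value: negative Gaussian trough at
#' `a_time`, positive Gaussian peak at `b_time`, plus a Gaussian-windowed
#' sinusoid (the OPs) centred on the ascending limb. With `op_amp = 0` the
#' kernel is exactly the sum of the two Gaussian lobes.
#'
#' @param t Time(s) in seconds from flash onset; vectorized.
#' @param params An [la3_params].
#' @return Model amplitude(s) in microvolts.
#' @export
la3_model <- function(t, params) {
  validate_la3_params(params)
  if (any(t < 0)) abort_validation("t must be >= 0")
  with(params,
       -a_amp * exp(-(t - a_time)^2 / (2 * a_width^2)) +
         b_amp * exp(-(t - b_time)^2 / (2 * b_width^2)) +
         op_amp * exp(-(t - op_center)^2 / (2 * op_width^2)) *
           sin(2 * pi * op_freq * (t - op_center)))
}

#' Noiseless 30 Hz flicker kernel
#'
#' Fundamental plus phase-locked harmonics; changing `phase` translates the
#' whole waveform in time.
#'
#' @param t Time(s) in seconds; vectorized.
#' @param params A [flicker_params].
#' @return Model amplitude(s) in microvolts.
#' @export
flicker_model <- function(t, params) {
  validate_flicker_params(params)
  f0 <- params$fundamental
  y <- params$amp * sin(2 * pi * f0 * t + params$phase)
  for (k in seq_along(params$harmonic_amps)) {
    h <- k + 1L
    y <- y + params$harmonic_amps[k] * sin(2 * pi * f0 * h * t + h * params$phase)
  }
  y
}

# Shared record-generation loop for both stimuli.
simulate_records <- function(kernel_fun, params, sex_effect, n_per_class,
                             fs, duration, seed, stimulus, id_prefix) {
  if (!is_scalar_num(fs) || fs <= 0) abort_validation("fs must be > 0")
  n_samp <- round(duration * fs)
  if (n_samp < 2L) abort_validation("duration * fs must be >= 2")
  if (is.null(names(n_per_class)))
    names(n_per_class) <- c("male", "female")[seq_along(n_per_class)]
  if (any(n_per_class < 0)) abort_validation("n_per_class must be >= 0")
  t <- (0:(n_samp - 1L)) / fs
  waves <- list()
  with_seed(seed, {
    for (cls in names(n_per_class)) {
      p <- apply_sex_effect(params, sex_effect, cls)
      kern <- kernel_fun(t, p)
      for (i in seq_len(n_per_class[[cls]])) {
        y <- kern
        if (p$noise_sd > 0) y <- y + stats::rnorm(n_samp, 0, p$noise_sd)
        drift <- if (!is.null(p$baseline_drift)) p$baseline_drift else 0
        if (drift > 0)
          y <- y + drift * sin(2 * pi * 2 * t + stats::runif(1, 0, 2 * pi))
        waves[[length(waves) + 1L]] <- erg_waveform(
          samples = y, fs = fs, stimulus = stimulus,
          subject_id = sprintf("%s_%s_%03d", id_prefix, cls, i),
          eye = if (i %% 2L == 1L) "left" else "right", sex = cls,
          provenance = "real", replicate_index = 1L)
      }
    }
  })
  erg_dataset(waves)
}

#' Simulate labelled LA3 waveforms
#'
#' Draws `n_per_class` independent records per class: the noiseless kernel
#' for class-specific parameters (base parameters with the [sex_effect]
#' applied to its target class) plus additive white Gaussian noise.
#' Deterministic given `seed`; with `noise_sd = 0` and zero drift every
#' record equals the kernel sampled on the time grid.
#'
#' @param params Base [la3_params].
#' @param effect A [sex_effect]; defaults to identity.
#' @param n_per_class Named counts, e.g. `c(male = 10, female = 20)`.
#' @param fs Sampling rate, Hz.
#' @param duration Record length, seconds; must contain `b_time`.
#' @param seed Integer RNG seed.
#' @return An [erg_dataset].
#' @export
simulate_la3 <- function(params = la3_params(), effect = identity_sex_effect(),
                         n_per_class = c(male = 10, female = 10),
                         fs = 1000, duration = 0.25, seed = 1) {
  validate_la3_params(params)
  if (params$b_time >= duration)
    abort_validation("duration too short to contain the b-wave peak")
  if (params$op_freq >= fs / 2)
    abort_validation("op_freq must be below the Nyquist frequency")
  simulate_records(la3_model, params, effect, n_per_class, fs, duration,
                   seed, "LA3", "sim")
}

#' Simulate labelled 30 Hz flicker waveforms
#'
#' @inheritParams simulate_la3
#' @param params Base [flicker_params].
#' @return An [erg_dataset].
#' @export
simulate_flicker30 <- function(params = flicker_params(),
                               effect = identity_sex_effect(),
                               n_per_class = c(male = 10, female = 10),
                               fs = 1000, duration = 0.30, seed = 1) {
  validate_flicker_params(params)
  top <- 30 * (1 + length(params$harmonic_amps))
  if (top >= fs / 2)
    abort_validation("highest harmonic must be below the Nyquist frequency")
  params$baseline_drift <- NULL
  simulate_records(flicker_model, params, effect, n_per_class, fs, duration,
                   seed, "FLICKER30", "sim")
}

# Deterministic subject/eye/replicate roster reproducing the study
# composition: LA3 170 waveforms (60 male / 110 female, 85 per eye),
# flicker 67 (18 male / 49 female, 33 left / 34 right). Only marginals are
# published; the joint eye-by-sex allocation is the simplest consistent one
# (males 30/30 LA3 and 9/9 flicker, females take the remainder).
study_roster <- function() {
  male_la3 <- expand.grid(subject_id = sprintf("S_M%02d", 1:15),
                          eye = c("left", "right"), replicate_index = 1:2,
                          stringsAsFactors = FALSE)
  fem_la3 <- expand.grid(subject_id = sprintf("S_F%02d", 1:27),
                         eye = c("left", "right"), replicate_index = 1:2,
                         stringsAsFactors = FALSE)
  fem_la3 <- rbind(fem_la3,
                   data.frame(subject_id = "S_F28", eye = c("left", "right"),
                              replicate_index = 1L, stringsAsFactors = FALSE))
  male_fl <- expand.grid(subject_id = sprintf("S_M%02d", 1:9),
                         eye = c("left", "right"), replicate_index = 1L,
                         stringsAsFactors = FALSE)
  fem_fl <- expand.grid(subject_id = sprintf("S_F%02d", 1:24),
                        eye = c("left", "right"), replicate_index = 1L,
                        stringsAsFactors = FALSE)
  fem_fl <- rbind(fem_fl,
                  data.frame(subject_id = "S_F25", eye = "right",
                             replicate_index = 1L, stringsAsFactors = FALSE))
  add <- function(df, sex, stimulus) cbind(df, sex = sex, stimulus = stimulus,
                                           stringsAsFactors = FALSE)
  rbind(add(male_la3, "male", "LA3"), add(fem_la3, "female", "LA3"),
        add(male_fl, "male", "FLICKER30"), add(fem_fl, "female", "FLICKER30"))
}

#' Build the study-emulation fixture
#'
#' Generates a dataset whose composition matches the study exactly for every
#' seed: 170 LA3 waveforms (60 male / 110 female, 85 per eye) and 67 flicker
#' waveforms (18 male / 49 female, 33 left / 34 right), with subject
#' identifiers reused across eyes and replicates to mimic within-subject
#' replicates. On top of the class effect, each subject receives random
#' multiplicative jitter on amplitude parameters and additive jitter on
#' timing parameters, so that replicates of one subject are correlated and
#' classes overlap realistically.
#'
#' @param la3,flicker Base model parameters.
#' @param effect_la3,effect_flicker Class effects (defaults: the package's
#'   modest male shifts).
#' @param fs Sampling rate, Hz.
#' @param duration_la3,duration_flicker Record lengths, seconds.
#' @param subject_sd_amp Log-scale SD of per-subject amplitude jitter.
#' @param subject_sd_time SD (seconds) of per-subject timing jitter.
#' @param seed Integer RNG seed; composition is identical across seeds, only
#'   parameters and noise vary.
#' @return An [erg_dataset] of 237 waveforms.
#' @export
make_study_fixture <- function(la3 = la3_params(), flicker = flicker_params(),
                               effect_la3 = default_sex_effect_la3(),
                               effect_flicker = default_sex_effect_flicker(),
                               fs = 1000, duration_la3 = 0.25,
                               duration_flicker = 0.30,
                               subject_sd_amp = 0.1, subject_sd_time = 0.001,
                               seed = 1) {
  validate_la3_params(la3)
  validate_flicker_params(flicker)
  if (la3$b_time >= duration_la3)
    abort_validation("duration_la3 too short to contain the b-wave peak")
  roster <- study_roster()
  subjects <- unique(roster$subject_id)
  waves <- vector("list", nrow(roster))
  with_seed(child_seed(seed, "fixture"), {
    jit <- list()
    for (s in subjects)
      jit[[s]] <- list(amp = exp(stats::rnorm(1, 0, subject_sd_amp)),
                       t_a = stats::rnorm(1, 0, subject_sd_time),
                       t_b = stats::rnorm(1, 0, subject_sd_time),
                       phase = stats::rnorm(1, 0, 0.2))
    t_la3 <- (0:(round(duration_la3 * fs) - 1L)) / fs
    t_fl <- (0:(round(duration_flicker * fs) - 1L)) / fs
    for (i in seq_len(nrow(roster))) {
      r <- roster[i, ]
      j <- jit[[r$subject_id]]
      if (r$stimulus == "LA3") {
        p <- apply_sex_effect(la3, effect_la3, r$sex)
        p$a_amp <- p$a_amp * j$amp; p$b_amp <- p$b_amp * j$amp
        p$op_amp <- p$op_amp * j$amp
        p$a_time <- p$a_time + j$t_a; p$b_time <- p$b_time + j$t_b
        validate_la3_params(p)
        y <- la3_model(t_la3, p) + stats::rnorm(length(t_la3), 0, p$noise_sd)
        tt <- t_la3
      } else {
        p <- apply_sex_effect(flicker, effect_flicker, r$sex)
        p$amp <- p$amp * j$amp
        p$phase <- p$phase + j$phase
        validate_flicker_params(p)
        y <- flicker_model(t_fl, p) + stats::rnorm(length(t_fl), 0, p$noise_sd)
        tt <- t_fl
      }
      waves[[i]] <- erg_waveform(y, fs, r$stimulus, r$subject_id, r$eye,
                                 r$sex, "real", r$replicate_index)
    }
  })
  erg_dataset(waves)
}
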