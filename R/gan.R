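#' Conditional GAN configuration
#'
#' Architecture and optimization settings for [erg_cgan()]. Defaults are the
#' smallest configuration adequate for a few hundred waveforms of a few
#' hundred samples: a fully connected generator (latent vector plus one-hot
#' class label through two leaky-ReLU hidden layers to a tanh output on the
#' normalized amplitude scale) and a mirrored discriminator, trained with
#' Adam at learning rate 2e-4 for 300 epochs at batch size 16.
#'
#' @param latent_dim Dimension of the generator's latent input.
#' @param generator_hidden,discriminator_hidden Hidden layer widths.
#' @param lr_g,lr_d Adam learning rates for generator/discriminator.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(latent_dim = 64, generator_hidden = c(128, 256),
                       discriminator_hidden = c(256, 128),
                       lr_g = 2e-4, lr_d = 2e-4, batch_size = 16,
                       epochs = 300) {
  if (latent_dim < 1 || epochs < 1 || batch_size < 1)
    abort_validation("latent_dim, epochs and batch_size must be >= 1")
  if (lr_g <= 0 || lr_d <= 0) abort_validation("learning rates must be > 0")
  structure(list(latent_dim = as.integer(latent_dim),
                 generator_hidden = as.integer(generator_hidden),
                 discriminator_hidden = as.integer(discriminator_hidden),
                 lr_g = lr_g, lr_d = lr_d,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs)),
            class = "gan_config")
}

gan_classes <- c("female", "male")

one_hot <- function(labels) {
  m <- matrix(0, nrow = length(labels), ncol = length(gan_classes))
  m[cbind(seq_along(labels), match(labels, gan_classes))] <- 1
  m
}

#' Fit a conditional GAN to labelled ERG waveforms
#'
#' Learns the class-conditioned distribution of fixed-length waveforms by
#' adversarial training: the generator maps a Gaussian latent vector plus a
#' one-hot sex label to a waveform on a normalized scale, the discriminator
#' scores waveform-plus-label pairs, and both are updated alternately under
#' the binary cross-entropy objective (non-saturating generator loss).
#' Amplitudes are min-max normalized to \[-1, 1\] over the whole training
#' set before training and de-normalized on sampling. Training is
#' deterministic given `seed` on a fixed platform.
#'
#' @param data An [erg_dataset] of a single stimulus with both sexes
#'   represented (or the target class with at least `batch_size` records).
#' @param config A [gan_config].
#' @param seed Integer RNG seed controlling initialization, shuffling and
#'   latent draws.
#' @param verbose Print the loss every 50 epochs.
#' @return An object of class `erg_cgan`: the trained generator and
#'   discriminator, normalization constants, acquisition metadata and a
#'   per-epoch training log. Use [simulate()][simulate.erg_cgan] or
#'   [generate_waveforms()] to sample from it.
#' @seealso [balance_with_synthetic()], [plausibility_gate()]
#' @export
erg_cgan <- function(data, config = gan_config(), seed = 1, verbose = FALSE) {
  if (!inherits(data, "erg_dataset") || length(data) == 0L)
    abort_validation("data must be a nonempty erg_dataset")
  m <- waveform_meta(data)
  if (length(unique(m$stimulus)) != 1L)
    abort_validation("train set must contain a single stimulus")
  if (length(unique(m$n_samples)) != 1L || length(unique(m$fs)) != 1L)
    abort_validation("train set waveforms must share length and fs")
  cls_counts <- table(factor(m$sex, gan_classes))
  if (sum(cls_counts > 0) < 2L && max(cls_counts) < config$batch_size)
    abort_validation("need both classes, or one class with >= batch_size records")
  sig_len <- m$n_samples[1]
  X <- t(vapply(data, `[[`, double(sig_len), "samples"))
  mn <- min(X); mx <- max(X)
  if (mx <= mn) abort_validation("degenerate training data: constant amplitudes")
  Xn <- 2 * (X - mn) / (mx - mn) - 1
  Y <- one_hot(m$sex)
  n <- nrow(Xn)
  n_cls <- length(gan_classes)

  G <- D <- NULL
  log_df <- data.frame(epoch = integer(config$epochs),
                       loss_d = double(config$epochs),
                       loss_g = double(config$epochs))
  with_seed(seed, {
    G <- nn_init(c(config$latent_dim + n_cls, config$generator_hidden, sig_len))
    D <- nn_init(c(sig_len + n_cls, config$discriminator_hidden, 1L))
    sG <- adam_init(G); sD <- adam_init(D)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ld <- lg <- 0; nb <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        bs <- length(idx)
        x_real <- Xn[idx, , drop = FALSE]
        y <- Y[idx, , drop = FALSE]

        # --- discriminator step ---
        z <- matrix(stats::rnorm(bs * config$latent_dim), nrow = bs)
        fg <- nn_forward(G, cbind(z, y), out_act = "tanh")
        fr <- nn_forward(D, cbind(x_real, y))
        ff <- nn_forward(D, cbind(fg$out, y))
        lr_ <- bce_logits(fr$out, 1)
        lf_ <- bce_logits(ff$out, 0)
        gr <- nn_backward(D, fr, lr_$dlogits)
        gf <- nn_backward(D, ff, lf_$dlogits)
        gd <- list(dW = Map(`+`, gr$dW, gf$dW), db = Map(`+`, gr$db, gf$db))
        up <- adam_step(D, gd, sD, config$lr_d)
        D <- up$net; sD <- up$state
        loss_d <- (lr_$loss + lf_$loss) / 2

        # --- generator step (fresh latent draw) ---
        z <- matrix(stats::rnorm(bs * config$latent_dim), nrow = bs)
        fg <- nn_forward(G, cbind(z, y), out_act = "tanh")
        fd <- nn_forward(D, cbind(fg$out, y))
        lgb <- bce_logits(fd$out, 1)          # non-saturating objective
        bd <- nn_backward(D, fd, lgb$dlogits)
        dFake <- bd$dX[, seq_len(sig_len), drop = FALSE]
        gg <- nn_backward(G, fg, dFake)
        up <- adam_step(G, gg, sG, config$lr_g)
        G <- up$net; sG <- up$state

        if (!is.finite(loss_d) || !is.finite(lgb$loss))
          abort("NaN/Inf loss during adversarial training; lower the learning rate or batch size",
                "ergsynth_training_error")
        ld <- ld + loss_d; lg <- lg + lgb$loss; nb <- nb + 1L
      }
      log_df[ep, ] <- list(ep, ld / nb, lg / nb)
      if (verbose && ep %% 50L == 0L)
        message(sprintf("epoch %d: loss_d=%.3f loss_g=%.3f", ep, ld / nb, lg / nb))
    }
  })
  structure(list(generator = G, discriminator = D, config = config,
                 stimulus = m$stimulus[1], fs = m$fs[1],
                 signal_length = sig_len,
                 norm = c(min = mn, max = mx),
                 classes = gan_classes,
                 train_counts = as.integer(cls_counts),
                 log = log_df, seed = seed),
            class = "erg_cgan")
}

#' @export
print.erg_cgan <- function(x, ...) {
  cat(sprintf("Conditional GAN for %s waveforms (%d samples @ %g Hz)\n",
              x$stimulus, x$signal_length, x$fs))
  cat(sprintf("  latent %d, generator %s, discriminator %s\n",
              x$config$latent_dim,
              paste(x$config$generator_hidden, collapse = "-"),
              paste(x$config$discriminator_hidden, collapse = "-")))
  cat(sprintf("  trained %d epochs on %d waveforms (%s)\n",
              nrow(x$log), sum(x$train_counts),
              paste(sprintf("%s=%d", x$classes, x$train_counts), collapse = ", ")))
  last <- x$log[nrow(x$log), ]
  cat(sprintf("  final losses: discriminator %.3f, generator %.3f\n",
              last$loss_d, last$loss_g))
  invisible(x)
}

#' @export
summary.erg_cgan <- function(object, ...) {
  print(object)
  cat("\nTraining log (every 10th epoch):\n")
  idx <- unique(c(seq(1L, nrow(object$log), by = 10L), nrow(object$log)))
  print(object$log[idx, ], row.names = FALSE)
  invisible(object$log)
}

#' Plot adversarial training losses
#'
#' @param x An [erg_cgan].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.erg_cgan <- function(x, ...) {
  graphics::matplot(x$log$epoch, cbind(x$log$loss_d, x$log$loss_g),
                    type = "l", lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "binary cross-entropy",
                    main = sprintf("CGAN training (%s)", x$stimulus), ...)
  graphics::legend("topright", c("discriminator", "generator"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Sample synthetic waveforms from a trained conditional GAN
#'
#' Draws latent vectors, runs the generator conditioned on the requested
#' class label, and de-normalizes back to microvolts. Deterministic given
#' `seed`.
#'
#' @param object A fitted [erg_cgan].
#' @param label Class to condition on (`"male"` or `"female"`).
#' @param n Number of waveforms.
#' @param seed Integer RNG seed.
#' @return An [erg_dataset] of `n` waveforms tagged `provenance =
#'   "synthetic"` with the conditioned label.
#' @export
generate_waveforms <- function(object, label, n, seed = 1) {
  if (!inherits(object, "erg_cgan")) abort_validation("object must be an erg_cgan")
  if (!label %in% object$classes)
    abort_validation(sprintf("unknown label '%s'", label))
  if (!is_scalar_num(n) || n < 1) abort_validation("n must be >= 1")
  n <- as.integer(n)
  out <- with_seed(seed, {
    z <- matrix(stats::rnorm(n * object$config$latent_dim), nrow = n)
    y <- one_hot(rep(label, n))
    nn_forward(object$generator, cbind(z, y), out_act = "tanh")$out
  })
  mn <- object$norm[["min"]]; mx <- object$norm[["max"]]
  amp <- (out + 1) / 2 * (mx - mn) + mn
  waves <- lapply(seq_len(n), function(i) {
    erg_waveform(amp[i, ], object$fs, object$stimulus,
                 subject_id = sprintf("synth_%s_%03d", label, i),
                 eye = if (i %% 2L == 1L) "left" else "right",
                 sex = label, provenance = "synthetic", replicate_index = 1L)
  })
  erg_dataset(waves)
}

#' @describeIn erg_cgan `simulate()` method: `simulate(fit, nsim, seed,
#'   label = "male")` draws `nsim` synthetic waveforms.
#' @param object,nsim,... Standard [stats::simulate()] arguments; `label`
#'   (the conditioning class) is passed through `...`.
#' @export
simulate.erg_cgan <- function(object, nsim = 1, seed = 1, ...) {
  dots <- list(...)
  label <- dots$label %||% "male"
  generate_waveforms(object, label, nsim, seed)
}

#' Augmentation policy
#'
#' How many synthetic target-class waveforms to append to a training set:
#' either a fixed fraction of the initial real dataset size (the study's
#' "20% of the initial real dataset size") or whatever count reaches class
#' parity. Both semantics are provided because the two descriptions cannot
#' hold simultaneously for this composition.
#'
#' @param synth_fraction Fraction of the initial real dataset size to add
#'   (default 0.20); used when `balance_to_parity = FALSE`.
#' @param target_class Label to upsample (default `"male"`, the minority).
#' @param balance_to_parity If `TRUE`, add exactly enough records for the
#'   target class to reach the size of the other class.
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(synth_fraction = 0.20, target_class = "male",
                                balance_to_parity = FALSE) {
  if (!is_scalar_num(synth_fraction) || synth_fraction <= 0 || synth_fraction > 1)
    abort_validation("synth_fraction must be in (0, 1]")
  target_class <- match.arg(target_class, gan_classes)
  structure(list(synth_fraction = synth_fraction, target_class = target_class,
                 balance_to_parity = isTRUE(balance_to_parity)),
            class = "augmentation_policy")
}

#' Augment a training set with synthetic minority waveforms
#'
#' Appends generator output for the policy's target class. In fraction mode
#' the number added is `round(synth_fraction * initial_size)`; in parity
#' mode it is the count needed for the target class to match the other
#' class. Real records are never modified or dropped.
#'
#' @param train_set An [erg_dataset] containing the target class.
#' @param g A fitted [erg_cgan].
#' @param policy An [augmentation_policy].
#' @param seed Integer RNG seed for the latent draws.
#' @param initial_size The "initial real dataset size" the fraction refers
#'   to; defaults to `length(train_set)`. In the full pipeline this is the
#'   pre-split dataset size.
#' @return The combined [erg_dataset] (real records first, then synthetic).
#' @export
balance_with_synthetic <- function(train_set, g, policy = augmentation_policy(),
                                   seed = 1, initial_size = length(train_set)) {
  if (!inherits(train_set, "erg_dataset") || length(train_set) == 0L)
    abort_validation("train_set must be a nonempty erg_dataset")
  m <- waveform_meta(train_set)
  if (!policy$target_class %in% m$sex)
    abort_validation("target class absent from train_set")
  n_add <- if (policy$balance_to_parity) {
    counts <- table(factor(m$sex, gan_classes))
    as.integer(max(counts) - counts[[policy$target_class]])
  } else {
    as.integer(round(policy$synth_fraction * initial_size))
  }
  if (n_add < 0) abort_validation("policy requires negative additions")
  if (n_add == 0L) return(train_set)
  synth <- generate_waveforms(g, policy$target_class, n_add, seed)
  c(train_set, synth)
}

#' Morphological plausibility gate for synthetic LA3 waveforms
#'
#' A coarse screen used to monitor generator quality (and optionally for
#' rejection sampling): a waveform passes when its global minimum falls in
#' the a-wave latency range, its global maximum comes after the minimum and
#' falls in the b-wave latency range, and its peak-to-peak amplitude is
#' within `range_factor` times the training data's amplitude range.
#'
#' @param dataset An [erg_dataset] of LA3 waveforms.
#' @param reference_range Peak-to-peak range (microvolts) of the training
#'   data; synthetic records beyond `range_factor` times it fail.
#' @param a_window,b_window Latency windows in seconds.
#' @param range_factor Allowed amplitude inflation.
#' @return Logical vector, one entry per waveform.
#' @export
plausibility_gate <- function(dataset, reference_range,
                              a_window = c(0.005, 0.025),
                              b_window = c(0.015, 0.060),
                              range_factor = 3) {
  vapply(dataset, function(w) {
    t <- wave_time(w)
    i_min <- which.min(w$samples)
    i_max <- which.max(w$samples)
    ptp <- w$samples[i_max] - w$samples[i_min]
    t[i_min] >= a_window[1] && t[i_min] <= a_window[2] &&
      i_max > i_min && t[i_max] >= b_window[1] && t[i_max] <= b_window[2] &&
      ptp <= range_factor * reference_range
  }, logical(1))
}

#' Save / load a trained conditional GAN
#'
#' The generator state is written as a single binary checkpoint (RDS) with
#' a JSON sidecar recording sampling rate, signal length, normalization
#' constants and the configuration, so a checkpoint can be audited without
#' loading it.
#'
#' @param object A fitted [erg_cgan].
#' @param path Checkpoint path (`.rds`); the sidecar is `path` + `.json`.
#' @return `path` invisibly (`write_cgan`); the [erg_cgan] (`read_cgan`).
#' @export
write_cgan <- function(object, path) {
  if (!inherits(object, "erg_cgan")) abort_validation("object must be an erg_cgan")
  saveRDS(object, path)
  sidecar <- list(stimulus = object$stimulus, fs = object$fs,
                  signal_length = object$signal_length,
                  normalization = as.list(object$norm),
                  classes = object$classes, seed = object$seed,
                  config = unclass(object$config),
                  epochs_trained = nrow(object$log))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cgan
#' @export
read_cgan <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "erg_cgan")) abort_parse("checkpoint is not an erg_cgan")
  obj
}
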