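#' Split a dataset into training and test partitions
#'
#' Disjoint, sex-stratified partition, deterministic given `seed`. With
#' `unit = "record"` each waveform is assigned independently and the test
#' side holds `round(test_fraction * n)` records per sex. With
#' `unit = "subject"` (the default) all replicates and both eyes of a
#' subject stay on one side, preventing within-subject leakage; the
#' per-sex test record count is then matched as closely as whole subjects
#' allow.
#'
#' @param dataset An [erg_dataset] containing both sexes.
#' @param test_fraction Fraction of records held out (0 < f < 1).
#' @param unit `"subject"` or `"record"`.
#' @param seed Integer RNG seed.
#' @return A list with elements `train` and `test` ([erg_dataset]s).
#' @export
split_dataset <- function(dataset, test_fraction = 0.2,
                          unit = c("subject", "record"), seed = 1) {
  unit <- match.arg(unit)
  if (!inherits(dataset, "erg_dataset") || length(dataset) < 2L)
    abort_validation("dataset must contain at least 2 waveforms")
  if (!is_scalar_num(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    abort_validation("test_fraction must be in (0, 1)")
  m <- waveform_meta(dataset)
  if (length(unique(m$sex)) < 2L)
    abort_validation("dataset must contain both classes")
  test_idx <- integer(0)
  with_seed(child_seed(seed, "split"), {
    for (cls in sort(unique(m$sex))) {
      cls_idx <- which(m$sex == cls)
      target <- round(test_fraction * length(cls_idx))
      if (unit == "record") {
        test_idx <- c(test_idx, sample(cls_idx, target))
      } else {
        subs <- unique(m$subject_id[cls_idx])
        subs <- subs[sample.int(length(subs))]
        counts <- vapply(subs, function(s) sum(m$subject_id[cls_idx] == s),
                         integer(1))
        cum <- cumsum(counts)
        k <- which.min(abs(cum - target))   # prefix closest to the target
        take <- subs[seq_len(k)]
        test_idx <- c(test_idx, cls_idx[m$subject_id[cls_idx] %in% take])
      }
    }
  })
  if (length(test_idx) == 0L || length(test_idx) == length(dataset))
    abort_validation("test_fraction leaves one side of the split empty")
  list(train = dataset[-test_idx], test = dataset[sort(test_idx)])
}

#' Experiment configuration
#'
#' Everything needed to run the full pipeline reproducibly: simulator
#' parameters and class effects (or a path to a dataset CSV), split
#' settings, GAN configuration, augmentation policy, low-pass cutoff,
#' feature windows, cross-validation spec and a root seed that fans out to
#' named per-stage streams.
#'
#' @param stimuli Stimuli to process (`"LA3"`, `"FLICKER30"`).
#' @param data_path Optional CSV of real waveforms ([read_dataset()]
#'   dialect); when `NULL` the study-emulation fixture is simulated.
#' @param la3,flicker,effect_la3,effect_flicker Simulator settings (ignored
#'   when `data_path` is given).
#' @param test_fraction,split_unit Split settings.
#' @param gan A [gan_config].
#' @param policy An [augmentation_policy].
#' @param lowpass A [lowpass_spec].
#' @param a_window,b_window Feature-extraction windows (seconds).
#' @param cv A [cv_spec].
#' @param seed Root seed.
#' @param out_dir Optional artifact directory.
#' @return An object of class `erg_config`.
#' @export
erg_config <- function(stimuli = c("LA3", "FLICKER30"), data_path = NULL,
                       la3 = la3_params(), flicker = flicker_params(),
                       effect_la3 = default_sex_effect_la3(),
                       effect_flicker = default_sex_effect_flicker(),
                       test_fraction = 0.2,
                       split_unit = c("subject", "record"),
                       gan = gan_config(), policy = augmentation_policy(),
                       lowpass = lowpass_spec(),
                       a_window = c(0.005, 0.025), b_window = c(0.015, 0.060),
                       cv = cv_spec(), seed = 1, out_dir = NULL) {
  split_unit <- match.arg(split_unit)
  stimuli <- match.arg(stimuli, c("LA3", "FLICKER30"), several.ok = TRUE)
  if (!is_scalar_num(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    abort_validation("test_fraction must be in (0, 1)")
  stopifnot(inherits(gan, "gan_config"), inherits(policy, "augmentation_policy"),
            inherits(lowpass, "lowpass_spec"), inherits(cv, "cv_spec"))
  structure(list(stimuli = stimuli, data_path = data_path, la3 = la3,
                 flicker = flicker, effect_la3 = effect_la3,
                 effect_flicker = effect_flicker,
                 test_fraction = test_fraction, split_unit = split_unit,
                 gan = gan, policy = policy, lowpass = lowpass,
                 a_window = a_window, b_window = b_window, cv = cv,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "erg_config")
}

#' Read / write an experiment configuration as YAML
#'
#' A human-editable subset of [erg_config()]: scalar fields plus nested
#' `la3`, `flicker`, `gan`, `policy`, `lowpass`, `cv` and sex-effect
#' blocks. Unknown fields are rejected by the constructors.
#'
#' @param path YAML file path.
#' @param config An `erg_config`.
#' @return `read_config`: an `erg_config`; `write_config`: `path`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (f in c("stimuli", "data_path", "test_fraction", "split_unit", "seed",
              "out_dir", "a_window", "b_window"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(y$la3)) args$la3 <- do.call(la3_params, y$la3)
  if (!is.null(y$flicker)) args$flicker <- do.call(flicker_params, y$flicker)
  if (!is.null(y$gan)) args$gan <- do.call(gan_config, y$gan)
  if (!is.null(y$policy)) args$policy <- do.call(augmentation_policy, y$policy)
  if (!is.null(y$lowpass)) args$lowpass <- do.call(lowpass_spec, y$lowpass)
  if (!is.null(y$cv)) args$cv <- do.call(cv_spec, y$cv)
  if (!is.null(y$effect_la3)) args$effect_la3 <- do.call(sex_effect, y$effect_la3)
  if (!is.null(y$effect_flicker))
    args$effect_flicker <- do.call(sex_effect, y$effect_flicker)
  do.call(erg_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "erg_config"))
  y <- list(stimuli = config$stimuli, data_path = config$data_path,
            test_fraction = config$test_fraction,
            split_unit = config$split_unit, seed = config$seed,
            out_dir = config$out_dir,
            a_window = config$a_window, b_window = config$b_window,
            la3 = unclass(config$la3), flicker = unclass(config$flicker),
            effect_la3 = unclass(config$effect_la3),
            effect_flicker = unclass(config$effect_flicker),
            gan = unclass(config$gan), policy = unclass(config$policy),
            lowpass = unclass(config$lowpass)[c("cutoff")],
            cv = unclass(config$cv)[c("n_folds", "seed")])
  yaml::write_yaml(y, path)
  invisible(path)
}

log_msg <- function(stage, fmt, ..., verbose = TRUE, file = NULL) {
  line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
  if (verbose) message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE)
  invisible(line)
}

#' Run the full synthesis-and-evaluation experiment
#'
#' Orchestrates the whole pipeline for each configured stimulus: obtain the
#' dataset (simulate the study-emulation fixture, or load a CSV), split it
#' into training and test subsets, fit the conditional GAN on the training
#' subset, generate and low-pass-smooth synthetic minority waveforms,
#' extract time-domain features, and evaluate the three training conditions
#' (original / oversampled / synthesized) on the untouched real test
#' subset. Fully reproducible from the configuration's root seed.
#'
#' @param config An [erg_config].
#' @param verbose Emit structured progress lines to stderr.
#' @return An object of class `erg_experiment`: `report` (rows for every
#'   stimulus by condition), `generators`, `splits` (record counts),
#'   `embeddings` (t-SNE coordinates per stimulus), `config`, `seed`. When
#'   `config$out_dir` is set, datasets, feature tables, reports (CSV +
#'   JSON), generator checkpoints, embedding coordinates and a run log are
#'   written there.
#' @export
run_experiment <- function(config = erg_config(), verbose = TRUE) {
  stopifnot(inherits(config, "erg_config"))
  out_dir <- config$out_dir
  log_file <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_file <- file.path(out_dir, "run.log")
    cat(sprintf("run_experiment seed=%d\n", config$seed), file = log_file)
  }
  lg <- function(stage, fmt, ...) log_msg(stage, fmt, ..., verbose = verbose,
                                          file = log_file)

  if (!is.null(config$data_path)) {
    lg("load", "reading %s", config$data_path)
    dataset <- read_dataset(config$data_path)
  } else {
    lg("simulate", "building study-emulation fixture (seed %d)", config$seed)
    dataset <- make_study_fixture(la3 = config$la3, flicker = config$flicker,
                                  effect_la3 = config$effect_la3,
                                  effect_flicker = config$effect_flicker,
                                  seed = child_seed(config$seed, "fixture"))
  }
  if (!is.null(out_dir)) write_dataset(dataset, file.path(out_dir, "dataset.csv"))

  reports <- list(); generators <- list(); splits <- list(); embeds <- list()
  for (st in config$stimuli) {
    sub <- subset_dataset(dataset, stimulus = st)
    if (length(sub) == 0L) abort_validation(sprintf("no %s records in dataset", st))
    sp <- split_dataset(sub, config$test_fraction, config$split_unit,
                        seed = child_seed(config$seed, paste0("split_", st)))
    splits[[st]] <- c(train = length(sp$train), test = length(sp$test))
    lg("split", "%s: %d train / %d test", st, length(sp$train), length(sp$test))

    lg("gan", "%s: training conditional GAN (%d epochs)", st,
       config$gan$epochs)
    g <- erg_cgan(sp$train, config$gan,
                  seed = child_seed(config$seed, paste0("gan_", st)))
    generators[[st]] <- g
    if (!is.null(out_dir))
      write_cgan(g, file.path(out_dir, sprintf("cgan_%s.rds", st)))

    feat_args <- if (st == "LA3")
      list(a_window = config$a_window, b_window = config$b_window) else list()
    lg("evaluate", "%s: original / oversampled / synthesized", st)
    rep_st <- do.call(run_conditions, c(
      list(real_train = sp$train, test = sp$test, generator = g,
           policy = config$policy, cv = config$cv, lowpass = config$lowpass,
           initial_size = length(sub),
           seed = child_seed(config$seed, paste0("cond_", st))),
      feat_args))
    reports[[st]] <- rep_st

    # visualization-only embedding of real + synthetic feature rows
    emb <- tryCatch({
      synth <- generate_waveforms(g, config$policy$target_class,
                                  n = max(5, round(0.2 * length(sub))),
                                  seed = child_seed(config$seed, paste0("emb_", st)))
      synth <- lowpass_dataset(synth, config$lowpass)
      rows <- rbind(do.call(feature_table, c(list(sp$train, quiet = TRUE), feat_args)),
                    do.call(feature_table, c(list(synth, quiet = TRUE), feat_args)))
      embed_features(rows, features = stimulus_features(st),
                     seed = child_seed(config$seed, paste0("tsne_", st)))
    }, error = function(e) NULL)
    embeds[[st]] <- emb
    if (!is.null(out_dir)) {
      ftab <- do.call(feature_table, c(list(sub, quiet = TRUE), feat_args))
      write_features(ftab, file.path(out_dir, sprintf("features_%s.csv", st)))
      if (!is.null(emb)) {
        utils::write.csv(emb, file.path(out_dir, sprintf("embedding_%s.csv", st)),
                         row.names = FALSE)
        grDevices::pdf(file.path(out_dir, sprintf("embedding_%s.pdf", st)))
        plot_embedding(emb, main = sprintf("t-SNE of %s features", st))
        grDevices::dev.off()
      }
    }
  }
  report <- do.call(rbind, lapply(unname(reports), as.data.frame))
  if (!is.null(out_dir))
    write_report(report, out_dir,
                 meta = list(seed = config$seed, splits = splits,
                             config = list(test_fraction = config$test_fraction,
                                           split_unit = config$split_unit,
                                           gan = unclass(config$gan),
                                           policy = unclass(config$policy),
                                           lowpass_cutoff = config$lowpass$cutoff)))
  structure(list(report = report, reports = reports, generators = generators,
                 splits = splits, embeddings = embeds, config = config,
                 seed = config$seed),
            class = "erg_experiment")
}

#' @export
print.erg_experiment <- function(x, ...) {
  cat(sprintf("ERG augmentation experiment (root seed %d)\n", x$seed))
  for (st in names(x$splits))
    cat(sprintf("  %s: %d train / %d test\n", st, x$splits[[st]]["train"],
                x$splits[[st]]["test"]))
  df <- x$report[, c("stimulus", "condition", "ba", "precision", "recall", "f1")]
  df[, 3:6] <- round(df[, 3:6], 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Two-dimensional t-SNE embedding of feature rows
#'
#' Visualization-only: maps the extracted time-domain features to the plane
#' so that real-male, real-female and synthetic-male rows can be compared,
#' carrying the grouping labels through.
#'
#' @param rows Feature data frame (from [feature_table()]).
#' @param features Feature column names; defaults to the LA3 set present.
#' @param perplexity t-SNE perplexity (capped at `(n - 1) / 3`).
#' @param seed Integer RNG seed.
#' @param max_iter Gradient-descent iterations.
#' @return `rows` with `x`, `y` coordinate columns and a `group` label
#'   (`provenance.sex`) appended.
#' @export
embed_features <- function(rows, features = NULL, perplexity = 10, seed = 1,
                           max_iter = 400) {
  if (!is.data.frame(rows) || nrow(rows) < 5L)
    abort_validation("need at least 5 feature rows")
  if (is.null(features))
    features <- intersect(c("ta_s", "la_uv", "tb_s", "lb_uv"), names(rows))
  X <- as.matrix(rows[, features, drop = FALSE])
  if (any(!is.finite(X))) abort_validation("features must be finite")
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) abort_validation("degenerate constant features")
  X <- scale(X, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  Y <- tsne_embed(X, perplexity = perplexity, max_iter = max_iter, seed = seed)
  out <- rows
  out$x <- Y[, 1]; out$y <- Y[, 2]
  out$group <- paste(rows$provenance, rows$sex, sep = ".")
  out
}

#' Plot a feature embedding
#'
#' @param emb Output of [embed_features()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_embedding <- function(emb, ...) {
  groups <- sort(unique(emb$group))
  cols <- grDevices::hcl.colors(max(3, length(groups)), "Dark 3")[seq_along(groups)]
  graphics::plot(emb$x, emb$y, col = cols[match(emb$group, groups)],
                 pch = 19, xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  graphics::legend("topright", groups, col = cols, pch = 19, bty = "n")
  invisible(emb)
}
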