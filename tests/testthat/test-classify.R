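test_that("confusion counts match the brute-force tally", {
  cc <- confusion_counts(c("m", "m", "f", "f"), c("m", "m", "f", "f"), "m")
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 2L, tn = 2L, fp = 0L, fn = 0L))
  cc <- confusion_counts(c("m", "f"), c("m", "m"), "m")
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 1L, tn = 0L, fp = 1L, fn = 0L))

  set.seed(3)
  for (i in 1:5) {
    y <- sample(c("male", "female"), 500, replace = TRUE)
    p <- sample(c("male", "female"), 500, replace = TRUE)
    cc <- confusion_counts(y, p, "male")
    expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
                 brute_confusion(y, p, "male"))
  }
  expect_error(confusion_counts(c("a", "b", "c"), c("a", "b", "c"), "a"),
               class = "ergsynth_validation_error")
  expect_error(confusion_counts(c("a", "b"), c("a", "b"), "z"),
               class = "ergsynth_validation_error")
})

test_that("metric formulas reproduce hand arithmetic and the published worked example", {
  # hand-computed: tp=3, fn=1, tn=2, fp=2
  m <- compute_metrics(structure(list(tp = 3, fn = 1, tn = 2, fp = 2,
                                      positive = "male"),
                                 class = "confusion_counts"))
  expect_equal(m$recall, 0.75)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$balanced_accuracy, 0.625)
  expect_equal(m$precision, 0.6)
  expect_equal(round(m$f1, 3), 0.667)

  # perfect classifier
  p <- compute_metrics(structure(list(tp = 5, fn = 0, tn = 7, fp = 0,
                                      positive = "male"),
                                 class = "confusion_counts"))
  expect_equal(unlist(p[c("precision", "recall", "specificity",
                          "balanced_accuracy", "f1")]),
               c(precision = 1, recall = 1, specificity = 1,
                 balanced_accuracy = 1, f1 = 1))

  # the published precision/recall pair for the synthesized light-adapted set
  expect_equal(round(f1_score(0.809, 0.850), 3), 0.829)
})

test_that("undefined ratios raise a distinct signal, never a silent zero", {
  cc <- structure(list(tp = 0, fn = 0, tn = 3, fp = 1, positive = "male"),
                  class = "confusion_counts")
  expect_error(compute_metrics(cc), class = "ergsynth_undefined_metric")
  m <- compute_metrics(cc, undefined = "nan")
  expect_true(is.nan(m$recall))
  expect_error(f1_score(0, 0), class = "ergsynth_undefined_metric")
})

test_that("metric identities hold on random prediction vectors", {
  set.seed(11)
  for (i in 1:20) {
    y <- sample(c("male", "female"), 80, replace = TRUE, prob = c(0.3, 0.7))
    p <- sample(c("male", "female"), 80, replace = TRUE)
    if (length(unique(y)) < 2) next
    cc <- confusion_counts(y, p, "male")
    m <- compute_metrics(cc, undefined = "nan")
    expect_equal(m$balanced_accuracy, (m$recall + m$specificity) / 2)
    if (!is.nan(m$f1))
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
    # swapping the positive class swaps sensitivity and specificity
    m2 <- compute_metrics(confusion_counts(y, p, "female"), undefined = "nan")
    expect_equal(m2$recall, m$specificity)
    expect_equal(m2$specificity, m$recall)
    expect_equal(m2$balanced_accuracy, m$balanced_accuracy)
  }
})

test_that("random oversampling balances while retaining every original row", {
  rows <- data.frame(id = 1:14, sex = rep(c("female", "male"), c(10, 4)),
                     f = rnorm(14))
  out <- random_oversample(rows, seed = 5)
  expect_equal(sum(out$sex == "male"), 10)
  expect_equal(sum(out$sex == "female"), 10)
  expect_true(all(rows$id %in% out$id))
  expect_identical(out[1:14, ], rows)       # originals untouched, in place
  # minority originals are a sub-multiset of the output minority rows
  expect_true(all(table(rows$id[rows$sex == "male"]) <=
                    table(factor(out$id[out$sex == "male"], levels = 1:14))[11:14]))

  balanced <- data.frame(sex = rep(c("male", "female"), 5))
  expect_identical(random_oversample(balanced), balanced)
  expect_identical(random_oversample(rows, seed = 9),
                   random_oversample(rows, seed = 9))
  expect_error(random_oversample(data.frame(sex = rep("male", 4))),
               class = "ergsynth_validation_error")
})

blob_rows <- function(n_per_class, sep, seed) {
  set.seed(seed)
  data.frame(
    sex = rep(c("male", "female"), each = n_per_class),
    f1 = rnorm(2 * n_per_class) + rep(c(0, sep), each = n_per_class),
    f2 = rnorm(2 * n_per_class) + rep(c(0, sep), each = n_per_class))
}

test_that("separable classes are classified almost perfectly", {
  train <- blob_rows(60, 6, 1)
  test <- blob_rows(15, 6, 2)
  ev <- fit_and_evaluate(train, test, c("f1", "f2"))
  expect_gte(ev$metrics$balanced_accuracy, 0.95)
})

test_that("permuted labels give chance-level balanced accuracy", {
  bas <- vapply(1:5, function(s) {
    set.seed(100 + s)
    rows <- data.frame(sex = sample(rep(c("male", "female"), 100)),
                       f1 = rnorm(200), f2 = rnorm(200))
    ev <- fit_and_evaluate(rows[1:160, ], rows[161:200, ], c("f1", "f2"),
                           cv = cv_spec(seed = s))
    ev$metrics$balanced_accuracy
  }, double(1))
  expect_lt(abs(mean(bas) - 0.5), 0.1)
})

test_that("evaluation is deterministic and guards its contracts", {
  train <- blob_rows(30, 2, 3)
  test <- blob_rows(10, 2, 4)
  e1 <- fit_and_evaluate(train, test, c("f1", "f2"), cv = cv_spec(seed = 7))
  e2 <- fit_and_evaluate(train, test, c("f1", "f2"), cv = cv_spec(seed = 7))
  expect_identical(e1$metrics, e2$metrics)
  expect_identical(e1$cv_table$cv_ba, e2$cv_table$cv_ba)

  single <- test; single$sex <- "male"
  expect_error(fit_and_evaluate(train, single, c("f1", "f2")),
               class = "ergsynth_undefined_metric")
  synth <- test; synth$provenance <- "synthetic"
  expect_error(fit_and_evaluate(train, synth, c("f1", "f2")),
               class = "ergsynth_validation_error")
  expect_error(cv_spec(grid = data.frame()), class = "ergsynth_validation_error")
})

test_that("the three conditions share one immutable test set", {
  la3 <- cached_la3(101)
  sp <- split_dataset(la3, 0.2, "record", seed = 3)
  rep_ <- run_conditions(sp$train, sp$test, generator = cached_tiny_gan(),
                         policy = augmentation_policy(),
                         cv = cv_spec(grid = default_rf_grid()[c(1, 8), ]),
                         initial_size = length(la3), seed = 5)
  expect_equal(nrow(rep_), 3L)
  expect_setequal(rep_$condition, c("original", "oversampled", "synthesized"))
  expect_equal(length(unique(rep_$test_hash)), 1L)
  expect_true(all(rep_$n_train[rep_$condition != "original"] >
                    rep_$n_train[rep_$condition == "original"]))
})
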