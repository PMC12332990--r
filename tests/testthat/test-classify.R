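test_that("roc_auc matches concordant-pair counting, including ties", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  set.seed(1)
  for (i in 1:30) {
    n <- sample(6:25, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_identical(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "class")
  # AUC inside its CI
  r2 <- roc_auc(stats::rnorm(40), rep(0:1, 20))
  expect_gte(r2$auc, r2$ci95[1]); expect_lte(r2$auc, r2$ci95[2])
})

test_that("youden_threshold attains the brute-force maximum with low-threshold ties", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_message(yt <- youden_threshold(r), "tie")
  expect_equal(unname(yt), c(0.35, 0.5))
  set.seed(2)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    scores <- round(stats::runif(n), 2)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    got <- suppressMessages(youden_threshold(roc_auc(scores, labels)))
    want <- oracle_youden(scores, labels)
    expect_equal(got[["J"]], want[["J"]], tolerance = 1e-12)
    # same J at the returned threshold
    sens <- mean(scores[labels == 1] >= got[["threshold"]])
    spec <- mean(scores[labels == 0] < got[["threshold"]])
    expect_equal(sens + spec - 1, want[["J"]], tolerance = 1e-12)
  }
})

test_that("confusion matrices obey their identities", {
  s <- c(0.2, 0.7, 0.4, 0.9); l <- c(0, 1, 1, 0)
  cm <- confusion_at_threshold(s, l, 0.5)
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 4)
  expect_equal(cm$accuracy, (cm$tp + cm$tn) / 4)
  expect_equal(confusion_at_threshold(s, l, 0)$sensitivity, 1)
  expect_equal(confusion_at_threshold(s, l, 0)$specificity, 0)
  expect_equal(confusion_at_threshold(s, l, 2)$sensitivity, 0)
  expect_equal(confusion_at_threshold(s, l, 2)$specificity, 1)
  # accuracy = (sens*P + spec*N) / (P+N) identically
  set.seed(3)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    s <- stats::runif(n); l <- sample(0:1, n, replace = TRUE)
    if (length(unique(l)) < 2) next
    cm <- confusion_at_threshold(s, l, stats::runif(1))
    P <- sum(l); N <- n - P
    expect_equal(cm$accuracy,
                 (cm$sensitivity * P + cm$specificity * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("delong_test flags degenerate self-comparison and matches a bootstrap oracle", {
  set.seed(4)
  l <- rep(0:1, each = 25)
  a <- stats::rnorm(50) + l
  d0 <- delong_test(a, a, l)
  expect_true(d0$degenerate)
  expect_equal(d0$p_value, 1)
  expect_equal(d0$difference, 0)

  b <- stats::rnorm(50) + 0.6 * l
  dl <- delong_test(a, b, l)
  # paired bootstrap on the AUC difference (2000 resamples)
  set.seed(5)
  diffs <- replicate(2000, {
    idx <- sample(50, replace = TRUE)
    while (length(unique(l[idx])) < 2) idx <- sample(50, replace = TRUE)
    oracle_auc(a[idx], l[idx]) - oracle_auc(b[idx], l[idx])
  })
  p_boot <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  expect_lt(abs(dl$p_value - p_boot), 0.05)
  expect_error(delong_test(a, b, rep(1, 50)), "class")
})

test_that("the classifier panel separates a planted-signal cohort and is seeded", {
  tb <- make_signal_table(n = 80, p_noise = 4, seed = 7)
  # strengthen the signal to make the cohort perfectly separable
  tb$signal_1 <- tb$label * 10 + stats::rnorm(80, 0, 0.1)
  sel <- structure(list(side = "left",
                        selected = c("signal_1", "signal_2", "signal_3"),
                        trace = c(input = 3)), class = "FeatureSelection")
  bench <- fit_classifiers(tb, sel, seed = 1)
  expect_equal(bench$roc[[bench$selected]]$auc, 1)
  bench2 <- fit_classifiers(tb, sel, seed = 1)
  expect_identical(bench$selected, bench2$selected)
  expect_identical(bench$scores, bench2$scores)
  expect_error(fit_classifiers(tb, sel, model_set = c("logistic", "mlp")),
               "supported")
  sm <- summarize_bench(bench)
  expect_equal(sm$auc, 100)
  expect_true(all(c("acc", "sens", "spec", "threshold") %in% names(sm)))
})

test_that("label-permuted cohorts give near-chance validation AUC", {
  aucs <- numeric(10)
  for (s in 1:10) {
    tb <- make_signal_table(n = 120, p_noise = 6, seed = 100 + s)
    set.seed(s)
    tb$label <- sample(tb$label)   # break any association
    if (length(unique(tb$label[tb$split == "train"])) < 2) next
    sel <- structure(list(side = "left",
                          selected = grep("noise|signal",
                                          names(tb), value = TRUE)[1:5],
                          trace = c(input = 5)), class = "FeatureSelection")
    bench <- fit_classifiers(tb, sel,
                             model_set = c("logistic", "naive_bayes", "knn"),
                             seed = s)
    aucs[s] <- bench$roc[[bench$selected]]$auc
  }
  # selection over models inflates the null slightly; stay in a sane band
  expect_true(all(aucs[aucs > 0] > 0.35 & aucs[aucs > 0] < 0.75))
})

test_that("every supported model trains and returns probability-like scores", {
  tb <- make_signal_table(n = 60, p_noise = 3, seed = 9)
  sel <- structure(list(side = "left",
                        selected = c("signal_1", "signal_2", "signal_3"),
                        trace = c(input = 3)), class = "FeatureSelection")
  bench <- fit_classifiers(tb, sel, seed = 2)
  expect_setequal(names(bench$models), adrenalseg:::SUPPORTED_MODELS)
  for (nm in names(bench$scores)) {
    expect_true(all(is.finite(bench$scores[[nm]])))
    expect_true(all(bench$scores[[nm]] >= 0 & bench$scores[[nm]] <= 1))
    expect_gt(bench$roc[[nm]]$auc, 0.7)  # clear signal: every model learns
  }
})
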