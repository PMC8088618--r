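test_that("classification metrics match hand-computed confusion examples", {
  m <- classification_metrics(structure(
    list(TP = 2, TN = 6, FP = 1, FN = 1), class = "confusion_counts"))
  expect_equal(m$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(m$recall, 2 / 3, tolerance = 1e-12)
  expect_equal(m$f_measure, 2 / 3, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.8)
  ## degenerate: no predicted/true positives found
  m0 <- classification_metrics(structure(
    list(TP = 0, TN = 5, FP = 0, FN = 5), class = "confusion_counts"))
  expect_equal(m0$f_measure, 0)
  expect_equal(m0$accuracy, 0.5)
  ## perfect classifier
  mp <- classification_metrics(confusion_counts(c(1, 1, 0), c(1, 1, 0)))
  expect_equal(unlist(mp), c(precision = 1, recall = 1, f_measure = 1,
                             accuracy = 1))
  ## accuracy * total = TP + TN exactly
  cc <- confusion_counts(c(1, 0, 1, 0, 1), c(1, 1, 0, 0, 1))
  mm <- classification_metrics(cc)
  expect_equal(mm$accuracy * 5, cc$TP + cc$TN)
})

test_that("auroc equals brute-force pair counting on an exhaustive sweep", {
  set.seed(11)
  score_pools <- list(runif(8), sample(c(0.2, 0.5, 0.9), 8, replace = TRUE),
                      rep(0.5, 8))
  for (n in 3:8) {
    for (pool in score_pools) {
      scores <- pool[seq_len(n)]
      for (mask in 1:(2^n - 2)) {
        labels <- as.integer(intToBits(mask))[seq_len(n)]
        if (sum(labels) %in% c(0, n)) next
        expect_equal(auroc(scores, labels), brute_auroc(scores, labels),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("auroc handles edge cases and single-class errors", {
  expect_equal(auroc(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(auroc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.2), c(1, 0, 1, 0)), 1)
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("auroc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- runif(50)
  labels <- rbinom(50, 1, 0.4)
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(labels, scores, levels = c(0, 1), direction = "<"))))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-10)
})

test_that("auprc follows average-precision stepping", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  ## single positive ranked last among 4: precision 1/4 at its recall step
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.1), c(0, 0, 0, 1)), 0.25)
  expect_error(auprc(c(0.5, 0.2), c(0, 0)), "positives")
  ## random scores: mean AP approximately the positive prevalence
  set.seed(21)
  ap <- replicate(200, {
    labels <- rbinom(200, 1, 0.3)
    if (sum(labels) == 0) NA_real_ else auprc(runif(200), labels)
  })
  ## average precision carries a small positive finite-sample bias, so the
  ## band is loose on the high side
  expect_equal(mean(ap, na.rm = TRUE), 0.3, tolerance = 0.1)
})

test_that("wilcoxon p-values match exact sign-assignment enumeration", {
  ## canonical all-positive n = 5 case
  a <- c(2, 3, 4, 5, 6); b <- c(1, 2, 3, 4, 5) - c(0, 0.5, 1, 1.5, 2)
  d <- a - b
  expect_equal(wilcoxon_signed_rank(a, b, "greater")$p_value, 0.03125)
  expect_equal(wilcoxon_signed_rank(a, b, "two.sided")$p_value, 0.0625)
  ## random small samples vs brute-force enumeration
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    x <- round(rnorm(n), 3)
    y <- round(rnorm(n), 3)
    if (any(x == y) || any(duplicated(abs(x - y)))) next
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(wilcoxon_signed_rank(x, y, alt)$p_value,
                   brute_wilcoxon(x - y, alt), tolerance = 1e-10,
                   info = sprintf("rep %d alt %s", rep, alt))
    }
  }
})

test_that("wilcoxon handles ties-with-self and zero differences", {
  expect_warning(res <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(res$p_value, 1)
  ## zero differences dropped, not counted
  res2 <- wilcoxon_signed_rank(c(1, 2, 5, 7), c(1, 2, 3, 4), "greater")
  expect_equal(res2$n_used, 2L)
})

test_that("cross_validate reports per-fold metrics with mean and SD", {
  bench <- tiny_benchmark(seed = 8)
  features <- bench_features(bench, emb_dim = 8, seed = 8)
  fa <- split_baseline(bench$pairs, 3, seed = 1)
  cfg <- small_training_config(seed = 1, epochs = 8L)
  cv <- cross_validate(bench$pairs, fa, features, cfg, mode = "network")
  expect_equal(nrow(cv$per_fold), 3L)
  expect_named(cv$summary, c("statistic", "auroc", "auprc", "f_measure",
                             "accuracy"))
  expect_equal(cv$summary$statistic, c("mean", "sd"))
  expect_equal(cv$summary$auroc[1], mean(cv$per_fold$auroc))
  ## population SD
  x <- cv$per_fold$auroc
  expect_equal(cv$summary$auroc[2], sqrt(mean((x - mean(x))^2)))
  expect_equal(nrow(cv$predictions), nrow(bench$pairs))
})
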