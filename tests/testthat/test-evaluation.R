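# Confusion counts, the five metrics, macro averaging, fold construction,
# and the cross-validation protocol.

test_that("confusion counts tally one-vs-rest outcomes", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0), positive = 1)
  expect_equal(unlist(cc), c(tp = 2L, tn = 2L, fp = 0L, fn = 0L))
  cc2 <- confusion_counts(c(1, 0), c(0, 1), positive = 1)
  expect_equal(unlist(cc2), c(tp = 0L, tn = 0L, fp = 1L, fn = 1L))
  expect_error(confusion_counts(c(1, 0), c(1), 1), "equal length")
  # brute-force enumeration over all binary label pairings of length 2
  for (a1 in 0:1) for (a2 in 0:1) for (b1 in 0:1) for (b2 in 0:1) {
    y <- c(a1, a2); p <- c(b1, b2)
    cc <- confusion_counts(y, p, positive = 1)
    expect_equal(cc$tp, sum(y == 1 & p == 1))
    expect_equal(cc$tn, sum(y == 0 & p == 0))
    expect_equal(cc$fp, sum(y == 0 & p == 1))
    expect_equal(cc$fn, sum(y == 1 & p == 0))
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 2L)
  }
})

test_that("classification metrics match the confusion-ratio definitions", {
  rep <- classification_metrics(list(tp = 40, fn = 10, tn = 45, fp = 5))
  expect_equal(rep$accuracy, 0.85)
  expect_equal(rep$precision, 40 / 45)
  expect_equal(rep$precision, 0.8889, tolerance = 1e-4)
  expect_equal(rep$sensitivity, 0.80)
  expect_equal(rep$specificity, 0.90)
  expect_equal(rep$f1, 2 * (40 / 45) * 0.8 / ((40 / 45) + 0.8))
  expect_equal(rep$f1, 0.8421, tolerance = 1e-4)
  perfect <- classification_metrics(list(tp = 3, tn = 7, fp = 0, fn = 0))
  expect_true(all(unlist(perfect[1:5]) == 1))
  degen <- classification_metrics(list(tp = 0, tn = 5, fp = 0, fn = 4))
  expect_equal(degen$sensitivity, 0)
  expect_equal(degen$f1, 0)
  expect_true(degen$degenerate)
  expect_error(classification_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)),
               "no samples")
})

test_that("metrics agree with direct recomputation for every small label vector", {
  # exhaustive check over all binary label configurations of length 1..8
  for (n in c(2, 5, 8)) {
    for (case in seq_len(min(4^2, 2^(2 * min(n, 4))))) {
      set.seed(case + n * 100)
      y <- sample(0:1, n, replace = TRUE)
      p <- sample(0:1, n, replace = TRUE)
      rep <- classification_metrics(confusion_counts(y, p, positive = 1))
      tp <- sum(y & p); tn <- sum(!y & !p); fp <- sum(!y & p); fn <- sum(y & !p)
      expect_equal(rep$accuracy, (tp + tn) / n)
      if (tp + fn > 0) expect_equal(rep$sensitivity, tp / (tp + fn))
      if (tp + fp > 0) expect_equal(rep$precision, tp / (tp + fp))
      if (fp + tn > 0) expect_equal(rep$specificity, tn / (fp + tn))
      if (rep$precision > 0 && rep$sensitivity > 0) {
        expect_gte(rep$f1, min(rep$precision, rep$sensitivity) - 1e-12)
        expect_lte(rep$f1, max(rep$precision, rep$sensitivity) + 1e-12)
      }
    }
  }
})

test_that("macro averaging is the unweighted mean over class reports", {
  r1 <- classification_metrics(list(tp = 8, fn = 2, tn = 9, fp = 1))
  r2 <- classification_metrics(list(tp = 10, fn = 0, tn = 8, fp = 2))
  avg <- macro_average(dplyr::bind_rows(r1, r2))
  expect_equal(avg$sensitivity, (0.8 + 1.0) / 2)
  expect_equal(avg$accuracy, mean(c(r1$accuracy, r2$accuracy)))
  same <- macro_average(dplyr::bind_rows(r1, r1, r1))
  expect_equal(same$f1, r1$f1)
  expect_error(macro_average(r1[0, ]), "no class")
})

test_that("k-fold splits are disjoint, covering, stratified and deterministic", {
  labels <- rep(c(0, 1), each = 50)
  folds <- kfold_split(labels, k = 10, seed = 3)
  expect_length(folds, 10)
  all_ids <- sort(unlist(folds))
  expect_equal(all_ids, 1:100)                    # covering, each id once
  expect_true(all(lengths(folds) == 10))
  for (f in folds) expect_equal(sum(labels[f] == 1), 5)   # stratified
  expect_identical(folds, kfold_split(labels, k = 10, seed = 3))
  expect_false(identical(folds, kfold_split(labels, k = 10, seed = 4)))
  expect_warning(kfold_split(c(1, rep(0, 19)), k = 10, seed = 1), "fewer than")
})

test_that("group-aware folds never split a recording", {
  set.seed(61)
  groups <- rep(sprintf("rec%02d", 1:20), each = 23)
  labels <- rep(rep(c(0, 1), each = 10), each = 23)
  folds <- kfold_split(labels, k = 5, seed = 2, groups = groups)
  expect_equal(sort(unlist(folds)), seq_along(labels))
  for (f in folds) {
    for (g in unique(groups[f])) {
      expect_true(all(which(groups == g) %in% f))
    }
  }
})

test_that("cross-validation trains per fold on disjoint data and averages", {
  set.seed(62)
  sig <- lapply(1:40, function(i) rnorm(16, mean = ifelse(i <= 20, 2, -2)))
  d <- tibble::tibble(signal = sig, label = rep(c(1L, 2L), each = 20),
                      recording_id = rep(sprintf("r%02d", 1:10), each = 4))
  cfg <- micro_config()
  cfg$lr <- 5e-3
  cv <- pmm_cross_validate(d, cfg, k = 2, seed = 1, epochs = 8)
  expect_s3_class(cv, "pmm_cv")
  expect_equal(nrow(cv$folds), 2)
  expect_equal(sum(cv$folds$n_test), 40)
  expect_equal(cv$summary$accuracy, mean(cv$folds$accuracy))
  # strongly separated classes should be learned even by the micro model
  expect_gt(cv$summary$accuracy, 0.8)
  expect_equal(glance(cv)$k, 2)
  expect_equal(nrow(tidy(cv)), 2)
})
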