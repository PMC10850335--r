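#' Confusion counts for one positive class
#'
#' Tallies TP / TN / FP / FN treating `positive` as the abnormal (seizure)
#' class and everything else as normal. For multi-class problems this is the
#' one-vs-rest tally for that class.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive the label counted as positive.
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred, positive) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  pt <- y_true == positive
  pp <- y_pred == positive
  tibble::tibble(tp = sum(pt & pp), tn = sum(!pt & !pp),
                 fp = sum(!pt & pp), fn = sum(pt & !pp))
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP + TN) / total`, precision `TP / (TP + FP)`, sensitivity
#' `TP / (TP + FN)`, specificity `TN / (FP + TN)` and F1, the harmonic mean
#' of precision and sensitivity. Metrics with a zero denominator are
#' reported as 0 and flagged in the `degenerate` column.
#'
#' @param cc confusion counts: a tibble/list with `tp`, `tn`, `fp`, `fn`
#'   (as returned by [confusion_counts()]).
#' @return One-row tibble: `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `f1`, `degenerate`.
#' @export
classification_metrics <- function(cc) {
  tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("no samples to score", call. = FALSE)
  safe <- function(num, den) if (den > 0) num / den else 0
  precision <- safe(tp, tp + fp)
  sensitivity <- safe(tp, tp + fn)
  f1 <- if (precision + sensitivity > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else 0
  tibble::tibble(
    accuracy = (tp + tn) / total,
    precision = precision,
    sensitivity = sensitivity,
    specificity = safe(tn, fp + tn),
    f1 = f1,
    degenerate = (tp + fp == 0) || (tp + fn == 0) || (fp + tn == 0)
  )
}

#' Macro-average per-class metric reports
#'
#' Unweighted mean of each metric over one-vs-rest class reports.
#'
#' @param reports tibble of per-class metric rows (stacked
#'   [classification_metrics()] outputs).
#' @return One-row tibble of averaged metrics.
#' @export
macro_average <- function(reports) {
  if (nrow(reports) < 1L) stop("no class reports to average", call. = FALSE)
  cols <- c("accuracy", "precision", "sensitivity", "specificity", "f1")
  out <- tibble::as_tibble(as.list(colMeans(reports[cols])))
  out$degenerate <- any(reports$degenerate)
  out
}

## metrics for a full multi-class prediction: binary tasks score the
## positive class directly, multi-class tasks macro-average one-vs-rest
score_predictions <- function(y_true, y_pred, positive = NULL) {
  classes <- sort(unique(y_true))
  if (length(classes) == 2L && !is.null(positive)) {
    return(classification_metrics(confusion_counts(y_true, y_pred, positive)))
  }
  per_class <- dplyr::bind_rows(lapply(classes, function(cl) {
    classification_metrics(confusion_counts(y_true, y_pred, cl))
  }))
  macro_average(per_class)
}

#' Stratified (optionally group-aware) k-fold split
#'
#' Partitions sample indices into `k` folds, stratified by label so each
#' fold holds approximately the same class mix. With `groups` given (e.g.
#' source recording ids), all samples of one group land in the same fold,
#' preventing leakage of windows from a single recording across the
#' train/test boundary. Deterministic for a fixed seed.
#'
#' @param labels per-sample labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @param groups optional per-sample group ids.
#' @return List of `k` integer index vectors (disjoint, covering).
#' @export
kfold_split <- function(labels, k = 10, seed = 0, groups = NULL) {
  n <- length(labels)
  if (n < k) stop("need at least k samples", call. = FALSE)
  set.seed(seed)
  folds <- vector("list", k)
  if (is.null(groups)) {
    for (cl in sort(unique(labels))) {
      ids <- which(labels == cl)
      if (length(ids) < k) {
        warning(sprintf("class %s has fewer than k = %d members; best-effort stratification",
                        cl, k))
      }
      ids <- ids[sample.int(length(ids))]
      assign_to <- (seq_along(ids) - 1L) %% k + 1L
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], ids[assign_to == f])
      }
    }
  } else {
    # group label = label of the group's first sample (windows of one
    # recording share a class); groups dealt round-robin within class
    gid <- as.character(groups)
    glab <- tapply(as.character(labels), gid, function(x) x[1])
    sizes <- numeric(k)
    for (cl in sort(unique(glab))) {
      gs <- names(glab)[glab == cl]
      gs <- gs[sample.int(length(gs))]
      for (g in gs) {
        f <- which.min(sizes)
        folds[[f]] <- c(folds[[f]], which(gid == g))
        sizes[f] <- sizes[f] + sum(gid == g)
      }
    }
  }
  lapply(folds, sort)
}

#' k-fold cross-validation of a PMM configuration
#'
#' Trains a fresh model on the complement of each fold and scores it on the
#' held-out fold; binary tasks report metrics for the `positive` class,
#' multi-class tasks macro-average one-vs-rest.
#'
#' @param data tibble with `signal` list-column and `label` column;
#'   a `recording_id` column enables group-aware splitting.
#' @param config a [pmm_config()].
#' @param k number of folds (default 10).
#' @param seed seed for both splitting and per-fold training.
#' @param positive positive label for binary scoring; default the largest
#'   label value.
#' @param group_aware keep all windows of a recording in one fold
#'   (default TRUE when `recording_id` is present).
#' @param epochs optional override of the configured epoch count.
#' @param verbose print per-fold progress.
#' @return A `pmm_cv` list: `folds` (per-fold metric tibble) and `summary`
#'   (metric means over folds).
#' @export
pmm_cross_validate <- function(data, config, k = 10, seed = 0, positive = NULL,
                               group_aware = "recording_id" %in% names(data),
                               epochs = NULL, verbose = FALSE) {
  groups <- if (isTRUE(group_aware) && "recording_id" %in% names(data)) {
    data$recording_id
  }
  folds <- kfold_split(data$label, k = k, seed = seed, groups = groups)
  if (is.null(positive) && length(unique(data$label)) == 2L) {
    positive <- max(data$label)
  }
  fold_reports <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(nrow(data)), test_idx)
    fit <- pmm_train(config, data[train_idx, ], seed = seed + f, epochs = epochs)
    pred <- predict(fit, data[test_idx, ])
    rep <- score_predictions(data$label[test_idx], pred, positive)
    fold_reports[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f,
                                                         n_test = length(test_idx)),
                                          rep)
    if (verbose) {
      message(sprintf("fold %d/%d: accuracy %.3f", f, k, rep$accuracy))
    }
  }
  folds_tbl <- dplyr::bind_rows(fold_reports)
  cols <- c("accuracy", "precision", "sensitivity", "specificity", "f1")
  summary <- tibble::as_tibble(as.list(colMeans(folds_tbl[cols])))
  structure(list(folds = folds_tbl, summary = summary, k = k, seed = seed,
                 config = config),
            class = "pmm_cv")
}

#' @export
print.pmm_cv <- function(x, ...) {
  cat(sprintf("<pmm_cv> %d-fold cross-validation (seed %d)\n", x$k, x$seed))
  print(x$summary)
  invisible(x)
}
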