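#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a PMM model
#'
#' @param x a trained `pmm_model`.
#' @param ... unused.
#' @return Tibble with one row per epoch: `epoch`, `loss`, `accuracy`, `lr`.
#' @method tidy pmm_model
#' @export
tidy.pmm_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), loss = double(),
                          accuracy = double(), lr = double()))
  }
  x$history
}

#' One-row summary of a PMM model
#'
#' @param x a `pmm_model`.
#' @param ... unused.
#' @return Tibble: class count, parameter count, epochs trained, final
#'   loss/accuracy, enabled components.
#' @method glance pmm_model
#' @export
glance.pmm_model <- function(x, ...) {
  cfg <- x$config
  last <- if (!is.null(x$history)) utils::tail(x$history, 1) else
    tibble::tibble(loss = NA_real_, accuracy = NA_real_)
  tibble::tibble(
    n_classes = cfg$n_classes,
    n_params = pmm_count_params(x),
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = last$loss,
    final_accuracy = last$accuracy,
    use_pfe = cfg$use_pfe, use_rdlstm = cfg$use_rdlstm,
    use_mfl = cfg$use_mfl, use_attention = cfg$use_attention
  )
}

#' Tidy per-fold cross-validation metrics
#'
#' @param x a `pmm_cv` from [pmm_cross_validate()].
#' @param ... unused.
#' @return The per-fold metric tibble.
#' @method tidy pmm_cv
#' @export
tidy.pmm_cv <- function(x, ...) x$folds

#' One-row summary of a cross-validation run
#'
#' @param x a `pmm_cv`.
#' @param ... unused.
#' @return Tibble of fold-averaged metrics plus `k` and `seed`.
#' @method glance pmm_cv
#' @export
glance.pmm_cv <- function(x, ...) {
  dplyr::bind_cols(x$summary, tibble::tibble(k = x$k, seed = x$seed))
}

#' Plot the training loss and accuracy trace
#'
#' @param object a trained `pmm_model`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot pmm_model
#' @export
autoplot.pmm_model <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h[, c("epoch", "loss", "accuracy")],
                              -"epoch", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "PMM training trace")
}

#' Plot per-fold cross-validation metrics
#'
#' @param object a `pmm_cv`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot pmm_cv
#' @export
autoplot.pmm_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tidy(object)[, c("fold", "accuracy", "sensitivity", "specificity", "f1")],
    -"fold", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = NULL, title = "Cross-validated metrics by fold")
}

#' Plot example segments by class
#'
#' @param data segment tibble (`signal` list-column + `label`).
#' @param n_per_class segments drawn per class.
#' @return A ggplot of signal traces faceted by class.
#' @export
plot_segments <- function(data, n_per_class = 3) {
  picks <- dplyr::slice_head(dplyr::group_by(data, .data$label), n = n_per_class)
  picks <- dplyr::mutate(picks, segment = dplyr::row_number())
  long <- tidyr::unnest(
    dplyr::mutate(picks, t = purrr::map(.data$signal, seq_along)),
    c("signal", "t"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$signal,
                                     group = .data$segment)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~label, ncol = 1, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sample", y = "amplitude")
}

#' @importFrom rlang .data
NULL
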