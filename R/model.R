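#' Configure a positional multi-length mutual-attention (PMM) network
#'
#' Bundles the architecture and training hyper-parameters: the gated
#' convolutional encoder, the residual dilated LSTM stack (dilation rates
#' 1, 2, 4 by default), the mutual-attention block, the classifier, and the
#' Adam schedule (initial learning rate 3e-4, multiplied by `1 - 0.001`
#' after every epoch).
#'
#' Ablation flags reconstruct the component variants: `use_pfe` switches the
#' positional gate + residual in the encoder blocks, `use_rdlstm` the
#' residual dilated cell (otherwise a plain LSTM cell), `use_mfl` the
#' multi-layer stack (otherwise a single recurrent layer), and
#' `use_attention` the mutual-attention reinforcement (which requires the
#' multi-layer stack for its three taps).
#'
#' @param n_classes number of classes, `>= 2`.
#' @param input_len segment length in samples (default 178).
#' @param encoder_channels channel widths of the encoder blocks.
#' @param kernel odd convolution kernel width.
#' @param pool max-pool window after each encoder block.
#' @param rrelu_range RReLU slope bounds `c(p, q)`.
#' @param hidden recurrent hidden size; must equal the last encoder width
#'   unless the input embedding adapts it.
#' @param dilations dilation rate per recurrent layer, bottom-up.
#' @param heads attention head count `T`.
#' @param scale attention scaling `S`; default `sqrt(hidden / heads)`.
#' @param use_pfe,use_rdlstm,use_mfl,use_attention ablation flags.
#' @param lr,lr_decay,epochs,batch_size Adam training schedule.
#' @return A `pmm_config` list.
#' @export
pmm_config <- function(n_classes, input_len = 178,
                       encoder_channels = c(16, 32, 64), kernel = 3, pool = 2,
                       rrelu_range = c(1 / 8, 1 / 3),
                       hidden = 64, dilations = c(1, 2, 4),
                       heads = 4, scale = NULL,
                       use_pfe = TRUE, use_rdlstm = TRUE,
                       use_mfl = TRUE, use_attention = TRUE,
                       lr = 3e-4, lr_decay = 1e-3, epochs = 100,
                       batch_size = 64) {
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  if (lr <= 0) stop("lr must be > 0", call. = FALSE)
  if (use_attention && !use_mfl) {
    stop("mutual attention needs the three-tap multi-layer stack (use_mfl = TRUE)",
         call. = FALSE)
  }
  if (use_attention && use_mfl && length(dilations) < 3) {
    stop("mutual attention needs at least 3 recurrent layers", call. = FALSE)
  }
  if (use_attention && use_rdlstm && anyDuplicated(dilations[seq_len(3)])) {
    stop("dilation rates feeding the attention taps must be pairwise distinct",
         call. = FALSE)
  }
  if (is.null(scale)) scale <- sqrt(hidden / heads)
  structure(list(
    n_classes = as.integer(n_classes), input_len = as.integer(input_len),
    encoder_channels = as.integer(encoder_channels),
    kernel = as.integer(kernel), pool = as.integer(pool),
    rrelu_range = rrelu_range,
    hidden = as.integer(hidden), dilations = as.integer(dilations),
    heads = as.integer(heads), scale = scale,
    use_pfe = use_pfe, use_rdlstm = use_rdlstm,
    use_mfl = use_mfl, use_attention = use_attention,
    lr = lr, lr_decay = lr_decay, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size)
  ), class = "pmm_config")
}

#' Ablation variants of the PMM network
#'
#' Maps a named component variant to its flag combination: `"original"`
#' (plain conv encoder + single plain LSTM + classifier), `"rdlstm"`,
#' `"pfeblock"`, `"mfl"`, `"mfr"`, or `"full"`.
#'
#' @param variant variant name.
#' @param ... passed to [pmm_config()].
#' @return A `pmm_config`.
#' @export
pmm_variant <- function(variant = c("full", "original", "rdlstm", "pfeblock",
                                    "mfl", "mfr"), ...) {
  variant <- match.arg(variant)
  flags <- switch(variant,
    original = list(use_pfe = FALSE, use_rdlstm = FALSE, use_mfl = FALSE,
                    use_attention = FALSE),
    rdlstm   = list(use_pfe = FALSE, use_rdlstm = TRUE, use_mfl = FALSE,
                    use_attention = FALSE),
    pfeblock = list(use_pfe = TRUE, use_rdlstm = FALSE, use_mfl = FALSE,
                    use_attention = FALSE),
    mfl      = list(use_pfe = FALSE, use_rdlstm = FALSE, use_mfl = TRUE,
                    use_attention = FALSE),
    mfr      = list(use_pfe = FALSE, use_rdlstm = FALSE, use_mfl = TRUE,
                    use_attention = TRUE),
    full     = list(use_pfe = TRUE, use_rdlstm = TRUE, use_mfl = TRUE,
                    use_attention = TRUE))
  do.call(pmm_config, c(flags, list(...)))
}

#' Reduced configuration for quick CPU experiments
#'
#' A narrower network (encoder widths 8/16/32, hidden 32) with a short,
#' higher-learning-rate Adam schedule (20 epochs, lr 2e-3, batch 32) suited
#' to small synthetic studies and continuous-integration runs.
#'
#' @inheritParams pmm_config
#' @param ... overrides passed to [pmm_config()].
#' @export
pmm_reduced_config <- function(n_classes, input_len = 178, ...) {
  args <- list(n_classes = n_classes, input_len = input_len,
               encoder_channels = c(8, 16, 32), hidden = 32,
               epochs = 20, batch_size = 32, lr = 2e-3)
  args[names(list(...))] <- list(...)
  do.call(pmm_config, args)
}

#' Initialize a PMM model from a configuration
#'
#' Draws all weights (scaled-uniform fan-in initialization; classifier
#' zero-initialized so untrained predictions are uniform) and zeroes the
#' batch-normalization running statistics.
#'
#' @param config a [pmm_config()].
#' @param seed optional integer seed for the weight draw.
#' @return A `pmm_model`.
#' @export
pmm_init <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- c(1L, config$encoder_channels)
  enc <- vector("list", length(config$encoder_channels))
  for (i in seq_along(enc)) {
    enc[[i]] <- pfe_block(ch[i], ch[i + 1], kernel = config$kernel,
                          pool = config$pool, rrelu_range = config$rrelu_range)
    enc[[i]]$gated <- config$use_pfe
    if (!config$use_pfe) {
      enc[[i]]$proj_w <- NULL
      enc[[i]]$proj_b <- NULL
    }
  }
  enc_out <- utils::tail(config$encoder_channels, 1)
  H <- config$hidden
  n_layers <- if (config$use_mfl) length(config$dilations) else 1L
  embed <- NULL
  rec <- vector("list", n_layers)
  if (config$use_rdlstm) {
    embed <- list(W = array(stats::runif(H * enc_out, -1, 1) * sqrt(3 / enc_out),
                            c(H, enc_out, 1L)),
                  b = numeric(H))
    for (i in seq_len(n_layers)) {
      d <- if (config$use_mfl) config$dilations[i] else 1L
      rec[[i]] <- rdlstm_layer(H, H, dilation = d)
    }
  } else {
    for (i in seq_len(n_layers)) {
      input <- if (i == 1L) enc_out else H
      cell <- lstm_cell(input, H)
      cell$dilation <- 1L
      rec[[i]] <- cell
    }
  }
  att <- if (config$use_attention) {
    attention_params(H, heads = config$heads, scale = config$scale)
  }
  cls <- list(W = matrix(0, config$n_classes, H), b = numeric(config$n_classes))
  structure(list(config = config,
                 params = list(enc = enc, embed = embed, rec = rec,
                               att = att, cls = cls),
                 classes = seq_len(config$n_classes),
                 history = NULL),
            class = "pmm_model")
}

## builds the full forward graph; `params` leaves may be arrays or ag nodes
pmm_graph <- function(params, config, x_node, training = FALSE) {
  node <- encoder_graph(x_node, params$enc, training)
  taps <- multi_length_graph(node, params$rec, params$embed,
                             shortcut = config$use_rdlstm)
  if (config$use_attention) {
    qkv_taps <- taps[seq_len(3)]
    qkv <- project_qkv_graph(qkv_taps, params$att, training)
    heads3 <- multi_head_graph(qkv$Q, qkv$K, qkv$V, params$att)
    fat <- ag_conv1d(ag_concat_ch(heads3), params$att$fuse_w,
                     params$att$fuse_b, "same")
    feat <- ag_mean_time(fat)
  } else {
    feat <- ag_mean_time(taps[[length(taps)]])
  }
  ag_linear(feat, params$cls$W, params$cls$b)
}

## coerce signals (tibble with `signal` list-column, [n x len] matrix,
## list of vectors, single vector) to a [n x 1 x len] feature map
signals_to_fm <- function(data) {
  if (is.data.frame(data)) {
    if (!"signal" %in% names(data)) {
      stop("data frame input needs a `signal` list-column", call. = FALSE)
    }
    data <- data$signal
  }
  if (is.list(data)) {
    len <- unique(lengths(data))
    if (length(len) != 1L) stop("segments must share one length", call. = FALSE)
    data <- do.call(rbind, lapply(data, as.double))
  }
  if (is.numeric(data) && is.null(dim(data))) data <- matrix(data, 1L)
  if (is.matrix(data)) return(array(data, c(nrow(data), 1L, ncol(data))))
  if (is.array(data) && length(dim(data)) == 3L) return(data)
  stop("cannot interpret input signals", call. = FALSE)
}

#' Forward pass of the PMM network
#'
#' Runs encoder, recurrent stack, attention fusion, global time pooling and
#' the softmax classifier, returning one probability row per segment.
#'
#' @param model a [pmm_init()]ed or [pmm_train()]ed `pmm_model`.
#' @param x segments: tibble with a `signal` list-column, `[n x len]`
#'   matrix, list of equal-length vectors, or a single vector.
#' @param training evaluation mode (FALSE, deterministic) or training mode
#'   (TRUE: sampled RReLU slopes, batch statistics).
#' @return `[n x n_classes]` matrix of class probabilities.
#' @export
pmm_forward <- function(model, x, training = FALSE) {
  xf <- signals_to_fm(x)
  logits <- ag_value(pmm_graph(model$params, model$config, ag_const(xf), training))
  softmax_logits(logits)
}

#' Softmax classification layer
#'
#' `P(y = c | s) = exp(theta_c . s) / sum_j exp(theta_j . s)` for each class
#' parameter row of `theta`.
#'
#' @param s feature vector or `[n x features]` matrix.
#' @param theta `[n_classes x features]` parameter matrix.
#' @param bias optional per-class bias.
#' @return Probability vector, or matrix with one row per row of `s`.
#' @export
softmax_classify <- function(s, theta, bias = 0) {
  S <- if (is.matrix(s)) s else matrix(s, 1L)
  logits <- S %*% t(theta) + matrix(rep_len(bias, nrow(theta)),
                                    nrow(S), nrow(theta), byrow = TRUE)
  P <- softmax_logits(logits)
  if (is.matrix(s)) P else as.vector(P)
}

#' Mean categorical cross-entropy
#'
#' Mean over samples of `-log p(true class)`, with probabilities clipped at
#' `1e-12`.
#'
#' @param y_true integer class labels in `1..C`.
#' @param y_prob `[n x C]` row-stochastic probability matrix.
#' @return Non-negative scalar loss.
#' @export
cross_entropy_loss <- function(y_true, y_prob) {
  if (!is.matrix(y_prob)) y_prob <- matrix(y_prob, 1L)
  if (length(y_true) != nrow(y_prob)) {
    stop("one label per probability row required", call. = FALSE)
  }
  if (any(abs(rowSums(y_prob) - 1) > 1e-6) || any(y_prob < -1e-12)) {
    stop("probability rows must be non-negative and sum to 1", call. = FALSE)
  }
  if (any(y_true < 1L | y_true > ncol(y_prob))) {
    stop("labels out of range", call. = FALSE)
  }
  -mean(log(pmax(y_prob[cbind(seq_along(y_true), y_true)], 1e-12)))
}

## ---- trainable-leaf bookkeeping --------------------------------------------

.leaf_skip <- c("dilation", "p", "q", "pool", "gated", "S", "heads",
                "eps", "momentum", "stats")

leaf_paths <- function(x, path = character()) {
  if (is.environment(x)) return(list())
  if (is.numeric(x)) return(list(path))
  if (is.list(x)) {
    out <- list()
    for (nm in names(x)) {
      if (nm %in% .leaf_skip || is.null(x[[nm]])) next
      out <- c(out, leaf_paths(x[[nm]], c(path, nm)))
    }
    # unnamed list (e.g. list of blocks/layers)
    if (is.null(names(x))) {
      for (i in seq_along(x)) {
        out <- c(out, leaf_paths(x[[i]], c(path, as.character(i))))
      }
    }
    return(out)
  }
  list()
}

get_leaf <- function(l, path) {
  for (p in path) {
    idx <- suppressWarnings(as.integer(p))
    l <- if (!is.na(idx) && is.null(names(l))) l[[idx]] else l[[p]]
  }
  l
}

set_leaf <- function(l, path, value) {
  p <- path[1]
  idx <- suppressWarnings(as.integer(p))
  key <- if (!is.na(idx) && is.null(names(l))) idx else p
  if (length(path) == 1L) {
    l[[key]] <- value
  } else {
    l[[key]] <- set_leaf(l[[key]], path[-1], value)
  }
  l
}

#' Count trainable parameters of a PMM model
#'
#' @param model a `pmm_model` (or a `pmm_config`, which is initialized with
#'   zero-cost deterministic weights first).
#' @return Integer number of trainable scalar parameters.
#' @export
pmm_count_params <- function(model) {
  if (inherits(model, "pmm_config")) model <- pmm_init(model, seed = 0)
  sum(vapply(leaf_paths(model$params),
             function(p) length(get_leaf(model$params, p)), numeric(1)))
}

#' Train a PMM network with Adam under cross-entropy
#'
#' Minibatch Adam with the per-epoch multiplicative learning-rate decay
#' `lr_epoch = lr * (1 - lr_decay)^(epoch - 1)`. Fully reproducible for a
#' fixed seed. Labels may be arbitrary integer/character codes; they are
#' mapped to classes `1..C` in sorted order and restored by `predict()`.
#'
#' @param x a `pmm_config` (a fresh model is initialized) or an existing
#'   `pmm_model` to continue training.
#' @param data tibble with a `signal` list-column and a `label` column.
#' @param seed integer seed driving initialization, shuffling and RReLU
#'   slope sampling.
#' @param epochs optional override of the configured epoch count.
#' @param verbose print per-epoch loss to stderr.
#' @return A trained `pmm_model` with a `history` tibble (epoch, loss,
#'   accuracy, lr).
#' @export
pmm_train <- function(x, data, seed = 0, epochs = NULL, verbose = FALSE) {
  set.seed(seed)
  if (inherits(x, "pmm_config")) {
    model <- pmm_init(x)
  } else if (inherits(x, "pmm_model")) {
    model <- x
  } else {
    stop("x must be a pmm_config or pmm_model", call. = FALSE)
  }
  config <- model$config
  if (is.null(epochs)) epochs <- config$epochs
  xf <- signals_to_fm(data)
  labs <- data$label
  classes <- sort(unique(labs))
  if (length(classes) > config$n_classes) {
    stop("more label values than configured classes", call. = FALSE)
  }
  y <- match(labs, classes)
  n <- dim(xf)[1]
  if (n < 1L) stop("empty training set", call. = FALSE)

  paths <- leaf_paths(model$params)
  adam_m <- lapply(paths, function(p) get_leaf(model$params, p) * 0)
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  hist <- vector("list", epochs)

  for (epoch in seq_len(epochs)) {
    lr <- config$lr * (1 - config$lr_decay)^(epoch - 1)
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0; ep_correct <- 0L
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      xb <- xf[idx, , , drop = FALSE]
      yb <- y[idx]
      node_params <- model$params
      nodes <- vector("list", length(paths))
      for (i in seq_along(paths)) {
        nodes[[i]] <- ag_param(get_leaf(model$params, paths[[i]]))
        node_params <- set_leaf(node_params, paths[[i]], nodes[[i]])
      }
      logits <- pmm_graph(node_params, config, ag_const(xb), training = TRUE)
      loss <- ag_cross_entropy(logits, yb, config$n_classes)
      lv <- ag_value(loss)
      if (!is.finite(lv)) {
        stop(sprintf("non-finite loss at epoch %d; try a smaller learning rate",
                     epoch), call. = FALSE)
      }
      grads <- ag_backward(loss)
      step <- step + 1L
      for (i in seq_along(paths)) {
        g <- ag_grad(grads, nodes[[i]])
        adam_m[[i]] <- b1 * adam_m[[i]] + (1 - b1) * g
        adam_v[[i]] <- b2 * adam_v[[i]] + (1 - b2) * g * g
        mhat <- adam_m[[i]] / (1 - b1^step)
        vhat <- adam_v[[i]] / (1 - b2^step)
        upd <- get_leaf(model$params, paths[[i]]) -
          lr * mhat / (sqrt(vhat) + adam_eps)
        model$params <- set_leaf(model$params, paths[[i]], upd)
      }
      ep_loss <- ep_loss + lv * length(idx)
      pred <- max.col(ag_value(logits), ties.method = "first")
      ep_correct <- ep_correct + sum(pred == yb)
    }
    hist[[epoch]] <- tibble::tibble(epoch = epoch, loss = ep_loss / n,
                                    accuracy = ep_correct / n, lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  lr %.2e",
                      epoch, ep_loss / n, ep_correct / n, lr))
    }
  }
  model$history <- dplyr::bind_rows(hist)
  model$classes <- classes
  model$seed <- seed
  model
}

#' Predict class labels or probabilities
#'
#' Argmax over the forward-pass probability rows; ties resolve to the
#' lowest class index.
#'
#' @param object a `pmm_model`.
#' @param newdata segments in any layout accepted by [pmm_forward()].
#' @param type `"class"` for labels, `"prob"` for the probability matrix.
#' @param ... unused.
#' @return Vector of labels (original coding) or a probability matrix.
#' @export
predict.pmm_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  P <- pmm_forward(object, newdata, training = FALSE)
  if (type == "prob") return(P)
  object$classes[max.col(P, ties.method = "first")]
}

#' @export
print.pmm_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<pmm_model> %d classes, input %d, hidden %d, dilations %s\n",
              cfg$n_classes, cfg$input_len, cfg$hidden,
              paste(cfg$dilations, collapse = ",")))
  cat(sprintf("  flags: pfe=%s rdlstm=%s mfl=%s attention=%s;  %d parameters\n",
              cfg$use_pfe, cfg$use_rdlstm, cfg$use_mfl, cfg$use_attention,
              pmm_count_params(x)))
  if (!is.null(x$history)) {
    last <- utils::tail(x$history, 1)
    cat(sprintf("  trained %d epochs, final loss %.4f, train accuracy %.3f\n",
                nrow(x$history), last$loss, last$accuracy))
  }
  invisible(x)
}

#' @export
print.pmm_config <- function(x, ...) {
  cat(sprintf("<pmm_config> %d classes; encoder %s (k=%d, pool=%d); hidden %d; dil %s; heads %d\n",
              x$n_classes, paste(x$encoder_channels, collapse = "-"),
              x$kernel, x$pool, x$hidden,
              paste(x$dilations, collapse = ","), x$heads))
  invisible(x)
}
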