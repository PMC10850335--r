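#' Row-wise softmax
#'
#' Normalizes each row of a score matrix into a probability distribution,
#' shifting by the row maximum first so large scores cannot overflow.
#'
#' @param z numeric matrix (or vector, treated as one row).
#' @return Row-stochastic matrix of the same shape.
#' @export
softmax_rows <- function(z) {
  zm <- if (is.matrix(z)) z else matrix(z, 1L)
  if (!all(is.finite(zm))) stop("softmax_rows: non-finite scores", call. = FALSE)
  m <- zm[cbind(seq_len(nrow(zm)), max.col(zm, ties.method = "first"))]
  e <- exp(zm - m)
  out <- e / rowSums(e)
  if (is.matrix(z)) out else as.vector(out)
}

#' Mutual scaled-dot attention between three feature streams
#'
#' `softmax_rows(A %*% t(B) / S) %*% C`, with rows indexing time positions.
#' The three mutual combinations used by the network are
#' `f(Q, K, V)`, `f(Q, V, K)` and `f(V, K, Q)`.
#'
#' @param A,B score operands, `[positions x features]` matrices (vectors are
#'   single positions).
#' @param C aggregated stream; must have as many rows as `B`.
#' @param S positive scaling parameter of the dot-product scores.
#' @return `[positions x features]` matrix of attention outputs.
#' @export
mutual_scaled_attention <- function(A, B, C, S = 1) {
  Am <- if (is.matrix(A)) A else matrix(A, 1L)
  Bm <- if (is.matrix(B)) B else matrix(B, 1L)
  Cm <- if (is.matrix(C)) C else matrix(C, 1L)
  if (S <= 0) stop("S must be > 0", call. = FALSE)
  if (ncol(Am) != ncol(Bm)) stop("A and B must share the feature dimension", call. = FALSE)
  if (nrow(Cm) != nrow(Bm)) stop("C must have one row per row of B", call. = FALSE)
  softmax_rows(Am %*% t(Bm) / S) %*% Cm
}

#' Construct mutual-attention parameters
#'
#' Holds the batch-normalization affine terms and running statistics for the
#' three recurrent taps, the query/key/value projections, the per-pair
#' multi-head mixing matrices, and the fusing 1x1 convolution.
#'
#' @param feature_dim feature dimension of the taps (recurrent hidden size).
#' @param heads number of attention heads `T`; must divide `feature_dim`.
#' @param scale scaling parameter `S`; default `sqrt(feature_dim / heads)`.
#' @param out_channels channels of the fused output map.
#' @param init `"glorot"` random or `"zero"` / `"identity"` deterministic.
#' @param eps,momentum batch-normalization stabilizer and running-average
#'   momentum.
#' @return An `attention_params` list.
#' @export
attention_params <- function(feature_dim, heads = 4, scale = NULL,
                             out_channels = feature_dim,
                             init = c("glorot", "zero", "identity"),
                             eps = 1e-5, momentum = 0.1) {
  init <- match.arg(init)
  if (feature_dim %% heads != 0L) {
    stop(sprintf("feature_dim %d is not divisible by heads = %d", feature_dim, heads),
         call. = FALSE)
  }
  if (is.null(scale)) scale <- sqrt(feature_dim / heads)
  mk <- function(r, c) {
    m <- switch(init,
                glorot = matrix(stats::runif(r * c, -1, 1) * sqrt(3 / c), r, c),
                zero = matrix(0, r, c),
                identity = diag(1, r, c))
    array(m, c(r, c, 1L))  # width-1 conv kernel == per-step linear map
  }
  bn <- function() list(gamma = rep(1, feature_dim), beta = numeric(feature_dim),
                        stats = as.environment(list(mean = numeric(feature_dim),
                                                    var = rep(1, feature_dim))))
  structure(list(
    bn_q = bn(), bn_k = bn(), bn_v = bn(),
    Wq = mk(feature_dim, feature_dim), bq = numeric(feature_dim),
    Wk = mk(feature_dim, feature_dim), bk = numeric(feature_dim),
    Wv = mk(feature_dim, feature_dim), bv = numeric(feature_dim),
    Wqk = mk(feature_dim, feature_dim),
    Wqv = mk(feature_dim, feature_dim),
    Wvk = mk(feature_dim, feature_dim),
    fuse_w = if (init == "identity") {
      array(cbind(diag(1 / 3, out_channels, feature_dim),
                  diag(1 / 3, out_channels, feature_dim),
                  diag(1 / 3, out_channels, feature_dim)),
            c(out_channels, 3L * feature_dim, 1L))
    } else {
      array(if (init == "zero") 0 else
              stats::runif(out_channels * 3 * feature_dim, -1, 1) *
                sqrt(3 / (3 * feature_dim)),
            c(out_channels, 3L * feature_dim, 1L))
    },
    fuse_b = numeric(out_channels),
    S = scale, heads = as.integer(heads), eps = eps, momentum = momentum
  ), class = "attention_params")
}

#' Normalize taps and project to query, key and value
#'
#' Each tap is batch-normalized per feature over batch and time (batch
#' statistics while training, running averages in evaluation, then affine
#' scale/shift) and passed through its linear projection.
#'
#' @param inputs list of the three taps `F_q`, `F_k`, `F_v`, each a
#'   `[batch x feature x length]` array (matrices/vectors are promoted).
#' @param params an [attention_params()].
#' @param training use batch statistics and update the running averages.
#' @return `list(Q, K, V)` of `[batch x feature x length]` arrays.
#' @export
project_qkv <- function(inputs, params, training = FALSE) {
  nodes <- project_qkv_graph(lapply(inputs, function(x) ag_const(as_feature_map(x))),
                             params, training)
  lapply(nodes, ag_value)
}

project_qkv_graph <- function(nodes, params, training = FALSE) {
  eps <- ag_value(params$eps %||% 1e-5)
  mom <- ag_value(params$momentum %||% 0.1)
  one <- function(x, bn, W, b) {
    xn <- ag_batchnorm(x, bn$gamma, bn$beta, bn$stats, training, eps, mom)
    if (!ag_is_node(W) && length(dim(W)) != 3L) {
      W <- array(W, c(nrow(W), ncol(W), 1L))
    }
    ag_conv1d(xn, W, b, "same")
  }
  list(Q = one(nodes[[1]], params$bn_q, params$Wq, params$bq),
       K = one(nodes[[2]], params$bn_k, params$Wk, params$bk),
       V = one(nodes[[3]], params$bn_v, params$Wv, params$bv))
}

#' Multi-head mutual attention over the three projected streams
#'
#' Splits the feature dimension into `T` head slices, runs the three mutual
#' scaled attentions per head, concatenates head outputs along the feature
#' axis and applies the per-pair linear mixing matrices.
#'
#' @param Q,K,V projected streams: `[batch x feature x length]` arrays or
#'   `[positions x features]` matrices for a single sample.
#' @param params an [attention_params()].
#' @return List with `A_qk`, `A_qv`, `A_vk` in the layout of the inputs.
#' @export
multi_head_mutual_attention <- function(Q, K, V, params) {
  as_arr <- function(x) {
    if (is.array(x) && length(dim(x)) == 3L) x else
      aperm(array(as.matrix(x), c(nrow(as.matrix(x)), ncol(as.matrix(x)), 1L)), c(3, 2, 1))
  }
  mat_in <- !(is.array(Q) && length(dim(Q)) == 3L)
  nodes <- multi_head_graph(ag_const(as_arr(Q)), ag_const(as_arr(K)),
                            ag_const(as_arr(V)), params)
  out <- lapply(nodes, ag_value)
  if (mat_in) out <- lapply(out, function(a) t(matrix(a[1, , ], dim(a)[2], dim(a)[3])))
  names(out) <- c("A_qk", "A_qv", "A_vk")
  out
}

multi_head_graph <- function(Q, K, V, params) {
  S <- ag_value(params$S); heads <- ag_value(params$heads)
  mix <- function(node, W) {
    if (!ag_is_node(W) && length(dim(W)) != 3L) {
      W <- array(W, c(nrow(W), ncol(W), 1L))
    }
    ag_conv1d(node, W, numeric(dim(ag_value(W))[1]), "same")
  }
  list(mix(ag_mh_attention(Q, K, V, S, heads), params$Wqk),
       mix(ag_mh_attention(Q, V, K, S, heads), params$Wqv),
       mix(ag_mh_attention(V, K, Q, S, heads), params$Wvk))
}

#' Fuse the three multi-head attention outputs
#'
#' Concatenates `A_qk`, `A_qv`, `A_vk` along the feature axis and mixes them
#' with a width-1 convolution, yielding the reinforced feature map.
#'
#' @param A_qk,A_qv,A_vk `[batch x feature x length]` arrays.
#' @param params an [attention_params()].
#' @return `[batch x out_channels x length]` array.
#' @export
fuse_attention <- function(A_qk, A_qv, A_vk, params) {
  nodes <- lapply(list(A_qk, A_qv, A_vk), function(x) ag_const(as_feature_map(x)))
  ag_value(ag_conv1d(ag_concat_ch(nodes), params$fuse_w, params$fuse_b, "same"))
}
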