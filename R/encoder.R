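#' 1D convolution (cross-correlation) over a feature map
#'
#' Slides each output-channel kernel across the time axis and accumulates a
#' per-channel bias. `"same"` padding zero-pads symmetrically (odd kernels
#' only) so the output length equals the input length; `"valid"` keeps only
#' fully overlapping positions.
#'
#' @param x signal: numeric vector, `[channels x length]` matrix, or
#'   `[batch x channels x length]` array.
#' @param weights kernel: numeric vector (single in/out channel) or
#'   `[out_channels x in_channels x kernel]` array; `kernel` must be odd for
#'   `"same"` padding.
#' @param bias per-output-channel bias, recycled scalar allowed.
#' @param padding `"same"` or `"valid"`.
#' @return Convolved signal in the same layout as `x`.
#' @examples
#' conv1d(c(1, 2, 3, 4), c(1, -1), padding = "valid")  # -1 -1 -1
#' @export
conv1d <- function(x, weights, bias = 0, padding = c("same", "valid")) {
  padding <- match.arg(padding)
  xf <- as_feature_map(x)
  if (!is.array(weights) || length(dim(weights)) != 3L) {
    weights <- array(as.double(weights), c(1L, 1L, length(weights)))
  }
  Co <- dim(weights)[1]
  bias <- rep_len(as.double(bias), Co)
  y <- conv1d_fwd(xf, weights, bias, padding)
  fm_simplify(y, x)
}

#' Randomized leaky ReLU
#'
#' Identity for non-negative entries. Negative entries are scaled by a slope
#' drawn per element from U(p, q) when `training = TRUE`, and by the
#' deterministic midpoint (p + q) / 2 in evaluation mode.
#'
#' @param x numeric vector or array.
#' @param p,q slope bounds, `0 <= p < q < 1`.
#' @param training sample slopes (TRUE) or use the midpoint (FALSE).
#' @return Activated values, same shape as `x`.
#' @export
rrelu <- function(x, p = 1 / 8, q = 1 / 3, training = FALSE) {
  rrelu_fwd(x, p, q, training)$y
}

#' Sigmoid positional gate
#'
#' Elementwise logistic weight `exp(x) / (exp(x) + 1)` used to gate the
#' refined convolution branch of a positional feature encoding block by the
#' block input itself. Saturates without overflow for large `|x|`.
#'
#' @param x numeric vector or array.
#' @return Gate weights strictly in (0, 1).
#' @export
positional_gate <- function(x) sigmoid_stable(x)

#' Construct parameters for one positional feature encoding block
#'
#' A block is conv -> RReLU -> conv, gated elementwise by a sigmoid of the
#' block input and closed with a residual connection; a non-overlapping
#' max-pool follows. When the block widens the channel count a 1x1
#' projection of the input provides the matching gate and residual term.
#'
#' @param in_channels,out_channels channel counts entering/leaving the block.
#' @param kernel odd kernel width of both convolutions.
#' @param pool non-overlapping max-pool window applied after the block.
#' @param rrelu_range lower/upper slope bound `c(p, q)` of the RReLU.
#' @param init `"he"` scaled-uniform random weights or `"zero"`.
#' @return A `pfe_block` parameter list.
#' @export
pfe_block <- function(in_channels, out_channels, kernel = 3, pool = 2,
                      rrelu_range = c(1 / 8, 1 / 3), init = c("he", "zero")) {
  init <- match.arg(init)
  if (kernel %% 2L == 0L) stop("kernel must be odd for same-length padding", call. = FALSE)
  p <- rrelu_range[1]; q <- rrelu_range[2]
  if (!(p >= 0 && p < q && q < 1)) stop("rrelu_range must satisfy 0 <= p < q < 1", call. = FALSE)
  mk <- function(co, ci, k) {
    if (init == "zero") return(array(0, c(co, ci, k)))
    array(stats::runif(co * ci * k, -1, 1) * sqrt(3 / (ci * k)), c(co, ci, k))
  }
  params <- list(
    conv1_w = mk(out_channels, in_channels, kernel),
    conv1_b = numeric(out_channels),
    conv2_w = mk(out_channels, out_channels, kernel),
    conv2_b = numeric(out_channels),
    proj_w = if (in_channels != out_channels) mk(out_channels, in_channels, 1L) else NULL,
    proj_b = if (in_channels != out_channels) numeric(out_channels) else NULL,
    p = p, q = q, pool = as.integer(pool), gated = TRUE
  )
  structure(params, class = "pfe_block")
}

## forward through one block on ag nodes (used by both the public numeric
## API and the training graph); `params` entries may be ag nodes or arrays
pfe_block_graph <- function(x, params, training = FALSE) {
  p <- ag_value(params$p %||% 1 / 8); q <- ag_value(params$q %||% 1 / 3)
  h <- ag_conv1d(x, params$conv1_w, params$conv1_b, "same")
  h <- ag_rrelu(h, p, q, training)
  xo2 <- ag_conv1d(h, params$conv2_w, params$conv2_b, "same")
  fe <- x
  if (!is.null(params$proj_w)) {
    fe <- ag_conv1d(x, params$proj_w, params$proj_b, "same")
  }
  if (isTRUE(ag_value(params$gated))) {
    gate <- ag_sigmoid(fe)
    ag_add(ag_mul(gate, xo2), fe)
  } else {
    # ablation variant without the positional gate or residual
    xo2
  }
}

#' Forward pass of one positional feature encoding block
#'
#' Computes `F_o = sigmoid(F_e) * conv2(rrelu(conv1(F_e))) + F_e`, where the
#' gate and residual use the 1x1-projected input when the block changes the
#' channel count. Pooling is not applied here (see [encoder_forward()]).
#'
#' @param x input feature map (vector, matrix or 3D array).
#' @param params a [pfe_block()].
#' @inheritParams rrelu
#' @return Feature map with `out_channels` channels, same length as `x`.
#' @export
pfe_block_forward <- function(x, params, training = FALSE) {
  xf <- as_feature_map(x)
  fm_check(xf)
  y <- ag_value(pfe_block_graph(ag_const(xf), params, training))
  fm_simplify(y, x)
}

#' Positional feature encoding: stacked gated blocks with max-pooling
#'
#' Applies each block in turn, following every block with a non-overlapping
#' 1D max-pool of its `pool` window. The result is the positional feature
#' map fed to the multi-length recurrent stage.
#'
#' @param x input feature map.
#' @param blocks list of [pfe_block()] parameter sets.
#' @inheritParams rrelu
#' @return Encoded feature map (3D array for array input).
#' @export
encoder_forward <- function(x, blocks, training = FALSE) {
  xf <- as_feature_map(x)
  fm_check(xf)
  node <- ag_const(xf)
  node <- encoder_graph(node, blocks, training)
  fm_simplify(ag_value(node), x)
}

encoder_graph <- function(node, blocks, training = FALSE) {
  for (blk in blocks) {
    node <- pfe_block_graph(node, blk, training)
    w <- as.integer(ag_value(blk$pool))
    if (w > 1L) node <- ag_maxpool(node, w)
  }
  node
}
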