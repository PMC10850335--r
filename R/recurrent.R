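#' Construct LSTM cell parameters
#'
#' Twelve arrays: input weights `Wz, Wi, Wf, Wo` (`[hidden x input]`),
#' recurrent weights `Rz, Ri, Rf, Ro` (`[hidden x hidden]`) and biases
#' `bz, bi, bf, bo`, for the block input, input gate, forget gate and output
#' gate respectively.
#'
#' @param input_size dimension of the per-step input vector.
#' @param hidden_size dimension of the hidden and cell states.
#' @param init `"glorot"` scaled-uniform random weights or `"zero"`.
#' @return An `lstm_cell` parameter list.
#' @export
lstm_cell <- function(input_size, hidden_size, init = c("glorot", "zero")) {
  init <- match.arg(init)
  mk <- function(r, c) {
    if (init == "zero") return(matrix(0, r, c))
    matrix(stats::runif(r * c, -1, 1) * sqrt(3 / c), r, c)
  }
  par <- list(
    Wz = mk(hidden_size, input_size), Wi = mk(hidden_size, input_size),
    Wf = mk(hidden_size, input_size), Wo = mk(hidden_size, input_size),
    Rz = mk(hidden_size, hidden_size), Ri = mk(hidden_size, hidden_size),
    Rf = mk(hidden_size, hidden_size), Ro = mk(hidden_size, hidden_size),
    bz = numeric(hidden_size), bi = numeric(hidden_size),
    bf = numeric(hidden_size), bo = numeric(hidden_size)
  )
  structure(par, class = "lstm_cell")
}

#' One step of the standard LSTM cell
#'
#' Block input `z = tanh(Wz x + Rz h + bz)`; gates
#' `i, f, o = sigmoid(W x + R h + b)`; cell state `c = f * c_prev + i * z`;
#' hidden state `h = tanh(c) * o`.
#'
#' @param x_t input at time t, numeric vector or `[batch x input]` matrix.
#' @param h_prev,c_prev previous hidden/cell state, vector or
#'   `[batch x hidden]` matrix.
#' @param params an [lstm_cell()].
#' @return `list(h, c)` in the layout of the state inputs.
#' @export
lstm_cell_step <- function(x_t, h_prev, c_prev, params) {
  was_vec <- !is.matrix(x_t)
  X <- if (is.matrix(x_t)) x_t else matrix(x_t, 1L)
  H <- if (is.matrix(h_prev)) h_prev else matrix(h_prev, 1L)
  C <- if (is.matrix(c_prev)) c_prev else matrix(c_prev, 1L)
  hs <- nrow(params$Rz)
  if (ncol(X) != ncol(params$Wz) || ncol(H) != hs || ncol(C) != hs) {
    stop("lstm_cell_step: state/parameter shapes disagree", call. = FALSE)
  }
  b <- function(v) matrix(v, nrow(X), hs, byrow = TRUE)
  z <- tanh(X %*% t(params$Wz) + H %*% t(params$Rz) + b(params$bz))
  i <- sigmoid_stable(X %*% t(params$Wi) + H %*% t(params$Ri) + b(params$bi))
  f <- sigmoid_stable(X %*% t(params$Wf) + H %*% t(params$Rf) + b(params$bf))
  o <- sigmoid_stable(X %*% t(params$Wo) + H %*% t(params$Ro) + b(params$bo))
  cc <- f * C + i * z
  hh <- tanh(cc) * o
  if (was_vec) list(h = as.vector(hh), c = as.vector(cc)) else list(h = hh, c = cc)
}

#' Construct one residual dilated LSTM layer
#'
#' The cell of a residual dilated layer takes the hidden state of the layer
#' below at the current step together with this layer's own hidden and cell
#' states from `d` steps back, and adds the layer-below state as a shortcut
#' inside the output gate: `h' = o' * (tanh(c') + h_below)`.
#'
#' @param input_size,hidden_size state dimensions; the residual shortcut
#'   requires `input_size == hidden_size`.
#' @param dilation recurrence step gap `d >= 1`.
#' @inheritParams lstm_cell
#' @return An `rdlstm_layer` parameter list (an [lstm_cell()] plus dilation).
#' @export
rdlstm_layer <- function(input_size, hidden_size, dilation = 1,
                         init = c("glorot", "zero")) {
  if (dilation < 1) stop("dilation must be >= 1", call. = FALSE)
  if (input_size != hidden_size) {
    stop("residual dilated layer requires input_size == hidden_size", call. = FALSE)
  }
  par <- unclass(lstm_cell(input_size, hidden_size, match.arg(init)))
  par$dilation <- as.integer(dilation)
  structure(par, class = "rdlstm_layer")
}

#' One step of the residual dilated LSTM cell
#'
#' Gates are driven by the layer-below hidden state `h_below` and this
#' layer's dilated hidden state `h_dilated`; the cell state blends the
#' dilated cell state, and the hidden output adds the layer-below shortcut:
#' `c' = f' * c_dilated + i' * z'`, `h' = o' * (tanh(c') + h_below)`.
#'
#' @param h_below hidden state of the layer below at the current time step.
#' @param h_dilated,c_dilated this layer's states from `d` steps back.
#' @param params an [rdlstm_layer()] (or [lstm_cell()]).
#' @return `list(h, c)`.
#' @export
rdlstm_cell_step <- function(h_below, h_dilated, c_dilated, params) {
  st <- lstm_cell_step(h_below, h_dilated, c_dilated, params)
  o_gate <- local({
    X <- if (is.matrix(h_below)) h_below else matrix(h_below, 1L)
    H <- if (is.matrix(h_dilated)) h_dilated else matrix(h_dilated, 1L)
    b <- matrix(params$bo, nrow(X), nrow(params$Ro), byrow = TRUE)
    sigmoid_stable(X %*% t(params$Wo) + H %*% t(params$Ro) + b)
  })
  cc <- if (is.matrix(st$c)) st$c else matrix(st$c, 1L)
  xb <- if (is.matrix(h_below)) h_below else matrix(h_below, 1L)
  hh <- o_gate * (tanh(cc) + xb)
  if (is.matrix(h_below)) list(h = hh, c = st$c) else list(h = as.vector(hh), c = st$c)
}

#' Run a residual dilated LSTM layer over a sequence
#'
#' Iterates the residual dilated cell over `t = 1..L`; steps with `t <= d`
#' read zero dilated states. Dilation `d` partitions the sequence into `d`
#' interleaved subsequences that evolve independently.
#'
#' @param x input sequence: `[batch x hidden x length]` array, or a
#'   `[hidden x length]` matrix / length-L vector for a single sample.
#' @param params an [rdlstm_layer()].
#' @return Hidden-state sequence in the layout of `x`.
#' @export
rdlstm_layer_forward <- function(x, params) {
  xf <- as_feature_map(x)
  r <- rdlstm_layer_fwd(xf, params, params$dilation %||% 1L, shortcut = TRUE)
  fm_simplify(r$h, x)
}

#' Multi-length feature learning: hierarchically stacked residual dilated LSTMs
#'
#' Embeds the encoded features into the hidden space and feeds them through
#' the stack bottom-up (default dilation rates 1, 2, 4); each layer consumes
#' the hidden sequence of the layer below. The per-layer hidden sequences
#' are returned as taps; the last three feed the mutual-attention stage as
#' `F_q`, `F_k`, `F_v`.
#'
#' @param x encoded feature map `[batch x channels x length]` (vector and
#'   matrix inputs are promoted).
#' @param layers list of [rdlstm_layer()]s, ordered bottom-up.
#' @param embed optional `list(W, b)` linear input embedding applied
#'   per time step before the first layer (required when the channel count
#'   differs from the hidden size).
#' @return List of `[batch x hidden x length]` tap arrays, one per layer.
#' @export
multi_length_forward <- function(x, layers, embed = NULL) {
  xf <- as_feature_map(x)
  node <- ag_const(xf)
  taps <- multi_length_graph(node, layers, embed)
  lapply(taps, ag_value)
}

multi_length_graph <- function(node, layers, embed = NULL, shortcut = TRUE) {
  if (!is.null(embed)) {
    W <- embed$W
    if (!ag_is_node(W) && length(dim(W)) != 3L) {
      W <- array(W, c(nrow(W), ncol(W), 1L))  # 1x1 conv == per-step linear map
    }
    node <- ag_conv1d(node, W, embed$b, "same")
  }
  taps <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    lay <- layers[[i]]
    d <- as.integer(ag_value(lay$dilation %||% 1L))
    node <- ag_rdlstm_layer(node, lay[c("Wz", "Wi", "Wf", "Wo",
                                        "Rz", "Ri", "Rf", "Ro",
                                        "bz", "bi", "bf", "bo")],
                            d, shortcut = shortcut)
    taps[[i]] <- node
  }
  taps
}
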