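## Numeric forward/backward kernels for every layer type, plus their
## ag_node wrappers. All feature maps are [batch x channels x length]
## double arrays; backward formulas are verified against central finite
## differences in the test suite.

#' Coerce a signal to the canonical feature-map array
#'
#' Feature maps are `[batch x channels x length]` arrays. A numeric vector is
#' promoted to one batch element with one channel; a matrix is read as
#' `[channels x length]` for a single batch element.
#'
#' @param x numeric vector, matrix or 3D array.
#' @return A 3D double array.
#' @export
as_feature_map <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) return(x * 1.0)
  if (is.matrix(x)) return(array(aperm(x, c(1, 2)), c(1L, nrow(x), ncol(x))))
  if (is.numeric(x)) return(array(as.double(x), c(1L, 1L, length(x))))
  stop("cannot interpret input as a feature map", call. = FALSE)
}

fm_check <- function(x) {
  if (!all(is.finite(x))) stop("feature map contains non-finite values", call. = FALSE)
  invisible(x)
}

## drop batch/channel singleton dims for vector-in/vector-out convenience
fm_simplify <- function(y, like) {
  if (is.array(like) && length(dim(like)) == 3L) return(y)
  if (is.matrix(like)) return(matrix(y[1, , ], dim(y)[2], dim(y)[3]))
  if (dim(y)[2] == 1L) return(as.vector(y[1, 1, ]))
  matrix(y[1, , ], dim(y)[2], dim(y)[3])
}

## ---- 1D convolution (cross-correlation) ------------------------------------

conv1d_fwd_ref <- function(x, w, b, padding = "same", want_cache = FALSE) {
  d <- dim(x); B <- d[1]; Ci <- d[2]; L <- d[3]
  if (L < 1L) stop("empty signal", call. = FALSE)
  dw <- dim(w); Co <- dw[1]; K <- dw[3]
  if (dw[2] != Ci) {
    stop(sprintf("conv1d: input has %d channels but weights expect %d", Ci, dw[2]),
         call. = FALSE)
  }
  if (K == 1L) {
    # width-1 kernels are a per-step linear map; skip padding and unfolding
    Xu <- matrix(aperm(x, c(2, 1, 3)), Ci, B * L)
    Y <- matrix(w, Co, Ci) %*% Xu + b
    y <- aperm(array(Y, c(Co, B, L)), c(2, 1, 3))
    return(if (want_cache) list(y = y, Xu = Xu, P = 0L, Lp = L) else y)
  }
  if (padding == "same") {
    if (K %% 2L == 0L) stop("'same' padding requires an odd kernel", call. = FALSE)
    P <- (K - 1L) %/% 2L
    xp <- array(0, c(B, Ci, L + 2L * P))
    xp[, , P + seq_len(L)] <- x
    Lout <- L
  } else if (padding == "valid") {
    xp <- x
    Lout <- L - K + 1L
    if (Lout < 1L) stop("signal shorter than kernel under 'valid' padding", call. = FALSE)
  } else {
    stop("padding must be 'same' or 'valid'", call. = FALSE)
  }
  Lp <- dim(xp)[3]
  # im2col: channel-major matrix [Ci*B x Lp]; time-window blocks are
  # contiguous column ranges, so unfolding is K cheap block copies
  Pm <- matrix(aperm(xp, c(2, 1, 3)), Ci * B, Lp)
  Xu <- matrix(0, Ci * K, B * Lout)
  for (k in seq_len(K)) {
    blk <- Pm[, k:(k + Lout - 1L), drop = FALSE]
    dim(blk) <- c(Ci, B * Lout)
    Xu[((k - 1L) * Ci + 1L):(k * Ci), ] <- blk
  }
  Wu <- matrix(w, Co, Ci * K)
  Y <- Wu %*% Xu + b
  y <- aperm(array(Y, c(Co, B, Lout)), c(2, 1, 3))
  if (want_cache) list(y = y, Xu = Xu, P = P <- if (padding == "same") (K - 1L) %/% 2L else 0L,
                       Lp = Lp) else y
}

conv1d_bwd_ref <- function(gy, x, w, padding = "same", cache = NULL) {
  d <- dim(x); B <- d[1]; Ci <- d[2]; L <- d[3]
  dw <- dim(w); Co <- dw[1]; K <- dw[3]
  Lout <- dim(gy)[3]
  P <- if (padding == "same") (K - 1L) %/% 2L else 0L
  Lp <- L + 2L * P
  if (is.null(cache)) {
    cache <- conv1d_fwd_ref(x, w, numeric(Co), padding, want_cache = TRUE)
  }
  Xu <- cache$Xu
  Gm <- matrix(aperm(gy, c(2, 1, 3)), nrow = Co)
  gb <- rowSums(Gm)
  gw <- array(Gm %*% t(Xu), dw)
  Wu <- matrix(w, Co, Ci * K)
  gXu <- crossprod(Wu, Gm)                     # [Ci*K x B*Lout]
  if (K == 1L) {
    gx <- aperm(array(gXu, c(Ci, B, L)), c(2, 1, 3))
    return(list(gx = gx, gw = gw, gb = gb))
  }
  gPm <- matrix(0, Ci * B, Lp)
  for (k in seq_len(K)) {
    blk <- gXu[((k - 1L) * Ci + 1L):(k * Ci), , drop = FALSE]
    dim(blk) <- c(Ci * B, Lout)
    idx <- k:(k + Lout - 1L)
    gPm[, idx] <- gPm[, idx, drop = FALSE] + blk
  }
  gxp <- aperm(array(gPm, c(Ci, B, Lp)), c(2, 1, 3))
  gx <- if (P > 0L) gxp[, , P + seq_len(L), drop = FALSE] else gxp
  list(gx = gx, gw = gw, gb = gb)
}


## compiled conv/pool front ends (pure-R *_ref versions above are the
## reference implementations)

conv1d_fwd <- function(x, w, b, padding = "same") {
  d <- dim(x); L <- d[3]
  dw <- dim(w); K <- dw[3]
  if (L < 1L) stop("empty signal", call. = FALSE)
  if (dw[2] != d[2]) {
    stop(sprintf("conv1d: input has %d channels but weights expect %d",
                 d[2], dw[2]), call. = FALSE)
  }
  if (padding == "same") {
    if (K %% 2L == 0L) stop("'same' padding requires an odd kernel", call. = FALSE)
  } else if (padding == "valid") {
    if (L - K + 1L < 1L) {
      stop("signal shorter than kernel under 'valid' padding", call. = FALSE)
    }
  } else {
    stop("padding must be 'same' or 'valid'", call. = FALSE)
  }
  conv1d_fwd_cpp(x, w, b, as.integer(padding == "same"))
}

conv1d_bwd <- function(gy, x, w, padding = "same") {
  r <- conv1d_bwd_cpp(gy, x, w, as.integer(padding == "same"))
  r$gb <- as.vector(r$gb)
  r
}

maxpool_fwd <- function(x, window) {
  w <- as.integer(window)
  if (w < 1L) stop("pool window must be >= 1", call. = FALSE)
  if (dim(x)[3] %/% w < 1L) stop("signal shorter than pooling window", call. = FALSE)
  r <- maxpool_fwd_cpp(x, w)
  list(y = r$y, idx = r$idx, window = w, in_len = dim(x)[3])
}

maxpool_bwd <- function(gy, cache, in_dim) {
  maxpool_bwd_cpp(gy, cache$idx, cache$window, in_dim[3])
}

ag_conv1d <- function(x, w, b, padding = "same") {
  x <- as_ag(x); w <- as_ag(w); b <- as_ag(b)
  xv <- x$value; wv <- w$value
  y <- conv1d_fwd(xv, wv, b$value, padding)
  ag_node(y, list(x, w, b), function(g) {
    bk <- conv1d_bwd(g, xv, wv, padding)
    list(bk$gx, bk$gw, bk$gb)
  })
}

## ---- randomized leaky ReLU -------------------------------------------------

rrelu_fwd <- function(x, p, q, training = FALSE) {
  if (!(p >= 0 && p < q && q < 1)) {
    stop("rrelu requires 0 <= p < q < 1", call. = FALSE)
  }
  m <- if (is.null(dim(x))) rep(1, length(x)) else array(1, dim(x))
  neg <- x < 0
  nneg <- sum(neg)
  if (nneg > 0L) {
    m[neg] <- if (training) stats::runif(nneg, p, q) else (p + q) / 2
  }
  list(y = x * m, slope = m)
}

ag_rrelu <- function(x, p, q, training = FALSE) {
  x <- as_ag(x)
  r <- rrelu_fwd(x$value, p, q, training)
  m <- r$slope
  ag_node(r$y, list(x), function(g) list(g * m))
}

## ---- non-overlapping 1D max pooling ----------------------------------------

maxpool_fwd_ref <- function(x, window) {
  d <- dim(x); B <- d[1]; C <- d[2]; L <- d[3]
  w <- as.integer(window)
  if (w < 1L) stop("pool window must be >= 1", call. = FALSE)
  Lout <- L %/% w
  if (Lout < 1L) stop("signal shorter than pooling window", call. = FALSE)
  arr <- array(x[, , seq_len(Lout * w), drop = FALSE], c(B, C, w, Lout))
  y <- array(arr[, , 1L, , drop = FALSE], c(B, C, Lout))
  idx <- array(1L, c(B, C, Lout))
  if (w > 1L) {
    for (s in 2:w) {
      cand <- array(arr[, , s, , drop = FALSE], c(B, C, Lout))
      upd <- cand > y
      y[upd] <- cand[upd]
      idx[upd] <- s
    }
  }
  list(y = y, idx = idx, window = w, in_len = L)
}

maxpool_bwd_ref <- function(gy, cache, in_dim) {
  B <- in_dim[1]; C <- in_dim[2]; L <- in_dim[3]
  Lout <- dim(gy)[3]
  gx <- array(0, in_dim)
  tpos <- (rep(seq_len(Lout) - 1L, each = B * C)) * cache$window + as.vector(cache$idx)
  lin <- rep(seq_len(B), times = C * Lout) +
    B * (rep(rep(seq_len(C), each = B), times = Lout) - 1L) +
    B * C * (tpos - 1L)
  gx[lin] <- gx[lin] + as.vector(gy)
  gx
}

ag_maxpool <- function(x, window) {
  x <- as_ag(x)
  r <- maxpool_fwd(x$value, window)
  in_dim <- dim(x$value)
  ag_node(r$y, list(x), function(g) list(maxpool_bwd(g, r, in_dim)))
}

## ---- batch normalization (per channel over batch x time) -------------------

batchnorm_fwd <- function(x, gamma, beta, run_mean, run_var, training = FALSE,
                          eps = 1e-5, momentum = 0.1) {
  d <- dim(x); B <- d[1]; C <- d[2]; L <- d[3]
  Xm <- matrix(aperm(x, c(2, 1, 3)), nrow = C)  # [C x (B*L)]
  n <- B * L
  if (training) {
    mu <- rowMeans(Xm)
    xc <- Xm - mu
    v <- rowMeans(xc * xc)
    new_mean <- (1 - momentum) * run_mean + momentum * mu
    vu <- if (n > 1L) v * n / (n - 1L) else v
    new_var <- (1 - momentum) * run_var + momentum * vu
  } else {
    mu <- run_mean
    v <- run_var
    xc <- Xm - mu
    new_mean <- run_mean
    new_var <- run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Ym <- gamma * xhat + beta
  y <- aperm(array(Ym, c(C, B, L)), c(2, 1, 3))
  list(y = y, xhat = xhat, inv = inv, xc = xc, n = n,
       new_mean = new_mean, new_var = new_var, training = training)
}

batchnorm_bwd <- function(gy, cache, gamma, in_dim) {
  B <- in_dim[1]; C <- in_dim[2]; L <- in_dim[3]
  Gm <- matrix(aperm(gy, c(2, 1, 3)), nrow = C)
  dgamma <- rowSums(Gm * cache$xhat)
  dbeta <- rowSums(Gm)
  dxhat <- Gm * gamma
  if (cache$training) {
    n <- cache$n
    dv <- rowSums(dxhat * cache$xc) * (-0.5) * cache$inv^3
    dmu <- -rowSums(dxhat) * cache$inv + dv * (-2) * rowMeans(cache$xc)
    dX <- dxhat * cache$inv + dv * 2 * cache$xc / n + dmu / n
  } else {
    dX <- dxhat * cache$inv
  }
  gx <- aperm(array(dX, c(C, B, L)), c(2, 1, 3))
  list(gx = gx, dgamma = dgamma, dbeta = dbeta)
}

## `stats_env` holds running mean/var; updated as a side effect in training
ag_batchnorm <- function(x, gamma, beta, stats_env, training = FALSE,
                         eps = 1e-5, momentum = 0.1) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  r <- batchnorm_fwd(x$value, gamma$value, beta$value,
                     stats_env$mean, stats_env$var, training, eps, momentum)
  if (training) {
    stats_env$mean <- r$new_mean
    stats_env$var <- r$new_var
  }
  in_dim <- dim(x$value)
  gv <- gamma$value
  ag_node(r$y, list(x, gamma, beta), function(g) {
    b <- batchnorm_bwd(g, r, gv, in_dim)
    list(b$gx, b$dgamma, b$dbeta)
  })
}

## ---- residual dilated LSTM layer (fused BPTT kernel) -----------------------

## x: [B x Din x L]. With `shortcut` (the residual dilated cell) the hidden
## output is o * (tanh(c) + x_t), which requires Din == H; the plain cell
## (shortcut = FALSE) is the standard LSTM and admits rectangular input
## weights. Dilated recurrence reads states from t - d; earlier steps see
## zero states.
rdlstm_layer_fwd_ref <- function(x, par, dilation, shortcut = TRUE) {
  d <- dim(x); B <- d[1]; Din <- d[2]; L <- d[3]
  H <- nrow(par$Rz)
  dd <- as.integer(dilation)
  if (dd < 1L) stop("dilation must be >= 1", call. = FALSE)
  if (shortcut && Din != H) {
    stop("residual cell requires input dim == hidden dim", call. = FALSE)
  }
  Wall <- rbind(par$Wz, par$Wi, par$Wf, par$Wo)       # [4H x Din]
  Rall <- rbind(par$Rz, par$Ri, par$Rf, par$Ro)       # [4H x H]
  tRall <- t(Rall)
  ball <- c(par$bz, par$bi, par$bf, par$bo)
  # input-side gate drives for every step in one matmul
  Xm <- matrix(aperm(x, c(1, 3, 2)), B * L, Din)      # rows (b, t)-major
  Ain <- Xm %*% t(Wall) + matrix(ball, B * L, 4L * H, byrow = TRUE)
  iz <- seq_len(H); ii <- H + iz; iff <- 2L * H + iz; io <- 3L * H + iz
  hs <- vector("list", L); cs <- vector("list", L)
  zs <- vector("list", L); is <- vector("list", L)
  fs <- vector("list", L); os <- vector("list", L); tcs <- vector("list", L)
  zero <- matrix(0, B, H)
  for (t in seq_len(L)) {
    rows <- seq.int((t - 1L) * B + 1L, t * B)
    A <- Ain[rows, , drop = FALSE]
    if (t > dd) {
      hd <- hs[[t - dd]]; cd <- cs[[t - dd]]
      A <- A + hd %*% tRall
    } else {
      cd <- zero
    }
    z <- tanh(A[, iz, drop = FALSE])
    i <- sigmoid_stable(A[, ii, drop = FALSE])
    f <- sigmoid_stable(A[, iff, drop = FALSE])
    o <- sigmoid_stable(A[, io, drop = FALSE])
    cc <- f * cd + i * z
    tc <- tanh(cc)
    ht <- if (shortcut) o * (tc + Xm[rows, , drop = FALSE]) else o * tc
    hs[[t]] <- ht; cs[[t]] <- cc
    zs[[t]] <- z; is[[t]] <- i; fs[[t]] <- f; os[[t]] <- o; tcs[[t]] <- tc
  }
  h <- array(unlist(hs, use.names = FALSE), c(B, H, L))
  list(h = h,
       cache = list(hs = hs, cs = cs, z = zs, i = is, f = fs, o = os, tc = tcs,
                    Xm = Xm, Wall = Wall, Rall = Rall,
                    dilation = dd, shortcut = shortcut))
}

rdlstm_layer_bwd_ref <- function(gy, x, par, cache) {
  d <- dim(x); B <- d[1]; Din <- d[2]; L <- d[3]
  H <- nrow(par$Rz)
  dd <- cache$dilation
  shortcut <- cache$shortcut
  Xm <- cache$Xm; Wall <- cache$Wall; Rall <- cache$Rall
  iz <- seq_len(H); ii <- H + iz; iff <- 2L * H + iz; io <- 3L * H + iz
  Gym <- matrix(aperm(gy, c(1, 3, 2)), B * L, H)
  GhAcc <- vector("list", L)   # gradients flowing back through h_{t-d}
  GcAcc <- vector("list", L)
  GA <- matrix(0, B * L, 4L * H)
  gR_all <- matrix(0, 4L * H, H)
  gx_short <- if (shortcut) matrix(0, B * L, Din) else NULL
  zero <- matrix(0, B, H)
  for (t in rev(seq_len(L))) {
    rows <- seq.int((t - 1L) * B + 1L, t * B)
    gh <- Gym[rows, , drop = FALSE]
    if (!is.null(GhAcc[[t]])) gh <- gh + GhAcc[[t]]
    gc <- if (is.null(GcAcc[[t]])) zero else GcAcc[[t]]
    o <- cache$o[[t]]; tc <- cache$tc[[t]]
    z <- cache$z[[t]]; i <- cache$i[[t]]; f <- cache$f[[t]]
    cd <- if (t > dd) cache$cs[[t - dd]] else zero
    if (shortcut) {
      xt <- Xm[rows, , drop = FALSE]
      go <- gh * (tc + xt)
      gx_short[rows, ] <- gh * o
    } else {
      go <- gh * tc
    }
    gc <- gc + gh * o * (1 - tc * tc)
    ga <- cbind(gc * i * (1 - z * z),        # d/d a_z
                gc * z * i * (1 - i),        # d/d a_i
                gc * cd * f * (1 - f),       # d/d a_f
                go * o * (1 - o))            # d/d a_o
    GA[rows, ] <- ga
    if (t > dd) {
      hd <- cache$hs[[t - dd]]
      gR_all <- gR_all + crossprod(ga, hd)
      ghd <- ga %*% Rall
      GhAcc[[t - dd]] <- if (is.null(GhAcc[[t - dd]])) ghd else GhAcc[[t - dd]] + ghd
      gcd <- gc * f
      GcAcc[[t - dd]] <- if (is.null(GcAcc[[t - dd]])) gcd else GcAcc[[t - dd]] + gcd
    }
  }
  gW_all <- crossprod(GA, Xm)                # [4H x Din]
  gb_all <- colSums(GA)
  gXm <- GA %*% Wall
  if (shortcut) gXm <- gXm + gx_short
  gx <- aperm(array(gXm, c(B, L, Din)), c(1, 3, 2))
  list(gx = gx,
       gW = list(Wz = gW_all[iz, , drop = FALSE], Wi = gW_all[ii, , drop = FALSE],
                 Wf = gW_all[iff, , drop = FALSE], Wo = gW_all[io, , drop = FALSE]),
       gR = list(Rz = gR_all[iz, , drop = FALSE], Ri = gR_all[ii, , drop = FALSE],
                 Rf = gR_all[iff, , drop = FALSE], Ro = gR_all[io, , drop = FALSE]),
       gb = list(bz = gb_all[iz], bi = gb_all[ii], bf = gb_all[iff], bo = gb_all[io]))
}


## compiled front ends; the *_ref pure-R kernels above are the reference
## implementations the test suite checks them against

rdlstm_layer_fwd <- function(x, par, dilation, shortcut = TRUE) {
  d <- dim(x); B <- d[1]; Din <- d[2]
  H <- nrow(par$Rz)
  dd <- as.integer(dilation)
  if (dd < 1L) stop("dilation must be >= 1", call. = FALSE)
  if (shortcut && Din != H) {
    stop("residual cell requires input dim == hidden dim", call. = FALSE)
  }
  Wall <- rbind(par$Wz, par$Wi, par$Wf, par$Wo)
  Rall <- rbind(par$Rz, par$Ri, par$Rf, par$Ro)
  ball <- c(par$bz, par$bi, par$bf, par$bo)
  r <- rdlstm_fwd_cpp(x, Wall, Rall, ball, dd, shortcut)
  list(h = r$h,
       cache = list(cpp = r, Wall = Wall, Rall = Rall,
                    dilation = dd, shortcut = shortcut))
}

rdlstm_layer_bwd <- function(gy, x, par, cache) {
  H <- nrow(par$Rz)
  cp <- cache$cpp
  r <- rdlstm_bwd_cpp(gy, cp$Xm, cache$Wall, cache$Rall,
                      cp$h, cp$c, cp$z, cp$i, cp$f, cp$o, cp$tc,
                      cache$dilation, cache$shortcut)
  iz <- seq_len(H); ii <- H + iz; iff <- 2L * H + iz; io <- 3L * H + iz
  list(gx = r$gx,
       gW = list(Wz = r$gW_all[iz, , drop = FALSE], Wi = r$gW_all[ii, , drop = FALSE],
                 Wf = r$gW_all[iff, , drop = FALSE], Wo = r$gW_all[io, , drop = FALSE]),
       gR = list(Rz = r$gR_all[iz, , drop = FALSE], Ri = r$gR_all[ii, , drop = FALSE],
                 Rf = r$gR_all[iff, , drop = FALSE], Ro = r$gR_all[io, , drop = FALSE]),
       gb = list(bz = r$gb_all[iz], bi = r$gb_all[ii],
                 bf = r$gb_all[iff], bo = r$gb_all[io]))
}

mh_attention_fwd <- function(Q, K, C, S, heads) {
  d <- dim(Q)
  if (!all(dim(K) == d) || !all(dim(C) == d)) {
    stop("attention inputs must share [batch x feature x length]", call. = FALSE)
  }
  if (d[2] %% heads != 0L) {
    stop(sprintf("feature dim %d not divisible by %d heads", d[2], heads),
         call. = FALSE)
  }
  if (S <= 0) stop("scaling parameter S must be > 0", call. = FALSE)
  list(O = mh_attn_fwd_cpp(Q, K, C, S, heads), heads = heads)
}

mh_attention_bwd <- function(gO, Q, K, C, S, cache) {
  mh_attn_bwd_cpp(gO, Q, K, C, S, cache$heads)
}

ag_rdlstm_layer <- function(x, par_nodes, dilation, shortcut = TRUE) {
  x <- as_ag(x)
  ord <- c("Wz", "Wi", "Wf", "Wo", "Rz", "Ri", "Rf", "Ro",
           "bz", "bi", "bf", "bo")
  par_nodes <- lapply(par_nodes[ord], as_ag)
  par <- lapply(par_nodes, ag_value)
  r <- rdlstm_layer_fwd(x$value, par, dilation, shortcut)
  xv <- x$value
  parents <- c(list(x), unname(par_nodes))
  ag_node(r$h, parents, function(g) {
    b <- rdlstm_layer_bwd(g, xv, par, r$cache)
    c(list(b$gx),
      unname(b$gW[c("Wz", "Wi", "Wf", "Wo")]),
      unname(b$gR[c("Rz", "Ri", "Rf", "Ro")]),
      unname(b$gb[c("bz", "bi", "bf", "bo")]))
  })
}

## ---- multi-head mutual scaled-dot attention (fused kernel) -----------------

## Q, K, C: [B x F x L]; per sample and head, scores are t(Qs) %*% Ks / S
## over time positions, rows soft-maxed, then aggregated over the rows of C.
mh_attention_fwd_ref <- function(Q, K, C, S, heads) {
  d <- dim(Q); B <- d[1]; F <- d[2]; L <- d[3]
  if (!all(dim(K) == d) || !all(dim(C) == d)) {
    stop("attention inputs must share [batch x feature x length]", call. = FALSE)
  }
  if (F %% heads != 0L) {
    stop(sprintf("feature dim %d not divisible by %d heads", F, heads), call. = FALSE)
  }
  if (S <= 0) stop("scaling parameter S must be > 0", call. = FALSE)
  Fh <- F %/% heads
  O <- array(0, c(B, F, L))
  Aw <- vector("list", B * heads)
  for (b in seq_len(B)) {
    for (h in seq_len(heads)) {
      idx <- ((h - 1L) * Fh + 1L):(h * Fh)
      Qs <- matrix(Q[b, idx, ], Fh, L)
      Ks <- matrix(K[b, idx, ], Fh, L)
      Cs <- matrix(C[b, idx, ], Fh, L)
      A <- softmax_rows(crossprod(Qs, Ks) / S)
      O[b, idx, ] <- Cs %*% t(A)
      Aw[[(b - 1L) * heads + h]] <- A
    }
  }
  list(O = O, A = Aw, heads = heads, Fh = Fh)
}

mh_attention_bwd_ref <- function(gO, Q, K, C, S, cache) {
  d <- dim(Q); B <- d[1]; F <- d[2]; L <- d[3]
  heads <- cache$heads; Fh <- cache$Fh
  gQ <- array(0, d); gK <- array(0, d); gC <- array(0, d)
  for (b in seq_len(B)) {
    for (h in seq_len(heads)) {
      idx <- ((h - 1L) * Fh + 1L):(h * Fh)
      Qs <- matrix(Q[b, idx, ], Fh, L)
      Ks <- matrix(K[b, idx, ], Fh, L)
      Cs <- matrix(C[b, idx, ], Fh, L)
      A <- cache$A[[(b - 1L) * heads + h]]
      g <- matrix(gO[b, idx, ], Fh, L)
      gC[b, idx, ] <- g %*% A
      gA <- crossprod(g, Cs)                # dL/dA[i, j] = sum_f g[f,i] Cs[f,j]
      rs <- rowSums(gA * A)
      gSc <- A * (gA - rs)
      gQ[b, idx, ] <- Ks %*% t(gSc) / S
      gK[b, idx, ] <- Qs %*% gSc / S
    }
  }
  list(gQ = gQ, gK = gK, gC = gC)
}

ag_mh_attention <- function(Q, K, C, S, heads) {
  Q <- as_ag(Q); K <- as_ag(K); C <- as_ag(C)
  Qv <- Q$value; Kv <- K$value; Cv <- C$value
  r <- mh_attention_fwd(Qv, Kv, Cv, S, heads)
  ag_node(r$O, list(Q, K, C), function(g) {
    b <- mh_attention_bwd(g, Qv, Kv, Cv, S, r)
    list(b$gQ, b$gK, b$gC)
  })
}

## ---- concatenation along the channel axis ----------------------------------

ag_concat_ch <- function(xs) {
  xs <- lapply(xs, as_ag)
  vals <- lapply(xs, ag_value)
  chans <- vapply(vals, function(v) dim(v)[2], numeric(1))
  d1 <- dim(vals[[1]])
  y <- array(0, c(d1[1], sum(chans), d1[3]))
  off <- 0L
  for (v in vals) {
    y[, off + seq_len(dim(v)[2]), ] <- v
    off <- off + dim(v)[2]
  }
  ag_node(y, xs, function(g) {
    out <- vector("list", length(vals))
    off <- 0L
    for (i in seq_along(vals)) {
      ci <- dim(vals[[i]])[2]
      out[[i]] <- g[, off + seq_len(ci), , drop = FALSE]
      off <- off + ci
    }
    out
  })
}

## ---- global average over time ----------------------------------------------

ag_mean_time <- function(x) {
  x <- as_ag(x)
  d <- dim(x$value); B <- d[1]; C <- d[2]; L <- d[3]
  y <- matrix(rowMeans(matrix(x$value, B * C, L)), B, C)
  ag_node(y, list(x), function(g) {
    list(array(rep(as.vector(g) / L, L), c(B, C, L)))
  })
}

## ---- dense layer on pooled features ----------------------------------------

ag_linear <- function(X, W, b) {
  X <- as_ag(X); W <- as_ag(W); b <- as_ag(b)
  Xv <- X$value; Wv <- W$value
  y <- Xv %*% t(Wv) + matrix(b$value, nrow(Xv), length(b$value), byrow = TRUE)
  ag_node(y, list(X, W, b), function(g) {
    list(g %*% Wv, t(g) %*% Xv, colSums(g))
  })
}

## ---- softmax cross-entropy from logits -------------------------------------

softmax_logits <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

ag_cross_entropy <- function(logits, labels, n_classes) {
  logits <- as_ag(logits)
  lv <- logits$value
  B <- nrow(lv)
  P <- softmax_logits(lv)
  picked <- P[cbind(seq_len(B), labels)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  ag_node(loss, list(logits), function(g) {
    G <- P
    G[cbind(seq_len(B), labels)] <- G[cbind(seq_len(B), labels)] - 1
    list(g * G / B)
  })
}
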