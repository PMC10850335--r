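# Reverse-mode gradients of every kernel against central finite differences,
# and exact agreement of the compiled kernels with their pure-R references.

test_that("elementwise node gradients match finite differences", {
  set.seed(11)
  x <- array(rnorm(12), c(2, 2, 3))
  for (op in list(
    list(ag = pmmnet:::ag_sigmoid, f = function(v) sum(1 / (1 + exp(-v)))),
    list(ag = pmmnet:::ag_tanh, f = function(v) sum(tanh(v)))
  )) {
    node <- pmmnet:::ag_param(x)
    out <- op$ag(node)
    grads <- pmmnet:::ag_backward(out, seed_grad = array(1, dim(x)))
    g <- pmmnet:::ag_grad(grads, node)
    expect_lt(max(abs(g - fd_grad(op$f, x))), 1e-7)
  }
})

test_that("conv1d compiled kernel equals the pure-R reference and FD", {
  set.seed(12)
  x <- array(rnorm(2 * 3 * 9), c(2, 3, 9))
  w <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  b <- rnorm(4)
  for (pad in c("same", "valid")) {
    y <- pmmnet:::conv1d_fwd(x, w, b, pad)
    expect_equal(y, pmmnet:::conv1d_fwd_ref(x, w, b, pad), tolerance = 1e-14)
    gy <- array(rnorm(length(y)), dim(y))
    bk <- pmmnet:::conv1d_bwd(gy, x, w, pad)
    ref <- pmmnet:::conv1d_bwd_ref(gy, x, w, pad)
    expect_equal(bk$gx, ref$gx, tolerance = 1e-12)
    expect_equal(bk$gw, ref$gw, tolerance = 1e-12)
    expect_equal(bk$gb, ref$gb, tolerance = 1e-12)
    loss <- function(ww) sum(pmmnet:::conv1d_fwd(x, ww, b, pad) * gy)
    expect_lt(max(abs(fd_grad(loss, w) - bk$gw)), 1e-6)
    lossx <- function(xx) sum(pmmnet:::conv1d_fwd(xx, w, b, pad) * gy)
    expect_lt(max(abs(fd_grad(lossx, x) - bk$gx)), 1e-6)
  }
})

test_that("max-pool routes gradient to the window argmax", {
  set.seed(13)
  x <- array(rnorm(2 * 2 * 10), c(2, 2, 10))
  r <- pmmnet:::maxpool_fwd(x, 3)
  expect_equal(r$y, pmmnet:::maxpool_fwd_ref(x, 3)$y)
  gy <- array(rnorm(length(r$y)), dim(r$y))
  gx <- pmmnet:::maxpool_bwd(gy, r, dim(x))
  loss <- function(xx) sum(pmmnet:::maxpool_fwd(xx, 3)$y * gy)
  expect_lt(max(abs(fd_grad(loss, x) - gx)), 1e-6)
  # tail samples beyond the last full window get zero gradient
  expect_true(all(gx[, , 10] == 0))
})

test_that("batch-norm gradients are exact in training and evaluation mode", {
  set.seed(14)
  x <- array(rnorm(3 * 2 * 4), c(3, 2, 4))
  gamma <- runif(2, 0.5, 1.5); beta <- rnorm(2)
  rm <- rnorm(2); rv <- runif(2, 0.5, 2)
  gy <- array(rnorm(length(x)), dim(x))
  for (training in c(TRUE, FALSE)) {
    fw <- pmmnet:::batchnorm_fwd(x, gamma, beta, rm, rv, training)
    bk <- pmmnet:::batchnorm_bwd(gy, fw, gamma, dim(x))
    lx <- function(xx) sum(pmmnet:::batchnorm_fwd(xx, gamma, beta, rm, rv, training)$y * gy)
    lg <- function(gg) sum(pmmnet:::batchnorm_fwd(x, gg, beta, rm, rv, training)$y * gy)
    lb <- function(bb) sum(pmmnet:::batchnorm_fwd(x, gamma, bb, rm, rv, training)$y * gy)
    expect_lt(max(abs(fd_grad(lx, x) - bk$gx)), 1e-6)
    expect_lt(max(abs(fd_grad(lg, gamma) - bk$dgamma)), 1e-6)
    expect_lt(max(abs(fd_grad(lb, beta) - bk$dbeta)), 1e-6)
  }
  # training mode updates running statistics toward the batch statistics
  fw <- pmmnet:::batchnorm_fwd(x, gamma, beta, rm, rv, TRUE, momentum = 0.1)
  expect_false(isTRUE(all.equal(fw$new_mean, rm)))
  expect_equal(fw$new_mean, 0.9 * rm + 0.1 * rowMeans(matrix(aperm(x, c(2, 1, 3)), 2)))
})

test_that("residual dilated LSTM BPTT matches the reference and FD", {
  set.seed(15)
  lay <- rdlstm_layer(3, 3, dilation = 2)
  par <- lay[c("Wz", "Wi", "Wf", "Wo", "Rz", "Ri", "Rf", "Ro",
               "bz", "bi", "bf", "bo")]
  x <- array(rnorm(2 * 3 * 7), c(2, 3, 7))
  fw <- pmmnet:::rdlstm_layer_fwd(x, par, 2, TRUE)
  expect_equal(fw$h, pmmnet:::rdlstm_layer_fwd_ref(x, par, 2, TRUE)$h,
               tolerance = 1e-14)
  gy <- array(rnorm(2 * 3 * 7), c(2, 3, 7))
  bk <- pmmnet:::rdlstm_layer_bwd(gy, x, par, fw$cache)
  lossx <- function(xx) sum(pmmnet:::rdlstm_layer_fwd(xx, par, 2, TRUE)$h * gy)
  expect_lt(max(abs(fd_grad(lossx, x) - bk$gx)), 1e-6)
  for (nm in c("Wz", "Rf", "bo")) {
    lossp <- function(v) {
      pp <- par; pp[[nm]][] <- v
      sum(pmmnet:::rdlstm_layer_fwd(x, pp, 2, TRUE)$h * gy)
    }
    got <- if (startsWith(nm, "W")) bk$gW[[nm]] else
      if (startsWith(nm, "R")) bk$gR[[nm]] else bk$gb[[nm]]
    expect_lt(max(abs(fd_grad(lossp, par[[nm]]) - got)), 1e-6)
  }
})

test_that("multi-head attention node gradients match reference and FD", {
  set.seed(16)
  d <- c(2, 4, 5)
  Q <- array(rnorm(prod(d)), d); K <- array(rnorm(prod(d)), d)
  C <- array(rnorm(prod(d)), d)
  fw <- pmmnet:::mh_attention_fwd(Q, K, C, 1.7, 2)
  expect_equal(fw$O, pmmnet:::mh_attention_fwd_ref(Q, K, C, 1.7, 2)$O,
               tolerance = 1e-14)
  gO <- array(rnorm(prod(d)), d)
  bk <- pmmnet:::mh_attention_bwd(gO, Q, K, C, 1.7, fw)
  for (arg in c("Q", "K", "C")) {
    loss <- function(v) {
      a <- list(Q = Q, K = K, C = C); a[[arg]] <- v
      sum(pmmnet:::mh_attention_fwd(a$Q, a$K, a$C, 1.7, 2)$O * gO)
    }
    expect_lt(max(abs(fd_grad(loss, get(arg)) - bk[[paste0("g", arg)]])), 1e-6)
  }
})

test_that("cross-entropy node gradient is softmax minus one-hot", {
  set.seed(17)
  logits <- matrix(rnorm(6), 2, 3)
  y <- c(2L, 3L)
  node <- pmmnet:::ag_param(logits)
  loss <- pmmnet:::ag_cross_entropy(node, y, 3L)
  grads <- pmmnet:::ag_backward(loss)
  g <- pmmnet:::ag_grad(grads, node)
  f <- function(l) {
    P <- pmmnet:::softmax_logits(l)
    -mean(log(P[cbind(1:2, y)]))
  }
  expect_lt(max(abs(fd_grad(f, logits) - g)), 1e-7)
})

test_that("gradient accumulates over reused nodes", {
  x <- pmmnet:::ag_param(2)
  y <- pmmnet:::ag_mul(x, x)          # x^2: dy/dx = 4
  grads <- pmmnet:::ag_backward(y)
  expect_equal(pmmnet:::ag_grad(grads, x), 4)
})
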