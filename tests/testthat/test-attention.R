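# Mutual-attention feature reinforcement: softmax, scaled-dot attention,
# multi-head splitting/mixing, normalization + projection, fusion.

test_that("softmax_rows is row-stochastic and shift-stable", {
  expect_equal(softmax_rows(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax_rows(c(0, log(2))), c(1 / 3, 2 / 3))
  expect_equal(softmax_rows(c(1000, 1000)), c(0.5, 0.5))
  set.seed(41)
  z <- matrix(rnorm(30, sd = 5), 5, 6)
  sm <- softmax_rows(z)
  expect_lt(max(abs(rowSums(sm) - 1)), 1e-12)
  expect_equal(softmax_rows(z + 123), sm, tolerance = 1e-12)
})

test_that("mutual scaled attention matches hand-computed cases", {
  # single position: softmax of a scalar is 1
  x <- c(0.3, -1.2)
  expect_equal(mutual_scaled_attention(x, x, x, S = 2), matrix(x, 1))
  # hand example
  out <- mutual_scaled_attention(matrix(c(1, 0), 1),
                                 matrix(c(1, 0, 0, 1), 2, byrow = TRUE),
                                 matrix(c(2, 0, 0, 4), 2, byrow = TRUE), S = 1)
  w <- exp(1) / (exp(1) + 1)
  expect_equal(as.vector(out), c(2 * w, 4 * (1 - w)), tolerance = 1e-4)
  expect_equal(as.vector(out), c(1.4622, 1.0756), tolerance = 1e-4)
  # S -> infinity flattens the weights to uniform: rows = column means of C
  Q <- matrix(rnorm(6), 2, 3); K <- matrix(rnorm(12), 4, 3)
  C <- matrix(rnorm(12), 4, 3)
  out2 <- mutual_scaled_attention(Q, K, C, S = 1e9)
  expect_equal(out2[1, ], colMeans(C), tolerance = 1e-6)
  expect_error(mutual_scaled_attention(Q, K, C[1:2, ], S = 1), "row")
})

test_that("attention rows are convex combinations of the value rows", {
  set.seed(42)
  Q <- matrix(rnorm(8), 4, 2); K <- matrix(rnorm(8), 4, 2)
  C <- matrix(rnorm(8), 4, 2)
  W <- softmax_rows(Q %*% t(K) / 1.5)
  expect_lt(max(abs(rowSums(W) - 1)), 1e-12)
  out <- mutual_scaled_attention(Q, K, C, S = 1.5)
  for (j in 1:2) {
    expect_true(all(out[, j] >= min(C[, j]) - 1e-12))
    expect_true(all(out[, j] <= max(C[, j]) + 1e-12))
  }
  # permuting key rows together with value rows leaves the output unchanged
  perm <- sample(4)
  expect_equal(mutual_scaled_attention(Q, K[perm, ], C[perm, ], S = 1.5), out,
               tolerance = 1e-12)
})

test_that("multi-head attention reduces to single-head at T = 1 and splits slices", {
  set.seed(43)
  L <- 5; F <- 6
  Qm <- matrix(rnorm(L * F), L, F); Km <- matrix(rnorm(L * F), L, F)
  Vm <- matrix(rnorm(L * F), L, F)
  p1 <- attention_params(F, heads = 1, scale = 2, init = "identity")
  out <- multi_head_mutual_attention(Qm, Km, Vm, p1)
  expect_equal(out$A_qk, mutual_scaled_attention(Qm, Km, Vm, S = 2),
               tolerance = 1e-12)
  expect_equal(out$A_qv, mutual_scaled_attention(Qm, Vm, Km, S = 2),
               tolerance = 1e-12)
  expect_equal(out$A_vk, mutual_scaled_attention(Vm, Km, Qm, S = 2),
               tolerance = 1e-12)
  # T = 2: heads act on disjoint feature slices independently
  p2 <- attention_params(F, heads = 2, scale = 2, init = "identity")
  out2 <- multi_head_mutual_attention(Qm, Km, Vm, p2)
  halves <- cbind(
    mutual_scaled_attention(Qm[, 1:3], Km[, 1:3], Vm[, 1:3], S = 2),
    mutual_scaled_attention(Qm[, 4:6], Km[, 4:6], Vm[, 4:6], S = 2))
  expect_equal(out2$A_qk, halves, tolerance = 1e-12)
  # zero mixing matrices null the output
  p0 <- attention_params(F, heads = 2, scale = 2, init = "zero")
  p0$bn_q$gamma[] <- 1
  out0 <- multi_head_mutual_attention(Qm, Km, Vm, p0)
  expect_true(all(out0$A_qk == 0) && all(out0$A_vk == 0))
  expect_error(attention_params(5, heads = 2), "divisible")
})

test_that("projection normalizes per feature then applies the linear maps", {
  set.seed(44)
  p <- attention_params(3, heads = 1, init = "identity")
  # already standardized input with identity projection passes through
  x <- array(rnorm(4 * 3 * 50), c(4, 3, 50))
  qkv <- project_qkv(list(x, x, x), p, training = TRUE)
  xn <- pmmnet:::batchnorm_fwd(x, rep(1, 3), rep(0, 3), numeric(3), rep(1, 3),
                               training = TRUE)$y
  expect_equal(qkv$Q, xn, tolerance = 1e-12)
  # constant feature normalizes to ~0 under the epsilon guard
  xc <- array(5, c(2, 3, 4))
  qc <- project_qkv(list(xc, xc, xc), p, training = TRUE)
  expect_lt(max(abs(qc$K)), 1e-6)
  # 2x2 toy with hand-set weights: affine map after normalization
  p2 <- attention_params(2, heads = 1, init = "zero")
  p2$Wq <- array(matrix(c(1, 0, 1, 1), 2, 2, byrow = TRUE), c(2, 2, 1))
  p2$bq <- c(0.5, -0.5)
  x2 <- array(rnorm(3 * 2 * 6), c(3, 2, 6))
  q2 <- project_qkv(list(x2, x2, x2), p2, training = TRUE)$Q
  x2n <- pmmnet:::batchnorm_fwd(x2, rep(1, 2), rep(0, 2), numeric(2), rep(1, 2),
                                training = TRUE)$y
  manual <- array(0, dim(x2))
  for (b in 1:3) for (t in 1:6) {
    manual[b, , t] <- matrix(c(1, 0, 1, 1), 2, 2, byrow = TRUE) %*% x2n[b, , t] +
      c(0.5, -0.5)
  }
  expect_equal(q2, manual, tolerance = 1e-12)
})

test_that("fusion concatenates the three streams through a width-1 conv", {
  set.seed(45)
  F <- 3; L <- 4
  X <- array(rnorm(2 * F * L), c(2, F, L))
  p <- attention_params(F, heads = 1, init = "identity")  # fuse = mean of streams
  expect_equal(fuse_attention(X, X, X, p), X, tolerance = 1e-12)
  pz <- attention_params(F, heads = 1, init = "zero")
  pz$fuse_b <- c(1, 2, 3)
  out <- fuse_attention(X, X, X, pz)
  expect_equal(out[1, , 2], c(1, 2, 3))
  expect_identical(dim(out), dim(X))       # same-length contract
})
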