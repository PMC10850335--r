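# LSTM cell, residual dilated cell and layer, hierarchical stack.

test_that("lstm cell follows the gate equations on hand-checked cases", {
  # zero parameters: gates 0.5, block input 0 -> states stay zero
  p0 <- const_cell(2, 2)
  st <- lstm_cell_step(c(1, -1), c(0, 0), c(0, 0), p0)
  expect_equal(st$h, c(0, 0))
  expect_equal(st$c, c(0, 0))
  # scalar case W = 1, R = 0, b = 0, x = 1, h = 0, c = 1
  p1 <- lstm_cell(1, 1, init = "zero")
  for (nm in c("Wz", "Wi", "Wf", "Wo")) p1[[nm]][] <- 1
  st1 <- lstm_cell_step(1, 0, 1, p1)
  sig1 <- plogis(1)
  expect_equal(st1$c, sig1 * 1 + sig1 * tanh(1), tolerance = 1e-12)
  expect_equal(st1$h, tanh(st1$c) * sig1, tolerance = 1e-12)
  # saturated forget gate preserves the cell state
  p2 <- const_cell(1, 1)
  p2$bf[] <- 50
  st2 <- lstm_cell_step(0, 0, 0.73, p2)
  expect_equal(st2$c, 0.73, tolerance = 1e-10)
  expect_error(lstm_cell_step(c(1, 2, 3), c(0, 0), c(0, 0), p0), "shapes")
})

test_that("lstm cell agrees with an independent scalar reference", {
  set.seed(31)
  for (rep in 1:20) {
    par <- lstm_cell(3, 4)
    x <- rnorm(3); h <- rnorm(4); cc <- rnorm(4)
    got <- lstm_cell_step(x, h, cc, par)
    ref <- scalar_lstm_ref(x, h, cc, par)
    expect_lt(max(abs(got$h - ref$h)), 1e-12)
    expect_lt(max(abs(got$c - ref$c)), 1e-12)
  }
})

test_that("residual dilated cell adds the layer-below shortcut in the output gate", {
  # zero parameters: h' = 0.5 * h_below
  p0 <- rdlstm_layer(3, 3, init = "zero")
  hb <- rnorm(3)
  st <- rdlstm_cell_step(hb, rep(0, 3), rep(0, 3), p0)
  expect_equal(st$h, 0.5 * hb)
  # with h_below = 0 the shortcut vanishes and the plain cell is recovered
  p1 <- rdlstm_layer(2, 2)
  st_rd <- rdlstm_cell_step(c(0, 0), c(0.3, -0.2), c(0.1, 0.4), p1)
  st_plain <- lstm_cell_step(c(0, 0), c(0.3, -0.2), c(0.1, 0.4), p1)
  expect_equal(st_rd$c, st_plain$c, tolerance = 1e-14)
  # scalar toy: all weights 1, h_below 1, zero states
  p2 <- rdlstm_layer(1, 1, init = "zero")
  for (nm in c("Wz", "Wi", "Wf", "Wo", "Rz", "Ri", "Rf", "Ro")) p2[[nm]][] <- 1
  st2 <- rdlstm_cell_step(1, 0, 0, p2)
  sig1 <- plogis(1)
  expect_equal(st2$c, sig1 * tanh(1), tolerance = 1e-12)
  expect_equal(st2$h, sig1 * (tanh(sig1 * tanh(1)) + 1), tolerance = 1e-12)
})

test_that("dilation d decomposes into d interleaved unit-dilation passes", {
  set.seed(32)
  for (d in c(2, 3, 4)) {
    lay <- rdlstm_layer(3, 3, dilation = d)
    L <- sample(c(d + 1, 2 * d, 11), 1)
    x <- array(rnorm(2 * 3 * L), c(2, 3, L))
    full <- rdlstm_layer_forward(x, lay)
    lay1 <- lay; lay1$dilation <- 1L
    inter <- array(0, dim(x))
    for (off in seq_len(d)) {
      idx <- seq(off, L, by = d)
      sub <- x[, , idx, drop = FALSE]
      inter[, , idx] <- rdlstm_layer_forward(sub, lay1)
    }
    expect_lt(max(abs(full - inter)), 1e-6)
  }
})

test_that("degenerate dilations behave as specified", {
  set.seed(33)
  lay <- rdlstm_layer(2, 2, dilation = 10)
  x <- array(rnorm(1 * 2 * 5), c(1, 2, 5))     # d >= L: no recurrent history
  out <- rdlstm_layer_forward(x, lay)
  byhand <- array(0, dim(x))
  for (t in 1:5) {
    st <- rdlstm_cell_step(matrix(x[, , t], 1), matrix(0, 1, 2),
                           matrix(0, 1, 2), lay)
    byhand[, , t] <- st$h
  }
  expect_equal(out, byhand, tolerance = 1e-12)
  expect_error(rdlstm_layer(2, 2, dilation = 0), "dilation")
  # zero-parameter layer halves its input everywhere
  lz <- rdlstm_layer(2, 2, dilation = 2, init = "zero")
  expect_equal(rdlstm_layer_forward(x, lz), 0.5 * x)
})

test_that("the hierarchical stack taps each layer's hidden sequence", {
  set.seed(34)
  layers <- lapply(c(1, 2, 4), function(d) rdlstm_layer(2, 2, dilation = d,
                                                        init = "zero"))
  x <- array(rnorm(2 * 2 * 8), c(2, 2, 8))
  taps <- multi_length_forward(x, layers)
  expect_length(taps, 3)
  expect_equal(taps[[1]], 0.5 * x)
  expect_equal(taps[[2]], 0.25 * x)
  expect_equal(taps[[3]], 0.125 * x)
  # single-timestep input: every dilation acts identically
  l1 <- rdlstm_layer(2, 2, dilation = 1)
  l4 <- l1; l4$dilation <- 4L
  x1 <- array(rnorm(2 * 2 * 1), c(2, 2, 1))
  expect_equal(rdlstm_layer_forward(x1, l1), rdlstm_layer_forward(x1, l4))
})

test_that("states stay finite over very long bounded inputs", {
  set.seed(35)
  lay <- rdlstm_layer(4, 4, dilation = 2)
  x <- array(tanh(rnorm(1 * 4 * 10000)), c(1, 4, 10000))
  out <- rdlstm_layer_forward(x, lay)
  expect_true(all(is.finite(out)))
})

test_that("a 2-layer stack is differentiable to FD accuracy", {
  set.seed(36)
  layers <- list(rdlstm_layer(4, 4, dilation = 1), rdlstm_layer(4, 4, dilation = 2))
  x <- array(rnorm(1 * 4 * 8), c(1, 4, 8))
  gy <- array(rnorm(1 * 4 * 8), c(1, 4, 8))
  node <- pmmnet:::ag_param(x)
  taps <- pmmnet:::multi_length_graph(node, layers)
  grads <- pmmnet:::ag_backward(taps[[2]], seed_grad = gy)
  g <- pmmnet:::ag_grad(grads, node)
  f <- function(xx) sum(multi_length_forward(xx, layers)[[2]] * gy)
  expect_lt(max_rel_err(fd_grad(f, x), g), 1e-4)
})
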