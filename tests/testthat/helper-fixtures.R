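# Shared fixtures: tiny deterministic parameter sets and an independent
# scalar LSTM reference used as the oracle for the vectorized cells.

# per-element scalar reference of the standard LSTM step
scalar_lstm_ref <- function(x, h, c, par) {
  H <- nrow(par$Rz)
  zn <- in_ <- fn <- on <- cn <- hn <- numeric(H)
  for (k in seq_len(H)) {
    az <- sum(par$Wz[k, ] * x) + sum(par$Rz[k, ] * h) + par$bz[k]
    ai <- sum(par$Wi[k, ] * x) + sum(par$Ri[k, ] * h) + par$bi[k]
    af <- sum(par$Wf[k, ] * x) + sum(par$Rf[k, ] * h) + par$bf[k]
    ao <- sum(par$Wo[k, ] * x) + sum(par$Ro[k, ] * h) + par$bo[k]
    zn[k] <- tanh(az)
    in_[k] <- 1 / (1 + exp(-ai))
    fn[k] <- 1 / (1 + exp(-af))
    on[k] <- 1 / (1 + exp(-ao))
    cn[k] <- fn[k] * c[k] + in_[k] * zn[k]
    hn[k] <- tanh(cn[k]) * on[k]
  }
  list(h = hn, c = cn)
}

# deterministic scalar-cell parameters with every weight set to `w`
const_cell <- function(input, hidden, w = 0) {
  par <- lstm_cell(input, hidden, init = "zero")
  if (w != 0) {
    for (nm in c("Wz", "Wi", "Wf", "Wo", "Rz", "Ri", "Rf", "Ro")) {
      par[[nm]][] <- w
    }
  }
  par
}

# a micro PMM configuration small enough for finite-difference sweeps
micro_config <- function(n_classes = 2) {
  pmm_config(n_classes = n_classes, input_len = 16,
             encoder_channels = 4, kernel = 3, pool = 2,
             hidden = 4, dilations = c(1, 2, 4), heads = 1,
             epochs = 2, batch_size = 4)
}

# central finite-difference gradient of f at x (numeric array)
fd_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- x[j] + eps
    xm <- x; xm[j] <- x[j] - eps
    g[j] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b, floor = 1e-8) {
  max(abs(a - b) / pmax(abs(a), abs(b), floor))
}

# tiny Bonn-style fixture directory: `n` recordings of `len` samples
write_bonn_fixture <- function(dir, n = 2, len = 4097, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  for (i in seq_len(n)) {
    writeLines(format(round(rnorm(len) * 40), scientific = FALSE),
               file.path(dir, sprintf("Z%03d.txt", i)))
  }
  dir
}
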