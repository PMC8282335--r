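test_that("LSTM step matches hand evaluation of the gate equations", {
  h <- 3
  W0 <- matrix(0, 4 * h, 1 + h)
  b0 <- numeric(4 * h)
  # zero parameters, zero cell state: gates 0.5, candidate 0, h = 0
  s <- lstm_step(0, numeric(h), numeric(h), W0, b0)
  expect_equal(s$f, rep(0.5, h))
  expect_equal(s$i, rep(0.5, h))
  expect_equal(s$o, rep(0.5, h))
  expect_equal(s$s, rep(0, h))
  expect_equal(s$h, rep(0, h))
  # zero parameters, C_prev = 2: C = 0.5*2 = 1, h = 0.5*tanh(1)
  s2 <- lstm_step(0, numeric(h), rep(2, h), W0, b0)
  expect_equal(s2$c, rep(1, h))
  expect_equal(s2$h, rep(0.5 * tanh(1), h))
  expect_equal(s2$h[1], 0.3808, tolerance = 1e-4)
  # gate codomain for arbitrary parameters
  set.seed(1)
  W <- matrix(rnorm(4 * h * (1 + h), sd = 2), 4 * h)
  b <- rnorm(4 * h)
  s3 <- lstm_step(1.3, rnorm(h), rnorm(h), W, b)
  for (g in list(s3$f, s3$i, s3$o)) {
    expect_true(all(g > 0 & g < 1))
  }
  expect_true(all(abs(s3$s) < 1))
  expect_error(lstm_step(0, numeric(h), numeric(h), W[, -1], b), "W must")
})

# independent oracle: unrolls the recurrences directly from the update
# equations, sharing no code with lstm_step/lstm_scan
unroll_oracle <- function(x, W1, b1, W2, b2) {
  h <- nrow(W1) / 4
  sg <- function(z) 1 / (1 + exp(-z))
  step <- function(xin, hp, cp, W, b) {
    z <- W %*% c(xin, hp) + b
    f <- sg(z[1:h]); i <- sg(z[h + 1:h]); s <- tanh(z[2 * h + 1:h])
    o <- sg(z[3 * h + 1:h])
    cc <- f * cp + i * s
    list(h = as.numeric(o * tanh(cc)), c = as.numeric(cc))
  }
  h1 <- c1 <- h2 <- c2 <- numeric(h)
  out <- matrix(0, h, length(x))
  for (t in seq_along(x)) {
    r1 <- step(x[t], h1, c1, W1, b1); h1 <- r1$h; c1 <- r1$c
    r2 <- step(h1, h2, c2, W2, b2); h2 <- r2$h; c2 <- r2$c
    out[, t] <- h2
  }
  out
}

test_that("LSTM scan equals the hand-unrolled oracle and reduces to one step", {
  set.seed(42)
  h <- 4
  for (len in c(1, 3, 5)) {
    W1 <- matrix(rnorm(4 * h * (1 + h), sd = 0.5), 4 * h)
    b1 <- rnorm(4 * h, sd = 0.2)
    W2 <- matrix(rnorm(4 * h * 2 * h, sd = 0.5), 4 * h)
    b2 <- rnorm(4 * h, sd = 0.2)
    x <- rnorm(len)
    expect_equal(lstm_scan(x, W1, b1, W2, b2),
                 unroll_oracle(x, W1, b1, W2, b2), tolerance = 1e-12)
  }
  # single-layer scan of one step reproduces lstm_step
  W1 <- matrix(rnorm(4 * h * (1 + h), sd = 0.5), 4 * h)
  b1 <- rnorm(4 * h)
  one <- lstm_scan(0.7, W1, b1)
  expect_equal(as.numeric(one), lstm_step(0.7, numeric(h), numeric(h),
                                          W1, b1)$h, tolerance = 1e-15)
  # zero input, zero parameters: zero hidden sequence
  expect_equal(lstm_scan(numeric(5), matrix(0, 4 * h, 1 + h), numeric(4 * h)),
               matrix(0, h, 5))
})

test_that("fully connected heads follow the layer equations", {
  # identity weights, zero bias, non-negative input: unchanged
  x <- c(2, 1, 0.5)
  expect_equal(fc_forward(x, list(diag(3)), list(numeric(3)), "linear"), x)
  # hand arithmetic: W = [1, -1], b = 0.5, input (2, 1) -> 1.5
  expect_equal(fc_forward(c(2, 1), list(matrix(c(1, -1), 1)), list(0.5),
                          "linear"), 1.5)
  # sigmoid output strictly in (0, 1)
  set.seed(3)
  p <- fc_forward(rnorm(4), list(matrix(rnorm(8), 2), matrix(rnorm(2), 1)),
                  list(rnorm(2), 10), "sigmoid")
  expect_true(p > 0 && p < 1)
  expect_error(fc_forward(1:3, list(diag(2)), list(numeric(2))), "length")
})

test_that("network forward pass is deterministic with dropout off", {
  cfg <- net_config(window = 31, hidden = 6, trans_hidden = 8,
                    class_hidden = 4)
  net <- init_net_params(cfg, seed = 5)
  x <- matrix(rnorm(2 * 31), 2, 31)
  f1 <- net_forward(net, x)
  f2 <- net_forward(net, x)
  expect_identical(f1, f2)
  expect_equal(dim(f1$translated), c(2, 31))
  expect_true(all(f1$prob > 0 & f1$prob < 1))
  # dropout p = 0 with the training flag on is the inference path
  cfg0 <- net_config(window = 31, hidden = 6, trans_hidden = 8,
                     class_hidden = 4, dropout = 0)
  net0 <- init_net_params(cfg0, seed = 5)
  expect_equal(net_forward(net0, x, training = TRUE, seed = 9),
               net_forward(net0, x))
})

test_that("dropout masks drop at the configured rate with inverted scaling", {
  m <- aptranslate:::.dropout_mask_cpp(2000, 500, 0.2, 42)
  rate <- mean(m == 0)
  expect_lt(abs(rate - 0.2), 0.005)          # within 0.5% of 0.2
  expect_equal(unique(m[m != 0]), 1 / 0.8)   # survivors rescaled by 1/(1-p)
  # deterministic given the seed
  expect_identical(m, aptranslate:::.dropout_mask_cpp(2000, 500, 0.2, 42))
})

test_that("parameter serialisation round-trips with shape validation", {
  cfg <- net_config(window = 21, hidden = 4, trans_hidden = 6,
                    class_hidden = 3)
  net <- init_net_params(cfg, seed = 2)
  path <- file.path(tempdir(), "netpars")
  save_net_params(net, path)
  back <- load_net_params(path)
  expect_equal(back$theta, net$theta)
  expect_equal(back$config$hidden, cfg$hidden)
  # block accessor reshapes consistently
  W1 <- net_param_block(net, "W1")
  expect_equal(dim(W1), c(16, 5))
  expect_equal(length(net$theta), n_net_params(cfg))
  expect_error(net_param_block(net, "nope"), "unknown block")
})
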