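test_that("loss components match hand arithmetic", {
  expect_equal(mse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse_loss(c(0, 0), c(1, 1)), 1)
  # homogeneity: scaling both by c multiplies the loss by c^2
  y <- c(0.5, -1, 2); yh <- c(0.2, -0.8, 2.5)
  expect_equal(mse_loss(3 * y, 3 * yh), 9 * mse_loss(y, yh))
  expect_error(mse_loss(1:3, 1:4), "length")

  expect_lt(cross_entropy(1, 1 - 1e-7), 1e-6)
  expect_equal(cross_entropy(1, 0.5), log(2))
  expect_equal(cross_entropy(0, 0.3), cross_entropy(1, 0.7))  # symmetry
  expect_error(cross_entropy(2, 0.5), "labels")

  # total loss: CE + MSE, reduces to each component
  expect_equal(total_loss(y, yh), mse_loss(y, yh))
  expect_equal(total_loss(y, yh, label = 1, prob = 0.5),
               mse_loss(y, yh) + log(2))
  expect_error(total_loss(numeric(0), numeric(0)), "empty")
})

test_that("ADAM matches the closed-form first step and scalar oracle", {
  cfg <- train_config()
  # first step: theta0 = 1, g = 4 -> mhat = 4, vhat = 16,
  # theta1 = 1 - 0.001*4/(4 + 1e-8)
  up <- adam_update(1, 4, adam_init(1), cfg)
  expect_equal(up$theta, 1 - 0.001 * 4 / (4 + 1e-8), tolerance = 1e-12)
  expect_equal(up$theta, 0.999, tolerance = 1e-6)

  # 100-step scalar oracle written independently of the implementation
  set.seed(9)
  g <- rnorm(100)
  th_o <- 0.3; m_o <- 0; v_o <- 0
  st <- adam_init(1); th <- 0.3
  for (t in 1:100) {
    m_o <- 0.1 * g[t] + 0.9 * m_o
    v_o <- 0.001 * g[t]^2 + 0.999 * v_o
    th_o <- th_o - 0.001 * (m_o / (1 - 0.9^t)) /
      (sqrt(v_o / (1 - 0.999^t)) + 1e-8)
    up <- adam_update(th, g[t], st, cfg)
    th <- up$theta; st <- up$state
    expect_equal(th, th_o, tolerance = 1e-12)
  }

  # constant gradient: step magnitude approaches alpha (sign descent)
  st <- adam_init(1); th <- 0
  for (t in 1:500) { up <- adam_update(th, 7, st, cfg); th2 <- up$theta
                     step <- th - th2; th <- th2; st <- up$state }
  expect_equal(step, 0.001, tolerance = 1e-5)

  # zero gradient: nothing moves
  up0 <- adam_update(c(1, 2), c(0, 0), adam_init(2), cfg)
  expect_equal(up0$theta, c(1, 2))
  expect_equal(up0$state$m, c(0, 0))
  expect_error(adam_update(1, NaN, adam_init(1), cfg), "index 1")
})

test_that("compiled in-place ADAM step equals the reference update", {
  cfg <- train_config()
  set.seed(4)
  n <- 57
  theta_ref <- rnorm(n); st <- adam_init(n)
  theta_cpp <- theta_ref + 0
  m <- numeric(n); v <- numeric(n)
  for (t in 1:20) {
    g <- rnorm(n)
    up <- adam_update(theta_ref, g, st, cfg)
    theta_ref <- up$theta; st <- up$state
    aptranslate:::.adam_step_cpp(theta_cpp, g, m, v, t, cfg$alpha,
                                 cfg$beta1, cfg$beta2, cfg$epsilon)
  }
  expect_equal(theta_cpp, theta_ref, tolerance = 1e-14)
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- net_config(window = 9, hidden = 4, trans_hidden = 5,
                    class_hidden = 3)
  net <- init_net_params(cfg, seed = 7)
  set.seed(7)
  theta <- net$theta + rnorm(length(net$theta), sd = 0.05)
  B <- 3
  X <- matrix(rnorm(9 * B), 9, B)
  Y <- matrix(rnorm(9 * B), 9, B)
  lab <- c(0, 1, 1)
  fl <- function(th) aptranslate:::.net_eval_cpp(
    X, th, 9L, 4L, 5L, 3L, 2L, 0, FALSE, 1, Y, lab, FALSE)$loss
  r <- aptranslate:::.net_eval_cpp(X, theta, 9L, 4L, 5L, 3L, 2L, 0, FALSE, 1,
                                   Y, lab, TRUE)
  eps <- 1e-5
  idx <- sample(length(theta), 80)
  for (i in idx) {
    tp <- theta; tp[i] <- tp[i] + eps; fp <- fl(tp)
    tp[i] <- theta[i] - eps; fm <- fl(tp)
    num <- (fp - fm) / (2 * eps)
    denom <- max(1e-6, abs(num) + abs(r$grad[i]))
    expect_lt(abs(num - r$grad[i]) / denom, 1e-4)
  }
})

test_that("a tiny network overfits a 4-sample toy dataset", {
  set.seed(2)
  w <- 21
  input <- matrix(rnorm(4 * w, sd = 0.5), 4, w)
  target <- matrix(rnorm(4 * w, sd = 0.5), 4, w)
  data <- list(input = input, target = target, label = c(0, 1, 0, 1),
               split = list(train = 1:4, validation = integer(0),
                            test = integer(0)))
  cfg <- net_config(window = w, hidden = 8, trans_hidden = 16,
                    class_hidden = 4, dropout = 0)
  fit <- train_network(data, cfg,
                       train_config(epochs = 500, batch_size = 4,
                                    patience = 500, seed = 2))
  final <- net_forward(fit$net, input)
  expect_lt(mse_loss(target, final$translated), 1e-3)
})

test_that("training is reproducible and its loss decreases initially", {
  data <- toy_prepared(n = 16, w = 31, seed = 5)
  cfg <- net_config(window = 31, hidden = 6, trans_hidden = 10,
                    class_hidden = 4)
  tcfg <- train_config(epochs = 12, batch_size = 8, seed = 3)
  f1 <- train_network(data, cfg, tcfg)
  f2 <- train_network(data, cfg, tcfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$theta, f2$net$theta)
  # mean training loss over the first epochs decreases
  h <- f1$history
  tot <- h$train_mse + h$train_ce
  expect_lt(mean(tail(tot, 4)), mean(head(tot, 4)))
  # divergence guard is wired through
  expect_error(train_network(data, cfg,
                             train_config(alpha = 0, epochs = 1)),
               "alpha")
})

test_that("translation-only training ignores labels and uses the MSE alone", {
  data <- toy_prepared(n = 12, w = 21, seed = 8)
  cfg <- build_translation_only_variant(
    net_config(window = 21, hidden = 4, trans_hidden = 8, class_hidden = 4))
  expect_identical(cfg$class_hidden, 0L)
  fit <- train_network(data, cfg, train_config(epochs = 3, batch_size = 8,
                                               seed = 1))
  expect_true(all(is.na(fit$history$train_ce)))
  rep <- suppressWarnings(evaluate_network(fit, data))
  expect_null(rep$auroc)
})
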