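#' Training loss components
#'
#' `mse_loss` is the mean squared difference over the samples of a trace
#' (and over traces when matrices are given).  `cross_entropy` is the
#' binary cross-entropy `-(y log p + (1-y) log(1-p))` with the predicted
#' probability clipped to `[delta, 1-delta]`.  `total_loss` is their
#' unweighted sum, each averaged over the batch -- the joint objective of
#' the multitask network.
#'
#' @param y,yhat true and predicted traces (vectors or matrices of equal
#'   shape).
#' @param label,prob binary labels (0/1) and predicted probabilities.
#' @param delta clipping constant for the probabilities.
#' @return Scalar loss.
#' @export
mse_loss <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("length mismatch: ", length(y), " vs ", length(yhat))
  mean((y - yhat)^2)
}

#' @rdname mse_loss
#' @export
cross_entropy <- function(label, prob, delta = 1e-7) {
  if (!all(label %in% c(0, 1))) stop("labels must be 0 or 1")
  p <- pmin(pmax(prob, delta), 1 - delta)
  mean(-(label * log(p) + (1 - label) * log(1 - p)))
}

#' @rdname mse_loss
#' @export
total_loss <- function(y, yhat, label = NULL, prob = NULL) {
  if (is.null(dim(y)) || nrow(y) == 0) {
    if (length(y) == 0) stop("empty batch")
  }
  j <- mse_loss(y, yhat)
  if (!is.null(label)) {
    if (is.null(prob)) stop("labels given without probabilities")
    j <- j + cross_entropy(label, prob)
  }
  j
}

#' Training hyperparameters
#'
#' Defaults: ADAM with learning rate
#' `alpha = 0.001`, momentum coefficients `beta1 = 0.9`, `beta2 = 0.999`,
#' `epsilon = 1e-8`; mini-batch 64; at most 300 epochs; dropout 0.2.
#' Training stops early when the validation total loss (smoothed over a
#' 3-epoch window to damp cross-entropy fluctuations on nearly separable
#' validation sets) has not improved for `patience` epochs, and the
#' parameters from the best-validation epoch are returned.
#'
#' @param alpha learning rate.
#' @param beta1,beta2 first/second moment coefficients.
#' @param epsilon divide-by-zero guard.
#' @param batch_size mini-batch size.
#' @param epochs hard cap on training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param seed master seed for shuffling and dropout masks.
#' @return A list of class `train_config`.
#' @export
train_config <- function(alpha = 0.001, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, batch_size = 64L, epochs = 300L,
                         patience = 20L, seed = 1L) {
  stopifnot(alpha > 0, beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
            batch_size >= 1, epochs >= 1, patience >= 1)
  structure(list(alpha = alpha, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 seed = seed),
            class = "train_config")
}

#' ADAM optimiser state and update
#'
#' `adam_init` zero-initialises the moment estimates; `adam_update`
#' applies one ADAM step: `m_t = (1-beta1) g + beta1 m_{t-1}`,
#' `v_t = (1-beta2) g^2 + beta2 v_{t-1}`, bias-corrected by
#' `(1 - beta1^t)` and `(1 - beta2^t)`, and
#' `theta' = theta - alpha * m_hat / (sqrt(v_hat) + epsilon)`.
#'
#' @param n number of parameters.
#' @param theta parameter vector.
#' @param grad gradient vector (same length).
#' @param state optimiser state from [adam_init()] (updated and returned).
#' @param config a [train_config()].
#' @return `adam_update` returns `list(theta = updated parameters,
#'   state = updated state)`.
#' @export
adam_init <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L)
}

#' @rdname adam_init
#' @export
adam_update <- function(theta, grad, state, config) {
  if (length(grad) != length(theta))
    stop("gradient length does not match parameters")
  if (any(!is.finite(grad))) {
    bad <- which(!is.finite(grad))[1]
    stop("non-finite gradient at parameter index ", bad)
  }
  t <- state$t + 1L
  m <- (1 - config$beta1) * grad + config$beta1 * state$m
  v <- (1 - config$beta2) * grad^2 + config$beta2 * state$v
  mhat <- m / (1 - config$beta1^t)
  vhat <- v / (1 - config$beta2^t)
  list(theta = theta - config$alpha * mhat / (sqrt(vhat) + config$epsilon),
       state = list(m = m, v = v, t = t))
}

#' Train the multitask network
#'
#' Mini-batch training of the joint loss (batch-mean cross-entropy plus
#' batch-mean translation MSE) with ADAM, dropout and validation-based
#' early stopping.  Gradients come from the compiled reverse-mode
#' (backprop-through-time) implementation.  The returned parameters are
#' those of the best-validation epoch; `history` records per-epoch train
#' and validation MSE, cross-entropy and classification accuracy.
#'
#' @param data a [prepare_dataset()] result (or any list with normalized
#'   `input`, `target` matrices, `label` vector and `split`).
#' @param net_cfg a [net_config()].
#' @param config a [train_config()].
#' @param init optional initial `net_params` (defaults to
#'   [init_net_params()] seeded from `config$seed`).
#' @param verbose print per-epoch progress.
#' @return A list of class `trained_net`: `net` (best `net_params`),
#'   `history` (data.frame), `best_epoch`, `epochs_run`.
#' @export
train_network <- function(data, net_cfg = net_config(),
                          config = train_config(), init = NULL,
                          verbose = FALSE) {
  stopifnot(!is.null(data$input), !is.null(data$target), !is.null(data$split))
  cfg <- net_cfg
  has_class <- cfg$class_hidden > 0
  X <- t(data$input)    # window x n
  Y <- t(data$target)
  lab <- data$label
  tr <- data$split$train
  va <- data$split$validation
  if (!length(tr)) stop("empty training split")

  net <- if (is.null(init)) init_net_params(cfg, seed = config$seed) else init
  theta <- net$theta
  if (length(theta) != n_net_params(cfg))
    stop("initial parameters do not match the network configuration")
  state <- adam_init(length(theta))

  rs <- local_rng(config$seed)
  on.exit(restore_rng(rs))

  eval_set <- function(idx, th) {
    r <- .net_eval_cpp(X[, idx, drop = FALSE], th, cfg$window, cfg$hidden,
                       cfg$trans_hidden, cfg$class_hidden, cfg$layers,
                       0, FALSE, 0,
                       Y[, idx, drop = FALSE],
                       if (has_class) lab[idx] else NULL, FALSE)
    acc <- if (has_class)
      mean((as.numeric(r$prob) >= 0.5) == (lab[idx] == 1)) else NA_real_
    c(mse = r$mse, ce = if (has_class) r$ce else NA_real_, acc = acc)
  }

  hist <- vector("list", config$epochs)
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  wait <- 0L
  epoch <- 0L
  val_hist <- numeric(0)
  theta <- theta + 0       # private copies: the compiled ADAM step
  m <- numeric(length(theta))  # updates these buffers in place
  v <- numeric(length(theta))
  tstep <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- tr[sample.int(length(tr))]
    nb <- ceiling(length(ord) / config$batch_size)
    bsum <- c(mse = 0, ce = 0, acc = 0)
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * config$batch_size + 1):
                   min(b * config$batch_size, length(ord))]
      drop_seed <- as.numeric(config$seed) * 1e6 + epoch * 1e3 + b
      r <- .net_eval_cpp(X[, idx, drop = FALSE], theta, cfg$window,
                         cfg$hidden, cfg$trans_hidden, cfg$class_hidden,
                         cfg$layers, cfg$dropout, TRUE, drop_seed,
                         Y[, idx, drop = FALSE],
                         if (has_class) lab[idx] else NULL, TRUE)
      if (!is.finite(r$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      tstep <- tstep + 1L
      .adam_step_cpp(theta, r$grad, m, v, tstep, config$alpha,
                     config$beta1, config$beta2, config$epsilon)
      bsum <- bsum + c(r$mse,
                       if (has_class) r$ce else NA_real_,
                       if (has_class)
                         mean((as.numeric(r$prob) >= 0.5) == (lab[idx] == 1))
                       else NA_real_)
    }
    # train-side metrics: batch averages from the pass just made
    mtr <- bsum / nb
    names(mtr) <- c("mse", "ce", "acc")
    mva <- if (length(va)) eval_set(va, theta) else mtr
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_mse = mtr[["mse"]], val_mse = mva[["mse"]],
                                train_ce = mtr[["ce"]], val_ce = mva[["ce"]],
                                train_acc = mtr[["acc"]], val_acc = mva[["acc"]])
    val_total <- mva[["mse"]] + if (has_class) mva[["ce"]] else 0
    # smooth the stopping/selection signal over 3 epochs: the cross-entropy
    # term fluctuates on nearly separable validation sets and a raw minimum
    # can be a single-epoch fluke
    val_hist <- c(val_hist, val_total)
    val_smooth <- mean(tail(val_hist, 3))
    if (verbose)
      message(sprintf("epoch %3d  train mse %.5f  val mse %.5f  val loss %.5f",
                      epoch, mtr[["mse"]], mva[["mse"]], val_total))
    if (val_smooth < best$loss - 1e-12) {
      best <- list(loss = val_smooth, theta = theta + 0, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  net$theta <- best$theta
  structure(list(net = net,
                 history = do.call(rbind, hist[!vapply(hist, is.null, TRUE)]),
                 best_epoch = best$epoch,
                 epochs_run = epoch,
                 train_config = config),
            class = "trained_net")
}

#' @export
print.trained_net <- function(x, ...) {
  h <- x$history
  cat(sprintf("<trained_net> %d epoch(s), best validation epoch %d\n",
              x$epochs_run, x$best_epoch))
  if (nrow(h)) {
    i <- which(h$epoch == x$best_epoch)
    cat(sprintf("  best val mse %.5f%s\n", h$val_mse[i],
                if (!is.na(h$val_ce[i]))
                  sprintf(", val ce %.5f, val acc %.3f", h$val_ce[i],
                          h$val_acc[i]) else ""))
  }
  invisible(x)
}
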