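#' Multitask network architecture configuration
#'
#' Two stacked LSTM layers scan the 701-sample normalized input; the full
#' flattened hidden sequence of the top layer feeds two fully connected
#' heads -- a translation head (one ReLU hidden layer, then a linear
#' 701-sample output) and a classification head (one ReLU hidden layer,
#' then a sigmoid probability).  Hidden sizes are tunable; `layers = 1`
#' builds the reduced-encoder ablation variant and `class_hidden = 0`
#' removes the classification head (translation-only variant).
#'
#' @param window input/output sequence length (samples).
#' @param hidden LSTM hidden units per layer.
#' @param trans_hidden units in the translation head's hidden layer.
#' @param class_hidden units in the classification head's hidden layer
#'   (0 = no classification head).
#' @param layers number of stacked LSTM layers (1 or 2).
#' @param dropout dropout probability applied (at train time) to LSTM
#'   outputs and FC hidden activations, with inverted scaling.
#' @return A list of class `net_config`.
#' @export
net_config <- function(window = 701L, hidden = 32L, trans_hidden = 128L,
                       class_hidden = 32L, layers = 2L, dropout = 0.2) {
  stopifnot(window >= 1, hidden >= 1, trans_hidden >= 1, class_hidden >= 0,
            layers %in% c(1L, 2L), dropout >= 0, dropout < 1)
  structure(list(window = as.integer(window), hidden = as.integer(hidden),
                 trans_hidden = as.integer(trans_hidden),
                 class_hidden = as.integer(class_hidden),
                 layers = as.integer(layers), dropout = dropout),
            class = "net_config")
}

#' Number of free parameters of a network configuration
#' @param config a [net_config()].
#' @return Integer parameter count.
#' @export
n_net_params <- function(config) {
  w <- config$window; h <- config$hidden
  n <- 4 * h * (1 + h) + 4 * h
  if (config$layers == 2) n <- n + 4 * h * (2 * h) + 4 * h
  n <- n + config$trans_hidden * (w * h) + config$trans_hidden +
    w * config$trans_hidden + w
  if (config$class_hidden > 0)
    n <- n + config$class_hidden * (w * h) + config$class_hidden +
      config$class_hidden + 1
  as.integer(n)
}

#' Initialise network parameters
#'
#' Weights are drawn uniformly in `[-r, r]` with `r = sqrt(6/(fan_in +
#' fan_out))` per block (Glorot scaling); biases start at zero.
#'
#' @param config a [net_config()].
#' @param seed RNG seed.
#' @return An object of class `net_params`: list with the flat parameter
#'   vector `theta` and the `config`.
#' @export
init_net_params <- function(config, seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  w <- config$window; h <- config$hidden
  th <- config$trans_hidden; ch <- config$class_hidden
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  blocks <- list(c(4 * h, 1 + h), c(4 * h, 0))
  if (config$layers == 2) blocks <- c(blocks, list(c(4 * h, 2 * h), c(4 * h, 0)))
  blocks <- c(blocks, list(c(th, w * h), c(th, 0), c(w, th), c(w, 0)))
  if (ch > 0) blocks <- c(blocks, list(c(ch, w * h), c(ch, 0), c(1, ch), c(1, 0)))
  theta <- unlist(lapply(blocks, function(b) {
    if (b[2] == 0) return(numeric(b[1]))               # bias
    r <- sqrt(6 / (b[1] + b[2]))
    runif(b[1] * b[2], -r, r)
  }))
  structure(list(theta = theta, config = config, seed = seed),
            class = "net_params")
}

#' @export
print.net_params <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<net_params> %d LSTM layer(s) x %d units, heads %d/%s, window %d (%s parameters)\n",
    cfg$layers, cfg$hidden, cfg$trans_hidden,
    if (cfg$class_hidden > 0) as.character(cfg$class_hidden) else "none",
    cfg$window, format(length(x$theta), big.mark = ",")))
  invisible(x)
}

#' One LSTM cell step (reference implementation)
#'
#' Pure-R evaluation of the gate equations: forget gate
#' `F = sigma(w_f [x; h] + b_f)`, input gate `I = sigma(w_i [x; h] + b_i)`,
#' candidate `S = tanh(w_s [x; h] + b_s)`, cell state
#' `C = F * C_prev + I * S`, output gate `O = sigma(w_o [x; h] + b_o)` and
#' hidden state `h = O * tanh(C)`.  The compiled training path implements
#' the identical arithmetic; this function is the inspectable reference.
#'
#' @param x input at this time step (length `in_dim`).
#' @param h_prev,c_prev previous hidden and cell state (length `hidden`).
#' @param W weight matrix `4*hidden x (in_dim + hidden)`, rows grouped as
#'   forget, input, candidate, output gates.
#' @param b bias vector of length `4*hidden`, grouped the same way.
#' @return List with `h`, `c` and the gate activations `f`, `i`, `s`, `o`.
#' @export
lstm_step <- function(x, h_prev, c_prev, W, b) {
  hn <- length(h_prev)
  if (length(c_prev) != hn) stop("h_prev and c_prev lengths differ")
  if (!is.matrix(W) || nrow(W) != 4 * hn ||
      ncol(W) != length(x) + hn)
    stop("W must be (4*hidden) x (in_dim + hidden)")
  if (length(b) != 4 * hn) stop("b must have length 4*hidden")
  z <- as.numeric(W %*% c(x, h_prev)) + b
  sigm <- function(u) 1 / (1 + exp(-u))
  f <- sigm(z[seq_len(hn)])
  i <- sigm(z[hn + seq_len(hn)])
  s <- tanh(z[2 * hn + seq_len(hn)])
  o <- sigm(z[3 * hn + seq_len(hn)])
  cc <- f * c_prev + i * s
  list(h = o * tanh(cc), c = cc, f = f, i = i, s = s, o = o)
}

#' Scan a sequence through (stacked) LSTM layers (reference implementation)
#'
#' Runs the input sequence through one or two stacked LSTM layers with
#' zero-initialised states and returns the top layer's hidden-state
#' sequence -- the features consumed by the fully connected heads.
#'
#' @param x numeric input sequence (scalars per step).
#' @param W1,b1 layer-1 parameters (see [lstm_step()]; `in_dim = 1`).
#' @param W2,b2 optional layer-2 parameters (`in_dim = hidden`).
#' @return Matrix `hidden x length(x)` of top-layer hidden states.
#' @export
lstm_scan <- function(x, W1, b1, W2 = NULL, b2 = NULL) {
  hn <- nrow(W1) / 4
  h1 <- numeric(hn); c1 <- numeric(hn)
  two <- !is.null(W2)
  if (two) { h2 <- numeric(hn); c2 <- numeric(hn) }
  out <- matrix(NA_real_, hn, length(x))
  for (t in seq_along(x)) {
    s1 <- lstm_step(x[t], h1, c1, W1, b1)
    h1 <- s1$h; c1 <- s1$c
    if (two) {
      s2 <- lstm_step(h1, h2, c2, W2, b2)
      h2 <- s2$h; c2 <- s2$c
      out[, t] <- h2
    } else out[, t] <- h1
  }
  out
}

#' Fully connected head forward pass (reference implementation)
#'
#' Applies `a_k = f(W_k a_{k-1} + b_k)` layer by layer.  Hidden layers use
#' ReLU; the final activation is `"linear"` (translation head) or
#' `"sigmoid"` (classification head).
#'
#' @param a0 input feature vector.
#' @param weights list of weight matrices.
#' @param biases list of bias vectors.
#' @param output one of `"linear"`, `"sigmoid"`.
#' @return Output vector (probability in (0,1) for `"sigmoid"`).
#' @export
fc_forward <- function(a0, weights, biases, output = c("linear", "sigmoid")) {
  output <- match.arg(output)
  a <- as.numeric(a0)
  nl <- length(weights)
  for (k in seq_len(nl)) {
    W <- weights[[k]]
    if (ncol(W) != length(a))
      stop("layer ", k, ": weight matrix expects input of length ", ncol(W),
           ", got ", length(a))
    z <- as.numeric(W %*% a) + biases[[k]]
    a <- if (k < nl) pmax(z, 0)
         else switch(output, linear = z, sigmoid = 1 / (1 + exp(-z)))
  }
  a
}

#' Forward pass of the multitask network
#'
#' Runs normalized input traces through the network.  With
#' `training = FALSE` dropout is disabled and the output is a deterministic
#' function of the input and parameters; with `training = TRUE` units are
#' dropped with the configured probability and survivors rescaled by
#' `1/(1-p)` (inverted dropout), so evaluation needs no rescaling.
#'
#' @param net a `net_params` object.
#' @param x normalized input: vector of length `window` or matrix
#'   (samples x window).
#' @param training logical; enables dropout.
#' @param seed dropout mask seed (ignored when `training = FALSE`).
#' @return List with `translated` (matrix samples x window) and `prob`
#'   (numeric vector; `NULL` for a translation-only network).
#' @export
net_forward <- function(net, x, training = FALSE, seed = 1L) {
  stopifnot(inherits(net, "net_params"))
  cfg <- net$config
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != cfg$window)
    stop("input has ", ncol(x), " samples per trace; network window is ",
         cfg$window)
  r <- .net_eval_cpp(t(x), net$theta, cfg$window, cfg$hidden,
                     cfg$trans_hidden, cfg$class_hidden, cfg$layers,
                     cfg$dropout, isTRUE(training), as.numeric(seed))
  list(translated = t(r$yhat),
       prob = if (!is.null(r$prob)) as.numeric(r$prob) else NULL)
}

# parameter-vector layout bookkeeping shared with the C++ core
net_param_shapes <- function(config) {
  w <- config$window; h <- config$hidden
  th <- config$trans_hidden; ch <- config$class_hidden
  shapes <- list(W1 = c(4 * h, 1 + h), b1 = c(4 * h, 1))
  if (config$layers == 2) shapes <- c(shapes, list(W2 = c(4 * h, 2 * h),
                                                   b2 = c(4 * h, 1)))
  shapes <- c(shapes, list(Wt1 = c(th, w * h), bt1 = c(th, 1),
                           Wt2 = c(w, th), bt2 = c(w, 1)))
  if (ch > 0) shapes <- c(shapes, list(Wc1 = c(ch, w * h), bc1 = c(ch, 1),
                                       Wc2 = c(1, ch), bc2 = c(1, 1)))
  shapes
}

#' Extract one named parameter block from a network
#'
#' @param net a `net_params` object.
#' @param name block name (`"W1"`, `"b1"`, `"W2"`, `"b2"`, `"Wt1"`, ...).
#' @return The block as a matrix (weights) or vector (biases).
#' @export
net_param_block <- function(net, name) {
  shapes <- net_param_shapes(net$config)
  if (!name %in% names(shapes))
    stop("unknown block '", name, "'; available: ",
         paste(names(shapes), collapse = ", "))
  off <- 0
  for (nm in names(shapes)) {
    sz <- prod(shapes[[nm]])
    if (nm == name) {
      block <- net$theta[(off + 1):(off + sz)]
      s <- shapes[[nm]]
      return(if (s[2] == 1) block else matrix(block, s[1], s[2]))
    }
    off <- off + sz
  }
}

#' Save / load network parameters
#'
#' Parameters are written as a portable two-file pair: a JSON manifest of
#' the architecture (shapes validated on load) and a plain-text vector of
#' parameter values.
#'
#' @param net a `net_params` object.
#' @param path base path (without extension); writes `path.json` and
#'   `path.theta.gz`.
#' @return `save_net_params` returns `path` invisibly; `load_net_params`
#'   the restored `net_params`.
#' @export
save_net_params <- function(net, path) {
  stopifnot(inherits(net, "net_params"))
  cfg <- net$config
  jsonlite::write_json(list(config = unclass(cfg),
                            n_params = length(net$theta)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- gzfile(paste0(path, ".theta.gz"), "wb")
  on.exit(close(con))
  writeBin(net$theta, con)
  invisible(path)
}

#' @rdname save_net_params
#' @export
load_net_params <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(net_config, meta$config[c("window", "hidden", "trans_hidden",
                                           "class_hidden", "layers", "dropout")])
  con <- gzfile(paste0(path, ".theta.gz"), "rb")
  on.exit(close(con))
  theta <- readBin(con, "double", n = meta$n_params + 1)
  if (length(theta) != meta$n_params || length(theta) != n_net_params(cfg))
    stop("parameter file does not match its manifest (",
         length(theta), " values, expected ", n_net_params(cfg), ")")
  structure(list(theta = theta, config = cfg), class = "net_params")
}
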