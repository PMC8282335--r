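#' Time-window grid for feature ablation
#'
#' Non-overlapping 100-ms windows covering the input sequence, the final
#' window absorbing the remainder (0--100, 100--200, ..., 600--701 ms for
#' the default 701-sample window).
#'
#' @param window sequence length, samples.
#' @param width window width, ms.
#' @return List of `c(from, to)` bounds in ms (half-open, 0-based).
#' @export
ablation_windows <- function(window = 701L, width = 100L) {
  starts <- seq(0L, window - width, by = width)
  out <- lapply(starts, function(s) c(s, s + width))
  out[[length(out)]][2] <- window   # final window absorbs the remainder
  out
}

# zero the columns of normalized input matrix inside [from, to) ms
zero_window <- function(x, win) {
  if (win[2] <= win[1]) stop("empty ablation window")
  cols <- (win[1] + 1):win[2]
  x[, cols] <- 0
  x
}

#' Feature ablation: retrain with one input time window zeroed
#'
#' Sets the normalized input values inside `window` to zero (the
#' population mean, since traces are centered) for the training,
#' validation and test inputs, retrains the network from scratch with the
#' same seeds and configuration, and evaluates on the ablated test set.
#' Comparing the resulting AUROC and MSE against the intact network
#' localises the AP phase the network relies on.
#'
#' @param data a [prepare_dataset()] result.
#' @param window `c(from, to)` bounds in ms.
#' @param net_cfg,config network and training configuration (identical to
#'   the intact run's).
#' @param reference optional intact `eval_report` for the same data.
#' @return An object of class `ablation_result`: list with `variant`,
#'   `window`, `report`, `reference`.
#' @export
feature_ablation <- function(data, window, net_cfg = net_config(),
                             config = train_config(), reference = NULL) {
  if (window[2] <= window[1]) stop("empty ablation window")
  if (window[1] < 0 || window[2] > ncol(data$input))
    stop("window bounds must lie within [0, ", ncol(data$input), "]")
  abl <- data
  abl$input <- zero_window(data$input, window)
  fit <- train_network(abl, net_cfg, config)
  rep <- evaluate_network(fit, abl)
  structure(list(variant = sprintf("window_%d_%d", window[1], window[2]),
                 window = window, report = rep, reference = reference),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result>", x$variant, "\n")
  print(x$report)
  if (!is.null(x$reference)) {
    cat("  reference (intact):\n")
    print(x$reference)
  }
  invisible(x)
}

#' Model-ablation variants
#'
#' `build_no_second_lstm_variant` reduces the encoder to a single LSTM
#' layer feeding the same heads; `build_translation_only_variant` removes
#' the classification head, so the loss reduces to the translation MSE
#' alone.  Both keep every other architectural choice fixed and have
#' strictly fewer parameters than the intact network.
#'
#' @param net_cfg the intact [net_config()].
#' @return A modified `net_config`.
#' @export
build_no_second_lstm_variant <- function(net_cfg = net_config()) {
  net_cfg$layers <- 1L
  net_cfg
}

#' @rdname build_no_second_lstm_variant
#' @export
build_translation_only_variant <- function(net_cfg = net_config()) {
  net_cfg$class_hidden <- 0L
  net_cfg
}

#' Locate the high-membrane-resistance window of the immature AP
#'
#' Computes the membrane-resistance series dV/dI of a noise-free baseline
#' immature action potential and returns the ablation window containing
#' the maximum |dV/dI| in the phase that immediately precedes the rapid
#' final repolarisation (the 100 ms before the steepest repolarisation
#' sample) -- the late plateau where inward and outward currents balance,
#' the net current becomes momentarily stationary (dI -> 0,
#' dV/dI -> infinity) and the collapse of the dome follows.  The upstroke
#' (a regenerative zero-crossing of the total current), the slow
#' mid-plateau and the diastolic interval are excluded deliberately.
#'
#' @param trace an `ap_trace` carrying voltage and total current (by
#'   default a freshly simulated noise-free baseline immature AP), or any
#'   list with `voltage` and `current`.
#' @param windows windows from [ablation_windows()].
#' @param cap,tol see [membrane_resistance_series()].
#' @param seed seed for the default baseline simulation.
#' @return Index into `windows` of the high-resistance window, with the
#'   time (ms) of the in-AP resistance maximum as attribute `peak_time`
#'   and the |resistance| series as attribute `resistance`.
#' @export
high_resistance_window <- function(trace = NULL,
                                   windows = ablation_windows(),
                                   cap = 1e4, tol = 1e-6, seed = 1L) {
  if (is.null(trace))
    trace <- simulate_ap(immature_params(),
                         pacing_protocol(spontaneous = TRUE,
                                         conditioning_beats = 5,
                                         noisy_beats = 1),
                         noise = noise_spec(xi = 0), seed = seed)
  r <- abs(membrane_resistance_series(trace$voltage, trace$current,
                                      cap = cap, tol = tol)$resistance)
  apd <- apd90(trace$voltage)
  # the phase of interest is where the inward and outward currents balance
  # (dI -> 0, dV/dI -> infinity) *immediately before* the rapid final
  # repolarisation.  Locate the steepest repolarisation sample and search
  # the preceding 100 ms; this excludes both the upstroke (a regenerative
  # zero-crossing of the total current) and the slow mid-plateau.
  v <- trace$voltage
  v_peak <- which.max(v)
  dvdt <- diff(v)
  t_collapse <- v_peak + which.min(dvdt[v_peak:min(length(dvdt), ceiling(apd))])
  in_ap <- seq(max(v_peak + 10, t_collapse - 100), t_collapse)
  peak <- in_ap[which.max(r[in_ap])]
  t_peak <- peak - 1  # sample index to ms on the 1-ms grid
  hit <- which(vapply(windows, function(w) t_peak >= w[1] && t_peak < w[2],
                      logical(1)))[1]
  structure(hit, peak_time = t_peak, resistance = r)
}

#' Run the full ablation study
#'
#' Trains the intact network, all feature-ablation windows, the
#' single-LSTM variant and the translation-only variant with one shared
#' data/seed/configuration setting (strict one-factor change per run), and
#' tabulates AUROC and MSE deltas against the intact network.
#'
#' @param data a [prepare_dataset()] result.
#' @param net_cfg,config intact configuration.
#' @param windows feature-ablation windows.
#' @param verbose print progress.
#' @return A list of class `ablation_study`: `intact` (trained net +
#'   report), `features` (list of `ablation_result`), `no_second_lstm`,
#'   `translation_only` (reports), and `summary` (data.frame).
#' @export
run_ablation_study <- function(data, net_cfg = net_config(),
                               config = train_config(),
                               windows = ablation_windows(ncol(data$input)),
                               verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("training intact network")
  intact_fit <- train_network(data, net_cfg, config)
  intact_rep <- evaluate_network(intact_fit, data)

  feats <- lapply(windows, function(w) {
    say(sprintf("feature ablation %d-%d ms", w[1], w[2]))
    feature_ablation(data, w, net_cfg, config, reference = intact_rep)
  })

  say("single-LSTM variant")
  fit1 <- train_network(data, build_no_second_lstm_variant(net_cfg), config)
  rep1 <- evaluate_network(fit1, data)
  say("translation-only variant")
  fit2 <- train_network(data, build_translation_only_variant(net_cfg), config)
  rep2 <- evaluate_network(fit2, data)

  rows <- lapply(feats, function(f)
    data.frame(variant = f$variant,
               auroc = f$report$auroc %||% NA_real_,
               mse = f$report$mse,
               d_auroc = (f$report$auroc %||% NA_real_) - intact_rep$auroc,
               d_mse = f$report$mse - intact_rep$mse))
  summary <- rbind(
    data.frame(variant = "intact", auroc = intact_rep$auroc,
               mse = intact_rep$mse, d_auroc = 0, d_mse = 0),
    do.call(rbind, rows),
    data.frame(variant = "no_second_lstm", auroc = rep1$auroc %||% NA_real_,
               mse = rep1$mse,
               d_auroc = (rep1$auroc %||% NA_real_) - intact_rep$auroc,
               d_mse = rep1$mse - intact_rep$mse),
    data.frame(variant = "translation_only", auroc = NA_real_,
               mse = rep2$mse, d_auroc = NA_real_,
               d_mse = rep2$mse - intact_rep$mse))

  structure(list(intact = list(fit = intact_fit, report = intact_rep),
                 features = feats,
                 no_second_lstm = rep1,
                 translation_only = rep2,
                 summary = summary),
            class = "ablation_study")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ablation_study <- function(x, ...) {
  cat("<ablation_study>\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
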