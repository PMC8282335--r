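#' Zero-phase low-pass filtering of action-potential traces
#'
#' Applies a low-pass Butterworth filter forward and then backward
#' (`signal::filtfilt`), so the net phase shift is zero and action-potential
#' timing (APD90 in particular) is preserved while the vertical noise is
#' removed.  Default: 4th-order, 100 Hz cutoff at 1 kHz sampling.
#'
#' @param x numeric vector, or matrix with one trace per row.
#' @param cutoff_hz filter cutoff, Hz; must be below the Nyquist frequency.
#' @param order filter order.
#' @param fs sampling rate, Hz (1 kHz for the 1-ms grid).
#' @return Filtered trace(s), same shape as the input.
#' @export
zero_phase_filter <- function(x, cutoff_hz = 100, order = 4, fs = 1000) {
  if (cutoff_hz >= fs / 2)
    stop("cutoff (", cutoff_hz, " Hz) must be below the Nyquist frequency (",
         fs / 2, " Hz)")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  filt1 <- function(v) {
    n <- length(v)
    npad <- min(n - 1, 100)
    if (n < 20) stop("trace too short to filter (", n, " samples)")
    # the forward/backward passes start from zero state, so bring both
    # edges to zero (linear detrend) and extend by odd reflection; the
    # transients then die out inside the discarded padding
    ramp <- v[1] + (v[n] - v[1]) * (seq_len(n) - 1) / (n - 1)
    u <- v - ramp
    ext <- c(2 * u[1] - u[(npad + 1):2], u, 2 * u[n] - u[(n - 1):(n - npad)])
    signal::filtfilt(bf, ext)[(npad + 1):(npad + n)] + ramp
  }
  if (is.matrix(x)) t(apply(x, 1, filt1)) else filt1(x)
}

#' Normalisation statistics from training traces
#'
#' Computes the per-population centering and scaling used before the
#' network: the mean voltage over all training traces of one cell type, and
#' the maximum absolute centered value (so normalized training traces lie in
#' `[-1, 1]`).  Statistics must be fitted on training traces only and are
#' reused for validation, test and any translated output.
#'
#' @param x matrix of training traces (rows) in mV, or a numeric vector.
#' @param cell_type `"immature"` or `"adult"` -- recorded so a stats object
#'   cannot silently be applied to the wrong population.
#' @param filter_settings optional list recording how the traces were
#'   filtered (stored for the manifest).
#' @return An object of class `norm_stats` with elements `mean`, `scale`,
#'   `cell_type`, `filter_settings`.
#' @export
fit_norm_stats <- function(x, cell_type, filter_settings = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (!nrow(x)) stop("need at least one trace")
  mu <- mean(x)
  sc <- max(abs(x - mu))
  if (sc == 0) stop("scale undefined: all centered values are zero")
  structure(list(mean = mu, scale = sc, cell_type = cell_type,
                 filter_settings = filter_settings),
            class = "norm_stats")
}

#' @export
print.norm_stats <- function(x, ...) {
  cat(sprintf("<norm_stats> %s: mean %.3f mV, scale %.3f mV\n",
              x$cell_type, x$mean, x$scale))
  invisible(x)
}

#' Normalise / denormalise traces
#'
#' `normalize_traces` maps mV to the unitless network scale,
#' `(V - mean)/scale`; `denormalize_traces` inverts it exactly.  Traces
#' from the fitted training set lie in `[-1, 1]`; held-out traces may
#' exceed that range.
#'
#' @param x vector or matrix of traces.
#' @param stats a [fit_norm_stats()] object.
#' @param cell_type optional; when given it is checked against the stats
#'   object's tag.
#' @return Transformed traces, same shape.
#' @export
normalize_traces <- function(x, stats, cell_type = NULL) {
  check_stats(stats, cell_type)
  (x - stats$mean) / stats$scale
}

#' @rdname normalize_traces
#' @export
denormalize_traces <- function(x, stats, cell_type = NULL) {
  check_stats(stats, cell_type)
  x * stats$scale + stats$mean
}

check_stats <- function(stats, cell_type) {
  if (!inherits(stats, "norm_stats")) stop("stats must be a norm_stats object")
  if (!is.null(cell_type) && !identical(cell_type, stats$cell_type))
    stop("normalisation stats are for cell type '", stats$cell_type,
         "', not '", cell_type, "'")
  invisible(TRUE)
}

#' Action-potential morphology features
#'
#' Extracts the standard morphology markers from one trace: maximum
#' diastolic potential (MDP, the minimum voltage before the upstroke),
#' maximum upstroke velocity (`v_max`, the peak of dV/dt), peak voltage,
#' and APD90 -- the time from the maximum-dV/dt sample to the first
#' downward crossing of `peak - 0.9 * (peak - MDP)`, with linear
#' interpolation between samples.
#'
#' @param trace an `ap_trace` or numeric voltage vector (mV).
#' @param dt sampling step, ms.
#' @return Named numeric vector: `apd90` (ms), `v_max` (mV/ms), `mdp`
#'   (mV), `peak` (mV).
#' @examples
#' v <- c(rep(-80, 10), rep(20, 300), rep(-80, 100))
#' morphology_features(v)[["apd90"]]  # 300
#' @export
morphology_features <- function(trace, dt = 1) {
  v <- if (inherits(trace, "ap_trace")) { dt <- trace$dt; trace$voltage }
       else as.numeric(trace)
  if (length(v) < 5) stop("trace too short")
  dvdt <- diff(v) / dt
  iup <- which.max(dvdt)              # max-slope interval
  if (dvdt[iup] <= 0) stop("no upstroke found (flat or decaying trace)")
  mdp <- min(v)                       # diastolic reference
  peak <- max(v[iup:length(v)])
  if (peak <= mdp) stop("degenerate trace: no excursion above diastolic level")
  lev <- peak - 0.9 * (peak - mdp)
  post <- v[(iup + 1):length(v)]      # anchored at the upstroke sample
  below <- which(post < lev)
  below <- below[below > which.max(post)[1]]  # after the peak
  if (!length(below))
    stop("incomplete repolarisation: trace never crosses the APD90 level")
  j <- below[1]
  # linear interpolation between samples j-1 and j (post indices)
  v1 <- post[j - 1]; v2 <- post[j]
  frac <- if (v1 == v2) 0 else (v1 - lev) / (v1 - v2)
  apd <- (j - 2 + frac) * dt  # time from the upstroke sample to the crossing
  c(apd90 = apd, v_max = max(dvdt), mdp = mdp, peak = peak)
}

#' @rdname morphology_features
#' @export
apd90 <- function(trace, dt = 1) morphology_features(trace, dt)[["apd90"]]
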