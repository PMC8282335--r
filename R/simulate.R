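#' Simulate one action-potential trace
#'
#' Integrates the reduced ionic model (Forward Euler, internal step
#' `dt_internal` <= 0.01 ms, output resampled to 1 ms), applies the
#' stochastic noise current during the final `noisy_beats` beats, and
#' records the final beat: a 701-sample window starting 5 ms before the
#' last upstroke (maximum-dV/dt marker).  Deterministic given `seed`.
#'
#' @param params an [immature_params()] or [adult_params()] set.
#' @param protocol a [pacing_protocol()]; immature cells use
#'   `spontaneous = TRUE`.
#' @param drug a [drug_spec()].
#' @param noise a [noise_spec()]; its `seed` is combined with `seed`.
#' @param seed integer seed for the noise stream (overrides `noise$seed`
#'   when given).
#' @param dt_internal internal integration step, ms (must be <= 0.01).
#' @param window samples in the recorded window (default 701 at 1 ms).
#' @param keep_full if `TRUE`, the full voltage/current time courses are
#'   retained in the result (`$full`).
#' @return An object of class `ap_trace`: list with `voltage` (mV,
#'   `window` samples at 1 ms), `current` (total ionic current over the
#'   same window, uA/uF), `dt` (1), `phenotype`, `condition`,
#'   `block_fraction`, `cycle_length` (ms, interval between the last two
#'   upstrokes), `seed`, and optionally `full`.
#' @examples
#' \donttest{
#' tr <- simulate_ap(adult_params(), pacing_protocol(conditioning_beats = 2,
#'                   noisy_beats = 1), noise = noise_spec(xi = 0))
#' range(tr$voltage)
#' }
#' @export
simulate_ap <- function(params,
                        protocol = pacing_protocol(),
                        drug = drug_spec("none"),
                        noise = noise_spec(),
                        seed = NULL,
                        dt_internal = 0.01,
                        window = 701L,
                        keep_full = FALSE) {
  stopifnot(inherits(params, "ionic_params"),
            inherits(protocol, "pacing_protocol"),
            inherits(drug, "drug_spec"),
            inherits(noise, "noise_spec"))
  if (is.null(seed)) seed <- noise$seed
  gkr_scale <- 1
  drug_mode <- 0L
  if (drug$mode == "simple_block") gkr_scale <- 1 - drug$block_fraction
  if (drug$mode == "state_dependent") drug_mode <- 1L

  res <- .simulate_ap_cpp(
    stats::setNames(as.numeric(params), names(params)),
    gkr_scale, drug_mode, drug$concentration, drug$k_on, drug$k_off,
    protocol$spontaneous, protocol$stim_amplitude, protocol$stim_duration,
    protocol$cycle_length, protocol$conditioning_beats, protocol$noisy_beats,
    noise$xi, dt_internal, noise$dt, params[["v_init"]], as.numeric(seed),
    tail_ms = window + 15)

  v <- res$voltage
  ups <- res$upstroke_times
  if (length(ups) < 1) stop("no upstroke detected in simulated trace")
  # last upstroke with a full window of trailing samples
  lead <- 5L
  ok <- ups[ups + (window - lead) <= (length(v) - 1) & ups >= lead]
  if (!length(ok)) stop("no upstroke has a full recording window after it")
  up <- ok[length(ok)]
  i0 <- as.integer(round(up)) - lead + 1L  # voltage index of window start (1-based)
  win <- v[i0:(i0 + window - 1L)]
  cur <- res$current[i0:(i0 + window - 1L)]

  cl <- if (length(ups) >= 2) diff(tail(ups, 2)) else NA_real_
  condition <- switch(drug$mode,
                      none = "drug_free",
                      simple_block = "simple_block",
                      state_dependent = "state_dependent")
  out <- structure(list(
    voltage = win,
    current = cur,
    dt = noise$dt,
    phenotype = attr(params, "phenotype"),
    condition = condition,
    block_fraction = drug$block_fraction,
    cycle_length = cl,
    upstroke_offset = lead,
    seed = seed
  ), class = "ap_trace")
  if (keep_full)
    out$full <- list(voltage = v, current = res$current,
                     upstroke_times = ups)
  validate_ap_trace(out)
  out
}

validate_ap_trace <- function(x) {
  if (!all(is.finite(x$voltage))) stop("non-finite voltage in AP trace")
  if (min(x$voltage) >= -40 || max(x$voltage) <= 0)
    stop("trace does not look like a valid action potential (needs min < -40 mV and max > 0 mV)")
  invisible(x)
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf("<ap_trace> %s / %s  (%d samples @ %g ms)\n",
              x$phenotype, x$condition, length(x$voltage), x$dt))
  cat(sprintf("  cycle length %.0f ms; V in [%.1f, %.1f] mV; seed %s\n",
              x$cycle_length, min(x$voltage), max(x$voltage),
              format(x$seed)))
  invisible(x)
}

#' Detect the cycle length of a voltage trace
#'
#' Upstrokes are located as maximum-dV/dt markers: contiguous runs where
#' dV/dt exceeds `threshold` (default 10 mV/ms) are reduced to their
#' maximum-slope sample, with runs closer than `refractory` merged.  The
#' returned cycle length is the interval between the last two upstrokes.
#'
#' @param trace an `ap_trace` or a numeric voltage vector (mV at `dt` ms).
#' @param dt sampling step, ms (taken from the trace when available).
#' @param threshold dV/dt threshold, mV/ms.
#' @param refractory minimum separation of distinct upstrokes, ms.
#' @return Cycle length in ms.
#' @examples
#' v <- rep(-80, 2000); v[c(11:13, 993:995)] <- c(-40, 20, 30, -40, 20, 30)
#' detect_cycle_length(v)  # 982
#' @export
detect_cycle_length <- function(trace, dt = 1, threshold = 10,
                                refractory = 250) {
  v <- if (inherits(trace, "ap_trace")) {
    dt <- trace$dt
    if (!is.null(trace$full)) trace$full$voltage else trace$voltage
  } else as.numeric(trace)
  ups <- find_upstrokes(v, dt, threshold, refractory)
  if (length(ups) < 2)
    stop("need at least 2 upstrokes to measure a cycle length (found ",
         length(ups), ")")
  diff(tail(ups, 2))
}

# upstroke times (ms) as max-dV/dt markers of threshold-exceeding runs
find_upstrokes <- function(v, dt = 1, threshold = 10, refractory = 250) {
  dvdt <- diff(v) / dt
  idx <- which(dvdt > threshold)
  if (!length(idx)) return(numeric(0))
  brk <- c(0, which(diff(idx) * dt > refractory), length(idx))
  vapply(seq_len(length(brk) - 1), function(k) {
    run <- idx[(brk[k] + 1):brk[k + 1]]
    run[which.max(dvdt[run])] * dt - dt
  }, numeric(1))
}

#' Membrane resistance time series dV/dI
#'
#' Estimates the instantaneous membrane resistance as the ratio of central
#' differences `(dV/dt) / (dI/dt)`.  Where `|dI|` falls below `tol` the
#' ratio diverges (the high-resistance plateau phase); such samples are
#' reported capped at `cap` (with the sign of the ratio) and flagged.
#'
#' @param voltage voltage samples, mV (or an `ap_trace`).
#' @param current total current samples on the same grid, uA/uF.
#' @param cap magnitude ceiling for the reported resistance.
#' @param tol `|dI|` below which the ratio is considered divergent.
#' @return A list with `resistance` (length of input; endpoints `NA`),
#'   `capped` (logical flags).
#' @examples
#' v <- seq(-80, -70, length.out = 101)
#' r <- membrane_resistance_series(v, 0.1 * (v + 85))  # ohmic, g = 0.1
#' r$resistance[50]  # 10
#' @export
membrane_resistance_series <- function(voltage, current, cap = 1e4,
                                       tol = 1e-6) {
  if (inherits(voltage, "ap_trace")) {
    current <- voltage$current
    voltage <- voltage$voltage
  }
  if (length(voltage) != length(current))
    stop("voltage and current must have the same length (",
         length(voltage), " vs ", length(current), ")")
  n <- length(voltage)
  dv <- c(NA, (voltage[-(1:2)] - voltage[1:(n - 2)]) / 2, NA)
  di <- c(NA, (current[-(1:2)] - current[1:(n - 2)]) / 2, NA)
  r <- dv / di
  capped <- !is.na(di) & abs(di) < tol
  r[capped] <- sign(r[capped]) * cap
  r[capped & (is.na(r) | r == 0)] <- cap
  big <- !is.na(r) & abs(r) > cap
  r[big] <- sign(r[big]) * cap
  list(resistance = r, capped = capped | big)
}
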