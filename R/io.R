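#' Write / read a paired population as CSV
#'
#' One row per paired sample: metadata columns (`id`, `condition`,
#' `label`, `block_fraction`, `cycle_length_ms`, `seed_input`,
#' `seed_target`) followed by the immature input voltages `in_0 ... in_N`
#' and the adult target voltages `out_0 ... out_N` (mV at 1-ms steps).
#'
#' @param population an `ap_population`.
#' @param path CSV file path.
#' @return `write_population_csv` returns `path` invisibly;
#'   `read_population_csv` an `ap_population` (without current series).
#' @export
write_population_csv <- function(population, path) {
  w <- ncol(population$input)
  df <- data.frame(id = seq_len(nrow(population$input)),
                   condition = population$condition,
                   label = population$label,
                   block_fraction = population$block_fraction,
                   cycle_length_ms = population$cycle_length,
                   seed_input = population$seed_input,
                   seed_target = population$seed_target)
  inm <- population$input
  colnames(inm) <- paste0("in_", seq_len(w) - 1)
  outm <- population$target
  colnames(outm) <- paste0("out_", seq_len(w) - 1)
  data.table::fwrite(cbind(df, inm, outm), path)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  dt <- data.table::fread(path)
  incol <- grep("^in_", names(dt), value = TRUE)
  outcol <- grep("^out_", names(dt), value = TRUE)
  if (!length(incol) || !length(outcol))
    stop("file does not look like a population CSV (no in_/out_ columns)")
  structure(list(input = as.matrix(dt[, incol, with = FALSE]),
                 target = as.matrix(dt[, outcol, with = FALSE]),
                 input_current = NULL,
                 label = dt$label,
                 condition = dt$condition,
                 block_fraction = dt$block_fraction,
                 cycle_length = dt$cycle_length_ms,
                 seed_input = dt$seed_input,
                 seed_target = dt$seed_target,
                 config = NULL),
            class = "ap_population")
}

#' Read action-potential traces from a generic numeric CSV
#'
#' Tolerant reader for deposited AP data: accepts a plain numeric matrix
#' with traces as rows or as columns (auto-detected -- the longer axis is
#' taken as time -- and overridable), with or without a header, and with
#' an optional leading time column (detected as a strictly increasing
#' equally spaced first column, which sets the sampling step).
#'
#' @param path CSV path.
#' @param orientation `"auto"`, `"rows"` (traces in rows) or `"columns"`.
#' @return A list with `traces` (matrix, one trace per row, mV) and `dt`
#'   (ms).
#' @export
read_ap_csv <- function(path, orientation = c("auto", "rows", "columns")) {
  orientation <- match.arg(orientation)
  dt <- tryCatch(data.table::fread(path, header = "auto"),
                 error = function(e) stop("cannot read '", path, "': ",
                                          conditionMessage(e)))
  m <- as.matrix(dt)
  if (!is.numeric(m)) {
    bad <- which(!vapply(dt, is.numeric, logical(1)))[1]
    stop("non-numeric values in column ", bad, " of '", path, "'")
  }
  step <- 1
  # leading time column?
  if (ncol(m) >= 2) {
    tc <- m[, 1]
    d <- diff(tc)
    if (length(d) > 2 && all(d > 0) && max(abs(d - d[1])) < 1e-6 * max(1, d[1])) {
      step <- d[1]
      m <- m[, -1, drop = FALSE]
      if (orientation == "auto") orientation <- "columns"
    }
  }
  if (orientation == "auto")
    orientation <- if (ncol(m) >= nrow(m)) "rows" else "columns"
  traces <- if (orientation == "rows") m else t(m)
  dimnames(traces) <- NULL
  list(traces = traces, dt = step)
}

#' Translate a raw immature trace into an adult trace
#'
#' The full translation path for one measured (or simulated) immature
#' action potential in mV: crop or pad to the network window at 1-ms
#' sampling (the last complete AP window is used for long recordings;
#' short traces are padded with their own diastolic value), zero-phase
#' filter, normalize with the *training* immature statistics, run the
#' network with dropout off, and denormalize the output with the adult
#' statistics.
#'
#' @param v immature trace, mV at `dt` ms.
#' @param net trained `net_params` (or `trained_net`).
#' @param stats_input,stats_target training [fit_norm_stats()] objects
#'   for the immature inputs and adult targets.
#' @param dt sampling step of `v`, ms.
#' @param cutoff_hz,order filter settings (match the training
#'   preprocessing).
#' @return List with `adult` (translated trace, mV, network window
#'   length), `prob` (drugged probability or `NULL`), `input_window`
#'   (the preprocessed input actually fed to the network, mV).
#' @export
translate_trace <- function(v, net, stats_input, stats_target, dt = 1,
                            cutoff_hz = 100, order = 4) {
  if (inherits(net, "trained_net")) net <- net$net
  stopifnot(inherits(net, "net_params"))
  check_stats(stats_input, "immature")
  check_stats(stats_target, "adult")
  w <- net$config$window
  if (dt != 1) {  # resample to the 1-ms grid
    t_old <- (seq_along(v) - 1) * dt
    t_new <- seq(0, max(t_old), by = 1)
    v <- stats::approx(t_old, v, xout = t_new)$y
  }
  win <- crop_to_window(v, w)
  fwin <- zero_phase_filter(win, cutoff_hz, order)
  xn <- normalize_traces(fwin, stats_input)
  fw <- net_forward(net, xn, training = FALSE)
  list(adult = denormalize_traces(as.numeric(fw$translated), stats_target),
       prob = if (!is.null(fw$prob)) fw$prob[1] else NULL,
       input_window = fwin)
}

# crop to the last upstroke-aligned window of length w (5-ms lead),
# padding with the diastolic (median of the lowest quartile) value
crop_to_window <- function(v, w, lead = 5L) {
  ups <- find_upstrokes(v)
  if (!length(ups))
    stop("no upstroke found in the trace; cannot align a window")
  diast <- median(v[v <= min(v) + 3])   # diastolic level: near the minimum
  # choose the last upstroke that leaves the most complete window
  up <- ups[length(ups)]
  for (u in rev(ups)) {
    if ((round(u) - lead + 1) >= 1 && (round(u) - lead + w) <= length(v)) {
      up <- u
      break
    }
    up <- u
  }
  i0 <- round(up) - lead + 1
  idx <- i0:(i0 + w - 1)
  out <- rep(diast, w)
  ok <- idx >= 1 & idx <= length(v)
  out[ok] <- v[idx[ok]]
  out
}

#' Run manifest
#'
#' A JSON-serialisable record of everything needed to reproduce a run:
#' the configuration, master seed, subpopulation sizes, split membership,
#' normalisation statistics and package version.
#'
#' @param population an `ap_population`.
#' @param split a `dataset_split`.
#' @param data optional `prepared_dataset` (adds the normalisation
#'   statistics).
#' @param extra named list merged into the manifest.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(population = NULL, split = NULL, data = NULL,
                         extra = list()) {
  m <- list(package_version = as.character(utils::packageVersion("aptranslate")),
            created = format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  if (!is.null(population)) {
    m$master_seed <- population$master_seed
    m$counts <- as.list(table(population$condition))
    cfg <- population$config
    if (!is.null(cfg)) {
      cfg$drug <- unclass(cfg$drug)
      m$population_config <- unclass(cfg)
    }
  }
  if (!is.null(split))
    m$split <- list(seed = split$seed, train = split$train,
                    validation = split$validation, test = split$test)
  if (!is.null(data))
    m$norm_stats <- list(
      input = data$stats_input[c("mean", "scale", "cell_type")],
      target = data$stats_target[c("mean", "scale", "cell_type")],
      filter = data$filter_settings)
  structure(c(m, extra), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
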