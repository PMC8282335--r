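#' Configuration of the paired action-potential population
#'
#' Defaults reproduce the reference population design: 208 drug-free pairs, a simple
#' conductance-scaling I_Kr block sweep of 1--50% in 1% increments with 5
#' beating rates per level (250 pairs), and 300 pairs under the
#' state-dependent block scheme -- 758 paired samples in total.  Each pair
#' is an immature (spontaneous) input trace and an adult target trace paced
#' at the immature trace's last-beat cycle length, with the physiological
#' noise current (`xi = 0.3`) applied to the final 100 beats of both.
#'
#' @param n_drug_free number of drug-free pairs.
#' @param block_levels simple-block fractions swept.
#' @param rates_per_level immature replicates (distinct noise seeds, hence
#'   beating rates) per block level.
#' @param n_state_dependent number of state-dependent-block pairs.
#' @param xi noise diffusion coefficient.
#' @param conditioning_beats,noisy_beats see [pacing_protocol()].
#' @param window samples per trace (701 at 1 ms).
#' @param drug state-dependent [drug_spec()] used for that subpopulation.
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_drug_free = 208L,
                              block_levels = seq(0.01, 0.50, by = 0.01),
                              rates_per_level = 5L,
                              n_state_dependent = 300L,
                              xi = 0.3,
                              conditioning_beats = 20L,
                              noisy_beats = 100L,
                              window = 701L,
                              drug = drug_spec("state_dependent")) {
  stopifnot(n_drug_free >= 0, n_state_dependent >= 0, rates_per_level >= 1,
            all(block_levels >= 0 & block_levels <= 0.5))
  structure(list(n_drug_free = as.integer(n_drug_free),
                 block_levels = block_levels,
                 rates_per_level = as.integer(rates_per_level),
                 n_state_dependent = as.integer(n_state_dependent),
                 xi = xi,
                 conditioning_beats = as.integer(conditioning_beats),
                 noisy_beats = as.integer(noisy_beats),
                 window = as.integer(window),
                 drug = drug),
            class = "population_config")
}

#' Build the paired immature/adult population
#'
#' For every sample an immature spontaneous trace is simulated with its own
#' derived noise seed; its last-beat cycle length is detected and the adult
#' partner is paced at exactly that cycle length (with its own noise seed).
#' Drugged conditions apply the same block scheme to both cells of a pair.
#' Labels are 0 for drug-free and 1 for drugged pairs.
#'
#' @param config a [population_config()].
#' @param seed master seed; per-sample seeds are derived deterministically.
#' @param progress print progress every 100 samples.
#' @return An object of class `ap_population`: list with matrices `input`
#'   and `target` (samples x window, mV), `input_current` (total ionic
#'   current under the immature traces), vectors `label`, `condition`,
#'   `block_fraction`, `cycle_length`, `seed_input`, `seed_target`, and the
#'   `config`.
#' @export
build_population <- function(config = population_config(), seed = 1L,
                             progress = FALSE) {
  stopifnot(inherits(config, "population_config"))
  plan <- population_plan(config)
  n <- nrow(plan)
  w <- config$window
  input <- matrix(NA_real_, n, w)
  target <- matrix(NA_real_, n, w)
  input_current <- matrix(NA_real_, n, w)
  cl <- numeric(n)
  base <- as.numeric(seed) * 1e7

  for (k in seq_len(n)) {
    cond <- plan$condition[k]
    drug <- switch(cond,
                   drug_free = drug_spec("none"),
                   simple_block = drug_spec("simple_block",
                                            block_fraction = plan$block_fraction[k]),
                   state_dependent = config$drug)
    seed_in <- base + 2 * k
    seed_tg <- base + 2 * k + 1
    imm <- tryCatch(
      simulate_ap(immature_params(),
                  pacing_protocol(spontaneous = TRUE,
                                  conditioning_beats = config$conditioning_beats,
                                  noisy_beats = config$noisy_beats),
                  drug = drug,
                  noise = noise_spec(xi = config$xi),
                  seed = seed_in, window = w),
      error = function(e) stop("immature simulation failed for sample ", k,
                               " (", cond, ", seed ", seed_in, "): ",
                               conditionMessage(e)))
    adu <- tryCatch(
      simulate_ap(adult_params(),
                  pacing_protocol(cycle_length = imm$cycle_length,
                                  conditioning_beats = config$conditioning_beats,
                                  noisy_beats = config$noisy_beats),
                  drug = drug,
                  noise = noise_spec(xi = config$xi),
                  seed = seed_tg, window = w),
      error = function(e) stop("adult simulation failed for sample ", k,
                               " (", cond, ", seed ", seed_tg, "): ",
                               conditionMessage(e)))
    input[k, ] <- imm$voltage
    input_current[k, ] <- imm$current
    target[k, ] <- adu$voltage
    cl[k] <- imm$cycle_length
    plan$seed_input[k] <- seed_in
    plan$seed_target[k] <- seed_tg
    if (progress && k %% 100 == 0)
      message("  simulated ", k, "/", n, " pairs")
  }

  structure(list(input = input,
                 target = target,
                 input_current = input_current,
                 label = plan$label,
                 condition = plan$condition,
                 block_fraction = plan$block_fraction,
                 cycle_length = cl,
                 seed_input = plan$seed_input,
                 seed_target = plan$seed_target,
                 config = config,
                 master_seed = seed),
            class = "ap_population")
}

# deterministic enumeration of the population composition
population_plan <- function(config) {
  simple <- expand.grid(rate = seq_len(config$rates_per_level),
                        block_fraction = config$block_levels)
  data.frame(
    condition = c(rep("drug_free", config$n_drug_free),
                  rep("simple_block", nrow(simple)),
                  rep("state_dependent", config$n_state_dependent)),
    block_fraction = c(rep(0, config$n_drug_free),
                       simple$block_fraction,
                       rep(NA_real_, config$n_state_dependent)),
    label = c(rep(0L, config$n_drug_free),
              rep(1L, nrow(simple)),
              rep(1L, config$n_state_dependent)),
    seed_input = NA_real_, seed_target = NA_real_,
    stringsAsFactors = FALSE)
}

#' @export
print.ap_population <- function(x, ...) {
  cat("<ap_population>", nrow(x$input), "paired samples x",
      ncol(x$input), "samples/trace\n")
  print(table(x$condition))
  invisible(x)
}

#' Subset a paired population
#'
#' @param x an `ap_population`.
#' @param i sample indices.
#' @param ... ignored.
#' @return An `ap_population` with the selected samples.
#' @export
`[.ap_population` <- function(x, i, ...) {
  out <- x
  for (f in c("input", "target", "input_current"))
    out[[f]] <- x[[f]][i, , drop = FALSE]
  for (f in c("label", "condition", "block_fraction", "cycle_length",
              "seed_input", "seed_target"))
    out[[f]] <- x[[f]][i]
  out
}

#' Stratified 70:10:20 dataset split
#'
#' Shuffles sample indices with a seeded RNG, stratifies by condition so
#' every split preserves the condition proportions to within one sample,
#' and assigns counts by floor-then-distribute-remainder.
#'
#' @param population an `ap_population`, or a character vector of condition
#'   tags.
#' @param ratios train/validation/test proportions summing to 1.
#' @param seed shuffle seed.
#' @return An object of class `dataset_split` with integer index vectors
#'   `train`, `validation`, `test`.
#' @export
split_dataset <- function(population, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  cond <- if (inherits(population, "ap_population")) population$condition
          else as.character(population)
  if (abs(sum(ratios) - 1) > 1e-9) stop("split ratios must sum to 1")
  if (length(ratios) != 3) stop("need train/validation/test ratios")
  n <- length(cond)
  if (n < 10) stop("need at least 10 samples to split")
  groups <- split(seq_len(n), cond)
  if (any(!lengths(groups)))
    stop("empty condition class after stratification")
  sets <- list(train = integer(0), validation = integer(0), test = integer(0))
  rs <- local_rng(seed)
  for (g in groups) {
    g <- g[sample.int(length(g))]
    m <- length(g)
    base <- floor(ratios * m)
    rem <- m - sum(base)
    # distribute the remainder to the largest fractional parts
    frac <- ratios * m - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
    idx <- cumsum(base)
    sets$train <- c(sets$train, g[seq_len(base[1])])
    if (base[2]) sets$validation <- c(sets$validation, g[(idx[1] + 1):idx[2]])
    if (base[3]) sets$test <- c(sets$test, g[(idx[2] + 1):idx[3]])
  }
  restore_rng(rs)
  structure(list(train = sort(sets$train),
                 validation = sort(sets$validation),
                 test = sort(sets$test),
                 seed = seed,
                 counts = vapply(sets, length, integer(1))),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / validation %d / test %d (seed %s)\n",
              length(x$train), length(x$validation), length(x$test),
              format(x$seed)))
  invisible(x)
}

# seeded RNG scoped to a computation: returns the previous state
local_rng <- function(seed) {
  prev <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  prev
}

restore_rng <- function(prev) {
  if (is.null(prev)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", prev, envir = globalenv())
  invisible(NULL)
}

#' Preprocess a population for network training
#'
#' Applies zero-phase filtering to inputs and targets, fits normalisation
#' statistics on the *training* traces only, and returns normalized
#' matrices together with the statistics and split.
#'
#' @param population an `ap_population`.
#' @param split a [split_dataset()] result (built from `population` when
#'   omitted).
#' @param cutoff_hz,order filter settings for [zero_phase_filter()].
#' @param split_seed seed used when `split` is omitted.
#' @return A list of class `prepared_dataset` with `input`, `target`
#'   (normalized matrices), `label`, `split`, `stats_input`,
#'   `stats_target`, `condition`.
#' @export
prepare_dataset <- function(population, split = NULL, cutoff_hz = 100,
                            order = 4, split_seed = 1L) {
  stopifnot(inherits(population, "ap_population"))
  if (is.null(split)) split <- split_dataset(population, seed = split_seed)
  fset <- list(cutoff_hz = cutoff_hz, order = order, fs = 1000)
  fin <- zero_phase_filter(population$input, cutoff_hz, order)
  ftg <- zero_phase_filter(population$target, cutoff_hz, order)
  stats_in <- fit_norm_stats(fin[split$train, , drop = FALSE], "immature", fset)
  stats_tg <- fit_norm_stats(ftg[split$train, , drop = FALSE], "adult", fset)
  structure(list(input = normalize_traces(fin, stats_in),
                 target = normalize_traces(ftg, stats_tg),
                 label = population$label,
                 condition = population$condition,
                 split = split,
                 stats_input = stats_in,
                 stats_target = stats_tg,
                 filter_settings = fset),
            class = "prepared_dataset")
}
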