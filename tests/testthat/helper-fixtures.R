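# Small simulation settings shared across tests: short protocols keep each
# simulated trace cheap while preserving the model's behaviour.
quick_protocol <- function(spontaneous = FALSE, cycle_length = 982,
                           conditioning_beats = 3, noisy_beats = 1)
  pacing_protocol(cycle_length = cycle_length,
                  conditioning_beats = conditioning_beats,
                  noisy_beats = noisy_beats,
                  spontaneous = spontaneous)

no_noise <- function(seed = 1L) noise_spec(xi = 0, seed = seed)

quick_immature <- function(seed = 1L, drug = drug_spec("none"), xi = 0,
                           beats = c(3, 2))
  simulate_ap(immature_params(),
              quick_protocol(TRUE, conditioning_beats = beats[1],
                             noisy_beats = beats[2]),
              drug = drug, noise = noise_spec(xi = xi), seed = seed)

quick_adult <- function(seed = 1L, drug = drug_spec("none"), xi = 0,
                        cycle_length = 982, beats = c(3, 1))
  simulate_ap(adult_params(),
              quick_protocol(FALSE, cycle_length, beats[1], beats[2]),
              drug = drug, noise = noise_spec(xi = xi), seed = seed)

# square-pulse action potential: baseline, plateau of `dur` ms, baseline
square_ap <- function(base = -80, top = 20, pre = 10, dur = 300, post = 100) {
  c(rep(base, pre), rep(top, dur), rep(base, post))
}

# tiny paired dataset built from scaled/shifted copies of simulated traces;
# cheap stand-in for network plumbing tests (not physiologic)
toy_prepared <- function(n = 12, w = 41, seed = 1) {
  set.seed(seed)
  tt <- seq(0, 1, length.out = w)
  input <- t(sapply(seq_len(n), function(i)
    sin(2 * pi * (tt + runif(1, 0, 0.2))) * runif(1, 0.5, 1)))
  target <- 0.5 * input + 0.1
  label <- rep(c(0, 1), length.out = n)
  target[label == 1, ] <- target[label == 1, ] + 0.3
  split <- list(train = 1:(n - 4), validation = (n - 3):(n - 2),
                test = (n - 1):n)
  stats <- fit_norm_stats(target * 50 - 40, "adult")
  list(input = input, target = target, label = label, split = split,
       stats_input = fit_norm_stats(input * 50 - 40, "immature"),
       stats_target = stats)
}
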