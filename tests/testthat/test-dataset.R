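test_that("default population plan enumerates 208 + 250 + 300 paired samples", {
  plan <- aptranslate:::population_plan(population_config())
  counts <- table(plan$condition)
  expect_equal(as.integer(counts[["drug_free"]]), 208)
  expect_equal(as.integer(counts[["simple_block"]]), 250)   # 50 levels x 5 rates
  expect_equal(as.integer(counts[["state_dependent"]]), 300)
  expect_equal(nrow(plan), 758)
  # label marginal: 208 drug-free zeros, 550 drugged ones
  expect_equal(sum(plan$label == 0), 208)
  expect_equal(sum(plan$label == 1), 550)
  # the simple-block sweep covers 1..50% with 5 replicates each
  bf <- plan$block_fraction[plan$condition == "simple_block"]
  expect_equal(sort(unique(bf)), seq(0.01, 0.5, by = 0.01))
  expect_true(all(table(bf) == 5))
})

test_that("population building is deterministic and pairs at matched cycle length", {
  cfg <- population_config(n_drug_free = 2, block_levels = 0.3,
                           rates_per_level = 2, n_state_dependent = 2,
                           conditioning_beats = 3, noisy_beats = 2)
  p1 <- build_population(cfg, seed = 5)
  p2 <- build_population(cfg, seed = 5)
  expect_identical(p1$input, p2$input)
  expect_identical(p1$target, p2$target)
  p3 <- build_population(cfg, seed = 6)
  expect_false(identical(p1$input, p3$input))

  expect_equal(nrow(p1$input), 6)
  expect_equal(ncol(p1$input), 701)
  expect_true(all(is.finite(p1$input)), all(is.finite(p1$target)))
  # every immature trace beats in the plausible range and the pair metadata
  # carries that cycle length (used to pace the adult partner)
  expect_true(all(p1$cycle_length > 800 & p1$cycle_length < 1300))
  # all traces look like APs
  expect_true(all(apply(p1$input, 1, min) < -40))
  expect_true(all(apply(p1$input, 1, max) > 0))
  expect_true(all(apply(p1$target, 1, max) > 0))
  # drugged immature traces are longer than drug-free ones on average
  a_free <- mean(apply(p1$input[p1$label == 0, , drop = FALSE], 1, apd90))
  a_drug <- mean(apply(p1$input[p1$label == 1, , drop = FALSE], 1, apd90))
  expect_gt(a_drug, a_free)
})

test_that("stratified split honours the 70:10:20 remainder rule", {
  # 758 samples with the default condition mix -> 530 / 76 / 152
  cond <- c(rep("drug_free", 208), rep("simple_block", 250),
            rep("state_dependent", 300))
  sp <- split_dataset(cond, seed = 1)
  expect_equal(length(sp$train), 530)
  expect_equal(length(sp$validation), 76)
  expect_equal(length(sp$test), 152)
  # disjoint and exhaustive
  all_idx <- sort(c(sp$train, sp$validation, sp$test))
  expect_equal(all_idx, seq_along(cond))
  # per-condition proportions preserved within one sample per split
  for (cl in unique(cond)) {
    n_cl <- sum(cond == cl)
    expect_lte(abs(sum(cond[sp$train] == cl) - 0.7 * n_cl), 1)
    expect_lte(abs(sum(cond[sp$validation] == cl) - 0.1 * n_cl), 1)
    expect_lte(abs(sum(cond[sp$test] == cl) - 0.2 * n_cl), 1)
  }
  # 10 samples of one condition -> exact 7/1/2
  sp10 <- split_dataset(rep("a", 10), seed = 2)
  expect_equal(unname(sp10$counts), c(7L, 1L, 2L))
  # determinism
  expect_identical(split_dataset(cond, seed = 9), split_dataset(cond, seed = 9))
  expect_error(split_dataset(rep("a", 5)), "at least 10")
  expect_error(split_dataset(cond, ratios = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("prepared datasets are normalized from training traces only", {
  cfg <- population_config(n_drug_free = 4, block_levels = c(0.2, 0.4),
                           rates_per_level = 1, n_state_dependent = 4,
                           conditioning_beats = 3, noisy_beats = 2)
  pop <- build_population(cfg, seed = 8)
  prep <- prepare_dataset(pop, split_seed = 8)
  expect_s3_class(prep$stats_input, "norm_stats")
  expect_identical(prep$stats_input$cell_type, "immature")
  expect_identical(prep$stats_target$cell_type, "adult")
  # training inputs lie in [-1, 1] by construction
  tr <- prep$split$train
  expect_lte(max(abs(prep$input[tr, ])), 1)
  expect_lte(max(abs(prep$target[tr, ])), 1)
  # round trip back to mV
  back <- denormalize_traces(prep$target, prep$stats_target)
  expect_lt(min(back), -80)
  expect_gt(max(back), 0)
})
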