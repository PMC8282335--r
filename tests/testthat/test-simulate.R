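test_that("noise-free simulation is deterministic and reproducible", {
  t1 <- quick_adult(seed = 1)
  t2 <- quick_adult(seed = 1)
  expect_identical(t1$voltage, t2$voltage)
  # and with noise, determinism holds for a fixed seed
  n1 <- quick_adult(seed = 7, xi = 0.3)
  n2 <- quick_adult(seed = 7, xi = 0.3)
  expect_identical(n1$voltage, n2$voltage)
  n3 <- quick_adult(seed = 8, xi = 0.3)
  expect_false(identical(n1$voltage, n3$voltage))
})

test_that("immature cell beats spontaneously near the matched cycle length", {
  tr <- quick_immature(seed = 2)
  expect_s3_class(tr, "ap_trace")
  # spontaneous rate within 10% of the 982-ms pacing-matched cycle length
  expect_gt(tr$cycle_length, 982 * 0.9)
  expect_lt(tr$cycle_length, 982 * 1.1)
})

test_that("phenotype morphology contract holds at baseline", {
  imm <- quick_immature(seed = 3)
  adu <- quick_adult(seed = 3, cycle_length = imm$cycle_length)
  fi <- morphology_features(imm)
  fa <- morphology_features(adu)
  # immature MDP in [-80, -70]; adult resting potential in [-92, -84]
  expect_gte(fi[["mdp"]], -80); expect_lte(fi[["mdp"]], -70)
  expect_gte(fa[["mdp"]], -92); expect_lte(fa[["mdp"]], -84)
  # adult upstroke faster, adult AP shorter, at the matched cycle length
  expect_gt(fa[["v_max"]], fi[["v_max"]])
  expect_lt(fa[["apd90"]], fi[["apd90"]])
  # both valid APs
  expect_gt(fi[["peak"]], 0)
  expect_gt(fa[["peak"]], 0)
})

test_that("adult cell is quiescent without stimulus and fires 1:1 when paced", {
  q <- aptranslate:::.simulate_ap_cpp(
    stats::setNames(as.numeric(adult_params()), names(adult_params())),
    1, 0L, 0, 0, 0, FALSE, 0, 1, 1000, 3L, 0L, 0, 0.01, 1, -87, 1, 710)
  expect_length(q$upstroke_times, 0)
  expect_lt(diff(range(q$voltage)), 2)   # settles at rest
  p <- aptranslate:::.simulate_ap_cpp(
    stats::setNames(as.numeric(adult_params()), names(adult_params())),
    1, 0L, 0, 0, 0, FALSE, 60, 1, 900, 4L, 1L, 0, 0.01, 1, -87, 1, 710)
  expect_length(p$upstroke_times, 5)     # one upstroke per stimulus
})

test_that("APD90 prolongs monotonically with simple I_Kr block", {
  apds <- vapply(c(0, 0.1, 0.2, 0.3, 0.4, 0.5), function(b) {
    drug <- if (b == 0) drug_spec("none") else
      drug_spec("simple_block", block_fraction = b)
    apd90(quick_adult(seed = 1, drug = drug))
  }, numeric(1))
  expect_true(all(diff(apds) > 0))
})

test_that("state-dependent block produces intermediate use-dependent APD prolongation", {
  base <- apd90(quick_adult(seed = 1, beats = c(8, 1)))
  full <- apd90(quick_adult(seed = 1, beats = c(8, 1),
                            drug = drug_spec("simple_block", block_fraction = 0.5)))
  sdep <- apd90(quick_adult(seed = 1, beats = c(8, 1),
                            drug = drug_spec("state_dependent")))
  expect_gt(sdep, base)
  expect_lt(sdep, full)
})

test_that("cycle length detection uses max-dV/dt markers", {
  # constructed trace: upstrokes at 10 ms and 992 ms
  v <- rep(-80, 1800)
  v[11:13] <- c(-40, 20, 30); v[14:300] <- 10
  v[993:995] <- c(-40, 20, 30); v[996:1300] <- 10
  expect_equal(detect_cycle_length(v), 982)
  # exactly periodic train, period 1000 ms
  vp <- rep(c(rep(-80, 700), rep(20, 300)), 3)
  expect_equal(detect_cycle_length(vp), 1000)
  # single beat: degenerate
  expect_error(detect_cycle_length(square_ap()), "2 upstrokes")
})

test_that("membrane resistance recovers ohmic behaviour and caps divergences", {
  v <- seq(-80, -60, length.out = 201)
  r <- membrane_resistance_series(v, 0.1 * (v + 88))
  expect_equal(unique(round(r$resistance[2:200], 9)), 10)
  r1 <- membrane_resistance_series(v, 1 * (v + 88))
  expect_equal(unique(round(r1$resistance[2:200], 9)), 1)
  # constant current (plateau): capped and flagged
  rp <- membrane_resistance_series(v, rep(2, 201), cap = 1e4)
  expect_true(all(rp$capped[2:200]))
  expect_true(all(abs(rp$resistance[2:200]) == 1e4))
  expect_error(membrane_resistance_series(v, 1:5), "length")
})

test_that("simulation rejects invalid inputs with informative errors", {
  expect_error(simulate_ap(adult_params(), quick_protocol(),
                           noise = noise_spec(), dt_internal = 0.05),
               "0.01")
  # a cell that cannot beat spontaneously errors out rather than hanging
  dead <- immature_params(c(g_f = 0, g_bna = 0, g_cal = 0))
  expect_error(
    simulate_ap(dead, pacing_protocol(spontaneous = TRUE,
                                      conditioning_beats = 1, noisy_beats = 1),
                noise = no_noise()),
    "spontaneous|action potential")
})
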