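test_that("R2 matches hand arithmetic and its invariances", {
  expect_equal(r2_score(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(1, 2, 3, 4)
  expect_equal(r2_score(y, rep(mean(y), 4)), 0)
  # hand computation: 1 - 0.06/2
  expect_equal(r2_score(c(1, 2, 3), c(1.1, 1.9, 3.2)), 0.97)
  # invariant under a shared affine map of truth and prediction
  yh <- c(1.1, 1.9, 3.2)
  expect_equal(r2_score(2 * c(1, 2, 3) - 5, 2 * yh - 5),
               r2_score(c(1, 2, 3), yh))
  expect_error(r2_score(c(2, 2, 2), c(1, 2, 3)), "variance")
})

test_that("classification metrics reproduce their confusion-count definitions", {
  # all correct
  m <- classification_metrics(c(0, 1, 1, 0), c(0.1, 0.9, 0.8, 0.2))
  expect_equal(m$accuracy_percent, 100)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  # the Table-1-like regime: TP 46, TN 46, FP 4, FN 4 -> 92% / 0.92 / 0.92
  lab <- c(rep(1, 50), rep(0, 50))
  prob <- c(rep(0.9, 46), rep(0.1, 4), rep(0.8, 4), rep(0.2, 46))
  m2 <- classification_metrics(lab, prob)
  expect_equal(c(m2$tp, m2$tn, m2$fp, m2$fn), c(46, 46, 4, 4))
  expect_equal(m2$accuracy_percent, 92)
  expect_equal(m2$recall, 0.92)
  expect_equal(m2$precision, 0.92)
  # recomputing the metrics from the reported counts reproduces them
  expect_equal(m2$accuracy_percent, 100 * (m2$tp + m2$tn) /
                 (m2$tp + m2$tn + m2$fp + m2$fn))
  expect_equal(m2$fpr, m2$fp / (m2$fp + m2$tn))
  # degenerate: everything predicted positive with balanced labels
  m3 <- classification_metrics(c(1, 1, 0, 0), rep(0.9, 4))
  expect_equal(m3$accuracy_percent, 50)
  expect_equal(m3$recall, 1)
  expect_equal(m3$precision, 0.5)
  # precision undefined (not zero) when nothing is predicted positive
  m4 <- classification_metrics(c(1, 0), c(0.1, 0.2))
  expect_true(is.na(m4$precision))
  expect_error(classification_metrics(c(0, 2), c(0.5, 0.5)), "labels")
})

# exhaustive pair-counting oracle: P(pos > neg) + 0.5 P(tie)
auroc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("AUROC equals the exhaustive pair-counting oracle", {
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1)), 1)
  expect_equal(auroc(c(1, 1, 0, 0), rep(0.5, 4)), 0.5)    # all ties
  # worked example: positives {0.9, 0.8}, negatives {0.85, 0.7} -> 3/4
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.85, 0.7)), 0.75)
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(4:20, 1)
    lab <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(auroc(lab, sc), auroc_pairs(lab, sc))
  }
  expect_error(auroc(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("AUROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (rep in 1:10) {
    lab <- c(0, 1, sample(0:1, 30, replace = TRUE))
    sc <- round(runif(32), 2)
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
      lab, sc, levels = c(0, 1), direction = "<", quiet = TRUE))))
    expect_equal(auroc(lab, sc), ref, tolerance = 1e-12)
  }
})

test_that("APD90 error averages absolute percentage differences", {
  sq300 <- square_ap(dur = 300)
  sq309 <- square_ap(dur = 309, post = 91)
  expect_equal(as.numeric(apd90_error(rbind(sq300), rbind(sq300))), 0)
  # 300 vs 309 ms -> 3%
  expect_equal(as.numeric(apd90_error(rbind(sq300), rbind(sq309))), 3,
               tolerance = 0.15)
  # unmeasurable traces are excluded and counted
  flat <- rbind(rep(-80, length(sq300)))
  e <- suppressWarnings(apd90_error(rbind(sq300, flat), rbind(sq309, flat)))
  expect_equal(attr(e, "n_failed"), 1)
  expect_equal(attr(e, "n_used"), 1)
})

test_that("evaluation report is deterministic and internally consistent", {
  data <- toy_prepared(n = 14, w = 31, seed = 4)
  cfg <- net_config(window = 31, hidden = 5, trans_hidden = 8,
                    class_hidden = 4)
  fit <- train_network(data, cfg, train_config(epochs = 4, batch_size = 8,
                                               seed = 6))
  r1 <- suppressWarnings(evaluate_network(fit, data,
                                          indices = seq_len(14)))
  r2 <- suppressWarnings(evaluate_network(fit, data,
                                          indices = seq_len(14)))
  expect_identical(r1[names(r1) != "apd90_error_percent"],
                   r2[names(r2) != "apd90_error_percent"])
  # confusion counts sum to the dataset size
  expect_equal(r1$tp + r1$tn + r1$fp + r1$fn, 14)
  expect_error(evaluate_network(fit, data, indices = integer(0)), "empty")
})
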