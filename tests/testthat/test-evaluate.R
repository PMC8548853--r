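# Metric suite and end-to-end classification.

test_that("compute_metrics matches the hand-worked confusion table", {
  # TP 9, FN 1, TN 8, FP 2
  df <- data.frame(
    pred = c(rep("t", 9), "b", rep("b", 8), rep("t", 2)),
    truth = c(rep("t", 10), rep("b", 10)),
    stringsAsFactors = FALSE)
  m <- compute_metrics(df, positive_class = "t")
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$tpr, 0.9)
  expect_equal(m$tnr, 0.8)
  expect_equal(m$precision, 9 / 11)
  expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(9L, 2L, 8L, 1L))
})

test_that("AUROC equals the known pairwise values", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # pos {0.9, 0.4}, neg {0.6, 0.1}: 3 of 4 pairs won
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
})

test_that("rank-statistic AUROC equals brute-force pair enumeration", {
  set.seed(31)
  for (i in 1:20) {
    np <- sample(1:100, 1); nn <- sample(1:100, 1)
    scores <- c(rnorm(np, 0.5), rnorm(nn))
    if (i %% 3 == 0) scores <- round(scores, 1)   # force ties
    pos <- rep(c(TRUE, FALSE), c(np, nn))
    expect_equal(auroc(scores, pos), auroc_brute(scores, pos))
  }
})

test_that("AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  scores <- rnorm(200); pos <- rbinom(200, 1, 0.4) == 1
  ref <- as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(scores, pos), ref, tolerance = 1e-12)
})

test_that("metrics are invariant to prediction order", {
  set.seed(33)
  df <- data.frame(pred = sample(c("a", "b"), 50, TRUE),
                   truth = sample(c("a", "b"), 50, TRUE),
                   p_b = runif(50), stringsAsFactors = FALSE)
  m1 <- compute_metrics(df, "b")
  m2 <- compute_metrics(df[sample(50), ], "b")
  expect_equal(unclass(m1), unclass(m2))
})

test_that("on a balanced set accuracy equals (tpr + tnr)/2", {
  set.seed(34)
  df <- data.frame(pred = sample(c("a", "b"), 200, TRUE),
                   truth = rep(c("a", "b"), 100), stringsAsFactors = FALSE)
  m <- compute_metrics(df, "b")
  expect_equal(m$accuracy, (m$tpr + m$tnr) / 2)
})

test_that("metrics needing both classes are NA for single-class truth", {
  df <- data.frame(pred = c("a", "b", "a"), truth = rep("a", 3),
                   p_b = c(0.1, 0.9, 0.2), stringsAsFactors = FALSE)
  m <- compute_metrics(df, positive_class = "b")
  expect_true(is.na(m$tpr))      # no positives in truth
  expect_true(is.na(m$auroc))
  expect_false(is.na(m$tnr))
  df2 <- data.frame(pred = "a", truth = c("b", "b"), p_b = c(.5, .6))
  m2 <- compute_metrics(df2, positive_class = "b")
  expect_true(is.na(m2$tnr))
})

test_that("missing truth labels are an error", {
  df <- data.frame(pred = c("a", "b"), truth = c("a", NA))
  expect_error(compute_metrics(df), "true label")
})

test_that("accuracy_by_group reproduces the simple cases", {
  df <- data.frame(read_id = sprintf("r%d", 1:6),
                   pred = c("a", "a", "a", "b", "b", "b"),
                   truth = c("a", "a", "a", "a", "a", "a"),
                   stringsAsFactors = FALSE)
  grp <- setNames(rep(c("g1", "g2"), each = 3), df$read_id)
  tab <- accuracy_by_group(df, grp)
  expect_equal(tab$group, c("g1", "g2"))
  expect_equal(tab$accuracy, c(1, 0))
  expect_equal(tab$n, c(3, 3))
  # single group equals overall accuracy
  one <- accuracy_by_group(df, setNames(rep("g", 6), df$read_id))
  expect_equal(one$accuracy, mean(df$pred == df$truth))
})

test_that("group accuracies aggregate to the overall accuracy", {
  set.seed(35)
  df <- data.frame(read_id = sprintf("r%03d", 1:300),
                   pred = sample(c("a", "b"), 300, TRUE),
                   truth = sample(c("a", "b"), 300, TRUE),
                   stringsAsFactors = FALSE)
  grp <- setNames(sample(c("s1", "s2", "s3"), 300, TRUE), df$read_id)
  tab <- accuracy_by_group(df, grp)
  expect_equal(sum(tab$n * tab$accuracy) / sum(tab$n),
               mean(df$pred == df$truth))
})

test_that("unmapped read ids are a validation error naming them", {
  df <- data.frame(read_id = c("r1", "r2"), pred = "a", truth = "a",
                   stringsAsFactors = FALSE)
  expect_error(accuracy_by_group(df, c(r1 = "g")), "r2")
})

test_that("classify_reads runs end to end with exclusions reported", {
  d <- small_windows(n_per_class = 25, delta = 2, seed = 21)
  fit <- porenet(d$x, d$y, config = tiny_config(ncol(d$x)),
                 control = train_control(batch_size = 16, epochs = 2, seed = 1))
  cfg <- sim_config(n_per_class = 15, delta = 2, read_length_median = 400,
                    adapter_len = c(200L, 300L), seed = 22)
  sq <- simulate_squiggles(cfg)$squiggles
  sq$tiny <- squiggle("tiny", 1:800, 5, 1402.882, 8192, 4000, "background")
  res <- classify_reads(fit, sq, skip = 300)
  expect_equal(nrow(res$predictions), 30)
  expect_equal(res$excluded$read_id, "tiny")
  probs <- as.matrix(res$predictions[, paste0("p_", fit$classes)])
  expect_equal(unname(rowSums(probs)), rep(1, 30), tolerance = 1e-6)
  expect_true(all(res$predictions$pred %in% fit$classes))
  expect_true(all(res$predictions$truth %in% c("background", "target")))
  m <- compute_metrics(res$predictions)
  expect_equal(m$positive_class, "target")
  expect_equal(m$tp + m$fp + m$tn + m$fn, 30L)
  # a batch with no classifiable reads errors
  expect_error(classify_reads(fit, list(sq$tiny), skip = 300),
               "no classifiable reads")
})
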