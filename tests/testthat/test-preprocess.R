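# Window extraction, outlier repair and MAD normalization.

test_that("trim_window extracts the half-open window after the skip", {
  s <- seq_len(6000)                       # value i at 0-based position i-1
  w <- trim_window(s, 1500, 3000)
  expect_length(w, 3000)
  expect_equal(w[1], 1501)                 # 0-based sample 1500
  expect_equal(w[3000], 4500)              # 0-based sample 4499
  w2 <- trim_window(seq_len(4500), 1000, 3000)
  expect_equal(range(w2), c(1001, 4000))
})

test_that("too-short reads are excluded with a warning, not an error", {
  expect_warning(res <- trim_window(seq_len(4499), 1500, 3000), "excluded")
  expect_null(res)
  expect_silent(trim_window(seq_len(4500), 1500, 3000))
})

test_that("replace_outliers reproduces the hand-computed example", {
  w <- c(8, 9, 10, 11, 12, 100, 12, 11, 10, 9)
  # median 10.5, MAD 1.5, modified z of 100 = 0.6745*89.5/1.5 = 40.2 > 3.5
  r <- replace_outliers(w)
  expect_equal(r$n_replaced, 1L)
  expect_equal(r$values[6], 12)            # mean of nearest clean neighbours
  expect_equal(r$values[-6], w[-6])
})

test_that("clean windows pass through outlier repair unchanged", {
  w <- c(1, 2, 3, 4, 5)                    # max modified z = 0.6745*2/1 = 1.35
  r <- replace_outliers(w)
  expect_equal(r$n_replaced, 0L)
  expect_identical(r$values, w)
})

test_that("outlier repair handles runs and edges", {
  w <- c(100, 10, 11, 10, 9, 11, 10, 9, 10, 11)
  r <- replace_outliers(w)
  expect_equal(r$values[1], 10)            # one-sided at the edge
  w2 <- c(10, 11, 9, 200, 210, 10, 11, 9, 10, 11)
  r2 <- replace_outliers(w2)
  expect_equal(r2$n_replaced, 2L)
  expect_equal(r2$values[4:5], c(9.5, 9.5))  # both flanked by 9 and 10
})

test_that("repair count equals positions flagged on the input window", {
  set.seed(11)
  for (i in 1:20) {
    w <- rnorm(200)
    spikes <- sample(200, sample(0:5, 1))
    w[spikes] <- w[spikes] + sample(c(-50, 50), length(spikes), TRUE)
    med <- median(w); mad <- median(abs(w - med))
    expected <- sum(0.6745 * abs(w - med) / mad > 3.5)
    expect_equal(replace_outliers(w)$n_replaced, expected)
  }
})

test_that("degenerate (zero-MAD) windows are an error", {
  expect_error(replace_outliers(rep(3, 10)), "degenerate")
  expect_error(mad_normalize(rep(3, 10)), "degenerate")
})

test_that("mad_normalize matches the hand computation", {
  r <- mad_normalize(c(1, 2, 3, 4, 5))
  expect_equal(r$values, c(-2, -1, 0, 1, 2))
  expect_equal(r$median, 3)
  expect_equal(r$mad, 1)
})

test_that("MAD normalization is invariant to affine distortion", {
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(500)
    a <- runif(1, 0.1, 10); b <- runif(1, -100, 100)
    expect_equal(mad_normalize(a * x + b)$values, mad_normalize(x)$values,
                 tolerance = 1e-9)
  }
})

test_that("normalized windows have median 0 and MAD 1", {
  set.seed(5)
  v <- mad_normalize(rnorm(1001, 50, 4))$values
  expect_lt(abs(median(v)), 1e-6)
  expect_lt(abs(median(abs(v - median(v))) - 1), 1e-6)
})

test_that("preprocess_read composes trim, repair and normalize", {
  cfg <- sim_config(n_per_class = 1, read_length_median = 400,
                    adapter_len = c(50L, 80L), seed = 12)
  sq <- simulate_squiggles(cfg)$squiggles[[1]]
  nw <- preprocess_read(sq, skip = 300, length = 1000)
  expect_s3_class(nw, "normalized_window")
  expect_length(nw$values, 1000)
  expect_lt(abs(median(nw$values)), 1e-6)
  expect_lt(abs(median(abs(nw$values)) - 1), 1e-6)
  # determinism
  nw2 <- preprocess_read(sq, skip = 300, length = 1000)
  expect_identical(nw$values, nw2$values)
  # DAC-unit path differs only by float noise (affine invariance)
  nw3 <- preprocess_read(sq, skip = 300, length = 1000, use_pA = FALSE)
  expect_equal(nw$values, nw3$values, tolerance = 1e-9)
})

test_that("preprocessing is idempotent on a clean normalized window", {
  set.seed(8)
  x <- pmin(3, pmax(-3, rnorm(800)))       # no sample beyond the 3.5 cutoff
  w1 <- preprocess_read(x, skip = 0, length = 800)$values
  w2 <- preprocess_read(w1, skip = 0, length = 800)$values
  expect_equal(w2, w1, tolerance = 1e-9)
})

test_that("a single large spike barely perturbs the rest of the window", {
  set.seed(9)
  x <- rnorm(3000)
  clean <- preprocess_read(x, skip = 0, length = 3000)$values
  mad_x <- median(abs(x - median(x)))
  xs <- x; i <- 1234; xs[i] <- xs[i] + 100 * mad_x
  spiked <- preprocess_read(xs, skip = 0, length = 3000)$values
  expect_lt(sqrt(mean((spiked[-i] - clean[-i])^2)), 1e-2)
})

test_that("batch preprocessing reports exclusions instead of failing", {
  sq <- small_squiggles(5, seed = 13)
  sq$short <- squiggle("shorty", 1:500, 5, 1402.882, 8192, 4000, "background")
  pp <- suppressWarnings(
    preprocess_squiggles(sq, skip = 300, length = 1000))
  expect_equal(nrow(pp$windows), 5)
  expect_equal(pp$excluded$read_id, "shorty")
  expect_match(pp$excluded$reason, "too short")
  expect_equal(ncol(pp$windows), 1000)
  expect_true(all(c("median", "mad", "n_outliers_replaced") %in% names(pp$stats)))
})
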