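# Squiggle simulator: pore models, single reads, corpora.

test_that("pore models cover all k-mers within the stated bands", {
  pm <- pore_model(6, seed = 1)
  expect_length(pm$mean, 4096)
  expect_length(pm$sd, 4096)
  expect_identical(pore_model(6, seed = 1)$mean, pm$mean)
  expect_false(identical(pore_model(6, seed = 2)$mean, pm$mean))
  pm1 <- pore_model(1, seed = 5)
  expect_length(pm1$mean, 4)
  expect_true(all(pm1$mean > 60 & pm1$mean < 120))
  expect_true(all(pm1$sd > 0.5 & pm1$sd < 3))
  expect_error(pore_model(0), "1..8")
  expect_error(pore_model(9), "1..8")
})

test_that("fixed dwell with no adapter gives the exact construction length", {
  pm <- pore_model(3, seed = 2)
  cfg <- sim_config(dwell = "fixed", adapter_len = c(0L, 0L), seed = 1)
  d <- round(cfg$sampling_rate / cfg$speed)        # 9 samples per k-mer
  s <- strrep("ACGT", 25)                          # 100 bases
  sq <- simulate_read(pm, s, cfg, seed = 3)
  expect_length(sq$raw, (100 - 3 + 1) * d)
})

test_that("simulated reads are reproducible given a seed", {
  pm <- pore_model(4, seed = 2)
  cfg <- sim_config(seed = 1)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  r1 <- simulate_read(pm, s, cfg, seed = 9)
  r2 <- simulate_read(pm, s, cfg, seed = 9)
  expect_identical(r1$raw, r2$raw)
  expect_false(identical(r1$raw, simulate_read(pm, s, cfg, seed = 10)$raw))
})

test_that("sequences shorter than k are rejected", {
  pm <- pore_model(6, seed = 1)
  expect_error(simulate_read(pm, "ACGT", sim_config(), seed = 1),
               "shorter than k")
  expect_error(simulate_read(pm, "ACGTNN", sim_config(), seed = 1),
               "non-ACGT")
})

test_that("mean samples per base matches sampling_rate / speed", {
  pm <- pore_model(3, seed = 4)
  cfg <- sim_config(adapter_len = c(0L, 0L), seed = 1)
  set.seed(44)
  nb <- 200
  lens <- replicate(200, {
    s <- paste(sample(c("A", "C", "G", "T"), nb, TRUE), collapse = "")
    length(simulate_read(pm, s, cfg)$raw) / (nb - 3 + 1)
  })
  expect_gte(mean(lens), 8.0)        # expected 8.889 at 4 kHz / 450 bp/s
  expect_lte(mean(lens), 9.8)
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 4000 / 450), 2 * se + 0.05)
})

test_that("the level shift moves perturbed k-mers in the expected direction", {
  pm <- pore_model(6, seed = 3)
  cfg0 <- sim_config(delta = 1, delta_units = "pA", noise_sd = 0,
                     adapter_len = c(0L, 0L), scale_sd = 0, drift_sd = 0,
                     dwell = "fixed", seed = 1)
  set.seed(60)
  s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  base <- simulate_read(pm, s, cfg0, perturb = FALSE, seed = 6)
  shift <- simulate_read(pm, s, cfg0, perturb = TRUE, seed = 6)
  diff <- current_pA(shift) - current_pA(base)
  kidx <- poreclass:::.kmer_indices(s, 6)
  mask <- poreclass:::.perturb_mask(cfg0, pm)[kidx]
  per_kmer <- colMeans(matrix(diff, 9))    # fixed dwell of 9 samples
  expect_true(all(abs(per_kmer[mask] - 1) < 0.2))   # +1 pA (quantised DAC)
  expect_true(all(abs(per_kmer[!mask]) < 0.2))
})

test_that("class mean current differs in the expected direction", {
  cfg <- sim_config(n_per_class = 30, delta = 1, read_length_median = 300,
                    adapter_len = c(0L, 0L), seed = 8)
  sim <- simulate_squiggles(cfg)
  mu <- vapply(sim$squiggles, function(s) mean(current_pA(s)), numeric(1))
  lab <- sim$manifest$label
  tt <- t.test(mu[lab == "target"], mu[lab == "background"],
               alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("generated corpora have the configured composition", {
  cfg <- sim_config(n_per_class = 20, seed = 5, read_length_median = 300,
                    adapter_len = c(100L, 150L))
  sim <- simulate_squiggles(cfg)
  expect_length(sim$squiggles, 40)
  expect_equal(unname(table(sim$manifest$label)[c("background", "target")]),
               c(20L, 20L), ignore_attr = TRUE)
  expect_identical(sim$manifest$read_id,
                   vapply(sim$squiggles, `[[`, character(1), "read_id"),
                   ignore_attr = TRUE)
})

test_that("generate_dataset writes a container and manifest that round trip", {
  dir <- withr::local_tempdir()
  f5 <- file.path(dir, "corpus.fast5")
  cfg <- sim_config(n_per_class = 8, read_length_median = 250,
                    adapter_len = c(80L, 120L), seed = 6)
  out <- generate_dataset(cfg, f5)
  man <- read_manifest(out$manifest)
  expect_equal(nrow(man), 16)
  back <- read_fast5(f5)
  expect_setequal(names(back), man$read_id)
  labs <- vapply(back, `[[`, character(1), "label")
  expect_identical(unname(labs[man$read_id]), man$label)
  # regeneration with the same seed is byte-identical
  dir2 <- withr::local_tempdir()
  f5b <- file.path(dir2, "corpus.fast5")
  out2 <- generate_dataset(cfg, f5b)
  expect_identical(readLines(out$manifest), readLines(out2$manifest))
  back2 <- read_fast5(f5b)
  expect_identical(lapply(back, `[[`, "raw"), lapply(back2, `[[`, "raw"))
})

test_that("default-length corpora almost never lose reads to the window", {
  cfg <- sim_config(n_per_class = 30, seed = 9)
  sim <- simulate_squiggles(cfg)
  pp <- suppressWarnings(
    preprocess_squiggles(sim$squiggles, skip = 1500, length = 3000))
  expect_gte(nrow(pp$windows) / 60, 0.99)
})

test_that("template sequences drive the simulated reads", {
  pm <- pore_model(4, seed = 2)
  tpl <- list(strrep("ACGG", 200), strrep("TTAA", 200))
  cfg <- sim_config(n_per_class = 3, templates = tpl,
                    read_length_median = 100, adapter_len = c(0L, 0L),
                    dwell = "fixed", noise_sd = 0, seed = 4)
  sim <- simulate_squiggles(cfg, pm)
  # reads from the two classes draw on different k-mer vocabularies,
  # so their level repertoires differ systematically
  mu <- vapply(sim$squiggles, function(s) mean(current_pA(s)), numeric(1))
  lab <- sim$manifest$label
  expect_gt(abs(mean(mu[lab == "target"]) - mean(mu[lab == "background"])), 1)
})
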