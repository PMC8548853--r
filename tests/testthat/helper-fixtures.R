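# Shared fixtures, all generated in code.

# a small architecture that keeps unit tests fast
tiny_config <- function(input_length = 300L, n_classes = 2L) {
  net_config(stem_channels = 4L, stem_kernel = 9L, stem_stride = 3L,
             n_layers = 2L, blocks_per_layer = 1L, channel_growth = 1.5,
             input_length = input_length, n_classes = n_classes)
}

# a handful of short simulated squiggles for I/O tests
small_squiggles <- function(n = 6L, seed = 42L, label = TRUE) {
  cfg <- sim_config(n_per_class = ceiling(n / 2), read_length_median = 200,
                    adapter_len = c(50L, 80L), seed = seed)
  sq <- simulate_squiggles(cfg)$squiggles
  sq <- sq[seq_len(n)]
  if (!label) sq <- lapply(sq, function(s) { s$label <- NULL; s })
  sq
}

# a small labelled corpus of preprocessed windows with a strong class
# difference, for fast training tests
small_windows <- function(n_per_class = 40L, delta = 2, seed = 7L,
                          skip = 300L, length = 1500L) {
  cfg <- sim_config(n_per_class = n_per_class, delta = delta,
                    read_length_median = 400, adapter_len = c(200L, 300L),
                    seed = seed)
  sim <- simulate_squiggles(cfg)
  pp <- preprocess_squiggles(sim$squiggles, skip = skip, length = length)
  list(x = pp$windows, y = pp$labels)
}

# brute-force AUROC over all positive x negative pairs (ties count 1/2)
auroc_brute <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}
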