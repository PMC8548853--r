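# Seeded squiggle simulator.
#
# Emulates the generative physics the classifier assumes: each k-mer in
# the pore draws a characteristic current level from a k-mer pore model;
# the molecule dwells on each k-mer for a geometric number of samples
# (mean = sampling_rate / translocation speed, ~8.9 samples per base at
# 4 kHz and 450 bp/s); Gaussian pore noise rides on the levels; a noisy
# adapter-like prefix of 1000-1500 samples precedes the insert; each read
# gets its own gain/offset distortion; and the current is quantised to
# integer DAC counts with stored channel calibration. Class differences
# are injected as a level shift on a chosen k-mer subset
# (methylation-like), via different GC composition, or via different
# template sequences.

.BASES <- c("A", "C", "G", "T")

#' Random k-mer pore model
#'
#' Draws a level table covering all `4^k` k-mers, with mean currents
#' uniform in a plausible pore band (60-120 pA) and per-k-mer noise
#' standard deviations uniform in (0.5, 3) pA. Deterministic given the
#' seed.
#'
#' @param k K-mer size, 1..8 (default 6).
#' @param seed Integer seed.
#' @return An object of class `"pore_model"`: list with `k`, `kmers`,
#'   `mean` and `sd` (named numeric vectors, pA) and `seed`.
#' @examples
#' pm <- pore_model(k = 1, seed = 7)
#' pm$mean
#' @export
pore_model <- function(k = 6L, seed = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 8L) stop("'k' must be in 1..8")
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  kmers <- do.call(paste0, rev(expand.grid(rep(list(.BASES), k),
                                           stringsAsFactors = FALSE)))
  kmers <- sort(kmers)
  n <- 4L^k
  structure(list(k = k, kmers = kmers,
                 mean = stats::setNames(stats::runif(n, 60, 120), kmers),
                 sd = stats::setNames(stats::runif(n, 0.5, 3), kmers),
                 seed = as.integer(seed)),
            class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("<pore_model> k=%d (%d k-mers), levels %.1f-%.1f pA (seed %d)\n",
              x$k, length(x$mean), min(x$mean), max(x$mean), x$seed))
  invisible(x)
}

# map a sequence string to 1-based k-mer indices into the sorted table
.kmer_indices <- function(sequence, k) {
  d <- match(strsplit(toupper(sequence), "")[[1]], .BASES) - 1L
  if (anyNA(d)) stop("sequence contains non-ACGT characters")
  n <- length(d) - k + 1L
  if (n < 1L) stop(sprintf("sequence shorter than k = %d", k))
  idx <- integer(n)
  for (j in 0:(k - 1L)) idx <- idx + d[(1L + j):(n + j)] * 4L^(k - 1L - j)
  idx + 1L
}

#' Simulation parameters for synthetic squiggle corpora
#'
#' Defaults describe a realistic desk-scale MinION-like run: 450 bp/s
#' translocation sampled at 4 kHz (about 8.9 samples per base), lognormal
#' read lengths with median 1000 bases, an adapter-like high-variance
#' prefix of 1000-1500 samples, mild per-read gain/offset distortion, and
#' quantisation to DAC counts at digitisation 8192 over a 1402.882 pA
#' range. The two classes differ by a level shift `delta` applied to a
#' k-mer subset (`perturbed_kmers`, default: all k-mers containing "CG",
#' emulating a methylation-like chemical difference) in the *last* class
#' only; `delta` defaults to robust z-units of the level table
#' (1.4826 x its plain MAD, about 23 pA for the default table), the same
#' robust scale the preprocessing's modified z-score is expressed on, so
#' that a unit shift is commensurate with the level spread the per-read
#' normalization preserves.
#' Classes can alternatively differ by GC composition (`gc`) or by
#' supplying per-class `templates`.
#'
#' @param n_per_class Reads per class (default 500).
#' @param classes Class labels; >= 2 (default background/target).
#' @param delta Level shift applied to the perturbed k-mers in the last
#'   class (default 1.0).
#' @param delta_units `"zmad"` (default; multiples of the level table's
#'   robust z-unit, 1.4826 x its plain MAD — the same scale the modified
#'   z-score and outlier threshold are expressed on), `"mad"` (plain MAD
#'   multiples) or `"pA"`.
#' @param perturbed_kmers Character vector of k-mers to shift; `NULL` =
#'   all k-mers containing `"CG"`.
#' @param gc Per-class GC fraction for random template sequences.
#' @param templates Optional per-class list of template sequences
#'   (character vectors or FASTA paths, read via Biostrings) from which
#'   read fragments are drawn; overrides `gc`.
#' @param read_length_median,read_length_sdlog Lognormal read length (in
#'   bases) median and log-sd.
#' @param speed Translocation speed, bp/s (default 450).
#' @param sampling_rate Sampling frequency, Hz (default 4000).
#' @param dwell `"geometric"` (default): memoryless per-k-mer dwell with
#'   mean `sampling_rate/speed` samples; `"fixed"`: every k-mer dwells
#'   exactly `round(sampling_rate/speed)` samples (no translocation-speed
#'   jitter).
#' @param noise_sd Extra Gaussian noise on top of the per-k-mer sd, pA.
#' @param adapter_len Range (samples) of the adapter-like prefix.
#' @param adapter_mean,adapter_sd Gaussian profile of the prefix, pA; the
#'   sd is large so the prefix is uninformative noise.
#' @param scale_sd,drift_sd Per-read gain (around 1) and offset (pA)
#'   jitter.
#' @param digitisation,range_pA DAC quantisation parameters.
#' @param offset_range Integer range of per-read channel offsets (DAC).
#' @param seed Master seed.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_per_class = 500L, classes = c("background", "target"),
                       delta = 1.0, delta_units = c("zmad", "mad", "pA"),
                       perturbed_kmers = NULL, gc = NULL, templates = NULL,
                       read_length_median = 1000, read_length_sdlog = 0.25,
                       speed = 450, sampling_rate = 4000,
                       dwell = c("geometric", "fixed"), noise_sd = 1.0,
                       adapter_len = c(1000L, 1500L), adapter_mean = 90,
                       adapter_sd = 15, scale_sd = 0.02, drift_sd = 2,
                       digitisation = 8192, range_pA = 1402.882,
                       offset_range = c(0L, 30L), seed = 1L) {
  delta_units <- match.arg(delta_units)
  dwell <- match.arg(dwell)
  if (length(classes) < 2L) stop("at least 2 classes are required")
  if (anyDuplicated(classes)) stop("class labels must be unique")
  stopifnot(n_per_class >= 1L, speed > 0, sampling_rate > 0,
            read_length_median > 0, read_length_sdlog > 0, noise_sd >= 0,
            length(adapter_len) == 2L, adapter_len[1] <= adapter_len[2],
            adapter_len[1] >= 0, scale_sd >= 0, drift_sd >= 0,
            digitisation > 0, range_pA > 0, delta >= 0)
  if (is.null(gc)) gc <- rep(0.5, length(classes))
  if (length(gc) == 1L) gc <- rep(gc, length(classes))
  stopifnot(length(gc) == length(classes), all(gc > 0), all(gc < 1))
  structure(list(n_per_class = as.integer(n_per_class), classes = classes,
                 delta = delta, delta_units = delta_units,
                 perturbed_kmers = perturbed_kmers, gc = gc,
                 templates = templates,
                 read_length_median = read_length_median,
                 read_length_sdlog = read_length_sdlog, speed = speed,
                 sampling_rate = sampling_rate, dwell = dwell,
                 noise_sd = noise_sd,
                 adapter_len = as.integer(adapter_len),
                 adapter_mean = adapter_mean, adapter_sd = adapter_sd,
                 scale_sd = scale_sd, drift_sd = drift_sd,
                 digitisation = digitisation, range_pA = range_pA,
                 offset_range = as.integer(offset_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# level shift in pA implied by the config for a given pore model
.delta_pA <- function(config, pore) {
  if (config$delta == 0) return(0)
  switch(config$delta_units,
         pA = config$delta,
         mad = config$delta * .raw_mad(pore$mean),
         zmad = config$delta * 1.4826 * .raw_mad(pore$mean))
}

# logical mask over the pore-model k-mers that receive the shift
.perturb_mask <- function(config, pore) {
  km <- if (is.null(config$perturbed_kmers)) {
    pore$kmers[grepl("CG", pore$kmers, fixed = TRUE)]
  } else config$perturbed_kmers
  pore$kmers %in% km
}

#' Simulate one squiggle from a sequence
#'
#' Walks the sequence k-mer by k-mer: each k-mer contributes a geometric
#' dwell (mean `sampling_rate/speed` samples) at its pore-model level,
#' optionally shifted for perturbed k-mers, plus Gaussian noise. An
#' adapter-like noisy prefix is prepended, the per-read gain/offset
#' distortion applied, and the trace quantised to integer DAC counts with
#' stored calibration. Uses the current RNG stream unless `seed` is given.
#'
#' @param pore A [pore_model()].
#' @param sequence Character DNA string, length >= `pore$k`.
#' @param config A [sim_config()].
#' @param read_id,label Identifier and class label for the squiggle.
#' @param perturb Apply the configured k-mer level shift to this read.
#' @param seed Optional seed for a self-contained deterministic read.
#' @return A [squiggle()].
#' @export
simulate_read <- function(pore, sequence, config = sim_config(),
                          read_id = "read", label = NULL, perturb = FALSE,
                          seed = NULL) {
  stopifnot(inherits(pore, "pore_model"), inherits(config, "sim_config"))
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(seed)
  }
  idx <- .kmer_indices(sequence, pore$k)
  levels <- unname(pore$mean[idx])
  sds <- unname(pore$sd[idx])
  if (perturb && config$delta > 0) {
    mask <- .perturb_mask(config, pore)[idx]
    levels[mask] <- levels[mask] + .delta_pA(config, pore)
  }
  m <- config$sampling_rate / config$speed          # mean dwell, samples
  dwell <- if (config$dwell == "fixed") rep.int(as.integer(round(m)), length(idx))
  else 1L + stats::rgeom(length(idx), prob = min(1, 1 / m))
  total <- sum(dwell)
  sig <- rep.int(levels, dwell) +
    stats::rnorm(total, 0, sqrt(rep.int(sds, dwell)^2 + config$noise_sd^2))
  if (config$adapter_len[2] > 0L) {
    alen <- if (config$adapter_len[1] == config$adapter_len[2])
      config$adapter_len[1]
    else sample(config$adapter_len[1]:config$adapter_len[2], 1L)
    sig <- c(stats::rnorm(alen, config$adapter_mean, config$adapter_sd), sig)
  }
  gain <- stats::rnorm(1, 1, config$scale_sd)
  drift <- stats::rnorm(1, 0, config$drift_sd)
  sig <- gain * sig + drift
  off <- sample(config$offset_range[1]:config$offset_range[2], 1L)
  raw <- as.integer(round(sig * config$digitisation / config$range_pA - off))
  squiggle(read_id, raw, offset = off, range_pA = config$range_pA,
           digitisation = config$digitisation,
           sampling_rate = config$sampling_rate, label = label)
}

# random DNA of n bases at a given GC fraction
.random_seq <- function(n, gc) {
  paste(sample(.BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# resolve per-class template pools: character vector of sequences or NULL
.resolve_templates <- function(templates, n_classes) {
  if (is.null(templates)) return(NULL)
  if (length(templates) != n_classes)
    stop("'templates' must supply one entry per class")
  lapply(templates, function(tp) {
    if (length(tp) == 1L && file.exists(tp)) {
      if (!requireNamespace("Biostrings", quietly = TRUE))
        stop("reading FASTA templates requires the Biostrings package")
      as.character(Biostrings::readDNAStringSet(tp))
    } else as.character(tp)
  })
}

#' Simulate a labelled two-class (or multi-class) squiggle corpus
#'
#' Generates `n_per_class` reads per class with lognormal read lengths,
#' drawing template sequences at the configured GC fraction (or fragments
#' of supplied templates). The k-mer level shift `delta` is applied to the
#' last class. Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param pore A [pore_model()]; default is `pore_model(6, config$seed)`.
#' @return A list with `squiggles` (named list of [squiggle()]) and
#'   `manifest` (data.frame `read_id`, `label`, `source_file` = "memory").
#' @seealso [generate_dataset()] to also write the FAST5 container and
#'   manifest to disk.
#' @export
simulate_squiggles <- function(config = sim_config(), pore = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(pore)) pore <- pore_model(6L, config$seed)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)
  tpl <- .resolve_templates(config$templates, length(config$classes))
  sq <- list()
  for (ci in seq_along(config$classes)) {
    cl <- config$classes[ci]
    perturb <- (ci == length(config$classes))
    for (i in seq_len(config$n_per_class)) {
      n_bases <- max(pore$k, round(stats::rlnorm(
        1, log(config$read_length_median), config$read_length_sdlog)))
      s <- if (!is.null(tpl)) {
        src <- tpl[[ci]][sample.int(length(tpl[[ci]]), 1L)]
        if (nchar(src) <= n_bases) src
        else substr(src, st <- sample.int(nchar(src) - n_bases, 1L),
                    st + n_bases - 1L)
      } else .random_seq(n_bases, config$gc[ci])
      rid <- sprintf("%s_%05d", cl, i)
      sq[[rid]] <- simulate_read(pore, s, config, read_id = rid, label = cl,
                                 perturb = perturb)
    }
  }
  manifest <- data.frame(
    read_id = names(sq),
    label = vapply(sq, `[[`, character(1), "label"),
    source_file = "memory", row.names = NULL, stringsAsFactors = FALSE)
  list(squiggles = sq, manifest = manifest)
}

#' Generate a synthetic corpus on disk
#'
#' Runs [simulate_squiggles()] and writes the reads to a multi-read FAST5
#' container plus a TSV label manifest. Regeneration with the same config
#' yields a byte-identical manifest and identical raw signal.
#'
#' @param config A [sim_config()].
#' @param fast5 Output container path.
#' @param manifest Output manifest TSV path (default: alongside `fast5`).
#' @param pore A [pore_model()]; default `pore_model(6, config$seed)`.
#' @return Invisibly, a list with `fast5`, `manifest` (paths) and the
#'   manifest data.frame.
#' @export
generate_dataset <- function(config = sim_config(), fast5,
                             manifest = paste0(fast5, ".manifest.tsv"),
                             pore = NULL) {
  sim <- simulate_squiggles(config, pore)
  write_fast5(sim$squiggles, fast5)
  mf <- sim$manifest
  mf$source_file <- basename(fast5)
  write_manifest(mf, manifest)
  invisible(list(fast5 = fast5, manifest = manifest, table = mf))
}
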