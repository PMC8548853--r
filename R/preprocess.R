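# Robust preprocessing of raw signal windows.
#
# A read is reduced to the fixed-length window the classifier consumes:
# the adapter-dominated prefix is skipped, `length` samples are kept,
# extreme samples (modified z-score > threshold) are replaced by their
# nearest clean neighbours, and the repaired window is centred/scaled by
# its median and median absolute deviation.

# plain (unscaled) median absolute deviation, median(|x - median(x)|)
.raw_mad <- function(x) stats::median(abs(x - stats::median(x)))

# Iglewicz-Hoaglin consistency constant for the modified z-score
.MODZ_CONST <- 0.6745

#' Extract the classification window from a raw signal
#'
#' Drops the first `skip` samples (adapter / pore-noise overestimate; 1500
#' for training corpora, 1000 is enough at inference time) and returns the
#' next `length` samples. A read too short to supply the full window is
#' excluded: `NULL` is returned with a warning, which batch drivers record
#' as an exclusion rather than an error.
#'
#' @param signal Numeric vector of raw samples.
#' @param skip Number of leading samples to discard (default 1500).
#' @param length Window length to keep (default 3000).
#' @return Numeric vector of `length` samples, or `NULL` if the read is too
#'   short.
#' @examples
#' w <- trim_window(seq_len(6000), skip = 1500, length = 3000)
#' range(w)  # samples 1501..4500 (1-based)
#' @export
trim_window <- function(signal, skip = 1500L, length = 3000L) {
  skip <- as.integer(skip); length <- as.integer(length)
  stopifnot(skip >= 0L, length >= 1L)
  if (base::length(signal) < skip + length) {
    warning(sprintf("read excluded: %d samples < skip (%d) + window (%d)",
                    base::length(signal), skip, length))
    return(NULL)
  }
  signal[(skip + 1L):(skip + length)]
}

#' Replace extreme samples by their nearest clean neighbours
#'
#' Flags every sample whose modified z-score
#' `0.6745 * |x - median(x)| / MAD(x)` exceeds `threshold` (3.5 by default)
#' and replaces it with the mean of the nearest non-flagged sample on each
#' side (a single neighbour at the window edges). Runs of consecutive
#' flagged samples all resolve to the same flanking clean values. The
#' flagging statistics are computed once on the input window.
#'
#' @param window Numeric vector, length >= 3.
#' @param threshold Modified z-score cutoff (default 3.5).
#' @return A list with `values` (repaired window) and `n_replaced`.
#' @examples
#' replace_outliers(c(8, 9, 10, 11, 12, 100, 12, 11, 10, 9))
#' @export
replace_outliers <- function(window, threshold = 3.5) {
  stopifnot(is.numeric(window), length(window) >= 3L)
  med <- stats::median(window)
  mad <- .raw_mad(window)
  if (mad <= 0)
    stop("degenerate signal: median absolute deviation is zero")
  bad <- (.MODZ_CONST * abs(window - med) / mad) > threshold
  n_bad <- sum(bad)
  if (n_bad == 0L)
    return(list(values = window, n_replaced = 0L))
  if (all(bad))
    stop("degenerate signal: every sample flagged as an outlier")
  good_idx <- which(!bad)
  out <- window
  for (i in which(bad)) {
    left <- good_idx[good_idx < i]
    right <- good_idx[good_idx > i]
    neigh <- c(if (length(left)) window[max(left)],
               if (length(right)) window[min(right)])
    out[i] <- mean(neigh)
  }
  list(values = out, n_replaced = as.integer(n_bad))
}

#' Normalize a window by its median and median absolute deviation
#'
#' Computes `(x - median(x)) / MAD(x)` with the plain (unscaled) MAD,
#' `median(|x - median(x)|)`. The result has median 0 and MAD 1 and is
#' invariant to any per-read affine distortion `a*x + b` (a > 0), which is
#' what removes channel-to-channel gain and offset drift.
#'
#' @param window Numeric vector with positive MAD.
#' @return A list with `values` (normalized window), `median` and `mad`
#'   (the statistics used).
#' @examples
#' mad_normalize(c(1, 2, 3, 4, 5))$values
#' @export
mad_normalize <- function(window) {
  stopifnot(is.numeric(window), length(window) >= 2L)
  med <- stats::median(window)
  mad <- .raw_mad(window)
  if (mad <= 0)
    stop("degenerate signal: median absolute deviation is zero")
  list(values = (window - med) / mad, median = med, mad = mad)
}

#' Preprocess one read into a normalized window
#'
#' Composition of [trim_window()], [replace_outliers()] and
#' [mad_normalize()], in that order; the normalization statistics are
#' recomputed on the repaired window. By default the raw DAC readings are
#' converted to picoamperes first; because MAD normalization is affine
#' invariant, classifying in DAC units instead (`use_pA = FALSE`) gives the
#' same windows up to floating-point noise.
#'
#' @param x A [squiggle()] or a numeric signal vector.
#' @param skip,length Window placement, see [trim_window()].
#' @param threshold Outlier cutoff, see [replace_outliers()].
#' @param use_pA Convert DAC readings to pA before normalizing (default
#'   TRUE; ignored for plain numeric input).
#' @return An object of class `"normalized_window"`: list with `values`
#'   (length-`length` numeric), `read_id`, and `stats` (`median`, `mad`,
#'   `n_outliers_replaced`); or `NULL` (with a warning) if the read is too
#'   short.
#' @export
preprocess_read <- function(x, skip = 1500L, length = 3000L, threshold = 3.5,
                            use_pA = TRUE) {
  if (inherits(x, "squiggle")) {
    sig <- if (use_pA) current_pA(x) else as.numeric(x$raw)
    rid <- x$read_id
  } else {
    sig <- as.numeric(x)
    rid <- NA_character_
  }
  w <- trim_window(sig, skip, length)
  if (is.null(w)) return(NULL)
  rep <- replace_outliers(w, threshold)
  nrm <- mad_normalize(rep$values)
  structure(list(values = nrm$values, read_id = rid,
                 stats = list(median = nrm$median, mad = nrm$mad,
                              n_outliers_replaced = rep$n_replaced)),
            class = "normalized_window")
}

#' Preprocess a batch of squiggles into a window matrix
#'
#' Applies [preprocess_read()] to every squiggle, collecting the surviving
#' windows into a matrix (one row per read) and reporting excluded reads
#' with their reasons instead of failing the batch.
#'
#' @inheritParams preprocess_read
#' @param squiggles List of [squiggle()] objects.
#' @return A list with:
#'   \describe{
#'     \item{windows}{numeric matrix, reads x `length`, rownames = read ids}
#'     \item{labels}{character vector of labels (NA where absent)}
#'     \item{stats}{data.frame of per-read `median`, `mad`, `n_outliers_replaced`}
#'     \item{excluded}{data.frame of `read_id`, `reason` for dropped reads}
#'   }
#' @export
preprocess_squiggles <- function(squiggles, skip = 1500L, length = 3000L,
                                 threshold = 3.5, use_pA = TRUE) {
  stopifnot(base::length(squiggles) > 0L)
  rows <- vector("list", base::length(squiggles))
  labs <- character(0); ids <- character(0)
  st <- list(); excl_id <- character(0); excl_why <- character(0)
  n_kept <- 0L
  for (sq in squiggles) {
    nw <- withCallingHandlers(
      tryCatch(preprocess_read(sq, skip, length, threshold, use_pA),
               error = function(e) structure(conditionMessage(e), class = "pp_err")),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(nw) || inherits(nw, "pp_err")) {
      excl_id <- c(excl_id, sq$read_id)
      excl_why <- c(excl_why, if (is.null(nw))
        sprintf("too short (%d samples < %d)", base::length(sq$raw),
                skip + length) else as.character(nw))
      next
    }
    n_kept <- n_kept + 1L
    rows[[n_kept]] <- nw$values
    ids <- c(ids, sq$read_id)
    labs <- c(labs, if (is.null(sq$label)) NA_character_ else sq$label)
    st[[n_kept]] <- nw$stats
  }
  windows <- if (n_kept)
    matrix(unlist(rows[seq_len(n_kept)]), nrow = n_kept, byrow = TRUE,
           dimnames = list(ids, NULL))
  else matrix(numeric(0), 0L, length)
  stats_df <- if (n_kept)
    data.frame(read_id = ids,
               median = vapply(st, `[[`, numeric(1), "median"),
               mad = vapply(st, `[[`, numeric(1), "mad"),
               n_outliers_replaced =
                 vapply(st, `[[`, integer(1), "n_outliers_replaced"))
  else data.frame(read_id = character(0), median = numeric(0),
                  mad = numeric(0), n_outliers_replaced = integer(0))
  list(windows = windows, labels = labs, stats = stats_df,
       excluded = data.frame(read_id = excl_id, reason = excl_why,
                             stringsAsFactors = FALSE))
}
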