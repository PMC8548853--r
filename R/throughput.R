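# Read-Until enrichment model.
#
# Compares the expected sequencing cost (total bases and wall time) of
# collecting a fixed number of target reads with and without
# classifier-driven ejection. Reads are target with probability c; the
# classifier sees speed*(t_signal + t_decide) bases of a read before
# deciding ("decision-point bases" b_d); an ejected read costs exactly b_d
# bases while a sequenced read costs its full length. Ejection frees the
# pore after an additional recapture wait t_eject, and the decision
# latency t_decide is charged to the Read-Until arm as pore time (the
# conservative accounting). All expectations depend on read lengths only
# through their means, which the Monte-Carlo oracle confirms.

#' Parameters of the Read-Until throughput model
#'
#' @param zbar Mean target read length, bases (default 3000).
#' @param hbar Mean non-target read length, bases (default 20 * `zbar`).
#' @param c Target concentration: fraction of captured reads that are
#'   target (default 0.1).
#' @param tpr,tnr Classifier true positive / true negative rates
#'   (default 0.9 each).
#' @param speed Sequencing speed, bp/s (default 450).
#' @param pores Active pores in the flow cell (default 500).
#' @param t_signal Seconds of signal consumed before classification
#'   (default 1.0).
#' @param t_decide Classification latency, seconds (default 0.8).
#' @param t_eject Eject-and-recapture wait, seconds (default 0.5).
#' @param n_targets Target reads required (default 1000; the gain ratios
#'   do not depend on it).
#' @return An object of class `"throughput_params"`.
#' @export
throughput_params <- function(zbar = 3000, hbar = 20 * zbar, c = 0.1,
                              tpr = 0.9, tnr = 0.9, speed = 450,
                              pores = 500, t_signal = 1.0, t_decide = 0.8,
                              t_eject = 0.5, n_targets = 1000) {
  stopifnot(zbar > 0, hbar > 0, speed > 0, pores > 0, n_targets > 0,
            c > 0, c <= 1, tpr >= 0, tpr <= 1, tnr >= 0, tnr <= 1,
            t_signal >= 0, t_decide >= 0, t_eject >= 0)
  structure(list(zbar = zbar, hbar = hbar, c = c, tpr = tpr, tnr = tnr,
                 speed = speed, pores = pores, t_signal = t_signal,
                 t_decide = t_decide, t_eject = t_eject,
                 n_targets = n_targets),
            class = "throughput_params")
}

#' Expected sequencing cost with and without Read-Until
#'
#' Closed-form expectations. Without Read-Until, `n_targets / c` reads are
#' needed and each costs its full length, so
#' `bases_without = (n_targets/c) * (c*zbar + (1-c)*hbar)`. With
#' Read-Until only accepted targets count, so `n_targets / (c*tpr)` reads
#' are needed; a read costs its full length if sequenced and the
#' decision-point bases `b_d = speed*(t_signal + t_decide)` if ejected:
#' `bases_with = (n_targets/(c*tpr)) * (c*(tpr*zbar + (1-tpr)*b_d) +
#' (1-c)*((1-tnr)*hbar + tnr*b_d))`. Times divide bases across
#' `speed * pores`, and the Read-Until arm additionally pays `t_eject` per
#' ejected read and `t_decide` per read, spread across the pores. Gains
#' are the without/with ratios.
#'
#' @param params A [throughput_params()].
#' @return An object of class `"throughput_result"`: list with
#'   `bases_without`, `bases_with`, `time_without`, `time_with` (seconds),
#'   `bases_gain`, `time_gain`, `reads_without`, `reads_with`, `b_d`, and
#'   the `params` used.
#' @examples
#' expected_totals(throughput_params())   # the headline ~10x regime
#' @export
expected_totals <- function(params = throughput_params()) {
  stopifnot(inherits(params, "throughput_params"))
  p <- params
  if (p$tpr <= 0)
    stop("infeasible: tpr = 0 means target reads are never accepted")
  b_d <- p$speed * (p$t_signal + p$t_decide)
  reads_wo <- p$n_targets / p$c
  bases_wo <- reads_wo * (p$c * p$zbar + (1 - p$c) * p$hbar)
  reads_w <- p$n_targets / (p$c * p$tpr)
  per_read_w <- p$c * (p$tpr * p$zbar + (1 - p$tpr) * b_d) +
    (1 - p$c) * ((1 - p$tnr) * p$hbar + p$tnr * b_d)
  bases_w <- reads_w * per_read_w
  ejected <- reads_w * (p$c * (1 - p$tpr) + (1 - p$c) * p$tnr)
  time_wo <- bases_wo / (p$speed * p$pores)
  time_w <- bases_w / (p$speed * p$pores) +
    (p$t_eject * ejected + p$t_decide * reads_w) / p$pores
  structure(list(bases_without = bases_wo, bases_with = bases_w,
                 time_without = time_wo, time_with = time_w,
                 bases_gain = bases_wo / bases_w,
                 time_gain = time_wo / time_w,
                 reads_without = reads_wo, reads_with = reads_w,
                 b_d = b_d, params = p),
            class = "throughput_result")
}

#' @export
print.throughput_result <- function(x, ...) {
  p <- x$params
  cat(sprintf("Read-Until throughput model (zbar %g bp, hbar %g bp, c %g, TPR %g, TNR %g, t_eject %g s)\n",
              p$zbar, p$hbar, p$c, p$tpr, p$tnr, p$t_eject))
  cat(sprintf("  bases: %.3e without vs %.3e with  -> gain %.2fx\n",
              x$bases_without, x$bases_with, x$bases_gain))
  cat(sprintf("  time:  %.3e s without vs %.3e s with -> gain %.2fx\n",
              x$time_without, x$time_with, x$time_gain))
  invisible(x)
}

#' Throughput gains over a grid of length ratios and concentrations
#'
#' Evaluates [expected_totals()] element-wise over an
#' `hbar/zbar` ratio axis and a target-concentration axis.
#'
#' @param params Base [throughput_params()]; `hbar` is overridden per
#'   cell as `ratio * zbar`, `c` per cell from `concentrations`.
#' @param ratios Ascending vector of non-target/target length ratios.
#' @param concentrations Ascending vector of target concentrations.
#' @return Long-format data.frame: `ratio`, `c`, `bases_without`,
#'   `bases_with`, `time_without`, `time_with`, `bases_gain`, `time_gain`.
#' @export
throughput_grid <- function(params = throughput_params(), ratios,
                            concentrations) {
  stopifnot(length(ratios) >= 1L, length(concentrations) >= 1L,
            all(is.finite(ratios)), all(is.finite(concentrations)),
            all(ratios > 0), !is.unsorted(ratios, strictly = TRUE),
            all(concentrations > 0), all(concentrations <= 1),
            !is.unsorted(concentrations, strictly = TRUE))
  cells <- expand.grid(ratio = ratios, c = concentrations)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    p <- params
    p$hbar <- cells$ratio[i] * p$zbar
    p$c <- cells$c[i]
    r <- expected_totals(p)
    data.frame(ratio = cells$ratio[i], c = cells$c[i],
               bases_without = r$bases_without, bases_with = r$bases_with,
               time_without = r$time_without, time_with = r$time_with,
               bases_gain = r$bases_gain, time_gain = r$time_gain)
  })
  do.call(rbind, rows)
}

#' Monte-Carlo oracle for the throughput model
#'
#' Simulates individual reads — Bernoulli(`c`) target status, exponential
#' lengths at the configured means, Bernoulli classifier decisions — under
#' the same cost accounting as [expected_totals()] and estimates the gains
#' with batch-means standard errors. Serves as an independent check of the
#' closed form.
#'
#' @param params A [throughput_params()].
#' @param n_reads Number of simulated reads (default 200000).
#' @param seed Integer seed.
#' @param n_batches Batches for the batch-means standard errors.
#' @return A list with `bases_gain`, `time_gain`, their standard errors
#'   `bases_gain_se`, `time_gain_se`, the per-target cost estimates, and
#'   `n_reads`.
#' @export
throughput_mc <- function(params = throughput_params(), n_reads = 2e5,
                          seed = 1L, n_batches = 50L) {
  stopifnot(inherits(params, "throughput_params"), n_reads >= 1)
  p <- params
  if (p$tpr <= 0) stop("infeasible: tpr = 0 means target reads are never accepted")
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  b_d <- p$speed * (p$t_signal + p$t_decide)
  is_t <- stats::runif(n_reads) < p$c
  len <- ifelse(is_t, stats::rexp(n_reads, 1 / p$zbar),
                stats::rexp(n_reads, 1 / p$hbar))
  u <- stats::runif(n_reads)
  keep <- ifelse(is_t, u < p$tpr, u >= p$tnr)   # sequenced to full length
  accepted <- is_t & keep
  cost_wo <- len
  cost_w <- ifelse(keep, len, b_d)
  time_w_read <- cost_w / (p$speed * p$pores) +
    (p$t_eject * (!keep) + p$t_decide) / p$pores
  time_wo_read <- cost_wo / (p$speed * p$pores)

  grp <- rep(seq_len(n_batches), length.out = n_reads)
  batch_gain <- function(num, den_flag, nmr2, den2_flag) {
    gb <- numeric(n_batches)
    for (b in seq_len(n_batches)) {
      s <- grp == b
      gb[b] <- (sum(num[s]) / sum(den_flag[s])) /
        (sum(nmr2[s]) / sum(den2_flag[s]))
    }
    gb
  }
  gb_bases <- batch_gain(cost_wo, is_t, cost_w, accepted)
  gb_time <- batch_gain(time_wo_read, is_t, time_w_read, accepted)
  list(bases_gain = mean(gb_bases),
       bases_gain_se = stats::sd(gb_bases) / sqrt(n_batches),
       time_gain = mean(gb_time),
       time_gain_se = stats::sd(gb_time) / sqrt(n_batches),
       bases_without_per_target = sum(cost_wo) / sum(is_t),
       bases_with_per_target = sum(cost_w) / sum(accepted),
       n_reads = n_reads)
}
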