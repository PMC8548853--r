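# Inference over read sets and the evaluation metric suite.

#' Classify raw reads end to end
#'
#' Preprocesses each squiggle ([preprocess_read()]: trim, outlier repair,
#' MAD normalization) and runs the fitted classifier over the surviving
#' windows in batches. Reads too short for the window (or otherwise
#' degenerate) are reported as exclusions with a reason instead of failing
#' the batch. At inference time a smaller adapter skip (1000 samples) is
#' sufficient, letting the decision happen earlier in the read.
#'
#' @param object A fitted [porenet()] model.
#' @param squiggles List of [squiggle()] objects.
#' @param skip Leading samples to discard (default 1000).
#' @param threshold Outlier repair cutoff (default 3.5).
#' @param use_pA Convert to picoamperes before normalizing (default TRUE).
#' @return A list with `predictions` (data.frame: `read_id`, one `p_<class>`
#'   probability column per class, `pred`, `truth` — `NA` where the squiggle
#'   carried no label) and `excluded` (data.frame: `read_id`, `reason`).
#' @export
classify_reads <- function(object, squiggles, skip = 1000L, threshold = 3.5,
                           use_pA = TRUE) {
  stopifnot(inherits(object, "porenet"))
  L <- object$net$config$input_length
  pp <- preprocess_squiggles(squiggles, skip = skip, length = L,
                             threshold = threshold, use_pA = use_pA)
  if (nrow(pp$windows) == 0L)
    stop("no classifiable reads: every read was excluded")
  probs <- predict(object, pp$windows, type = "prob")
  pred <- object$classes[max.col(probs, ties.method = "first")]
  out <- data.frame(read_id = rownames(pp$windows), probs,
                    pred = pred, truth = pp$labels,
                    row.names = NULL, check.names = FALSE)
  names(out)[1L + seq_along(object$classes)] <- paste0("p_", object$classes)
  list(predictions = out, excluded = pp$excluded)
}

#' Area under the ROC curve (rank statistic)
#'
#' AUROC computed as the Mann-Whitney rank statistic: the probability that
#' a uniformly random positive read receives a higher score than a
#' uniformly random negative read, with ties counted one half.
#'
#' @param scores Numeric score for the positive class.
#' @param positive Logical vector (TRUE = positive) of the same length.
#' @return AUROC in `[0, 1]`; `NA` if either class is absent.
#' @export
auroc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), is.logical(positive))
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Classification metric suite
#'
#' Confusion counts and the derived metric suite — accuracy, true positive
#' rate (recall), true negative rate, precision and AUROC — for a set of
#' predictions, with one class designated as the target (positive). Metrics
#' whose denominator is empty (e.g. TPR when no positive reads are present)
#' are reported as `NA`, not 0.
#'
#' @param predictions The `predictions` data.frame from [classify_reads()]
#'   (or any data.frame with `pred`, `truth` and a `p_<positive_class>`
#'   column), or the list returned by [classify_reads()].
#' @param positive_class The target class. Defaults to `"target"` when that
#'   label is present, otherwise to the last class in sorted order.
#' @return An object of class `"class_metrics"`: list with `accuracy`,
#'   `tpr`, `tnr`, `precision`, `auroc`, the counts `tp`, `fp`, `tn`, `fn`,
#'   and `positive_class`.
#' @examples
#' df <- data.frame(pred = c("t","t","b"), truth = c("t","b","b"),
#'                  p_t = c(.9, .6, .2))
#' compute_metrics(df, positive_class = "t")
#' @export
compute_metrics <- function(predictions, positive_class = NULL) {
  if (is.list(predictions) && !is.data.frame(predictions) &&
      !is.null(predictions$predictions))
    predictions <- predictions$predictions
  stopifnot(is.data.frame(predictions),
            all(c("pred", "truth") %in% names(predictions)))
  if (anyNA(predictions$truth))
    stop("every prediction needs a true label to compute metrics")
  classes <- sort(unique(c(predictions$truth, predictions$pred)))
  if (is.null(positive_class))
    positive_class <- if ("target" %in% classes) "target" else classes[length(classes)]
  pos_t <- predictions$truth == positive_class
  pos_p <- predictions$pred == positive_class
  tp <- sum(pos_t & pos_p);  fn <- sum(pos_t & !pos_p)
  fp <- sum(!pos_t & pos_p); tn <- sum(!pos_t & !pos_p)
  sc_col <- paste0("p_", positive_class)
  auc <- if (sc_col %in% names(predictions))
    auroc(predictions[[sc_col]], pos_t) else NA_real_
  div <- function(a, b) if (b > 0) a / b else NA_real_
  structure(list(accuracy = div(tp + tn, tp + tn + fp + fn),
                 tpr = div(tp, tp + fn), tnr = div(tn, tn + fp),
                 precision = div(tp, tp + fp), auroc = auc,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 positive_class = positive_class),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("Classification metrics (positive class: %s)\n", x$positive_class))
  cat(sprintf("  accuracy %.4f | TPR %.4f | TNR %.4f | precision %.4f | AUROC %.4f\n",
              x$accuracy, x$tpr, x$tnr, x$precision, x$auroc))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Accuracy broken down by read group
#'
#' Per-group accuracy (e.g. per species, per barcode) for a prediction
#' table. Every read must be mapped by the grouping; unmapped reads are a
#' validation error naming the offending ids.
#'
#' @param predictions As in [compute_metrics()]; needs a `read_id` column.
#' @param grouping Named character vector (`names` = read ids) or a
#'   data.frame with `read_id` and `group` columns.
#' @return Data.frame with columns `group`, `n`, `accuracy`, sorted by
#'   group label.
#' @export
accuracy_by_group <- function(predictions, grouping) {
  if (is.list(predictions) && !is.data.frame(predictions) &&
      !is.null(predictions$predictions))
    predictions <- predictions$predictions
  stopifnot(is.data.frame(predictions),
            all(c("read_id", "pred", "truth") %in% names(predictions)))
  if (is.data.frame(grouping)) {
    stopifnot(all(c("read_id", "group") %in% names(grouping)))
    grouping <- stats::setNames(as.character(grouping$group), grouping$read_id)
  }
  miss <- setdiff(predictions$read_id, names(grouping))
  if (length(miss))
    stop(sprintf("grouping does not map read id(s): %s",
                 paste(utils::head(miss, 10L), collapse = ", ")))
  grp <- grouping[predictions$read_id]
  correct <- predictions$pred == predictions$truth
  agg <- tapply(correct, grp, function(z) c(n = length(z), acc = mean(z)))
  out <- data.frame(group = names(agg),
                    n = vapply(agg, `[[`, numeric(1), "n"),
                    accuracy = vapply(agg, `[[`, numeric(1), "acc"),
                    row.names = NULL)
  out[order(out$group), , drop = FALSE]
}
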