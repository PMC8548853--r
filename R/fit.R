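# Model fitting: dataset splitting and the Adam training loop.

#' Training hyperparameters
#'
#' Defaults follow the published recipe for full-scale corpora: Adam with
#' learning rate 1e-3, minibatches of 1000 reads, 6 epochs. For the small
#' simulated corpora used in examples and tests a smaller batch (more
#' updates per epoch) and fewer epochs are appropriate.
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Reads per minibatch (default 1000).
#' @param epochs Training epochs (default 6).
#' @param seed Seed controlling shuffling (and the validation carve-out
#'   when no validation set is supplied).
#' @param val_fraction Fraction of the training data held out for
#'   validation when `x_val` is not given to [porenet()] (default 0.1).
#' @param device Informational device hint; only `"cpu"` is implemented.
#' @return An object of class `"train_control"`.
#' @export
train_control <- function(learning_rate = 1e-3, batch_size = 1000L,
                          epochs = 6L, seed = 1L, val_fraction = 0.1,
                          device = "cpu") {
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 1L,
            val_fraction > 0, val_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 val_fraction = val_fraction, device = device),
            class = "train_control")
}

#' Stratified train/validation/test split of a read manifest
#'
#' Splits the rows of a manifest (or any data.frame with `read_id` and
#' `label` columns) into disjoint, exhaustive, label-stratified subsets.
#' Within each class, reads are shuffled deterministically by `seed` and
#' allocated by largest-remainder rounding, so class proportions are
#' preserved to within one read.
#'
#' @param manifest Data.frame with at least `read_id` and `label` columns.
#' @param fractions Numeric length-3 vector (train, validation, test),
#'   positive, summing to 1.
#' @param seed Integer seed.
#' @return Named list of three data.frames (`train`, `val`, `test`).
#' @export
make_splits <- function(manifest, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(is.data.frame(manifest),
            all(c("read_id", "label") %in% names(manifest)),
            length(fractions) == 3L, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  parts <- list(integer(0), integer(0), integer(0))
  for (cl in sort(unique(manifest$label))) {
    rows <- which(manifest$label == cl)
    rows <- rows[sample.int(length(rows))]
    n <- length(rows)
    base <- floor(n * fractions)
    rem <- n * fractions - base
    extra <- order(rem, decreasing = TRUE)[seq_len(n - sum(base))]
    counts <- base
    counts[extra] <- counts[extra] + 1L
    if (any(counts < 1L))
      stop(sprintf("class '%s' (%d reads) cannot populate every split at fractions %s",
                   cl, n, paste(fractions, collapse = "/")))
    idx <- split(rows, rep.int(1:3, counts))
    for (s in 1:3) parts[[s]] <- c(parts[[s]], idx[[as.character(s)]])
  }
  out <- lapply(parts, function(p) manifest[sort(p), , drop = FALSE])
  names(out) <- c("train", "val", "test")
  out
}

#' Fit the raw-signal read classifier
#'
#' Trains the 1D bottleneck residual network on preprocessed, fixed-length
#' normalized signal windows by minimising the (multi-class) cross-entropy
#' with Adam. Minibatch shuffling is reseeded per epoch from
#' `control$seed`, so a fit is fully reproducible on one device. After
#' every epoch the validation loss and accuracy are recorded and the
#' parameters with the best validation accuracy (ties broken by lower
#' validation loss) are retained as the fitted model.
#'
#' @param x Numeric matrix of training windows, reads x samples (as
#'   produced by [preprocess_squiggles()]).
#' @param y Class labels (factor or character/integer vector, >= 2 levels).
#' @param config A [net_config()]; its `input_length` must equal `ncol(x)`.
#' @param control A [train_control()].
#' @param x_val,y_val Optional validation windows/labels. When absent, a
#'   stratified `control$val_fraction` of `x` is held out.
#' @param init_seed Seed for weight initialisation (default
#'   `control$seed`).
#' @param verbose Print one line per epoch.
#' @return An object of class `"porenet"` with components `net` (the
#'   fitted [build_net()] network), `classes`, `history` (per-epoch
#'   data.frame), `best_epoch`, `control` and `call`. Supports `print`,
#'   `summary`, `predict`, `coef` and `plot`.
#' @seealso [predict.porenet()], [classify_reads()]
#' @export
porenet <- function(x, y, config = NULL, control = train_control(),
                    x_val = NULL, y_val = NULL, init_seed = NULL,
                    verbose = FALSE) {
  if (is.null(dim(x)) || nrow(x) < 1L) stop("'x' must be a non-empty matrix of windows")
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  yf <- factor(y)
  classes <- levels(yf)
  if (length(classes) < 2L) stop("training data must contain at least 2 classes")
  if (is.null(config)) config <- net_config(input_length = ncol(x),
                                            n_classes = length(classes))
  stopifnot(inherits(config, "net_config"), inherits(control, "train_control"))
  if (config$input_length != ncol(x))
    stop(sprintf("config input_length (%d) != window length (%d)",
                 config$input_length, ncol(x)))
  if (config$n_classes != length(classes))
    stop(sprintf("config n_classes (%d) != observed classes (%d)",
                 config$n_classes, length(classes)))
  yi <- as.integer(yf)

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)

  if (is.null(x_val)) {
    set.seed(control$seed)
    hold <- unlist(lapply(split(seq_along(yi), yi), function(ix) {
      n_h <- max(1L, round(length(ix) * control$val_fraction))
      sample(ix, n_h)
    }), use.names = FALSE)
    x_val <- x[hold, , drop = FALSE]; yv <- yi[hold]
    x <- x[-hold, , drop = FALSE]; yi <- yi[-hold]
  } else {
    if (is.null(y_val) || nrow(x_val) != length(y_val))
      stop("'x_val' requires matching 'y_val'")
    yv <- as.integer(factor(y_val, levels = classes))
    if (anyNA(yv)) stop("validation labels outside the training classes")
  }
  if (nrow(x) < 1L) stop("empty training set after validation carve-out")

  net <- build_net(config, seed = if (is.null(init_seed)) control$seed else init_seed)
  opt <- .adam_init(net$params)
  n <- nrow(x)
  bs <- min(control$batch_size, n)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_accuracy = numeric(0),
                        seconds = numeric(0))
  best <- list(acc = -Inf, loss = Inf, params = net$params,
               buffers = net$buffers, epoch = 0L)

  for (ep in seq_len(control$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    set.seed(control$seed + ep)
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / bs))
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      ix <- batches[[bi]]
      mb <- .windows_to_batch(x[ix, , drop = FALSE], config$input_length)
      fwd <- .net_apply(net, mb$X, mb$B, train = TRUE, with_cache = TRUE)
      net$buffers <- fwd$buffers
      loss <- .ce_loss(fwd$probs, yi[ix])
      if (!is.finite(loss))
        stop(sprintf("non-finite training loss (%g) at epoch %d batch %d; try a lower learning rate",
                     loss, ep, bi))
      ep_loss <- ep_loss + loss * length(ix)
      bwd <- .net_backward(net, fwd$caches, .ce_grad(fwd$probs, yi[ix]))
      upd <- .adam_step(net$params, bwd$grads, opt, control$learning_rate)
      net$params <- upd$params
      opt <- upd$state
    }
    val <- .eval_batches(net, x_val, yv)
    history <- rbind(history, data.frame(
      epoch = ep, train_loss = ep_loss / n, val_loss = val$loss,
      val_accuracy = val$accuracy,
      seconds = proc.time()[["elapsed"]] - t0))
    if (val$accuracy > best$acc ||
        (val$accuracy == best$acc && val$loss < best$loss)) {
      best <- list(acc = val$accuracy, loss = val$loss, params = net$params,
                   buffers = net$buffers, epoch = ep)
    }
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f, val loss %.4f, val acc %.3f (%.1fs)",
                      ep, ep_loss / n, val$loss, val$accuracy,
                      history$seconds[ep]))
  }
  net$params <- best$params
  net$buffers <- best$buffers
  structure(list(net = net, classes = classes, control = control,
                 history = history, best_epoch = best$epoch,
                 call = match.call()),
            class = "porenet")
}

# batched evaluation-mode loss/accuracy
.eval_batches <- function(net, x, yi, batch = 512L) {
  n <- nrow(x)
  loss <- 0; correct <- 0
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch))) {
    mb <- .windows_to_batch(x[ix, , drop = FALSE], net$config$input_length)
    pr <- .net_apply(net, mb$X, mb$B, train = FALSE, with_cache = FALSE)$probs
    loss <- loss + .ce_loss(pr, yi[ix]) * length(ix)
    correct <- correct + sum(apply(pr, 2L, which.max) == yi[ix])
  }
  list(loss = loss / n, accuracy = correct / n)
}

#' @export
print.porenet <- function(x, ...) {
  cat(sprintf("Raw-signal read classifier (%s)\n",
              paste(x$classes, collapse = " vs ")))
  cat(sprintf("  trained %d epoch(s), lr %g, batch %d; best epoch %d (val accuracy %.3f)\n",
              nrow(x$history), x$control$learning_rate,
              x$control$batch_size, x$best_epoch,
              x$history$val_accuracy[x$best_epoch]))
  cat(sprintf("  %.1f KB of parameters; input %d samples\n",
              parameter_bytes(x$net) / 1024, x$net$config$input_length))
  invisible(x)
}

#' @export
summary.porenet <- function(object, ...) {
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  inv <- data.frame(
    tensor = names(object$net$params),
    shape = vapply(object$net$params, function(p)
      paste(if (is.null(dim(p))) length(p) else dim(p), collapse = "x"),
      character(1)))
  invisible(list(history = object$history, inventory = inv,
                 parameter_bytes = parameter_bytes(object$net)))
}

#' Predict class membership for signal windows
#'
#' @param object A fitted [porenet()] model.
#' @param newdata Matrix of normalized windows (reads x samples), a single
#'   window, or a list of `normalized_window` objects.
#' @param type `"prob"` for the probability matrix (one column per class)
#'   or `"class"` for the argmax labels (ties resolve to the lower class
#'   index).
#' @param ... Unused.
#' @return Probability matrix or factor of predicted labels.
#' @export
predict.porenet <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  probs <- net_forward(object$net, newdata)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs, ties.method = "first")],
         levels = object$classes)
}

#' @export
coef.porenet <- function(object, ...) object$net$params

#' @export
plot.porenet <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "b",
                    pch = 1:2, lty = 1, xlab = "epoch", ylab = "cross-entropy",
                    main = "loss", ...)
  graphics::legend("topright", c("train", "validation"), pch = 1:2, lty = 1,
                   col = 1:2, bty = "n")
  graphics::plot(h$epoch, h$val_accuracy, type = "b", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy", main = "validation accuracy")
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}
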