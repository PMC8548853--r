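# The compact 1D residual bottleneck classifier.
#
# Architecture: a wide-kernel stem convolution (kernel 19, stride 3,
# 20 channels by default) followed by `n_layers` residual layers of
# `blocks_per_layer` bottleneck blocks each. Layer widths grow by a factor
# of `channel_growth` (x1.5 -> 20, 30, 45, 68 channels). Each bottleneck
# halves its channel count through a 1x1 convolution, applies a strided
# kernel-3 convolution (stride 2, so the time axis shrinks by 2 per block),
# expands back through a second 1x1 convolution, and adds a projection
# shortcut whenever the shape changes; batch normalization and ReLU sit
# inside every block. A global average pool over time and a fully connected
# softmax head produce class probabilities. The default model stores well
# under 304 KB of 32-bit parameters.

.round_half_up <- function(x) floor(x + 0.5)

#' Architecture hyperparameters for the raw-signal classifier
#'
#' @param stem_channels Channels of the stem convolution (default 20).
#' @param stem_kernel,stem_stride Stem kernel width and stride (19, 3).
#' @param n_layers Number of residual layers (default 4).
#' @param blocks_per_layer Bottleneck blocks per layer (default 2).
#' @param channel_growth Per-layer channel multiplier (default 1.5); layer
#'   i has `round(stem_channels * channel_growth^(i-1))` channels.
#' @param block_stride Time-axis stride of a bottleneck block (default 2).
#' @param block_kernel Kernel width of the middle bottleneck convolution
#'   (default 3, zero-padded by `(block_kernel-1)/2`).
#' @param n_classes Number of output classes (>= 2).
#' @param input_length Samples per input window (default 3000).
#' @param stride_every_block If TRUE (default) every block strides; if
#'   FALSE only the first block of each layer does.
#' @return An object of class `"net_config"`.
#' @examples
#' cfg <- net_config()
#' cfg$widths   # 20 30 45 68
#' @export
net_config <- function(stem_channels = 20L, stem_kernel = 19L,
                       stem_stride = 3L, n_layers = 4L,
                       blocks_per_layer = 2L, channel_growth = 1.5,
                       block_stride = 2L, block_kernel = 3L,
                       n_classes = 2L, input_length = 3000L,
                       stride_every_block = TRUE) {
  if (n_classes < 2L) stop("'n_classes' must be >= 2")
  stopifnot(stem_channels >= 1L, stem_kernel >= 1L, stem_stride >= 1L,
            n_layers >= 1L, blocks_per_layer >= 1L, channel_growth > 1,
            block_stride >= 1L, block_kernel >= 1L, block_kernel %% 2L == 1L)
  if (input_length < stem_kernel)
    stop(sprintf("'input_length' (%d) too short for the stride pyramid; minimum is %d",
                 input_length, stem_kernel))
  widths <- as.integer(.round_half_up(stem_channels * channel_growth^(seq_len(n_layers) - 1)))
  if (any(diff(widths) <= 0))
    stop("layer channel counts must be strictly increasing; adjust 'channel_growth'")
  structure(list(stem_channels = as.integer(stem_channels),
                 stem_kernel = as.integer(stem_kernel),
                 stem_stride = as.integer(stem_stride),
                 n_layers = as.integer(n_layers),
                 blocks_per_layer = as.integer(blocks_per_layer),
                 channel_growth = channel_growth,
                 block_stride = as.integer(block_stride),
                 block_kernel = as.integer(block_kernel),
                 n_classes = as.integer(n_classes),
                 input_length = as.integer(input_length),
                 stride_every_block = isTRUE(stride_every_block),
                 widths = widths),
            class = "net_config")
}

# lengths of the feature maps along the trunk (stem output first)
.trunk_lengths <- function(config) {
  L <- .conv_out_len(config$input_length, config$stem_kernel,
                     config$stem_stride, 0L)
  lens <- L
  pad <- (config$block_kernel - 1L) %/% 2L
  for (i in seq_len(config$n_layers)) {
    for (j in seq_len(config$blocks_per_layer)) {
      s <- if (config$stride_every_block || j == 1L) config$block_stride else 1L
      L <- .conv_out_len(L, config$block_kernel, s, pad)
      lens <- c(lens, L)
    }
  }
  lens
}

#' Build the classifier network
#'
#' Instantiates the architecture described by a [net_config()] with Kaiming
#' (fan-out) initialised convolution weights; batch-norm scale/shift start
#' at 1/0 and running statistics at 0/1. Given the same configuration and
#' seed the parameter inventory is bit-identical across calls.
#'
#' @param config A [net_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `"resnet1d"`: list with `config`, `arch`
#'   (precomputed layer geometry), `params` (named list of weight arrays)
#'   and `buffers` (batch-norm running statistics).
#' @examples
#' net <- build_net(net_config(), seed = 1)
#' parameter_bytes(net) / 1024   # well under 304 KB
#' @export
build_net <- function(config = net_config(), seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  params <- list(); buffers <- list(); blocks <- list()
  pad <- (config$block_kernel - 1L) %/% 2L

  stem <- .conv_spec(1L, config$stem_channels, config$stem_kernel,
                     config$stem_stride, config$input_length, 0L)
  params[["stem.W"]] <- .kaiming_fanout(config$stem_channels, 1L, config$stem_kernel)
  params[["stem.g"]] <- rep(1, config$stem_channels)
  params[["stem.b"]] <- rep(0, config$stem_channels)
  buffers[["stem.rm"]] <- rep(0, config$stem_channels)
  buffers[["stem.rv"]] <- rep(1, config$stem_channels)

  L <- stem$Lout
  cin <- config$stem_channels
  for (i in seq_len(config$n_layers)) {
    w <- config$widths[i]
    mid <- as.integer(.round_half_up(w / 2))
    for (j in seq_len(config$blocks_per_layer)) {
      s <- if (config$stride_every_block || j == 1L) config$block_stride else 1L
      p <- sprintf("l%db%d", i, j)
      blk <- list(name = p, cin = cin, mid = mid, cout = w, stride = s,
                  c1 = .conv_spec(cin, mid, 1L, 1L, L, 0L),
                  c2 = .conv_spec(mid, mid, config$block_kernel, s, L, pad),
                  c3 = NULL, sc = NULL)
      Lout <- blk$c2$Lout
      blk$c3 <- .conv_spec(mid, w, 1L, 1L, Lout, 0L)
      proj <- (s != 1L || cin != w)
      if (proj) blk$sc <- .conv_spec(cin, w, 1L, s, L, 0L)

      params[[paste0(p, ".c1.W")]] <- .kaiming_fanout(mid, cin, 1L)
      params[[paste0(p, ".bn1.g")]] <- rep(1, mid)
      params[[paste0(p, ".bn1.b")]] <- rep(0, mid)
      params[[paste0(p, ".c2.W")]] <- .kaiming_fanout(mid, mid, config$block_kernel)
      params[[paste0(p, ".bn2.g")]] <- rep(1, mid)
      params[[paste0(p, ".bn2.b")]] <- rep(0, mid)
      params[[paste0(p, ".c3.W")]] <- .kaiming_fanout(w, mid, 1L)
      params[[paste0(p, ".bn3.g")]] <- rep(1, w)
      params[[paste0(p, ".bn3.b")]] <- rep(0, w)
      buffers[[paste0(p, ".bn1.rm")]] <- rep(0, mid)
      buffers[[paste0(p, ".bn1.rv")]] <- rep(1, mid)
      buffers[[paste0(p, ".bn2.rm")]] <- rep(0, mid)
      buffers[[paste0(p, ".bn2.rv")]] <- rep(1, mid)
      buffers[[paste0(p, ".bn3.rm")]] <- rep(0, w)
      buffers[[paste0(p, ".bn3.rv")]] <- rep(1, w)
      if (proj) {
        params[[paste0(p, ".sc.W")]] <- .kaiming_fanout(w, cin, 1L)
        params[[paste0(p, ".scbn.g")]] <- rep(1, w)
        params[[paste0(p, ".scbn.b")]] <- rep(0, w)
        buffers[[paste0(p, ".scbn.rm")]] <- rep(0, w)
        buffers[[paste0(p, ".scbn.rv")]] <- rep(1, w)
      }
      blocks[[p]] <- blk
      L <- Lout
      cin <- w
    }
  }
  # head uses fan-in scaling: with as few output units as classes, fan-out
  # scaling would give order-unity logit weights and saturated softmax at init
  params[["fc.W"]] <- matrix(stats::rnorm(config$n_classes * cin,
                                          sd = sqrt(2 / cin)),
                             config$n_classes, cin)
  params[["fc.b"]] <- rep(0, config$n_classes)

  structure(list(config = config,
                 arch = list(stem = stem, blocks = blocks, trunk_len = L,
                             trunk_channels = cin),
                 params = params, buffers = buffers),
            class = "resnet1d")
}

#' @export
print.resnet1d <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<resnet1d> %d-class raw-signal classifier\n", cfg$n_classes))
  cat(sprintf("  stem: 1->%d ch, kernel %d stride %d\n",
              cfg$stem_channels, cfg$stem_kernel, cfg$stem_stride))
  cat(sprintf("  %d layers x %d bottleneck blocks, widths %s\n",
              cfg$n_layers, cfg$blocks_per_layer,
              paste(cfg$widths, collapse = "/")))
  cat(sprintf("  input %d samples -> trunk length %d; %d parameters (%.1f KB as float32)\n",
              cfg$input_length, x$arch$trunk_len,
              sum(lengths(x$params)) + sum(lengths(x$buffers)),
              parameter_bytes(x) / 1024))
  invisible(x)
}

#' Serialized parameter storage of a network
#'
#' Counts every stored scalar — convolution and fully connected weights,
#' batch-norm scale/shift and their running statistics — at 4 bytes
#' (32-bit float), matching what a checkpoint of the model occupies.
#'
#' @param net A [build_net()] network.
#' @return Integer number of bytes.
#' @export
parameter_bytes <- function(net) {
  stopifnot(inherits(net, "resnet1d"))
  4L * (sum(lengths(net$params)) + sum(lengths(net$buffers)))
}

# ---- forward / backward ----------------------------------------------

# X: flat minibatch matrix (1, input_length * B). Returns logits, probs,
# per-layer caches (when with_cache) and updated running buffers (when
# train).
.net_apply <- function(net, X, B, train = FALSE, with_cache = FALSE) {
  p <- net$params; bf <- net$buffers; keep <- with_cache
  caches <- if (keep) list() else NULL

  st <- net$arch$stem
  cf <- .conv_f(st, p[["stem.W"]], X, B)
  bn <- .bn_f(p[["stem.g"]], p[["stem.b"]], bf[["stem.rm"]], bf[["stem.rv"]],
              cf$Y, train)
  bf[["stem.rm"]] <- bn$rm; bf[["stem.rv"]] <- bn$rv
  rl <- .relu_f(bn$Y)
  h <- rl$Y
  if (keep) caches$stem <- list(Xc = cf$Xc, bn = bn[c("xhat", "is", "train")],
                                mask = rl$mask)

  for (blk in net$arch$blocks) {
    nm <- blk$name
    a1 <- .conv_f(blk$c1, p[[paste0(nm, ".c1.W")]], h, B)
    b1 <- .bn_f(p[[paste0(nm, ".bn1.g")]], p[[paste0(nm, ".bn1.b")]],
                bf[[paste0(nm, ".bn1.rm")]], bf[[paste0(nm, ".bn1.rv")]],
                a1$Y, train)
    bf[[paste0(nm, ".bn1.rm")]] <- b1$rm; bf[[paste0(nm, ".bn1.rv")]] <- b1$rv
    r1 <- .relu_f(b1$Y)
    a2 <- .conv_f(blk$c2, p[[paste0(nm, ".c2.W")]], r1$Y, B)
    b2 <- .bn_f(p[[paste0(nm, ".bn2.g")]], p[[paste0(nm, ".bn2.b")]],
                bf[[paste0(nm, ".bn2.rm")]], bf[[paste0(nm, ".bn2.rv")]],
                a2$Y, train)
    bf[[paste0(nm, ".bn2.rm")]] <- b2$rm; bf[[paste0(nm, ".bn2.rv")]] <- b2$rv
    r2 <- .relu_f(b2$Y)
    a3 <- .conv_f(blk$c3, p[[paste0(nm, ".c3.W")]], r2$Y, B)
    b3 <- .bn_f(p[[paste0(nm, ".bn3.g")]], p[[paste0(nm, ".bn3.b")]],
                bf[[paste0(nm, ".bn3.rm")]], bf[[paste0(nm, ".bn3.rv")]],
                a3$Y, train)
    bf[[paste0(nm, ".bn3.rm")]] <- b3$rm; bf[[paste0(nm, ".bn3.rv")]] <- b3$rv
    if (!is.null(blk$sc)) {
      as_ <- .conv_f(blk$sc, p[[paste0(nm, ".sc.W")]], h, B)
      bs <- .bn_f(p[[paste0(nm, ".scbn.g")]], p[[paste0(nm, ".scbn.b")]],
                  bf[[paste0(nm, ".scbn.rm")]], bf[[paste0(nm, ".scbn.rv")]],
                  as_$Y, train)
      bf[[paste0(nm, ".scbn.rm")]] <- bs$rm; bf[[paste0(nm, ".scbn.rv")]] <- bs$rv
      short <- bs$Y
    } else { as_ <- NULL; bs <- NULL; short <- h }
    ro <- .relu_f(.cpp_add(b3$Y, short))
    if (keep)
      caches[[nm]] <- list(
        Xc1 = a1$Xc, bn1 = b1[c("xhat", "is", "train")], m1 = r1$mask,
        Xc2 = a2$Xc, bn2 = b2[c("xhat", "is", "train")], m2 = r2$mask,
        Xc3 = a3$Xc, bn3 = b3[c("xhat", "is", "train")],
        Xcs = if (!is.null(as_)) as_$Xc,
        bns = if (!is.null(bs)) bs[c("xhat", "is", "train")],
        mo = ro$mask)
    h <- ro$Y
  }

  pl <- .pool_f(h, net$arch$trunk_channels, net$arch$trunk_len, B)
  logits <- p[["fc.W"]] %*% pl$Y + p[["fc.b"]]
  if (keep) caches$head <- list(pooled = pl$Y, pool_dims = pl$dims)
  list(logits = logits, probs = .softmax(logits), caches = caches,
       buffers = bf)
}

# dlogits (n_classes, B) -> list(grads = named list, dX = (1, L*B))
.net_backward <- function(net, caches, dlogits, B = ncol(dlogits)) {
  p <- net$params
  g <- list()
  hd <- caches$head
  g[["fc.W"]] <- tcrossprod(dlogits, hd$pooled)
  g[["fc.b"]] <- rowSums(dlogits)
  dh <- .pool_b(hd$pool_dims, crossprod(p[["fc.W"]], dlogits))

  for (blk in rev(net$arch$blocks)) {
    nm <- blk$name
    cc <- caches[[nm]]
    dsum <- .relu_b(cc$mo, dh)
    bb3 <- .bn_b(p[[paste0(nm, ".bn3.g")]], cc$bn3, dsum)
    g[[paste0(nm, ".bn3.g")]] <- bb3$dg; g[[paste0(nm, ".bn3.b")]] <- bb3$db
    cb3 <- .conv_b(blk$c3, p[[paste0(nm, ".c3.W")]], cc$Xc3, bb3$dX, B)
    g[[paste0(nm, ".c3.W")]] <- cb3$dW
    dr2 <- .relu_b(cc$m2, cb3$dX)
    bb2 <- .bn_b(p[[paste0(nm, ".bn2.g")]], cc$bn2, dr2)
    g[[paste0(nm, ".bn2.g")]] <- bb2$dg; g[[paste0(nm, ".bn2.b")]] <- bb2$db
    cb2 <- .conv_b(blk$c2, p[[paste0(nm, ".c2.W")]], cc$Xc2, bb2$dX, B)
    g[[paste0(nm, ".c2.W")]] <- cb2$dW
    dr1 <- .relu_b(cc$m1, cb2$dX)
    bb1 <- .bn_b(p[[paste0(nm, ".bn1.g")]], cc$bn1, dr1)
    g[[paste0(nm, ".bn1.g")]] <- bb1$dg; g[[paste0(nm, ".bn1.b")]] <- bb1$db
    cb1 <- .conv_b(blk$c1, p[[paste0(nm, ".c1.W")]], cc$Xc1, bb1$dX, B)
    g[[paste0(nm, ".c1.W")]] <- cb1$dW
    din <- cb1$dX
    if (!is.null(blk$sc)) {
      bbs <- .bn_b(p[[paste0(nm, ".scbn.g")]], cc$bns, dsum)
      g[[paste0(nm, ".scbn.g")]] <- bbs$dg; g[[paste0(nm, ".scbn.b")]] <- bbs$db
      cbs <- .conv_b(blk$sc, p[[paste0(nm, ".sc.W")]], cc$Xcs, bbs$dX, B)
      g[[paste0(nm, ".sc.W")]] <- cbs$dW
      din <- .cpp_add(din, cbs$dX)
    } else {
      din <- .cpp_add(din, dsum)
    }
    dh <- din
  }

  cs <- caches$stem
  dst <- .relu_b(cs$mask, dh)
  bbs <- .bn_b(p[["stem.g"]], cs$bn, dst)
  g[["stem.g"]] <- bbs$dg; g[["stem.b"]] <- bbs$db
  cbs <- .conv_b(net$arch$stem, p[["stem.W"]], cs$Xc, bbs$dX, B)
  g[["stem.W"]] <- cbs$dW
  list(grads = g, dX = cbs$dX)
}

# coerce user-facing windows (vector, matrix rows, normalized_window or a
# list thereof) into the internal (1, L, B) array
.windows_to_batch <- function(x, input_length) {
  if (inherits(x, "normalized_window")) x <- matrix(x$values, nrow = 1L)
  if (is.list(x) && !is.data.frame(x))
    x <- do.call(rbind, lapply(x, function(w)
      if (inherits(w, "normalized_window")) w$values else as.numeric(w)))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != input_length)
    stop(sprintf("windows have %d samples; the network expects %d",
                 ncol(x), input_length))
  # flat (1, L*B) minibatch: B contiguous blocks of L samples
  list(X = matrix(t(x), nrow = 1L), B = nrow(x))
}

#' Forward pass: class probabilities for signal windows
#'
#' Runs the network in evaluation mode (batch-norm uses running
#' statistics) and returns one probability row per window; rows lie on the
#' probability simplex.
#'
#' @param net A [build_net()] network.
#' @param windows Numeric vector (one window), matrix (windows x samples),
#'   or list of windows / `normalized_window` objects.
#' @return Matrix (windows x classes) of probabilities.
#' @export
net_forward <- function(net, windows) {
  stopifnot(inherits(net, "resnet1d"))
  mb <- .windows_to_batch(windows, net$config$input_length)
  t(.net_apply(net, mb$X, mb$B, train = FALSE, with_cache = FALSE)$probs)
}

#' @description `net_logits()` returns the pre-softmax scores instead.
#' @rdname net_forward
#' @export
net_logits <- function(net, windows) {
  stopifnot(inherits(net, "resnet1d"))
  mb <- .windows_to_batch(windows, net$config$input_length)
  t(.net_apply(net, mb$X, mb$B, train = FALSE, with_cache = FALSE)$logits)
}

#' Integrated-gradients attribution for one window
#'
#' Attributes the pre-softmax score of `target_class` to the individual
#' signal samples by integrating the input gradient along the straight
#' path from `baseline` to `window` (midpoint Riemann sum with `steps`
#' points), evaluated with the network in evaluation mode. By the
#' completeness property the attributions sum to
#' `score(window) - score(baseline)` up to the quadrature error.
#'
#' @param net A [build_net()] network.
#' @param window Numeric vector of `input_length` samples (or a
#'   `normalized_window`).
#' @param baseline Reference window of the same length (default all zeros,
#'   i.e. the per-read median signal level after MAD normalization).
#' @param steps Number of quadrature points (default 64).
#' @param target_class Class index (1-based) whose score is attributed.
#' @return Numeric vector of per-sample attributions, length
#'   `input_length`.
#' @export
integrated_gradients <- function(net, window, baseline = NULL, steps = 64L,
                                 target_class = 1L) {
  stopifnot(inherits(net, "resnet1d"), steps >= 1L)
  if (inherits(window, "normalized_window")) window <- window$values
  window <- as.numeric(window)
  L <- net$config$input_length
  if (length(window) != L)
    stop(sprintf("window has %d samples; expected %d", length(window), L))
  if (is.null(baseline)) baseline <- numeric(L)
  if (inherits(baseline, "normalized_window")) baseline <- baseline$values
  if (length(baseline) != L)
    stop(sprintf("baseline has %d samples; expected %d (window length)",
                 length(baseline), L))
  if (target_class < 1L || target_class > net$config$n_classes)
    stop("'target_class' out of range")
  diff <- window - baseline
  alphas <- (seq_len(steps) - 0.5) / steps
  path <- outer(alphas, diff) + matrix(baseline, steps, L, byrow = TRUE)
  mb <- .windows_to_batch(path, L)
  fwd <- .net_apply(net, mb$X, mb$B, train = FALSE, with_cache = TRUE)
  dlog <- matrix(0, net$config$n_classes, steps)
  dlog[target_class, ] <- 1
  bwd <- .net_backward(net, fwd$caches, dlog, mb$B)
  avg_grad <- rowMeans(matrix(bwd$dX, L, steps))
  diff * avg_grad
}

#' Save or load a network checkpoint
#'
#' A checkpoint is a single file holding the named parameter tensors, the
#' batch-norm running statistics and the embedded [net_config()].
#'
#' @param net A [build_net()] network.
#' @param path Checkpoint file path.
#' @return `save_net` returns `path` invisibly; `load_net` the network.
#' @export
save_net <- function(net, path) {
  stopifnot(inherits(net, "resnet1d"))
  saveRDS(list(config = unclass(net$config), params = net$params,
               buffers = net$buffers), path)
  invisible(path)
}

#' @rdname save_net
#' @export
load_net <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(net_config, ck$config[setdiff(names(ck$config), "widths")])
  net <- build_net(cfg, seed = 0L)
  stopifnot(identical(names(net$params), names(ck$params)))
  net$params <- ck$params
  net$buffers <- ck$buffers
  net
}
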