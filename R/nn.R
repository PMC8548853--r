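# Internal neural-network primitives.
#
# Minibatches are held as 3-d arrays dim (channels, length, batch).
# Convolutions run as im2col gathers followed by one BLAS matmul; the
# gather index only depends on (channels-in, kernel, stride, pad, length),
# so it is precomputed per layer when the network is built. All gradients
# are derived analytically and verified against finite differences in the
# test suite.

.conv_out_len <- function(L, k, stride, pad = 0L) {
  (L + 2L * pad - k) %/% stride + 1L
}

# Precompute an im2col gather spec for one convolution. Minibatches are
# flat (C, L*B) matrices (B contiguous column blocks of length L); the
# gather index is 1-based into one (Cin, Lin) block, with 0 marking
# zero-padding positions.
.conv_spec <- function(Cin, Cout, k, stride, Lin, pad = 0L) {
  Lout <- .conv_out_len(Lin, k, stride, pad)
  if (Lout < 1L)
    stop(sprintf("input length %d too short for kernel %d stride %d", Lin, k, stride))
  spec <- list(Cin = Cin, Cout = Cout, k = k, stride = stride,
               pad = pad, Lin = Lin, Lout = Lout)
  if (!(k == 1L && stride == 1L && pad == 0L)) {
    starts <- (seq_len(Lout) - 1L) * stride
    u <- as.vector(outer(seq_len(k), starts, `+`)) - pad  # unpadded col, 1-based
    base <- ifelse(u >= 1L & u <= Lin, (u - 1L) * Cin, NA_integer_)
    idx <- rep(base, each = Cin) + rep(seq_len(Cin), times = k * Lout)
    idx[is.na(idx)] <- 0L
    spec$idx <- as.integer(idx)
  }
  spec
}

# forward: X (Cin, Lin*B), W (Cout, Cin*k) -> list(Y (Cout, Lout*B), Xc)
.conv_f <- function(spec, W, X, B) {
  Xc <- if (is.null(spec$idx)) X            # 1x1 stride-1: pure matmul
  else .cpp_gather(X, spec$idx, B, spec$Cin * spec$Lin, spec$Cin * spec$k)
  list(Y = W %*% Xc, Xc = Xc)
}

# backward: dY (Cout, Lout*B) -> list(dW, dX (Cin, Lin*B))
.conv_b <- function(spec, W, Xc, dY, B) {
  dW <- tcrossprod(dY, Xc)
  dXc <- crossprod(W, dY)
  dX <- if (is.null(spec$idx)) dXc
  else .cpp_scatter(dXc, spec$idx, B, spec$Cin * spec$Lin, spec$Cin)
  list(dW = dW, dX = dX)
}

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

# X (C, N) with N = L*B; heavy lifting in the fused C++ kernels.
.bn_f <- function(g, b, rm, rv, X, train) {
  if (train) {
    r <- .cpp_bn_train(X, g, b, .BN_EPS)
    rm <- (1 - .BN_MOMENTUM) * rm + .BN_MOMENTUM * r$m
    rv <- (1 - .BN_MOMENTUM) * rv + .BN_MOMENTUM * r$v
  } else {
    r <- .cpp_bn_eval(X, g, b, rm, rv, .BN_EPS)
  }
  list(Y = r$Y, xhat = r$xhat, is = r$is, rm = rm, rv = rv, train = train)
}

.bn_b <- function(g, cache, dY) {
  r <- .cpp_bn_bwd(dY, cache$xhat, cache$is, g, cache$train)
  list(dg = r$dg, db = r$db, dX = r$dX)
}

# the ReLU output doubles as the backward mask
.relu_f <- function(X) {
  Y <- .cpp_relu(X)
  list(Y = Y, mask = Y)
}

.relu_b <- function(mask, dY) .cpp_relu_bwd(dY, mask)

# global average pool over the length axis: (C, L*B) -> (C, B)
.pool_f <- function(X, C, L, B) {
  list(Y = .cpp_pool_fwd(X, C, L, B), dims = c(C, L, B))
}

.pool_b <- function(dims, dY) {
  .cpp_pool_bwd(dY, dims[1L], dims[2L], dims[3L])
}

# softmax over rows of logits (n_classes, B)
.softmax <- function(z) {
  z <- z - matrix(apply(z, 2L, max), nrow(z), ncol(z), byrow = TRUE)
  e <- exp(z)
  e / matrix(colSums(e), nrow(z), ncol(z), byrow = TRUE)
}

# mean cross-entropy; y integer class 1..K per column
.ce_loss <- function(probs, y) {
  B <- ncol(probs)
  p <- probs[cbind(y, seq_len(B))]
  -mean(log(pmax(p, 1e-12)))
}

# gradient of mean CE wrt logits
.ce_grad <- function(probs, y) {
  B <- ncol(probs)
  d <- probs
  d[cbind(y, seq_len(B))] <- d[cbind(y, seq_len(B))] - 1
  d / B
}

# ---- Adam -------------------------------------------------------------

.adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)   # keeps each tensor's shape
  list(m = zeros, v = zeros, t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Kaiming normal initialisation in fan-out mode: sd = sqrt(2 / fan_out),
# fan_out = out_channels * kernel_size for a convolution.
.kaiming_fanout <- function(n_out, n_in, k = 1L) {
  matrix(stats::rnorm(n_out * n_in * k, sd = sqrt(2 / (n_out * k))),
         n_out, n_in * k)
}
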