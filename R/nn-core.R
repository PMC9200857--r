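# Minimal neural-network core: 1-D convolutions (im2col + BLAS matmul),
# leaky-ReLU, global average pooling, dense layers, softmax cross-entropy
# and ADAM. Signals are stored time-major: a batch of n sequences of length
# T with C channels is a (n*T) x C matrix whose row for (sample i, time t)
# is (t-1)*n + i. The temporal classifier uses the same machinery with
# n = 1 and "same" zero padding.

lrelu <- function(x) pmax(x, 0) + 0.01 * pmin(x, 0)
lrelu_grad <- function(x) ifelse(x > 0, 1, 0.01)

he_init <- function(n_in, n_out, gain = sqrt(2)) {
  matrix(stats::rnorm(n_in * n_out, 0, gain / sqrt(n_in)), n_in, n_out)
}

conv_layer <- function(c_in, c_out, fw, stride = 1L, dilation = 1L,
                       pad = c("valid", "same"), act = "lrelu") {
  pad <- match.arg(pad)
  list(type = "conv", fw = fw, stride = stride, dilation = dilation,
       pad = pad, act = act, c_in = c_in, c_out = c_out,
       W = he_init(fw * c_in, c_out), b = numeric(c_out))
}

dense_layer <- function(d_in, d_out, act = "lrelu") {
  list(type = "dense", act = act,
       W = he_init(d_in, d_out, gain = if (act == "linear") 1 else sqrt(2)),
       b = numeric(d_out))
}

conv_out_len <- function(T_in, layer) {
  if (layer$pad == "same") {
    stopifnot(layer$stride == 1L)
    T_in
  } else {
    span <- (layer$fw - 1L) * layer$dilation + 1L
    (T_in - span) %/% layer$stride + 1L
  }
}

conv_tap_times <- function(T_in, T_out, layer, f) {
  p <- if (layer$pad == "same") ((layer$fw - 1L) * layer$dilation) %/% 2L else 0L
  (0:(T_out - 1L)) * layer$stride - p + (f - 1L) * layer$dilation + 1L
}

conv_forward <- function(Xm, n, T_in, layer) {
  T_out <- conv_out_len(T_in, layer)
  X2 <- matrix(0, n * T_out, layer$fw * layer$c_in)
  for (f in seq_len(layer$fw)) {
    tf <- conv_tap_times(T_in, T_out, layer, f)
    v <- which(tf >= 1L & tf <= T_in)
    if (length(v) == 0) next
    out_rows <- rep((v - 1L) * n, each = n) + rep(seq_len(n), length(v))
    in_rows <- rep((tf[v] - 1L) * n, each = n) + rep(seq_len(n), length(v))
    X2[out_rows, ((f - 1L) * layer$c_in + 1L):(f * layer$c_in)] <-
      Xm[in_rows, , drop = FALSE]
  }
  Z <- X2 %*% layer$W
  Z <- sweep(Z, 2, layer$b, "+")
  A <- if (layer$act == "lrelu") lrelu(Z) else Z
  list(A = A, cache = list(X2 = X2, Z = Z, n = n, T_in = T_in, T_out = T_out))
}

conv_backward <- function(dA, cache, layer) {
  dZ <- if (layer$act == "lrelu") dA * lrelu_grad(cache$Z) else dA
  gW <- crossprod(cache$X2, dZ)
  gb <- colSums(dZ)
  dX2 <- dZ %*% t(layer$W)
  n <- cache$n
  dXm <- matrix(0, n * cache$T_in, layer$c_in)
  for (f in seq_len(layer$fw)) {
    tf <- conv_tap_times(cache$T_in, cache$T_out, layer, f)
    v <- which(tf >= 1L & tf <= cache$T_in)
    if (length(v) == 0) next
    out_rows <- rep((v - 1L) * n, each = n) + rep(seq_len(n), length(v))
    in_rows <- rep((tf[v] - 1L) * n, each = n) + rep(seq_len(n), length(v))
    dXm[in_rows, ] <- dXm[in_rows, ] +
      dX2[out_rows, ((f - 1L) * layer$c_in + 1L):(f * layer$c_in), drop = FALSE]
  }
  list(dX = dXm, gW = gW, gb = gb)
}

gap_forward <- function(Xm, n, T_in) {
  rowsum(Xm, group = rep_len(seq_len(n), n * T_in), reorder = TRUE) / T_in
}

gap_backward <- function(dOut, n, T_in) {
  dOut[rep(seq_len(n), T_in), , drop = FALSE] / T_in
}

dense_forward <- function(X, layer) {
  Z <- sweep(X %*% layer$W, 2, layer$b, "+")
  A <- if (layer$act == "lrelu") lrelu(Z) else Z
  list(A = A, cache = list(X = X, Z = Z))
}

dense_backward <- function(dA, cache, layer) {
  dZ <- if (layer$act == "lrelu") dA * lrelu_grad(cache$Z) else dA
  list(dX = dZ %*% t(layer$W), gW = crossprod(cache$X, dZ), gb = colSums(dZ))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# weighted soft-target cross-entropy; returns loss and dLogits
weighted_ce <- function(logits, targets, w) {
  P <- softmax_rows(logits)
  sw <- sum(w)
  if (sw <= 0) return(list(loss = NA_real_, dLogits = logits * 0, P = P))
  loss <- -sum(w * rowSums(targets * log(pmax(P, 1e-12)))) / sw
  dLogits <- (P - targets) * (w / sw)
  list(loss = loss, dLogits = dLogits, P = P)
}

# ADAM update; layer carries its own moment estimates
adam_step <- function(layer, gW, gb, lr, beta1, beta2, eps, t) {
  if (is.null(layer$mW)) {
    layer$mW <- layer$W * 0; layer$vW <- layer$W * 0
    layer$mb <- layer$b * 0; layer$vb <- layer$b * 0
  }
  layer$mW <- beta1 * layer$mW + (1 - beta1) * gW
  layer$vW <- beta2 * layer$vW + (1 - beta2) * gW^2
  layer$mb <- beta1 * layer$mb + (1 - beta1) * gb
  layer$vb <- beta2 * layer$vb + (1 - beta2) * gb^2
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  layer$W <- layer$W - lr * (layer$mW / c1) / (sqrt(layer$vW / c2) + eps)
  layer$b <- layer$b - lr * (layer$mb / c1) / (sqrt(layer$vb / c2) + eps)
  layer
}

# run a stack of conv layers (time-major), then GAP, then dense layers
stack_forward <- function(stack, Xm, n, T_in) {
  caches <- vector("list", length(stack$layers))
  A <- Xm; T_cur <- T_in
  for (i in seq_along(stack$layers)) {
    ly <- stack$layers[[i]]
    if (ly$type == "conv") {
      r <- conv_forward(A, n, T_cur, ly)
      caches[[i]] <- c(r$cache, list(kind = "conv"))
      A <- r$A; T_cur <- r$cache$T_out
    } else if (ly$type == "gap") {
      caches[[i]] <- list(kind = "gap", n = n, T_in = T_cur)
      A <- gap_forward(A, n, T_cur); T_cur <- 1L
    } else {
      r <- dense_forward(A, ly)
      caches[[i]] <- c(r$cache, list(kind = "dense"))
      A <- r$A
    }
  }
  list(out = A, caches = caches)
}

stack_backward <- function(stack, dOut, caches) {
  grads <- vector("list", length(stack$layers))
  dA <- dOut
  for (i in rev(seq_along(stack$layers))) {
    ly <- stack$layers[[i]]
    ca <- caches[[i]]
    if (ca$kind == "conv") {
      r <- conv_backward(dA, ca, ly)
      grads[[i]] <- list(gW = r$gW, gb = r$gb); dA <- r$dX
    } else if (ca$kind == "gap") {
      grads[i] <- list(NULL)
      dA <- gap_backward(dA, ca$n, ca$T_in)
    } else {
      r <- dense_backward(dA, ca, ly)
      grads[[i]] <- list(gW = r$gW, gb = r$gb); dA <- r$dX
    }
  }
  list(grads = grads, dX = dA)
}

stack_adam <- function(stack, grads, lr, beta1, beta2, eps, t) {
  for (i in seq_along(stack$layers)) {
    if (is.null(grads[[i]])) next
    stack$layers[[i]] <- adam_step(stack$layers[[i]], grads[[i]]$gW,
                                   grads[[i]]$gb, lr, beta1, beta2, eps, t)
  }
  stack
}

# strip optimizer state (used when snapshotting best-epoch weights)
stack_weights <- function(stack) {
  lapply(stack$layers, function(ly) ly[c("W", "b")])
}
stack_set_weights <- function(stack, ws) {
  for (i in seq_along(ws)) {
    if (is.null(ws[[i]]) || is.null(ws[[i]]$W)) next
    stack$layers[[i]]$W <- ws[[i]]$W
    stack$layers[[i]]$b <- ws[[i]]$b
  }
  stack
}
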