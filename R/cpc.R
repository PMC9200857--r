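#' Contrastive predictive coding configuration
#'
#' CPC learns, without labels, an encoder whose latent best supports
#' distinguishing the true future latent from negative samples. The frame
#' encoder (same architecture as the supervised classifier, output width
#' `latent_dim`) maps each frame to `Z_t`; a gated recurrent unit (GRU)
#' summarizes the past into a context `C_t`; a linear projection predicts
#' `Z_{t+k}` from `C_t`; and the InfoNCE loss scores the true future
#' against `n_negatives` frames drawn from the same recording.
#'
#' @param latent_dim encoder latent width (default 128).
#' @param k prediction distance in frames (default 5, about 5.8 s at
#'   60-sample hop and 52 Hz).
#' @param n_negatives number of negative samples (default 10).
#' @param epochs training epochs (default 50).
#' @param hidden GRU hidden width.
#' @param lr ADAM learning rate.
#' @param seed integer seed.
#' @return a `cpc_config` list.
#' @export
cpc_config <- function(latent_dim = 128L, k = 5L, n_negatives = 10L,
                       epochs = 50L, hidden = 128L, lr = 1e-3, seed = 1L) {
  stopifnot(k >= 1, n_negatives >= 1, epochs >= 0)
  list(latent_dim = as.integer(latent_dim), k = as.integer(k),
       n_negatives = as.integer(n_negatives), epochs = as.integer(epochs),
       hidden = as.integer(hidden), lr = lr, seed = as.integer(seed))
}

#' Prediction look-ahead horizon in seconds
#'
#' With 50%-overlap frames the hop between consecutive frames is
#' `hop / rate` seconds, so predicting `k` frames ahead looks
#' `k * hop / rate` seconds into the future.
#'
#' @param cfg a [cpc_config()].
#' @param hop frame hop in samples.
#' @param rate sampling rate in Hz.
#' @return look-ahead in seconds.
#' @export
cpc_lookahead_s <- function(cfg = cpc_config(), hop = 60L, rate = 52) {
  cfg$k * hop / rate
}

#' InfoNCE loss
#'
#' Cross-entropy of identifying the positive (true future latent) among
#' `1 + n_negatives` candidates under a dot-product similarity score. With
#' uninformative (equal) scores the expected loss is
#' `log(1 + n_negatives)`; perfect separation drives it to 0.
#'
#' @param pred m x d matrix of predicted future latents.
#' @param positive m x d matrix of true future latents.
#' @param negatives m x n_neg x d array of negative-sample latents.
#' @return mean loss (scalar, >= 0).
#' @export
infonce_loss <- function(pred, positive, negatives) {
  pred <- rbind(pred); positive <- rbind(positive)
  if (length(dim(negatives)) == 2)
    negatives <- array(negatives, c(1, dim(negatives)))
  m <- nrow(pred); n_neg <- dim(negatives)[2]
  S <- matrix(0, m, 1 + n_neg)
  S[, 1] <- rowSums(pred * positive)
  for (j in seq_len(n_neg))
    S[, j + 1] <- rowSums(pred * negatives[, j, , drop = TRUE])
  P <- softmax_rows(S)
  mean(-log(pmax(P[, 1], 1e-12)))
}

gru_init <- function(d_in, d_h) {
  s <- 1 / sqrt(d_h)
  rn <- function(a, b) matrix(stats::runif(a * b, -s, s), a, b)
  list(Wxr = rn(d_in, d_h), Whr = rn(d_h, d_h), br = numeric(d_h),
       Wxz = rn(d_in, d_h), Whz = rn(d_h, d_h), bz = numeric(d_h),
       Wxn = rn(d_in, d_h), Whn = rn(d_h, d_h), bn = numeric(d_h),
       bhn = numeric(d_h), d_in = d_in, d_h = d_h)
}

sigm <- function(x) 1 / (1 + exp(-x))

gru_forward <- function(gru, Z) {
  T_len <- nrow(Z); dh <- gru$d_h
  Xr <- sweep(Z %*% gru$Wxr, 2, gru$br, "+")
  Xz <- sweep(Z %*% gru$Wxz, 2, gru$bz, "+")
  Xn <- sweep(Z %*% gru$Wxn, 2, gru$bn, "+")
  H <- matrix(0, T_len, dh)
  R <- matrix(0, T_len, dh); Zt <- matrix(0, T_len, dh)
  N <- matrix(0, T_len, dh); HWN <- matrix(0, T_len, dh)
  h <- numeric(dh)
  for (t in seq_len(T_len)) {
    r <- sigm(Xr[t, ] + drop(h %*% gru$Whr))
    z <- sigm(Xz[t, ] + drop(h %*% gru$Whz))
    hwn <- drop(h %*% gru$Whn) + gru$bhn
    nn <- tanh(Xn[t, ] + r * hwn)
    h <- (1 - z) * nn + z * h
    R[t, ] <- r; Zt[t, ] <- z; N[t, ] <- nn; HWN[t, ] <- hwn; H[t, ] <- h
  }
  list(H = H, cache = list(R = R, Zt = Zt, N = N, HWN = HWN, H = H, Z = Z))
}

gru_backward <- function(gru, dH, cache) {
  T_len <- nrow(dH); dh <- gru$d_h
  g <- lapply(gru[c("Wxr", "Whr", "Wxz", "Whz", "Wxn", "Whn")],
              function(w) w * 0)
  g$br <- numeric(dh); g$bz <- numeric(dh); g$bn <- numeric(dh)
  g$bhn <- numeric(dh)
  dZ <- cache$Z * 0
  dh_next <- numeric(dh)
  for (t in rev(seq_len(T_len))) {
    h_prev <- if (t > 1) cache$H[t - 1, ] else numeric(dh)
    d <- dH[t, ] + dh_next
    r <- cache$R[t, ]; z <- cache$Zt[t, ]; nn <- cache$N[t, ]
    hwn <- cache$HWN[t, ]
    dn <- d * (1 - z)
    dz <- d * (h_prev - nn)
    dh_prev <- d * z
    da_n <- dn * (1 - nn^2)
    dr <- da_n * hwn
    dhwn <- da_n * r
    g$Wxn <- g$Wxn + tcrossprod(cache$Z[t, ], da_n)
    g$bn <- g$bn + da_n
    g$Whn <- g$Whn + tcrossprod(h_prev, dhwn)
    g$bhn <- g$bhn + dhwn
    dh_prev <- dh_prev + drop(gru$Whn %*% dhwn)
    da_z <- dz * z * (1 - z)
    g$Wxz <- g$Wxz + tcrossprod(cache$Z[t, ], da_z)
    g$bz <- g$bz + da_z
    g$Whz <- g$Whz + tcrossprod(h_prev, da_z)
    dh_prev <- dh_prev + drop(gru$Whz %*% da_z)
    da_r <- dr * r * (1 - r)
    g$Wxr <- g$Wxr + tcrossprod(cache$Z[t, ], da_r)
    g$br <- g$br + da_r
    g$Whr <- g$Whr + tcrossprod(h_prev, da_r)
    dh_prev <- dh_prev + drop(gru$Whr %*% da_r)
    dZ[t, ] <- drop(gru$Wxr %*% da_r) + drop(gru$Wxz %*% da_z) +
               drop(gru$Wxn %*% da_n)
    dh_next <- dh_prev
  }
  list(grads = g, dZ = dZ)
}

gru_adam <- function(gru, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  for (nm in names(grads)) {
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- grads[[nm]] * 0
      state$v[[nm]] <- grads[[nm]] * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    gru[[nm]] <- gru[[nm]] - lr * (state$m[[nm]] / (1 - beta1^t)) /
      (sqrt(state$v[[nm]] / (1 - beta2^t)) + eps)
  }
  list(gru = gru, state = state)
}

#' Train a CPC model on unannotated recordings
#'
#' Trains the frame encoder, GRU context model and linear prediction head
#' end-to-end with ADAM on the InfoNCE objective. Negatives are drawn
#' uniformly per time step from the same recording (excluding the positive
#' frame) and resampled every epoch.
#'
#' @param frame_list list of frame arrays (one per recording), each
#'   `n x 120 x 24`.
#' @param cfg a [cpc_config()].
#' @param enc optional [encoder_spec()] override (latent width is forced to
#'   `cfg$latent_dim`).
#' @return a `cpc_model`: encoder stack, GRU, projection head,
#'   normalization, per-epoch mean loss log.
#' @export
cpc_train <- function(frame_list, cfg = cpc_config(), enc = NULL) {
  if (length(frame_list) == 0) stop("no recordings supplied")
  frame_list <- lapply(frame_list, frames_array)
  lens <- vapply(frame_list, function(x) dim(x)[1], integer(1))
  if (any(lens < cfg$k + 12))
    stop("each recording needs at least k + 12 frames")
  enc <- enc %||% encoder_spec(latent_dim = cfg$latent_dim)
  enc$latent_dim <- cfg$latent_dim
  set.seed(cfg$seed)
  base <- build_model(enc, temporal_spec(2L), c("a", "b"), seed = cfg$seed)
  encoder <- base$encoder
  gru <- gru_init(cfg$latent_dim, cfg$hidden)
  gru_state <- list(m = list(), v = list())
  # small-scale init keeps initial similarity scores near zero, so the
  # untrained loss sits at the log(1 + n_neg) chance baseline
  Wp <- matrix(stats::rnorm(cfg$hidden * cfg$latent_dim, 0, 0.01),
               cfg$hidden, cfg$latent_dim)
  bp <- numeric(cfg$latent_dim)
  proj_state <- list(mW = Wp * 0, vW = Wp * 0, mb = bp, vb = bp)

  all_x <- abind_frames(frame_list)
  norm <- list(mean = apply(all_x, 3, mean),
               sd = pmax(apply(all_x, 3, stats::sd), 1e-6))
  rm(all_x)

  log <- numeric(0)
  step <- 0L
  for (ep in seq_len(max(cfg$epochs, 0L))) {
    ep_loss <- 0; ep_m <- 0
    for (ri in sample.int(length(frame_list))) {
      X3 <- normalize_frames(frame_list[[ri]], norm)
      T_len <- dim(X3)[1]
      m <- T_len - cfg$k
      Xm <- matrix(X3, T_len * 120L, 24L)
      er <- stack_forward(encoder, Xm, T_len, 120L)
      Z <- er$out
      gf <- gru_forward(gru, Z)
      C <- gf$H
      pred <- sweep(C[seq_len(m), , drop = FALSE] %*% Wp, 2, bp, "+")
      pos_idx <- seq_len(m) + cfg$k
      neg <- matrix(sample.int(T_len, m * cfg$n_negatives, replace = TRUE),
                    m, cfg$n_negatives)
      while (any(bad <- neg == pos_idx))
        neg[bad] <- sample.int(T_len, sum(bad), replace = TRUE)
      S <- matrix(0, m, 1 + cfg$n_negatives)
      S[, 1] <- rowSums(pred * Z[pos_idx, , drop = FALSE])
      for (j in seq_len(cfg$n_negatives))
        S[, j + 1] <- rowSums(pred * Z[neg[, j], , drop = FALSE])
      P <- softmax_rows(S)
      loss <- mean(-log(pmax(P[, 1], 1e-12)))
      ep_loss <- ep_loss + loss * m; ep_m <- ep_m + m
      dS <- P; dS[, 1] <- dS[, 1] - 1; dS <- dS / m
      dpred <- dS[, 1] * Z[pos_idx, , drop = FALSE]
      dZ <- Z * 0
      dZ[pos_idx, ] <- dZ[pos_idx, ] + dS[, 1] * pred
      for (j in seq_len(cfg$n_negatives)) {
        dpred <- dpred + dS[, j + 1] * Z[neg[, j], , drop = FALSE]
        contrib <- rowsum(dS[, j + 1] * pred, group = neg[, j])
        rows <- as.integer(rownames(contrib))
        dZ[rows, ] <- dZ[rows, ] + contrib
      }
      gWp <- crossprod(C[seq_len(m), , drop = FALSE], dpred)
      gbp <- colSums(dpred)
      dC <- rbind(dpred %*% t(Wp), matrix(0, cfg$k, cfg$hidden))
      gb <- gru_backward(gru, dC, gf$cache)
      dZ <- dZ + gb$dZ
      be <- stack_backward(encoder, dZ, er$caches)
      step <- step + 1L
      encoder <- stack_adam(encoder, be$grads, cfg$lr, 0.9, 0.999, 1e-8,
                            step)
      up <- gru_adam(gru, gb$grads, gru_state, cfg$lr, step)
      gru <- up$gru; gru_state <- up$state
      proj_state$mW <- 0.9 * proj_state$mW + 0.1 * gWp
      proj_state$vW <- 0.999 * proj_state$vW + 0.001 * gWp^2
      proj_state$mb <- 0.9 * proj_state$mb + 0.1 * gbp
      proj_state$vb <- 0.999 * proj_state$vb + 0.001 * gbp^2
      Wp <- Wp - cfg$lr * (proj_state$mW / (1 - 0.9^step)) /
        (sqrt(proj_state$vW / (1 - 0.999^step)) + 1e-8)
      bp <- bp - cfg$lr * (proj_state$mb / (1 - 0.9^step)) /
        (sqrt(proj_state$vb / (1 - 0.999^step)) + 1e-8)
    }
    log <- c(log, ep_loss / max(ep_m, 1))
  }
  structure(list(encoder = encoder, gru = gru, Wp = Wp, bp = bp,
                 norm = norm, cfg = cfg, enc_spec = enc, loss_log = log),
            class = "cpc_model")
}

#' Mean InfoNCE loss of a CPC model on a set of recordings
#'
#' Evaluation-only pass with freshly sampled negatives (deterministic given
#' `seed`).
#'
#' @param model a `cpc_model`.
#' @param frame_list list of frame arrays.
#' @param seed seed for negative sampling.
#' @return mean InfoNCE loss.
#' @export
cpc_evaluate <- function(model, frame_list, seed = 1L) {
  set.seed(seed)
  cfg <- model$cfg
  tot <- 0; n <- 0
  for (X3 in lapply(frame_list, frames_array)) {
    lat <- extract_latents(model, X3)
    T_len <- nrow(lat$Z)
    m <- T_len - cfg$k
    pred <- sweep(lat$C[seq_len(m), , drop = FALSE] %*% model$Wp, 2,
                  model$bp, "+")
    pos_idx <- seq_len(m) + cfg$k
    neg <- matrix(sample.int(T_len, m * cfg$n_negatives, replace = TRUE),
                  m, cfg$n_negatives)
    while (any(bad <- neg == pos_idx))
      neg[bad] <- sample.int(T_len, sum(bad), replace = TRUE)
    negs <- array(0, c(m, cfg$n_negatives, ncol(lat$Z)))
    for (j in seq_len(cfg$n_negatives))
      negs[, j, ] <- lat$Z[neg[, j], ]
    tot <- tot + infonce_loss(pred, lat$Z[pos_idx, , drop = FALSE],
                              negs) * m
    n <- n + m
  }
  tot / n
}

#' Extract CPC latent sequences
#'
#' Pure function of the inputs and weights: returns the per-frame encoder
#' latents `Z_t` and GRU context vectors `C_t` for external analysis.
#'
#' @param model a `cpc_model`.
#' @param frames frame array or `frame_array`.
#' @return list with matrices `Z` and `C` (rows = frames).
#' @export
extract_latents <- function(model, frames) {
  X3 <- normalize_frames(frames_array(frames), model$norm)
  T_len <- dim(X3)[1]
  Xm <- matrix(X3, T_len * 120L, 24L)
  er <- stack_forward(model$encoder, Xm, T_len, 120L)
  gf <- gru_forward(model$gru, er$out)
  list(Z = er$out, C = gf$H)
}
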