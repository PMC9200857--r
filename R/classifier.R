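#' Classifier architecture and training configuration
#'
#' The classifier is a dual-module convolutional network. The encoder
#' performs frame-level sensor fusion: a stack of strided 1-D convolutions
#' with leaky-ReLU activations over the 120 x 24 frame, global average
#' pooling, and a dense projection to a 160-dimensional frame latent. The
#' temporal module models frame-to-frame dynamics with a stack of dilated
#' (1, 2, 4, 8) same-padded temporal convolutions over the latent sequence
#' and emits per-frame softmax probabilities for the track's categories.
#' Posture, movement and carrying are trained as separate models sharing
#' this architecture.
#'
#' @param latent_dim encoder output width (default 160).
#' @param channels widths of the encoder conv stack.
#' @param filter_widths,strides conv filter sizes and strides.
#' @return an `encoder_spec` list.
#' @export
encoder_spec <- function(latent_dim = 160L, channels = c(32L, 48L, 64L),
                         filter_widths = c(7L, 5L, 3L),
                         strides = c(3L, 2L, 2L)) {
  stopifnot(length(channels) == length(filter_widths),
            length(channels) == length(strides), latent_dim >= 1)
  list(latent_dim = latent_dim, channels = channels,
       filter_widths = filter_widths, strides = strides,
       input_shape = c(120L, 24L))
}

#' @rdname encoder_spec
#' @param hidden temporal conv width.
#' @param dilations dilation factors of the temporal conv stack.
#' @param filter_width temporal filter size (odd).
#' @param n_classes number of output categories.
#' @export
temporal_spec <- function(n_classes, hidden = 64L,
                          dilations = c(1L, 2L, 4L, 8L), filter_width = 3L) {
  stopifnot(n_classes >= 2, filter_width %% 2 == 1)
  list(n_classes = n_classes, hidden = hidden, dilations = dilations,
       filter_width = filter_width)
}

#' @rdname encoder_spec
#' @param batch_frames minibatch length in consecutive frames.
#' @param lr ADAM learning rate.
#' @param beta1,beta2,eps ADAM moment parameters.
#' @param epochs training epochs.
#' @param sample_dropout_p probability of zeroing a time sample (all
#'   channels) of an input frame during training.
#' @param sensor_dropout_p probability of zeroing one whole sensor's six
#'   channels for a batch element.
#' @param val_fraction fraction of frames held out for validation-based
#'   epoch selection.
#' @param seed integer seed controlling init, batching and dropout.
#' @export
train_config <- function(batch_frames = 100L, lr = 1e-4, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8, epochs = 200L,
                         sample_dropout_p = 0.3, sensor_dropout_p = 0.3,
                         val_fraction = 0.2, seed = 1L) {
  stopifnot(val_fraction > 0, val_fraction < 1, epochs >= 0,
            sample_dropout_p >= 0, sample_dropout_p <= 1,
            sensor_dropout_p >= 0, sensor_dropout_p <= 1)
  list(batch_frames = as.integer(batch_frames), lr = lr, beta1 = beta1,
       beta2 = beta2, eps = eps, epochs = as.integer(epochs),
       sample_dropout_p = sample_dropout_p,
       sensor_dropout_p = sensor_dropout_p,
       val_fraction = val_fraction, seed = as.integer(seed))
}

#' Build an (untrained) motor-ability classifier model
#'
#' Initializes encoder and temporal-module weights deterministically from
#' the seed. The forward pass maps an `n x 120 x 24` frame array to an
#' `n x K` row-stochastic probability matrix.
#'
#' @param enc an [encoder_spec()].
#' @param cls a [temporal_spec()].
#' @param classes category names (length must equal `cls$n_classes`).
#' @param seed integer seed for weight initialization.
#' @return a `motor_model`.
#' @export
build_model <- function(enc, cls, classes, seed = 1L) {
  stopifnot(length(classes) == cls$n_classes)
  set.seed(seed)
  layers <- list()
  c_in <- enc$input_shape[2]
  for (i in seq_along(enc$channels)) {
    layers[[length(layers) + 1]] <-
      conv_layer(c_in, enc$channels[i], enc$filter_widths[i],
                 stride = enc$strides[i], pad = "valid", act = "lrelu")
    c_in <- enc$channels[i]
  }
  layers[[length(layers) + 1]] <- list(type = "gap")
  layers[[length(layers) + 1]] <- dense_layer(c_in, enc$latent_dim, "lrelu")
  encoder <- list(layers = layers)

  tlayers <- list()
  d <- enc$latent_dim
  for (dil in cls$dilations) {
    tlayers[[length(tlayers) + 1]] <-
      conv_layer(d, cls$hidden, cls$filter_width, stride = 1L,
                 dilation = dil, pad = "same", act = "lrelu")
    d <- cls$hidden
  }
  tlayers[[length(tlayers) + 1]] <- dense_layer(d, cls$n_classes, "linear")
  temporal <- list(layers = tlayers)

  structure(list(encoder = encoder, temporal = temporal,
                 enc_spec = enc, cls_spec = cls, classes = classes,
                 norm = NULL, trained = FALSE, log = NULL,
                 selected_epoch = NA_integer_),
            class = "motor_model")
}

frames_array <- function(frames) {
  if (inherits(frames, "frame_array")) frames$frames else frames
}

# [n, T, C] -> time-major (n*T) x C
to_time_major <- function(X3) {
  n <- dim(X3)[1]; T_len <- dim(X3)[2]; C <- dim(X3)[3]
  m <- matrix(aperm(X3, c(1, 2, 3)), n * T_len, C)
  m
}

normalize_frames <- function(X3, norm) {
  if (is.null(norm)) return(X3)
  for (c3 in seq_len(dim(X3)[3]))
    X3[, , c3] <- (X3[, , c3] - norm$mean[c3]) / norm$sd[c3]
  X3
}

model_forward <- function(model, X3, want_cache = FALSE) {
  n <- dim(X3)[1]
  Xm <- to_time_major(X3)
  er <- stack_forward(model$encoder, Xm, n, dim(X3)[2])
  latent <- er$out                                    # n x latent_dim
  tr <- stack_forward(model$temporal, latent, 1L, n)  # sequence of length n
  logits <- tr$out
  out <- list(latent = latent, logits = logits, probs = softmax_rows(logits))
  if (want_cache) { out$enc_cache <- er$caches; out$tmp_cache <- tr$caches }
  out
}

#' Predict per-frame category probabilities
#'
#' Deterministic inference pass (no dropout): returns per-frame softmax
#' probabilities and hard argmax labels.
#'
#' @param object a trained `motor_model`.
#' @param frames a `frame_array` or `n x 120 x 24` array.
#' @param ... unused.
#' @return list: `probs` (n x K matrix), `labels` (character), `latent`.
#' @export
predict.motor_model <- function(object, frames, ...) {
  X3 <- frames_array(frames)
  if (length(dim(X3)) != 3 ||
      !all(dim(X3)[2:3] == object$enc_spec$input_shape))
    stop("frame shape mismatch: expected n x ",
         object$enc_spec$input_shape[1], " x ",
         object$enc_spec$input_shape[2])
  X3 <- normalize_frames(X3, object$norm)
  fw <- model_forward(object, X3)
  colnames(fw$probs) <- object$classes
  list(probs = fw$probs,
       labels = object$classes[max.col(fw$probs, ties.method = "first")],
       latent = fw$latent)
}

#' Inverse-frequency class weights
#'
#' Loss weights proportional to the inverse occurrence probability of each
#' target class in the training data, normalized to mean 1 over the classes
#' present. Absent classes get `NA` and are excluded from the loss.
#'
#' @param targets character/factor labels, or an n x K (soft) target matrix.
#' @param classes category names (required for label input).
#' @return named numeric weight vector.
#' @export
class_weights <- function(targets, classes = NULL) {
  if (is.matrix(targets)) {
    classes <- classes %||% colnames(targets)
    freq <- colSums(targets) / sum(targets)
  } else {
    classes <- classes %||% sort(unique(as.character(targets)))
    freq <- as.numeric(table(factor(targets, classes))) / length(targets)
  }
  w <- ifelse(freq > 0, 1 / freq, NA_real_)
  present <- !is.na(w)
  w[present] <- w[present] / mean(w[present])
  stats::setNames(w, classes)
}

one_hot <- function(labels, classes) {
  m <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  m[cbind(seq_along(labels), match(labels, classes))] <- 1
  m
}

macro_f1 <- function(target, predicted, classes) {
  cm <- table(factor(target, classes), factor(predicted, classes))
  per_class_metrics(as.matrix(cm))$macro_f1
}

apply_input_dropout <- function(X3, p_sample, p_sensor) {
  n <- dim(X3)[1]; T_len <- dim(X3)[2]
  if (p_sample > 0) {
    mask <- matrix(stats::runif(n * T_len) < p_sample, n, T_len)
    for (c3 in seq_len(dim(X3)[3])) X3[, , c3][mask] <- 0
  }
  if (p_sensor > 0) {
    drop <- stats::runif(n) < p_sensor
    which_s <- sample.int(4, n, replace = TRUE)
    for (i in which(drop))
      X3[i, , (which_s[i] - 1) * 6 + 1:6] <- 0
  }
  X3
}

#' Train a motor-ability classifier
#'
#' Minibatch gradient descent (ADAM) on weighted categorical cross-entropy
#' over batches of consecutive frames. Sample dropout zeroes random time
#' samples of the input; sensor dropout zeroes all six channels of one
#' random sensor for a batch element. An 80/20 frame-level train/validation
#' split is used and the returned model carries the weights of the epoch
#' with the best validation unweighted-average F1, plus the full training
#' log.
#'
#' @param model a `motor_model` from [build_model()].
#' @param frames `frame_array` or array, aligned with `targets`.
#' @param targets character labels or an n x K target matrix (columns in
#'   `model$classes` order); soft targets from [iar_refine()] are accepted.
#' @param cfg a [train_config()].
#' @param frame_weights optional per-frame weights (0 excludes a frame).
#' @return the trained `motor_model`.
#' @export
train_classifier <- function(model, frames, targets, cfg = train_config(),
                             frame_weights = NULL) {
  X3 <- frames_array(frames)
  n <- dim(X3)[1]
  if (is.matrix(targets)) {
    Tm <- targets
  } else {
    targets <- as.character(targets)
    Tm <- one_hot(targets, model$classes)
  }
  stopifnot(nrow(Tm) == n)
  hard <- model$classes[max.col(Tm, ties.method = "first")]
  if (length(unique(hard)) < 2)
    stop("training targets contain a single class")
  set.seed(cfg$seed)

  ch_mean <- apply(X3, 3, mean)
  ch_sd <- pmax(apply(X3, 3, stats::sd), 1e-6)
  model$norm <- list(mean = ch_mean, sd = ch_sd)
  Xn <- normalize_frames(X3, model$norm)

  w_class <- class_weights(Tm, model$classes)
  w_frame <- w_class[match(hard, model$classes)]
  w_frame[is.na(w_frame)] <- 0
  if (!is.null(frame_weights)) w_frame <- w_frame * frame_weights

  val_idx <- sample.int(n, max(1L, round(cfg$val_fraction * n)))
  is_val <- rep(FALSE, n); is_val[val_idx] <- TRUE
  w_train <- w_frame; w_train[is_val] <- 0

  n_chunks <- ceiling(n / cfg$batch_frames)
  chunk_of <- function(j) {
    a <- (j - 1L) * cfg$batch_frames + 1L
    a:min(j * cfg$batch_frames, n)
  }
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    val_f1 = numeric(0))
  best_f1 <- -Inf; best_w <- NULL; best_epoch <- NA_integer_
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ep_loss <- 0; ep_n <- 0
    for (j in sample.int(n_chunks)) {
      idx <- chunk_of(j)
      if (all(w_train[idx] == 0)) next
      Xb <- apply_input_dropout(Xn[idx, , , drop = FALSE],
                                cfg$sample_dropout_p, cfg$sensor_dropout_p)
      fw <- model_forward(model, Xb, want_cache = TRUE)
      ce <- weighted_ce(fw$logits, Tm[idx, , drop = FALSE], w_train[idx])
      if (!is.finite(ce$loss))
        stop("non-finite training loss at epoch ", ep,
             " (check input scaling / learning rate)")
      ep_loss <- ep_loss + ce$loss * sum(w_train[idx] > 0)
      ep_n <- ep_n + sum(w_train[idx] > 0)
      bt <- stack_backward(model$temporal, ce$dLogits, fw$tmp_cache)
      be <- stack_backward(model$encoder, bt$dX, fw$enc_cache)
      step <- step + 1L
      model$temporal <- stack_adam(model$temporal, bt$grads, cfg$lr,
                                   cfg$beta1, cfg$beta2, cfg$eps, step)
      model$encoder <- stack_adam(model$encoder, be$grads, cfg$lr,
                                  cfg$beta1, cfg$beta2, cfg$eps, step)
    }
    fw <- model_forward(model, Xn)
    pred <- model$classes[max.col(fw$probs, ties.method = "first")]
    keep <- is_val & w_frame > 0
    vf1 <- macro_f1(hard[keep], pred[keep], model$classes)
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / max(ep_n, 1),
                                 val_f1 = vf1))
    if (!is.na(vf1) && vf1 > best_f1) {
      best_f1 <- vf1
      best_w <- list(enc = stack_weights(model$encoder),
                     tmp = stack_weights(model$temporal))
      best_epoch <- ep
    }
  }
  if (!is.null(best_w)) {
    model$encoder <- stack_set_weights(model$encoder, best_w$enc)
    model$temporal <- stack_set_weights(model$temporal, best_w$tmp)
  }
  model$trained <- cfg$epochs > 0
  model$log <- log
  model$selected_epoch <- best_epoch
  model
}

#' Recording-level ten-fold cross-validation
#'
#' Splits recordings into ten folds at the subject level (no subject is
#' split across folds), trains a model per fold on the remaining
#' recordings, predicts each held-out recording once, and compounds all
#' held-out confusions into a single matrix.
#'
#' @param recordings list of `list(frames, labels, subject)`; `labels` are
#'   per-frame target labels for the trained track.
#' @param classes category names of the track.
#' @param cfg a [train_config()].
#' @param enc,cls architecture specs (defaults [encoder_spec()] /
#'   [temporal_spec()]).
#' @param n_folds number of folds (default 10).
#' @return list: `predictions` (per recording), `confusion`
#'   (`compound_confusion`), `fold_of` (fold index per recording).
#' @export
crossvalidate_tenfold <- function(recordings, classes, cfg = train_config(),
                                  enc = encoder_spec(), cls = NULL,
                                  n_folds = 10L) {
  if (length(recordings) < n_folds)
    stop("fewer than ", n_folds,
         " recordings: use leave-one-subject-out (LOSO) instead")
  cls <- cls %||% temporal_spec(length(classes))
  subjects <- vapply(recordings, function(r) r$subject, character(1))
  set.seed(cfg$seed)
  uniq <- sample(unique(subjects))
  fold_of_subj <- stats::setNames(rep_len(seq_len(n_folds), length(uniq)),
                                  uniq)
  fold_of <- unname(fold_of_subj[subjects])
  preds <- vector("list", length(recordings))
  pairs <- list()
  for (f in sort(unique(fold_of))) {
    tr_idx <- which(fold_of != f)
    te_idx <- which(fold_of == f)
    Xtr <- abind_frames(lapply(recordings[tr_idx], function(r)
      frames_array(r$frames)))
    ytr <- unlist(lapply(recordings[tr_idx], function(r) r$labels))
    model <- build_model(enc, cls, classes, seed = cfg$seed + f)
    model <- train_classifier(model, Xtr, ytr, cfg)
    for (i in te_idx) {
      p <- predict(model, recordings[[i]]$frames)
      preds[[i]] <- p
      pairs[[length(pairs) + 1]] <-
        list(target = recordings[[i]]$labels, predicted = p$labels)
    }
  }
  list(predictions = preds,
       confusion = compound_confusion(pairs, classes),
       fold_of = fold_of)
}

abind_frames <- function(lst) {
  n <- sum(vapply(lst, function(x) dim(x)[1], integer(1)))
  d <- dim(lst[[1]])
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 0L
  for (x in lst) {
    out[(at + 1):(at + dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

#' Train and evaluate the active-carrying detector (ACD)
#'
#' Collapses the five-class carrying annotation to a binary target
#' (`active_carry` vs everything else), trains the shared architecture on
#' it, and evaluates with leave-one-subject-out cross-validation,
#' compounding held-out confusions.
#'
#' @param recordings list of `list(frames, carrying, subject)` where
#'   `carrying` holds per-frame five-class carrying labels.
#' @param cfg a [train_config()].
#' @param enc encoder spec.
#' @return list: `confusion` (2x2, classes `active_carry` / `other`),
#'   `metrics` (from [per_class_metrics()]), `predictions`, `folds`.
#' @export
train_acd <- function(recordings, cfg = train_config(),
                      enc = encoder_spec()) {
  classes <- c("other", "active_carry")
  collapse <- function(lab) ifelse(lab == "active_carry",
                                   "active_carry", "other")
  subjects <- vapply(recordings, function(r) r$subject, character(1))
  uniq <- unique(subjects)
  preds <- vector("list", length(recordings))
  pairs <- list()
  for (s in uniq) {
    tr_idx <- which(subjects != s)
    te_idx <- which(subjects == s)
    Xtr <- abind_frames(lapply(recordings[tr_idx],
                               function(r) frames_array(r$frames)))
    ytr <- collapse(unlist(lapply(recordings[tr_idx],
                                  function(r) r$carrying)))
    model <- build_model(enc, temporal_spec(2L), classes,
                         seed = cfg$seed + match(s, uniq))
    model <- train_classifier(model, Xtr, ytr, cfg)
    for (i in te_idx) {
      p <- predict(model, recordings[[i]]$frames)
      preds[[i]] <- p
      pairs[[length(pairs) + 1]] <-
        list(target = collapse(recordings[[i]]$carrying),
             predicted = p$labels)
    }
  }
  cm <- compound_confusion(pairs, classes)
  list(confusion = cm, metrics = per_class_metrics(cm),
       predictions = preds, folds = uniq)
}

#' Mask frames retained after active-carrying filtering
#'
#' Frames predicted as `active_carry` are excluded from downstream
#' distribution analyses.
#'
#' @param predictions prediction object from [predict.motor_model()] (or a
#'   character vector of binary carrying labels).
#' @return logical mask, `TRUE` for retained frames; attribute
#'   `retained_fraction`.
#' @export
acd_filter <- function(predictions) {
  labels <- if (is.character(predictions)) predictions else predictions$labels
  mask <- labels != "active_carry"
  if (!any(mask))
    warning("all frames flagged as active carrying; no frames retained")
  attr(mask, "retained_fraction") <- mean(mask)
  mask
}
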