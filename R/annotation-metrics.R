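#' Read / write annotation files
#'
#' Annotation files are CSV with columns `rater,track,start_s,end_s,label`
#' using half-open second intervals `[start_s, end_s)`.
#'
#' @param path file path.
#' @return [read_annotations()]: an `annotation_set`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  raters <- sort(unique(df$rater))
  n <- max(df$end_s)
  tracks <- list()
  for (tr in unique(df$track)) {
    mat <- matrix("unlabeled", nrow = n, ncol = length(raters),
                  dimnames = list(NULL, raters))
    sub <- df[df$track == tr, ]
    for (i in seq_len(nrow(sub)))
      mat[(sub$start_s[i] + 1):sub$end_s[i], sub$rater[i]] <- sub$label[i]
    tracks[[tr]] <- mat
  }
  structure(list(raters = raters, n_seconds = n, tracks = tracks),
            class = "annotation_set")
}

#' @rdname read_annotations
#' @param ann an `annotation_set`.
#' @export
write_annotations <- function(ann, path) {
  rows <- list()
  for (tr in names(ann$tracks)) {
    m <- ann$tracks[[tr]]
    for (r in seq_len(ncol(m))) {
      rl <- rle(m[, r])
      e <- cumsum(rl$lengths)
      rows[[length(rows) + 1]] <-
        data.frame(rater = colnames(m)[r] %||% paste0("rater", r),
                   track = tr, start_s = e - rl$lengths, end_s = e,
                   label = rl$values, stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Map per-second multi-rater annotations onto analysis frames
#'
#' For each frame and rater the frame label is the annotated category
#' covering the largest share of the frame's time interval (plurality-time
#' assignment; ties broken by the track's fixed priority order). Rater
#' labels are compounded into a per-frame distribution over categories, a
#' hard majority label, and an ambiguity flag. Frames with more than half
#' of their interval outside the annotation span are marked excluded.
#'
#' @param ann an `annotation_set` covering the recording (seconds counted
#'   from the signal origin).
#' @param frames a `frame_array` from [make_frames()].
#' @return a `frame_labels` object: per track, `per_rater`
#'   (frames x raters character matrix), `dist` (frames x categories
#'   proportion-of-raters matrix), `hard` labels, and `ambiguous` flags;
#'   plus shared `excluded` flags and `frame_times`.
#' @export
frames_from_annotations <- function(ann, frames) {
  stopifnot(inherits(ann, "annotation_set"))
  n_f <- dim(frames$frames)[1]
  span <- frames$frame_len / frames$rate
  fs <- frames$frame_times - span / 2
  fe <- fs + span
  out <- list()
  excluded <- rep(FALSE, n_f)
  for (tr in names(ann$tracks)) {
    m <- ann$tracks[[tr]]
    cls <- track_classes(tr)
    prio <- track_priority(tr)
    n_r <- ncol(m)
    per_rater <- matrix("unlabeled", n_f, n_r)
    for (i in seq_len(n_f)) {
      s0 <- floor(fs[i]); s1 <- ceiling(fe[i]) - 1
      secs <- s0:s1
      w <- pmin(fe[i], secs + 1) - pmax(fs[i], secs)
      inside <- secs >= 0 & secs < ann$n_seconds & w > 1e-9
      unlab_t <- sum(w[!inside])
      if (unlab_t > span / 2) excluded[i] <- TRUE
      if (!any(inside)) next
      secs_i <- secs[inside]; w_i <- w[inside]
      for (r in seq_len(n_r)) {
        lab <- m[secs_i + 1, r]
        tot <- rowsum(w_i, lab)
        best <- rownames(tot)[tot == max(tot)]
        if (length(best) > 1)
          best <- best[order(match(best, c(prio, "unlabeled")))][1]
        per_rater[i, r] <- best
      }
    }
    dist <- t(apply(per_rater, 1, function(lab) {
      tab <- table(factor(lab, levels = c(cls, "unlabeled")))
      as.numeric(tab) / n_r
    }))
    colnames(dist) <- c(cls, "unlabeled")
    hard <- apply(dist, 1, function(p) {
      p <- p[cls]
      if (all(p == 0)) return("unlabeled")
      best <- names(p)[p == max(p)]
      if (length(best) > 1) best <- best[order(match(best, prio))][1]
      best
    })
    ambiguous <- apply(per_rater, 1, function(lab) length(unique(lab)) > 1)
    out[[tr]] <- list(per_rater = per_rater, dist = dist, hard = hard,
                      ambiguous = ambiguous)
  }
  structure(list(tracks = out, excluded = excluded,
                 frame_times = frames$frame_times),
            class = "frame_labels")
}

#' Compound a confusion matrix over recordings and rater pairs
#'
#' Sums aligned (target, predicted) label-sequence pairs into a single
#' K x K count matrix (rows = target class). Summing confusions over the
#' whole corpus before computing statistics avoids the instability of
#' per-recording metrics under strong class imbalance.
#'
#' @param pairs list of `list(target = , predicted = )` character vectors.
#' @param classes category names.
#' @return a `compound_confusion`: integer matrix with `n_items` attribute.
#' @export
compound_confusion <- function(pairs, classes) {
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(target = classes, predicted = classes))
  for (p in pairs) {
    stopifnot(length(p$target) == length(p$predicted))
    keep <- p$target != "unlabeled" & p$predicted != "unlabeled"
    tg <- p$target[keep]; pd <- p$predicted[keep]
    unknown <- setdiff(unique(c(tg, pd)), classes)
    if (length(unknown) > 0)
      stop("unknown class label: ", paste(unknown, collapse = ", "))
    cm <- cm + table(factor(tg, classes), factor(pd, classes))
  }
  structure(as.matrix(cm), class = "compound_confusion",
            n_items = sum(cm))
}

#' Fleiss' kappa (multi-rater) and its two-rater specialization
#'
#' For an `annotation_set`, computes standard multi-rater Fleiss' kappa on
#' the item x category count table of the requested track (items =
#' seconds labelled by all raters). For a confusion matrix, computes the
#' two-rater chance-corrected agreement (Cohen-type): observed diagonal
#' proportion corrected by the product-of-marginals chance rate.
#'
#' @param x an `annotation_set` or a (compound) confusion matrix.
#' @param track track name (annotation-set form).
#' @return kappa in `[-1, 1]`.
#' @export
fleiss_kappa <- function(x, track = NULL) {
  if (inherits(x, "annotation_set")) {
    m <- x$tracks[[track]]
    if (is.null(m)) stop("no such track: ", track)
    keep <- rowSums(m == "unlabeled") == 0
    m <- m[keep, , drop = FALSE]
    cls <- sort(unique(as.vector(m)))
    counts <- vapply(cls, function(k) rowSums(m == k), numeric(nrow(m)))
    if (!is.matrix(counts)) counts <- matrix(counts, nrow = nrow(m))
    return(fleiss_kappa_counts(counts))
  }
  cm <- unclass(as.matrix(x))
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12)
    stop("kappa undefined: all items in a single category")
  (po - pe) / (1 - pe)
}

#' @rdname fleiss_kappa
#' @param counts item x category count matrix (each row sums to the number
#'   of raters).
#' @export
fleiss_kappa_counts <- function(counts) {
  n_r <- unique(rowSums(counts))
  if (length(n_r) != 1) stop("all items must be rated by the same number of raters")
  if (n_r < 2) stop("need at least 2 raters")
  N <- nrow(counts)
  p_j <- colSums(counts) / (N * n_r)
  P_i <- (rowSums(counts^2) - n_r) / (n_r * (n_r - 1))
  Pbar <- mean(P_i)
  Pe <- sum(p_j^2)
  if (abs(1 - Pe) < 1e-12)
    stop("kappa undefined: all items in a single category")
  (Pbar - Pe) / (1 - Pe)
}

#' Per-class and overall metrics from a confusion matrix
#'
#' Standard confusion-matrix statistics: per-class recall, precision, F1
#' and a class-specific kappa (one-vs-rest collapse followed by the
#' two-rater kappa), plus overall accuracy and the unweighted average F1
#' over classes with support. Metrics for empty classes are `NA`
#' (undefined), not zero.
#'
#' @param cm confusion matrix (rows = target).
#' @return list with `per_class` data.frame, `accuracy`, `macro_f1`.
#' @export
per_class_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  n <- sum(cm)
  k <- nrow(cm)
  cls <- rownames(cm)
  recall <- precision <- f1 <- kap <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    tp <- cm[i, i]; fn <- sum(cm[i, ]) - tp; fp <- sum(cm[, i]) - tp
    if (tp + fn > 0) recall[i] <- tp / (tp + fn)
    if (tp + fp > 0) precision[i] <- tp / (tp + fp)
    if (!is.na(recall[i]) && !is.na(precision[i]) &&
        (recall[i] + precision[i]) > 0)
      f1[i] <- 2 * recall[i] * precision[i] / (recall[i] + precision[i])
    if (tp + fn > 0) {
      tn <- n - tp - fn - fp
      m2 <- matrix(c(tp, fn, fp, tn), 2, 2, byrow = TRUE)
      kap[i] <- tryCatch(fleiss_kappa(m2), error = function(e) NA_real_)
    }
  }
  list(per_class = data.frame(class = cls, recall = recall,
                              precision = precision, f1 = f1,
                              kappa = kap, stringsAsFactors = FALSE),
       accuracy = sum(diag(cm)) / n,
       macro_f1 = mean(f1, na.rm = TRUE))
}

#' Iterative annotation refinement (IAR)
#'
#' Produces probabilistic training targets that combine multi-rater label
#' distributions with a classifier's posterior on contested frames.
#' Uncontested frames (all raters agree) keep their one-hot targets.
#' Contested frames are re-targeted as
#' `(1 - alpha) * rater_distribution + alpha * classifier_posterior`
#' (renormalized), and training/refinement alternates until fewer than
#' `tol` of all frames change or `max_iter` is reached. A classifier
#' posterior is consistent across similar frames, so the refined targets
#' trade rater idiosyncrasy for internal consistency.
#'
#' @param rater_dist frames x categories matrix of rater label proportions
#'   (rows sum to 1), e.g. `frame_labels$tracks$posture$dist` without the
#'   unlabeled column, renormalized.
#' @param train callable: given the current target matrix, trains a model
#'   and returns the posterior matrix (same shape).
#' @param alpha mixing weight of the classifier posterior in `[0, 1]`.
#' @param max_iter maximum refine iterations.
#' @param tol stop when the altered-frame fraction drops below this.
#' @return list: `targets`, `iterations`, `altered_fraction`, `contested`.
#' @export
iar_refine <- function(rater_dist, train, alpha = 0.5, max_iter = 3L,
                       tol = 0.01) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  stopifnot(all(abs(rowSums(rater_dist) - 1) < 1e-6))
  contested <- apply(rater_dist, 1, max) < 1 - 1e-9
  targets <- rater_dist
  if (!any(contested) || alpha == 0)
    return(list(targets = targets, iterations = 0L, altered_fraction = 0,
                contested = contested))
  altered <- NA_real_
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    post <- train(targets)
    stopifnot(all(dim(post) == dim(targets)))
    new <- targets
    mix <- (1 - alpha) * rater_dist[contested, , drop = FALSE] +
           alpha * post[contested, , drop = FALSE]
    new[contested, ] <- mix / rowSums(mix)
    altered <- mean(apply(abs(new - targets), 1, max) > 1e-3)
    targets <- new
    if (altered < tol) break
  }
  list(targets = targets, iterations = it, altered_fraction = altered,
       contested = contested)
}
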