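#' Recording-level motor-ability distributions
#'
#' Aggregates per-frame (or per-second) posture and movement labels over
#' the retained (non-carrying) portion of a recording into the feature
#' vector used by the BIMS model: the fused posture occupancy distribution
#' (supine, prone, side, crawl posture, sitting, standing) and, for each
#' fused posture, the conditional distribution over fused movement classes
#' (still, proto, elementary, fluent, pivot, roll, transition).
#' Conditional blocks of postures never observed are zero-filled and
#' flagged unsupported.
#'
#' @param posture,movement aligned label vectors (full taxonomy; fused
#'   labels are also accepted).
#' @param mask logical retain mask (e.g. from [acd_filter()]); default all.
#' @return a `motor_features` object: `posture` (6-vector summing to 1),
#'   `movement` (list of 7-vectors per fused posture), `supported` flags,
#'   `n_frames` retained.
#' @export
compute_distributions <- function(posture, movement, mask = NULL) {
  stopifnot(length(posture) == length(movement))
  if (is.null(mask)) mask <- rep(TRUE, length(posture))
  keep <- mask & posture != "unlabeled" & movement != "unlabeled"
  if (!any(keep)) stop("no retained frames to compute distributions from")
  p <- fuse_lr(posture[keep])
  m <- fuse_lr(movement[keep])
  fp <- fused_posture_classes()
  fm <- fused_movement_classes()
  ptab <- table(factor(p, fp))
  pv <- as.numeric(ptab) / sum(ptab)
  names(pv) <- fp
  mv <- list()
  supported <- stats::setNames(as.numeric(ptab) > 0, fp)
  for (f in fp) {
    if (supported[f]) {
      t2 <- table(factor(m[p == f], fm))
      mv[[f]] <- stats::setNames(as.numeric(t2) / sum(t2), fm)
    } else {
      mv[[f]] <- stats::setNames(numeric(length(fm)), fm)
    }
  }
  structure(list(posture = pv, movement = mv, supported = supported,
                 n_frames = sum(keep)),
            class = "motor_features")
}

#' Flatten a motor-features object into a numeric vector
#'
#' Order: 6 posture fractions, then 7 conditional movement fractions for
#' each fused posture (42), giving 48 features. Attribute `block` labels
#' each feature's block; `active` marks features belonging to supported
#' blocks.
#'
#' @param f a `motor_features`.
#' @return named numeric vector of length 48.
#' @export
features_as_vector <- function(f) {
  fp <- fused_posture_classes()
  v <- c(f$posture, unlist(f$movement))
  block <- c(rep("posture", length(f$posture)),
             rep(fp, each = length(fused_movement_classes())))
  names(v) <- c(paste0("posture.", names(f$posture)),
                paste0(rep(fp, each = length(fused_movement_classes())), ".",
                       rep(fused_movement_classes(), length(fp))))
  active <- block == "posture" | f$supported[block]
  attr(v, "block") <- block
  attr(v, "active") <- unname(active)
  v
}

#' BIMS rescaling of a motor-ability age prediction
#'
#' Maps a predicted motor-ability age in months to the bounded 0-100
#' maturity score: `(predicted_age - 4) * 100 / (16 - 4)`, so 4 months
#' maps to 0 and 16 months (and beyond, where the description scheme
#' saturates) to 100.
#'
#' @param predicted_age_months predicted age in months.
#' @return BIMS score.
#' @export
bims_rescale <- function(predicted_age_months) {
  (predicted_age_months - 4) * 100 / (16 - 4)
}

#' Fit the age-binned Gaussian normative model
#'
#' Diagonal-covariance Gaussian models of the motor-ability feature vector
#' are estimated at 1-month age-bin centres from 4 to 16 months. Each bin
#' uses recordings within +/- 1 month of the centre; if fewer than 3 fall
#' in the window, the recordings with the smallest age difference to the
#' centre are added until 3 are reached (ties broken toward the younger
#' recording). Ages above 16 months are pooled into the 16-month bin.
#' Per-feature standard deviations are floored at 1e-4 for stability.
#'
#' @param cohort list of `list(subject, age, features)` entries (as from
#'   [generate_age_cohort()] or built from [compute_distributions()]).
#' @param centers bin centres in months.
#' @param min_members minimum recordings per bin.
#' @param sd_floor standard-deviation floor.
#' @return a `bims_model`: per-bin centre, member indices, `mu`, `sigma`.
#' @export
fit_age_bins <- function(cohort, centers = 4:16, min_members = 3L,
                         sd_floor = 1e-4) {
  if (length(cohort) < min_members)
    stop("cohort must contain at least ", min_members, " recordings")
  ages <- vapply(cohort, function(r) r$age, numeric(1))
  X <- t(vapply(cohort, function(r) features_as_vector(r$features),
                numeric(48)))
  act <- t(vapply(cohort, function(r)
    attr(features_as_vector(r$features), "active"), logical(48)))
  bins <- list()
  for (b in centers) {
    inside <- which(abs(ages - b) <= 1 + 1e-9)
    if (b == max(centers)) inside <- union(inside, which(ages > max(centers)))
    if (length(inside) < min_members) {
      outside <- setdiff(seq_along(cohort), inside)
      # nearest-age fill; equidistant candidates resolve toward the younger
      ord <- outside[order(abs(ages[outside] - b), ages[outside])]
      inside <- c(inside, ord[seq_len(min_members - length(inside))])
    }
    mu <- sig <- numeric(ncol(X))
    for (j in seq_len(ncol(X))) {
      rows <- inside[act[inside, j]]
      if (length(rows) == 0) rows <- inside
      mu[j] <- mean(X[rows, j])
      sig[j] <- if (length(rows) > 1) stats::sd(X[rows, j]) else 0
    }
    sig <- pmax(sig, sd_floor)
    bins[[as.character(b)]] <- list(center = b, members = inside,
                                    mu = mu, sigma = sig)
  }
  structure(list(bins = bins, centers = centers, sd_floor = sd_floor,
                 feature_names = colnames(X)),
            class = "bims_model")
}

#' Predict motor-ability age and BIMS score
#'
#' Computes the diagonal-Gaussian log-likelihood of the recording's feature
#' vector under every age bin (including the normalization constant),
#' converts to relative weights after subtracting the maximum
#' log-likelihood (underflow-safe), and returns the likelihood-weighted
#' average of the bin centre ages together with its BIMS rescaling.
#' Features in unsupported conditional blocks of the input are masked out
#' of the likelihood rather than penalizing it.
#'
#' @param model a `bims_model`.
#' @param x a `motor_features` object (or 48-feature vector).
#' @return a `bims_prediction`: `log_lik` per bin, `weights`,
#'   `predicted_age`, `bims`.
#' @export
predict_age <- function(model, x) {
  if (inherits(x, "motor_features")) {
    v <- features_as_vector(x)
    active <- attr(v, "active")
  } else {
    v <- x
    active <- attr(v, "active") %||% rep(TRUE, length(v))
  }
  ll <- vapply(model$bins, function(b)
    sum(stats::dnorm(v[active], b$mu[active], b$sigma[active], log = TRUE)),
    numeric(1))
  if (all(!is.finite(ll))) stop("degenerate model: all likelihoods are zero")
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  centers <- vapply(model$bins, function(b) b$center, numeric(1))
  age <- sum(w * centers)
  structure(list(log_lik = ll, weights = w, predicted_age = age,
                 bims = bims_rescale(age)),
            class = "bims_prediction")
}

#' Leave-one-subject-out evaluation of the BIMS predictor
#'
#' For each subject, the age-bin model is refit without any of that
#' subject's recordings and the held-out recordings are scored. Target
#' ages above 16 months are evaluated as 16 (the saturation bound of the
#' description scheme).
#'
#' @param cohort list of `list(subject, age, features)`.
#' @param centers,min_members,sd_floor passed to [fit_age_bins()].
#' @return list: `predictions` data.frame (subject, age, target_age,
#'   predicted_age, bims), `pearson_r`, `mae`.
#' @export
loso_evaluate <- function(cohort, centers = 4:16, min_members = 3L,
                          sd_floor = 1e-4) {
  subjects <- vapply(cohort, function(r) r$subject, character(1))
  if (length(unique(subjects)) < 4)
    stop("need at least 4 subjects for LOSO evaluation")
  rows <- list()
  for (s in unique(subjects)) {
    holdout <- which(subjects == s)
    fit <- fit_age_bins(cohort[-holdout], centers, min_members, sd_floor)
    for (i in holdout) {
      p <- predict_age(fit, cohort[[i]]$features)
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, age = cohort[[i]]$age,
        target_age = min(cohort[[i]]$age, max(centers)),
        predicted_age = p$predicted_age, bims = p$bims,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  r <- if (stats::sd(df$target_age) > 0 && stats::sd(df$predicted_age) > 0)
    stats::cor(df$target_age, df$predicted_age) else NA_real_
  list(predictions = df, pearson_r = r,
       mae = mean(abs(df$predicted_age - df$target_age)))
}

#' Recording-length robustness of the BIMS estimate
#'
#' From source recordings of at least `min_source_min` minutes, random-
#' start subsegments of increasing length are sampled; the motor-ability
#' distributions are recomputed on each subsegment, scored against a model
#' fitted without the segment's subject (LOSO), and the absolute age error
#' summarized per segment length (median, IQR, range over iterations).
#'
#' @param long_recordings list of `list(subject, age, posture, movement,
#'   mask)` with per-second labels of recordings >= `min_source_min` min.
#' @param cohort cohort used to fit the age-bin models.
#' @param lengths_min segment lengths in minutes.
#' @param n_iterations random segments per length.
#' @param min_source_min minimum usable source length (minutes).
#' @param seed integer seed.
#' @return data.frame: one row per length with `median_mae`, `iqr_lo`,
#'   `iqr_hi`, `min_mae`, `max_mae`, `n_iterations`.
#' @export
length_robustness <- function(long_recordings, cohort,
                              lengths_min = seq(10, 100, by = 10),
                              n_iterations = 1000L, min_source_min = 120,
                              seed = 1L) {
  set.seed(seed)
  durs <- vapply(long_recordings, function(r) length(r$posture),
                 numeric(1)) / 60
  usable <- which(durs >= min_source_min)
  if (length(usable) == 0) stop("no recording reaches the source length")
  long_recordings <- long_recordings[usable]
  durs <- durs[usable]
  subjects <- vapply(long_recordings, function(r) r$subject, character(1))
  cohort_subj <- vapply(cohort, function(r) r$subject, character(1))
  fits <- lapply(unique(subjects), function(s)
    fit_age_bins(cohort[cohort_subj != s]))
  names(fits) <- unique(subjects)
  out <- list()
  for (L in lengths_min) {
    if (any(L > durs)) {
      warning("segment length ", L, " min exceeds a source recording; ",
              "skipping those recordings")
    }
    ok <- which(durs >= L)
    if (length(ok) == 0) next
    err <- numeric(n_iterations)
    for (it in seq_len(n_iterations)) {
      ri <- ok[((it - 1) %% length(ok)) + 1]
      rec <- long_recordings[[ri]]
      n_s <- length(rec$posture)
      seg <- L * 60
      start <- sample.int(n_s - seg + 1L, 1L)
      idx <- start:(start + seg - 1L)
      mask <- if (is.null(rec$mask)) NULL else rec$mask[idx]
      f <- compute_distributions(rec$posture[idx], rec$movement[idx], mask)
      p <- predict_age(fits[[rec$subject]], f)
      err[it] <- abs(p$predicted_age - min(rec$age, 16))
    }
    q <- stats::quantile(err, c(0.25, 0.5, 0.75))
    out[[length(out) + 1]] <- data.frame(
      length_min = L, median_mae = q[[2]], iqr_lo = q[[1]], iqr_hi = q[[3]],
      min_mae = min(err), max_mae = max(err), mean_mae = mean(err),
      n_iterations = n_iterations)
  }
  do.call(rbind, out)
}

#' Likelihood-weighted AIMS predictor
#'
#' The same binned Gaussian likelihood machinery as the BIMS age model,
#' with bins over the clinical AIMS score instead of age, evaluated with
#' leave-one-subject-out cross-validation.
#'
#' @param cohort list of `list(subject, age, features, aims)` entries with
#'   AIMS scores.
#' @param bin_width spacing of AIMS bin centres.
#' @param min_members minimum recordings per bin.
#' @param sd_floor standard-deviation floor.
#' @return list: `predictions` data.frame (subject, aims, predicted_aims),
#'   `pearson_r`, `mae`.
#' @export
aims_predict <- function(cohort, bin_width = 5, min_members = 3L,
                         sd_floor = 1e-4) {
  scored <- Filter(function(r) !is.null(r$aims) && !is.na(r$aims), cohort)
  if (length(scored) < 3) stop("need at least 3 AIMS-scored recordings")
  scores <- vapply(scored, function(r) r$aims, numeric(1))
  centers <- seq(floor(min(scores)), ceiling(max(scores)), by = bin_width)
  if (length(centers) < 1) centers <- mean(scores)
  subjects <- vapply(scored, function(r) r$subject, character(1))
  rows <- list()
  for (s in unique(subjects)) {
    ho <- which(subjects == s)
    train <- scored[-ho]
    if (length(train) < min_members) train <- scored
    relab <- lapply(train, function(r) {
      r$age <- r$aims    # reuse the age-bin fitter on the AIMS axis
      r
    })
    fit <- fit_age_bins(relab, centers = centers,
                        min_members = min(min_members, length(relab)),
                        sd_floor = sd_floor)
    for (i in ho) {
      p <- predict_age(fit, scored[[i]]$features)
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, aims = scored[[i]]$aims,
        predicted_aims = p$predicted_age, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  r <- if (stats::sd(df$predicted_aims) > 0)
    stats::cor(df$aims, df$predicted_aims) else NA_real_
  list(predictions = df, pearson_r = r,
       mae = mean(abs(df$predicted_aims - df$aims)))
}
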