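#' Simulate a ground-truth state sequence
#'
#' Semi-Markov generator for per-second labels on the posture, movement and
#' carrying tracks. Posture occupancy is produced by time-budgeted segment
#' allocation: each class receives a total number of seconds equal to its
#' age-dependent prior share, that budget is cut into dwell segments with
#' negative-binomial lengths, and segment order is shuffled. Empirical
#' occupancy therefore converges to the configured prior by construction as
#' duration grows, while transition-rate statistics remain meaningful.
#' Movement labels are drawn semi-Markov within each posture segment from
#' the age prior restricted to the posture's permitted movements; carrying
#' is an independent semi-Markov layer.
#'
#' @param cfg a [sim_config()].
#' @return A `state_sequence`: data.frame with columns `second`, `posture`,
#'   `movement`, `carrying`, one row per second; attributes `age_months`.
#' @export
simulate_state_sequence <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$duration_s
  prior <- age_priors(cfg, "posture")
  if (length(prior) == 0 || all(prior == 0)) stop("empty posture taxonomy")

  budgets <- allocate_counts(prior, n)
  segs_label <- character(0); segs_len <- integer(0)
  for (cls in names(budgets)) {
    rem <- budgets[[cls]]
    while (rem > 0) {
      d <- min(rem, draw_dwell(cfg$dwell_params$posture, cfg$dwell_params$size))
      segs_label <- c(segs_label, cls); segs_len <- c(segs_len, d)
      rem <- rem - d
    }
  }
  ord <- sample.int(length(segs_len))
  segs_label <- segs_label[ord]; segs_len <- segs_len[ord]
  posture <- rep(segs_label, segs_len)

  constraints <- posture_movement_constraints()
  mv_prior <- age_priors(cfg, "movement")
  movement <- character(n)
  pos <- 1L
  for (i in seq_along(segs_len)) {
    len <- segs_len[i]
    allowed <- constraints[[segs_label[i]]]
    pr <- mv_prior[allowed]
    if (sum(pr) == 0) pr[] <- 1
    pr <- pr / sum(pr)
    filled <- 0L
    while (filled < len) {
      d <- min(len - filled,
               draw_dwell(cfg$dwell_params$movement, cfg$dwell_params$size))
      movement[(pos + filled):(pos + filled + d - 1L)] <-
        sample(names(pr), 1L, prob = pr)
      filled <- filled + d
    }
    pos <- pos + len
  }

  carrying <- character(0)
  cp <- cfg$carrying_prior
  while (length(carrying) < n) {
    d <- draw_dwell(cfg$dwell_params$carrying, cfg$dwell_params$size)
    carrying <- c(carrying, rep(sample(names(cp), 1L, prob = cp), d))
  }
  carrying <- carrying[seq_len(n)]

  out <- data.frame(second = seq_len(n) - 1L, posture = posture,
                    movement = movement, carrying = carrying,
                    stringsAsFactors = FALSE)
  attr(out, "age_months") <- cfg$age_months
  class(out) <- c("state_sequence", "data.frame")
  out
}

# largest-remainder allocation of n seconds across classes by prior
allocate_counts <- function(prior, n) {
  raw <- prior * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(base), names(prior))
}

draw_dwell <- function(mu, size) {
  max(1L, stats::rnbinom(1L, size = size, mu = mu - 1) + 1L)
}

#' Synthesize multi-sensor IMU signals from a state sequence
#'
#' For each of the four limb sensors, acceleration is the posture's gravity
#' vector (from the fixed orientation lookup) plus movement-class-dependent
#' sinusoidal oscillation plus white noise; angular velocity is a per-sensor
#' constant gyroscope bias plus oscillation plus noise. Active carrying adds
#' a common-mode low-frequency component to all sensors (adult locomotion).
#' Packets are emitted at a nominal 52 Hz with Gaussian timestamp jitter
#' and random drops. With all noise terms zero and `still` movement, the
#' accelerometer reads exactly the gravity vector and the gyroscope exactly
#' the true bias.
#'
#' @param seq a `state_sequence`.
#' @param cfg the [sim_config()] used to generate it.
#' @return A `sim_recording`: list with `streams` (per sensor, data.frame
#'   `t, ax, ay, az, gx, gy, gz`), `ground_truth`, `gyro_bias_true`
#'   (4 x 3 matrix, deg/s) and `metadata`.
#' @export
synthesize_imu <- function(seq, cfg) {
  stopifnot(inherits(seq, "state_sequence"))
  if (nrow(seq) == 0) stop("state sequence is empty")
  set.seed(cfg$seed + 1L)
  orient <- posture_orientations()
  unknown <- setdiff(unique(seq$posture), names(orient))
  if (length(unknown) > 0)
    stop("unknown posture label: ", paste(unknown, collapse = ", "))
  dyn <- movement_dynamics()
  g <- 9.81
  rate <- cfg$rate_hz
  n_sec <- nrow(seq)

  # contiguous runs of identical (posture, movement, carrying)
  key <- paste(seq$posture, seq$movement, seq$carrying)
  r <- rle(key)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  runs <- data.frame(start_s = run_start - 1L, end_s = run_end,
                     posture = seq$posture[run_start],
                     movement = seq$movement[run_start],
                     carrying = seq$carrying[run_start],
                     stringsAsFactors = FALSE)

  bias <- matrix(stats::runif(12, -cfg$noise$gyro_bias_range,
                              cfg$noise$gyro_bias_range), nrow = 4)
  rownames(bias) <- sensor_ids()

  # per-run common-mode carrying oscillation parameters
  carry_f <- stats::runif(nrow(runs), 0.8, 2)
  carry_ph <- stats::runif(nrow(runs), 0, 2 * pi)

  streams <- list()
  for (s in sensor_ids()) {
    ideal <- seq(0, n_sec - 1 / rate, by = 1 / rate)
    tt <- ideal + stats::rnorm(length(ideal), 0, cfg$noise$packet_jitter_sd)
    tt <- sort(pmax(tt, 0))
    tt <- tt + cumsum(c(0, diff(tt) <= 0)) * 1e-6    # enforce strictly increasing
    keep <- stats::runif(length(tt)) >= cfg$noise$packet_drop_p
    tt <- tt[keep]
    sig <- matrix(0, nrow = length(tt), ncol = 6)
    run_of <- findInterval(tt, runs$start_s)
    run_of[run_of < 1] <- 1L
    run_of[run_of > nrow(runs)] <- nrow(runs)
    for (ri in seq_len(nrow(runs))) {
      idx <- which(run_of == ri)
      if (length(idx) == 0) next
      t_i <- tt[idx]
      d <- dyn[[runs$movement[ri]]]
      grav <- g * orient[[runs$posture[ri]]][s, ]
      acc <- matrix(rep(grav, each = length(idx)), ncol = 3)
      gyr <- matrix(rep(bias[s, ], each = length(idx)), ncol = 3)
      if (d$a > 0) {
        amp_scale <- stats::rlnorm(1, 0, 0.35)   # overlap between tiers
        f <- stats::runif(2, d$band[1], d$band[2])
        for (c3 in 1:3) {
          a_c <- d$a * amp_scale * stats::runif(1, 0.4, 1)
          g_c <- d$g * amp_scale * stats::runif(1, 0.4, 1)
          ph <- stats::runif(2, 0, 2 * pi)
          osc <- sin(2 * pi * f[1] * t_i + ph[1]) +
                 0.5 * sin(2 * pi * f[2] * t_i + ph[2])
          acc[, c3] <- acc[, c3] + a_c * osc
          gyr[, c3] <- gyr[, c3] + g_c * osc
        }
      }
      if (runs$carrying[ri] == "active_carry") {
        osc <- sin(2 * pi * carry_f[ri] * t_i + carry_ph[ri])
        acc <- acc + 2.5 * osc     # same phase on every sensor and channel
        gyr <- gyr + 40 * osc
      }
      sig[idx, 1:3] <- acc
      sig[idx, 4:6] <- gyr
    }
    if (cfg$noise$accel_sd > 0)
      sig[, 1:3] <- sig[, 1:3] +
        stats::rnorm(3 * nrow(sig), 0, cfg$noise$accel_sd)
    if (cfg$noise$gyro_sd > 0)
      sig[, 4:6] <- sig[, 4:6] +
        stats::rnorm(3 * nrow(sig), 0, cfg$noise$gyro_sd)
    df <- data.frame(t = tt, sig)
    names(df) <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
    streams[[s]] <- df
  }

  structure(list(streams = streams, ground_truth = seq,
                 gyro_bias_true = bias,
                 metadata = list(subject = sprintf("sim%06d", cfg$seed),
                                 age_months = cfg$age_months,
                                 rate_hz = rate)),
            class = "sim_recording")
}

#' Simulate multi-rater annotations of a state sequence
#'
#' Emulates the two dominant disagreement modes of video annotation:
#' per-second label confusion and temporal jitter of segment boundaries.
#' Each rater independently perturbs the ground-truth segment boundaries by
#' Gaussian jitter and then draws each second's label from the confusion
#' row of the (jittered) true label.
#'
#' @param seq a `state_sequence`.
#' @param confusion named list (`posture`, `movement`, `carrying`) of
#'   row-stochastic confusion matrices (rows = true class), or `NULL` for
#'   defaults that emulate high posture and moderate movement agreement.
#' @param boundary_jitter_s SD (seconds) of boundary jitter.
#' @param n_raters number of raters (>= 2).
#' @param seed integer seed.
#' @return An `annotation_set`: list with `raters`, `n_seconds`, and
#'   `tracks` (per track, an `n_seconds x n_raters` character matrix).
#' @export
simulate_raters <- function(seq, confusion = NULL, boundary_jitter_s = 0.3,
                            n_raters = 3L, seed = 1L) {
  stopifnot(inherits(seq, "state_sequence"))
  if (n_raters < 2) stop("n_raters must be >= 2 (agreement is undefined)")
  set.seed(seed)
  if (is.null(confusion))
    confusion <- list(posture = default_confusion("posture", 0.985),
                      movement = default_confusion("movement", 0.85),
                      carrying = default_confusion("carrying", 0.97))
  for (tr in names(confusion)) {
    rs <- rowSums(confusion[[tr]])
    if (any(abs(rs - 1) > 1e-8)) stop("confusion rows must normalize to 1")
  }
  n <- nrow(seq)
  tracks <- list()
  for (tr in c("posture", "movement", "carrying")) {
    cm <- confusion[[tr]]
    truth <- seq[[tr]]
    mat <- matrix("", nrow = n, ncol = n_raters)
    for (r in seq_len(n_raters)) {
      jit <- jitter_boundaries(truth, boundary_jitter_s)
      cls <- rownames(cm)
      idx <- match(jit, cls)
      lab <- character(n)
      for (k in seq_along(cls)) {
        w <- which(idx == k)
        if (length(w))
          lab[w] <- cls[apply(stats::rmultinom(length(w), 1, cm[k, ]),
                              2, which.max)]
      }
      mat[, r] <- lab
    }
    colnames(mat) <- paste0("rater", seq_len(n_raters))
    tracks[[tr]] <- mat
  }
  structure(list(raters = paste0("rater", seq_len(n_raters)),
                 n_seconds = n, tracks = tracks),
            class = "annotation_set")
}

default_confusion <- function(track, acc) {
  cls <- track_classes(track)
  k <- length(cls)
  cm <- matrix((1 - acc) / (k - 1), k, k, dimnames = list(cls, cls))
  diag(cm) <- acc
  cm
}

jitter_boundaries <- function(labels, sd_s) {
  if (sd_s <= 0) return(labels)
  n <- length(labels)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  if (length(ends) > 1) {
    b <- ends[-length(ends)] + stats::rnorm(length(ends) - 1, 0, sd_s)
    b <- pmin(pmax(round(b), 1), n - 1)
    b <- sort(b)
    starts <- c(1, b + 1)
    lens <- diff(c(0, b, n))
    keep <- lens > 0
    rep(r$values[keep], lens[keep])
  } else labels
}

#' Generate an age cohort of motor-ability feature vectors
#'
#' Draws recording-level feature vectors (posture fractions and
#' posture-conditional movement fractions on the fused taxonomies) for a
#' cohort of subjects with ages spread over `age_range`. Each simplex block
#' is drawn from a Dirichlet distribution centred on the age-dependent mean
#' trajectory with total concentration `concentration`; `Inf` gives the
#' noiseless mean trajectory itself.
#'
#' @param n_recordings number of recordings (>= 2).
#' @param age_range numeric length-2, ages in months.
#' @param trajectory_params optional trajectory overrides (see
#'   [sim_config()]).
#' @param concentration Dirichlet concentration (> 0, may be `Inf`).
#' @param seed integer seed.
#' @return list of entries `list(subject, age, features)` where `features`
#'   is a `motor_features` object (see [compute_distributions()]).
#' @export
generate_age_cohort <- function(n_recordings, age_range = c(4, 16),
                                trajectory_params = NULL,
                                concentration = 100, seed = 1L) {
  if (n_recordings < 2) stop("n_recordings must be >= 2")
  if (!is.numeric(concentration) || concentration <= 0)
    stop("concentration must be > 0")
  set.seed(seed)
  ages <- sort(stats::runif(n_recordings, age_range[1], age_range[2]))
  lapply(seq_len(n_recordings), function(i) {
    mu <- mean_feature_vector(ages[i], trajectory_params)
    f <- mu
    if (is.finite(concentration)) {
      f$posture <- rdirichlet1(concentration * mu$posture)
      f$movement <- lapply(mu$movement,
                           function(m) rdirichlet1(concentration * m))
    }
    list(subject = sprintf("S%03d", i), age = ages[i], features = f)
  })
}

rdirichlet1 <- function(alpha) {
  alpha <- pmax(alpha, 1e-3)
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  stats::setNames(g / sum(g), names(alpha))
}

#' Mean motor-ability feature vector at a given age
#'
#' Evaluates the configured occupancy trajectories to give the expected
#' fused posture distribution and, for each fused posture, the conditional
#' fused movement distribution (the global movement prior restricted to the
#' posture's permitted movements and renormalized).
#'
#' @param age_months age in months.
#' @param trajectory_params optional overrides as in [sim_config()].
#' @return a `motor_features` object.
#' @export
mean_feature_vector <- function(age_months, trajectory_params = NULL) {
  cfg <- sim_config(age_months, 1, trajectory_params = trajectory_params,
                    noise = list(accel_sd = 0, gyro_sd = 0,
                                 gyro_bias_range = 0, packet_jitter_sd = 0,
                                 packet_drop_p = 0))
  pp <- age_priors(cfg, "posture")
  mp <- age_priors(cfg, "movement")
  fp <- fused_posture_classes()
  fm <- fused_movement_classes()
  posture <- stats::setNames(numeric(length(fp)), fp)
  for (cls in names(pp)) {
    f <- fuse_lr(cls)
    posture[f] <- posture[f] + pp[cls]
  }
  constraints <- posture_movement_constraints()
  movement <- list()
  for (f in fp) {
    full <- if (f == "side") "side_left" else f    # constraint sets match L/R
    allowed <- constraints[[full]]
    pr <- mp[allowed]
    pr <- pr / sum(pr)
    fused <- stats::setNames(numeric(length(fm)), fm)
    for (cls in names(pr)) {
      fc <- fuse_lr(cls)
      fused[fc] <- fused[fc] + pr[cls]
    }
    movement[[f]] <- fused
  }
  structure(list(posture = posture, movement = movement,
                 supported = stats::setNames(rep(TRUE, length(fp)), fp),
                 n_frames = NA_integer_),
            class = "motor_features")
}
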