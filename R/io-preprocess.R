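#' Write a recording to disk
#'
#' Emits the package's standard on-disk recording format: one CSV per
#' sensor with columns `t,ax,ay,az,gx,gy,gz`, a `meta.yaml` with subject
#' id, age and the sensor-to-file map, and (for simulated recordings) a
#' ground-truth annotation CSV `rater,track,start_s,end_s,label` with
#' half-open second intervals.
#'
#' @param rec a `sim_recording` (or a list with the same structure).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- stats::setNames(paste0(sensor_ids(), ".csv"), sensor_ids())
  for (s in names(rec$streams))
    utils::write.csv(rec$streams[[s]], file.path(dir, files[[s]]),
                     row.names = FALSE)
  meta <- list(subject = rec$metadata$subject,
               age_months = rec$metadata$age_months,
               rate_hz = rec$metadata$rate_hz,
               sensors = as.list(files))
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  if (!is.null(rec$ground_truth)) {
    gt <- rec$ground_truth
    rows <- do.call(rbind, lapply(c("posture", "movement", "carrying"),
      function(tr) {
        r <- rle(gt[[tr]])
        e <- cumsum(r$lengths)
        data.frame(rater = "truth", track = tr, start_s = e - r$lengths,
                   end_s = e, label = r$values, stringsAsFactors = FALSE)
      }))
    utils::write.csv(rows, file.path(dir, "annotations_truth.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a recording from disk
#'
#' Reads the four per-sensor packet CSVs and metadata written by
#' [write_recording()]. Validates the schema: all four sensors must be
#' present, every row must have a timestamp and six finite channel values,
#' and timestamps must be non-decreasing.
#'
#' @param path recording directory.
#' @return list with `streams` (per sensor data.frame), `metadata`, and
#'   `ground_truth` (a `state_sequence`, if the truth annotation file is
#'   present).
#' @export
read_recording <- function(path) {
  meta_file <- file.path(path, "meta.yaml")
  if (!file.exists(meta_file)) stop("missing meta.yaml in ", path)
  meta <- yaml::read_yaml(meta_file)
  missing <- setdiff(sensor_ids(), names(meta$sensors))
  streams <- list()
  for (s in setdiff(sensor_ids(), missing)) {
    f <- file.path(path, meta$sensors[[s]])
    if (!file.exists(f)) { missing <- c(missing, s); next }
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
    if (!all(need %in% names(df)))
      stop("sensor file ", f, " lacks columns: ",
           paste(setdiff(need, names(df)), collapse = ", "))
    df <- df[need]
    num <- vapply(df, function(col) suppressWarnings(as.numeric(col)),
                  numeric(nrow(df)))
    if (nrow(df) == 1) num <- matrix(num, nrow = 1)
    bad <- which(rowSums(!is.finite(num)) > 0)
    if (length(bad) > 0)
      stop("malformed row in ", f, " at line ", bad[1] + 1L)
    df[] <- as.data.frame(num)
    if (is.unsorted(df$t)) stop("timestamps not non-decreasing in ", f)
    streams[[s]] <- df
  }
  if (length(missing) > 0)
    stop("missing sensor stream(s): ", paste(sort(missing), collapse = ", "))
  gt <- NULL
  gt_file <- file.path(path, "annotations_truth.csv")
  if (file.exists(gt_file)) {
    ann <- utils::read.csv(gt_file, stringsAsFactors = FALSE)
    n <- max(ann$end_s)
    gt <- data.frame(second = seq_len(n) - 1L, posture = NA_character_,
                     movement = NA_character_, carrying = NA_character_,
                     stringsAsFactors = FALSE)
    for (i in seq_len(nrow(ann)))
      gt[[ann$track[i]]][(ann$start_s[i] + 1):ann$end_s[i]] <- ann$label[i]
    attr(gt, "age_months") <- meta$age_months
    class(gt) <- c("state_sequence", "data.frame")
  }
  list(streams = streams,
       metadata = list(subject = meta$subject, age_months = meta$age_months,
                       rate_hz = meta$rate_hz %||% 52),
       ground_truth = gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regularize packet timestamps onto an ideal uniform base
#'
#' Linearly interpolates one sensor's packets onto the uniform grid
#' `t0 + i / rate`. No extrapolation is performed: the grid is restricted
#' to the packet span (or to the supplied `[t0, t_end]` intersection span
#' when regularizing several sensors onto a common base).
#'
#' @param stream data.frame `t, ax..gz` for one sensor.
#' @param rate sampling rate in Hz (default 52).
#' @param t0 grid origin; default first packet time.
#' @param t_end grid end; default last packet time.
#' @return list: `t` (grid times), `x` (n x 6 matrix of channels).
#' @export
regularize_timestamps <- function(stream, rate = 52, t0 = NULL,
                                  t_end = NULL) {
  if (is.null(stream) || nrow(stream) < 2)
    stop("stream must contain at least 2 packets")
  if (diff(range(stream$t)) < 1 / rate)
    stop("packet span shorter than one sample period")
  t0 <- max(t0 %||% stream$t[1], stream$t[1])
  t_end <- min(t_end %||% stream$t[nrow(stream)], stream$t[nrow(stream)])
  grid <- seq(t0, t_end + 1e-12, by = 1 / rate)
  x <- vapply(c("ax", "ay", "az", "gx", "gy", "gz"),
              function(ch) stats::approx(stream$t, stream[[ch]], xout = grid,
                                         rule = 1)$y,
              numeric(length(grid)))
  list(t = grid, x = x)
}

#' Regularize a full 4-sensor recording to a 24-channel uniform signal
#'
#' Common time base: origin at the latest sensor start, end at the
#' earliest sensor end (the intersection span), so all 24 channels are
#' defined everywhere. Channel order is (left_arm, right_arm, left_leg,
#' right_leg) x (ax, ay, az, gx, gy, gz).
#'
#' @param rec list with `streams` as from [read_recording()] or a
#'   `sim_recording`.
#' @param rate sampling rate in Hz.
#' @return a `uniform_signal`: list with `x` (n x 24 matrix), `t0`, `rate`.
#' @export
regularize_recording <- function(rec, rate = 52) {
  st <- rec$streams[sensor_ids()]
  t0 <- max(vapply(st, function(s) s$t[1], numeric(1)))
  t_end <- min(vapply(st, function(s) s$t[nrow(s)], numeric(1)))
  parts <- lapply(st, regularize_timestamps, rate = rate, t0 = t0,
                  t_end = t_end)
  n <- min(vapply(parts, function(p) length(p$t), integer(1)))
  x <- do.call(cbind, lapply(parts, function(p) p$x[seq_len(n), , drop = FALSE]))
  colnames(x) <- as.vector(t(outer(sensor_ids(),
                                   c("ax", "ay", "az", "gx", "gy", "gz"),
                                   paste, sep = ".")))
  structure(list(x = x, t0 = t0, rate = rate), class = "uniform_signal")
}

gyro_cols <- function() as.vector(outer(4:6, (0:3) * 6, "+"))

#' Remove gyroscope bias from a uniform signal
#'
#' The bias of each gyroscope channel is estimated as the per-channel
#' median over the lowest-motion decile of 1-second windows, where motion
#' is ranked by the summed gyroscope variance of the sensor's three
#' channels. The estimate is subtracted from the gyroscope channels;
#' accelerometer channels are untouched.
#'
#' @param signal a `uniform_signal`.
#' @return the signal with bias-corrected gyroscope channels; the estimated
#'   bias is attached as attribute `gyro_bias` (named by channel).
#' @export
remove_gyro_bias <- function(signal) {
  x <- signal$x
  n <- nrow(x)
  win <- signal$rate
  n_win <- floor(n / win)
  bias <- stats::setNames(numeric(24), colnames(x))
  if (n_win >= 1) {
    wid <- rep(seq_len(n_win), each = win)
    idx <- seq_len(n_win * win)
    for (s in 0:3) {
      gcols <- s * 6 + 4:6
      v <- rowsum(x[idx, gcols, drop = FALSE]^2, wid) / win -
           (rowsum(x[idx, gcols, drop = FALSE], wid) / win)^2
      motion <- rowSums(v)
      k <- max(1L, floor(n_win / 10))
      still <- order(motion)[seq_len(k)]
      sel <- idx[wid %in% still]
      for (c3 in gcols) {
        b <- stats::median(x[sel, c3])
        x[, c3] <- x[, c3] - b
        bias[c3] <- b
      }
    }
  }
  out <- signal
  out$x <- x
  attr(out, "gyro_bias") <- bias[gyro_cols()]
  out
}

#' Seven-tap running median filter
#'
#' Per-channel temporal smoothing with a 7-sample running median. Edges are
#' handled by reflect padding, which preserves length, introduces no phase
#' shift, and leaves constant signals unchanged.
#'
#' @param signal a `uniform_signal` (or plain numeric matrix).
#' @return the filtered signal, same class and dimensions.
#' @export
median_filter7 <- function(signal) {
  x <- if (inherits(signal, "uniform_signal")) signal$x else as.matrix(signal)
  n <- nrow(x)
  if (n < 7) stop("median_filter7 requires at least 7 samples")
  pad <- 3L
  top <- x[(pad + 1):2, , drop = FALSE]
  bot <- x[(n - 1):(n - pad), , drop = FALSE]
  xp <- rbind(top, x, bot)
  y <- apply(xp, 2, function(col) stats::runmed(col, 7, endrule = "keep"))
  y <- y[(pad + 1):(pad + n), , drop = FALSE]
  dimnames(y) <- dimnames(x)
  if (inherits(signal, "uniform_signal")) { signal$x <- y; signal } else y
}

#' Cut a uniform signal into overlapping analysis frames
#'
#' Frames are 120 samples (2.3 s at 52 Hz) with 50% overlap (hop 60
#' samples); the trailing partial window is discarded. Frame `i` (1-based)
#' covers samples `[60(i-1) + 1, 60(i-1) + 120]`; the frame time is the
#' centre of that interval, used to join per-second annotations.
#'
#' @param signal a `uniform_signal` with at least 120 samples.
#' @param frame_len frame length in samples.
#' @param hop hop in samples.
#' @return a `frame_array`: list with `frames` (array
#'   `n_frames x frame_len x n_channels`), `frame_times` (centre time, s),
#'   `hop`, `frame_len`, `rate`, `t0`.
#' @export
make_frames <- function(signal, frame_len = 120L, hop = 60L) {
  x <- signal$x
  n <- nrow(x)
  if (n < frame_len) stop("need at least ", frame_len, " samples to frame")
  n_frames <- (n - frame_len) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  fr <- array(0, dim = c(n_frames, frame_len, ncol(x)))
  for (i in seq_len(n_frames))
    fr[i, , ] <- x[(starts[i] + 1):(starts[i] + frame_len), ]
  times <- signal$t0 + (starts + (frame_len - 1) / 2) / signal$rate
  structure(list(frames = fr, frame_times = times, hop = hop,
                 frame_len = frame_len, rate = signal$rate, t0 = signal$t0),
            class = "frame_array")
}

#' Full preprocessing pipeline
#'
#' Regularize to the 52 Hz common base, remove gyroscope bias (optional),
#' apply the seven-tap median filter, and frame. This is the deterministic
#' path from raw packets to the classifier's input.
#'
#' @param rec a recording as from [read_recording()] or [synthesize_imu()].
#' @param bias_removal apply gyroscope bias removal (default `TRUE`).
#' @param rate sampling rate (Hz).
#' @return a `frame_array`.
#' @export
preprocess_recording <- function(rec, bias_removal = TRUE, rate = 52) {
  sig <- regularize_recording(rec, rate = rate)
  if (bias_removal) sig <- remove_gyro_bias(sig)
  sig <- median_filter7(sig)
  make_frames(sig)
}
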