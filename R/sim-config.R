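#' Simulation configuration
#'
#' Builds the configuration object for the synthetic-data generator. The
#' generator emulates a four-sensor limb-worn inertial recording of an
#' infant: a per-second ground-truth state sequence on three tracks
#' (posture, movement, carrying), and 6-channel 52 Hz sensor packets whose
#' gravity orientation depends on posture and whose oscillation energy
#' depends on movement class.
#'
#' Age-dependent category occupancy follows logistic/bell trajectories
#' (prone and supine decreasing, standing and fluent increasing, crawling
#' bell-shaped around the end of the first year). Defaults encode the
#' qualitative developmental shapes; all curves can be overridden via
#' `trajectory_params`, or bypassed entirely with fixed `posture_prior` /
#' `movement_prior` vectors.
#'
#' @param age_months corrected age in months (>= 0).
#' @param duration_s recording duration in whole seconds (> 0).
#' @param seed integer seed controlling all randomness downstream.
#' @param trajectory_params optional list overriding trajectory curves; see
#'   [default_trajectories()].
#' @param dwell_params list with mean state dwell times in seconds
#'   (`posture`, `movement`, `carrying`) and the negative-binomial `size`
#'   controlling dwell dispersion.
#' @param noise list: `accel_sd` (m/s^2), `gyro_sd` (deg/s),
#'   `gyro_bias_range` (deg/s, bias drawn uniformly in +/- range),
#'   `packet_jitter_sd` (s), `packet_drop_p` (probability in `[0,1]`).
#' @param posture_prior optional fixed named posture prior (sums to 1);
#'   overrides trajectories.
#' @param movement_prior optional fixed named movement prior; overrides
#'   trajectories.
#' @param carrying_prior named prior over carrying classes.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(age_months, duration_s, seed = 1L,
                       trajectory_params = NULL,
                       dwell_params = list(posture = 12, movement = 4,
                                           carrying = 25, size = 10),
                       noise = list(accel_sd = 0.08, gyro_sd = 0.8,
                                    gyro_bias_range = 3,
                                    packet_jitter_sd = 0.002,
                                    packet_drop_p = 0.01),
                       posture_prior = NULL, movement_prior = NULL,
                       carrying_prior = c(independent = 0.90,
                                          passive_support = 0.04,
                                          active_support = 0.02,
                                          passive_carry = 0.02,
                                          active_carry = 0.02)) {
  if (!is.numeric(age_months) || length(age_months) != 1 || age_months < 0)
    stop("`age_months` must be a single non-negative number")
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0)
    stop("`duration_s` must be a single positive number")
  traj <- default_trajectories()
  if (!is.null(trajectory_params))
    traj[names(trajectory_params)] <- trajectory_params
  stopifnot(abs(sum(carrying_prior) - 1) < 1e-8)
  if (!is.null(posture_prior)) {
    if (is.null(names(posture_prior)) ||
        !all(names(posture_prior) %in% posture_classes()))
      stop("`posture_prior` names must be posture classes")
    if (length(posture_prior) == 0) stop("empty posture taxonomy")
  }
  p <- list(age_months = age_months,
            duration_s = as.integer(round(duration_s)),
            seed = as.integer(seed),
            trajectory_params = traj,
            dwell_params = dwell_params,
            noise = noise,
            posture_prior = posture_prior,
            movement_prior = movement_prior,
            carrying_prior = carrying_prior,
            rate_hz = 52)
  probs <- unlist(noise[c("packet_drop_p")])
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  class(p) <- "sim_config"
  p
}

#' Default age trajectories for category occupancy
#'
#' Each entry is `list(kind, mid, scale, amp, base)`: `kind = "logistic"`
#' gives `base + amp * plogis(sign * (age - mid) / scale)` (sign from
#' `dir`), `kind = "bell"` gives `base + amp * exp(-((age - mid)/scale)^2)`.
#' Curves are defined on the fused categories; left/right splits share their
#' fused curve equally. Values are relative weights, normalized to a prior
#' at a given age by [age_priors()].
#'
#' @return named list of trajectory parameter lists for both tracks.
#' @export
default_trajectories <- function() {
  list(
    posture = list(
      supine        = list(kind = "logistic", dir = -1, mid = 8,   scale = 1.6, amp = 0.45, base = 0.02),
      prone         = list(kind = "logistic", dir = -1, mid = 9.5, scale = 1.8, amp = 0.35, base = 0.03),
      side          = list(kind = "logistic", dir = -1, mid = 8,   scale = 2.0, amp = 0.10, base = 0.02),
      crawl_posture = list(kind = "bell",     mid = 10,   scale = 2.5, amp = 0.28, base = 0.01),
      sitting       = list(kind = "bell",     mid = 10.5, scale = 4.0, amp = 0.30, base = 0.04),
      standing      = list(kind = "logistic", dir = 1,  mid = 12,  scale = 1.6, amp = 0.60, base = 0.01)),
    movement = list(
      still      = list(kind = "logistic", dir = -1, mid = 9,  scale = 2.5, amp = 0.30, base = 0.15),
      proto      = list(kind = "logistic", dir = -1, mid = 10, scale = 2.5, amp = 0.25, base = 0.12),
      elementary = list(kind = "bell",     mid = 10, scale = 4.0, amp = 0.25, base = 0.06),
      fluent     = list(kind = "logistic", dir = 1,  mid = 12, scale = 1.6, amp = 0.45, base = 0.01),
      pivot      = list(kind = "bell",     mid = 8,  scale = 3.0, amp = 0.08, base = 0.01),
      roll       = list(kind = "bell",     mid = 7,  scale = 3.0, amp = 0.08, base = 0.01),
      transition = list(kind = "bell",     mid = 11, scale = 4.0, amp = 0.12, base = 0.02)))
}

traj_value <- function(par, age) {
  if (par$kind == "logistic")
    par$base + par$amp * stats::plogis(par$dir * (age - par$mid) / par$scale)
  else
    par$base + par$amp * exp(-((age - par$mid) / par$scale)^2)
}

split_lr <- function(prior) {
  # expand fused categories back to the full taxonomies, halving L/R pairs
  out <- c()
  for (nm in names(prior)) {
    if (nm == "side")
      out <- c(out, side_left = unname(prior[nm]) / 2,
               side_right = unname(prior[nm]) / 2)
    else if (nm == "pivot")
      out <- c(out, pivot_left = unname(prior[nm]) / 2,
               pivot_right = unname(prior[nm]) / 2)
    else if (nm == "roll")
      out <- c(out, roll_left = unname(prior[nm]) / 2,
               roll_right = unname(prior[nm]) / 2)
    else out <- c(out, stats::setNames(unname(prior[nm]), nm))
  }
  out
}

#' Age-dependent category priors
#'
#' Evaluates the configured occupancy trajectories at the configuration's
#' age and normalizes to a probability vector over the full (unfused)
#' taxonomy of the requested track. Fixed priors in the configuration take
#' precedence over trajectories.
#'
#' @param cfg a [sim_config()].
#' @param track `"posture"` or `"movement"`.
#' @return named numeric prior summing to 1.
#' @export
age_priors <- function(cfg, track = c("posture", "movement")) {
  track <- match.arg(track)
  fixed <- if (track == "posture") cfg$posture_prior else cfg$movement_prior
  if (!is.null(fixed)) {
    full <- stats::setNames(numeric(length(track_classes(track))),
                            track_classes(track))
    full[names(fixed)] <- fixed
    return(full / sum(full))
  }
  pars <- cfg$trajectory_params[[track]]
  w <- vapply(pars, traj_value, numeric(1), age = cfg$age_months)
  w <- split_lr(w)
  w <- w[track_classes(track)]
  w / sum(w)
}

#' Movement classes permitted within each posture
#'
#' The generator and the feature code enforce physical consistency between
#' the two tracks (e.g. no fluent walking while lying supine). Returned as
#' a named list: posture -> allowed movement classes.
#'
#' @return named list of character vectors.
#' @export
posture_movement_constraints <- function() {
  list(
    supine        = c("still", "proto", "elementary", "roll_left", "roll_right", "transition"),
    prone         = c("still", "proto", "elementary", "fluent", "pivot_left",
                      "pivot_right", "roll_left", "roll_right", "transition"),
    side_left     = c("still", "proto", "roll_left", "roll_right", "transition"),
    side_right    = c("still", "proto", "roll_left", "roll_right", "transition"),
    crawl_posture = c("still", "proto", "elementary", "fluent", "transition"),
    sitting       = c("still", "proto", "elementary", "transition"),
    standing      = c("still", "proto", "elementary", "fluent", "transition"))
}

#' Per-posture sensor gravity orientations
#'
#' Fixed lookup table giving, for each posture, the unit vector (in each
#' sensor's frame) along which gravity acts on the accelerometer. The
#' convention is arbitrary but fixed: what matters downstream is that the
#' 4-sensor orientation pattern differs between postures, making posture
#' recoverable from static acceleration.
#'
#' @return list: posture -> 4 x 3 matrix (rows = sensors in
#'   [sensor_ids()] order).
#' @export
posture_orientations <- function() {
  s2 <- sqrt(2) / 2
  m <- function(...) {
    x <- matrix(c(...), nrow = 4, byrow = TRUE)
    rownames(x) <- sensor_ids()
    x
  }
  list(
    supine        = m(0, 0, 1,  0, 0, 1,  0, 0, 1,  0, 0, 1),
    prone         = m(0, 0, -1, 0, 0, -1, 0, 0, -1, 0, 0, -1),
    side_left     = m(0, 1, 0,  0, 1, 0,  0, 1, 0,  0, 1, 0),
    side_right    = m(0, -1, 0, 0, -1, 0, 0, -1, 0, 0, -1, 0),
    crawl_posture = m(1, 0, 0,  1, 0, 0,  s2, 0, -s2, s2, 0, -s2),
    sitting       = m(0, 0, 1,  0, 0, 1,  1, 0, 0,  1, 0, 0),
    standing      = m(1, 0, 0,  1, 0, 0,  1, 0, 0,  1, 0, 0))
}

# movement class -> (accel amplitude m/s^2, gyro amplitude deg/s, freq band Hz)
movement_dynamics <- function() {
  list(
    still       = list(a = 0.0, g = 0,  band = c(0.5, 2)),
    proto       = list(a = 0.5, g = 15, band = c(0.5, 3)),
    elementary  = list(a = 1.1, g = 35, band = c(1, 6)),
    fluent      = list(a = 2.2, g = 80, band = c(2, 10)),
    pivot_left  = list(a = 0.8, g = 60, band = c(0.5, 4)),
    pivot_right = list(a = 0.8, g = 60, band = c(0.5, 4)),
    roll_left   = list(a = 1.0, g = 70, band = c(0.5, 4)),
    roll_right  = list(a = 1.0, g = 70, band = c(0.5, 4)),
    transition  = list(a = 1.5, g = 60, band = c(0.5, 5)))
}
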