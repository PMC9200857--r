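# Shared fixtures, all generated in code.

noiseless_noise <- function() {
  list(accel_sd = 0, gyro_sd = 0, gyro_bias_range = 0,
       packet_jitter_sd = 0, packet_drop_p = 0)
}

# a short simulated recording with frames and frame-level truth labels
sim_recording_fixture <- function(seed, age = 10, dur = 120, noise = NULL) {
  cfg <- if (is.null(noise)) sim_config(age, dur, seed = seed)
         else sim_config(age, dur, seed = seed, noise = noise)
  s <- simulate_state_sequence(cfg)
  rec <- synthesize_imu(s, cfg)
  fa <- preprocess_recording(rec)
  sec <- pmin(floor(fa$frame_times) + 1, nrow(s))
  list(cfg = cfg, seq = s, rec = rec, frames = fa,
       posture = s$posture[sec], movement = s$movement[sec],
       carrying = s$carrying[sec],
       subject = sprintf("S%03d", seed))
}

frame_band_power <- function(frame_ch, rate = 52, band = c(0.5, 10)) {
  n <- length(frame_ch)
  sp <- Mod(stats::fft(frame_ch - mean(frame_ch)))^2 / n
  f <- (seq_len(n) - 1) * rate / n
  sum(sp[f >= band[1] & f <= band[2]])
}

cross_entropy <- function(targets, truth_onehot) {
  -mean(rowSums(truth_onehot * log(pmax(targets, 1e-12))))
}
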