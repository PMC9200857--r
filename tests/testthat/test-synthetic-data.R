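test_that("degenerate posture prior yields an all-prone sequence", {
  cfg <- sim_config(10, 200, seed = 1, posture_prior = c(prone = 1))
  s <- simulate_state_sequence(cfg)
  expect_equal(unique(s$posture), "prone")
  expect_true(all(s$movement %in% posture_movement_constraints()$prone))
})

test_that("empirical occupancy matches the configured age prior", {
  cfg <- sim_config(14, 3600, seed = 1)
  s <- simulate_state_sequence(cfg)
  prior <- age_priors(cfg, "posture")
  emp <- table(factor(s$posture, posture_classes())) / nrow(s)
  expect_lt(abs(emp[["standing"]] - prior[["standing"]]), 0.05)
  # convergence of the whole distribution at longer duration
  cfg2 <- sim_config(10, 1e4, seed = 2)
  s2 <- simulate_state_sequence(cfg2)
  emp2 <- as.numeric(table(factor(s2$posture, posture_classes()))) / nrow(s2)
  expect_lt(sum(abs(emp2 - age_priors(cfg2, "posture"))), 0.03)
})

test_that("state sequences are deterministic under a fixed seed", {
  cfg <- sim_config(9, 600, seed = 7)
  expect_identical(simulate_state_sequence(cfg), simulate_state_sequence(cfg))
  s <- simulate_state_sequence(cfg)
  r1 <- synthesize_imu(s, cfg)
  r2 <- synthesize_imu(s, cfg)
  expect_identical(r1$streams, r2$streams)
  expect_identical(simulate_raters(s, seed = 3), simulate_raters(s, seed = 3))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(-1, 100), "age")
  expect_error(sim_config(10, 0), "duration")
})

test_that("static noise-free segments read pure gravity and true gyro bias", {
  cfg <- sim_config(5, 60, seed = 3, noise = noiseless_noise(),
                    posture_prior = c(supine = 1),
                    movement_prior = c(still = 1),
                    carrying_prior = c(independent = 1, passive_support = 0,
                                       active_support = 0, passive_carry = 0,
                                       active_carry = 0))
  s <- simulate_state_sequence(cfg)
  rec <- synthesize_imu(s, cfg)
  for (sn in sensor_ids()) {
    st <- rec$streams[[sn]]
    norms <- sqrt(st$ax^2 + st$ay^2 + st$az^2)
    expect_equal(norms, rep(9.81, nrow(st)), tolerance = 1e-12)
    expect_equal(unname(as.matrix(st[, c("gx", "gy", "gz")])),
                 matrix(rec$gyro_bias_true[sn, ], nrow(st), 3, byrow = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("fluent movement carries more 0.5-10 Hz band power than still", {
  mk <- function(mv) {
    cfg <- sim_config(12, 40, seed = 5, noise = noiseless_noise(),
                      posture_prior = c(standing = 1),
                      movement_prior = stats::setNames(1, mv))
    s <- simulate_state_sequence(cfg)
    rec <- synthesize_imu(s, cfg)
    frame_band_power(rec$streams$left_arm$ax[1:520])
  }
  expect_gt(mk("fluent"), mk("still"))
})

test_that("packet counts match duration x rate when drops are disabled", {
  cfg <- sim_config(8, 60, seed = 2, noise = noiseless_noise())
  s <- simulate_state_sequence(cfg)
  rec <- synthesize_imu(s, cfg)
  for (sn in sensor_ids())
    expect_true(abs(nrow(rec$streams[[sn]]) - 60 * 52) <= 1)
})

test_that("unknown posture labels are rejected by the signal synthesizer", {
  cfg <- sim_config(8, 30, seed = 2)
  s <- simulate_state_sequence(cfg)
  s$posture[1] <- "headstand"
  expect_error(synthesize_imu(s, cfg), "unknown posture")
})

test_that("identity confusion and zero jitter reproduce the ground truth", {
  # carrying prior rebalanced so every track shows at least two categories
  cfg <- sim_config(10, 300, seed = 4,
                    carrying_prior = c(independent = 0.6,
                                       passive_support = 0.2,
                                       active_support = 0,
                                       passive_carry = 0,
                                       active_carry = 0.2))
  s <- simulate_state_sequence(cfg)
  ident <- lapply(list(posture = posture_classes(),
                       movement = movement_classes(),
                       carrying = carrying_classes()),
                  function(cls) diag(length(cls)) |>
                    `dimnames<-`(list(cls, cls)))
  ann <- simulate_raters(s, confusion = ident, boundary_jitter_s = 0,
                         n_raters = 3, seed = 1)
  for (tr in c("posture", "movement", "carrying")) {
    expect_true(all(ann$tracks[[tr]] == s[[tr]]))
    expect_equal(fleiss_kappa(ann, tr), 1)
  }
})

test_that("uniform confusion drives agreement to chance level", {
  cfg <- sim_config(10, 1e4, seed = 4)
  s <- simulate_state_sequence(cfg)
  cls <- posture_classes()
  unif <- matrix(1 / length(cls), length(cls), length(cls),
                 dimnames = list(cls, cls))
  ann <- simulate_raters(s, confusion = list(posture = unif),
                         boundary_jitter_s = 0, n_raters = 2, seed = 1)
  expect_lt(abs(fleiss_kappa(ann, "posture")), 0.05)
})

test_that("rater simulation validates its inputs", {
  cfg <- sim_config(10, 30, seed = 1)
  s <- simulate_state_sequence(cfg)
  expect_error(simulate_raters(s, n_raters = 1), "n_raters")
  bad <- default_trajectories()
  cm <- matrix(0.6, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(simulate_raters(s, confusion = list(posture = cm)),
               "normalize")
})

test_that("age cohort features sit on the simplex and track age", {
  co <- generate_age_cohort(60, c(4, 16), concentration = 100, seed = 11)
  for (e in co) {
    expect_equal(sum(e$features$posture), 1, tolerance = 1e-9)
    for (m in e$features$movement)
      expect_equal(sum(m), 1, tolerance = 1e-9)
  }
  ages <- vapply(co, function(e) e$age, numeric(1))
  standing <- vapply(co, function(e) e$features$posture[["standing"]],
                     numeric(1))
  expect_gt(stats::cor(ages, standing, method = "spearman"), 0.8)
})

test_that("infinite concentration recovers the mean trajectory exactly", {
  co <- generate_age_cohort(3, c(8, 12), concentration = Inf, seed = 2)
  mu <- mean_feature_vector(co[[1]]$age)
  expect_equal(co[[1]]$features$posture, mu$posture)
  expect_equal(co[[1]]$features$movement, mu$movement)
})

test_that("cohort generation validates inputs and is seed-reproducible", {
  expect_error(generate_age_cohort(1), "n_recordings")
  expect_error(generate_age_cohort(10, concentration = 0), "concentration")
  expect_identical(generate_age_cohort(5, seed = 3),
                   generate_age_cohort(5, seed = 3))
})
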