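const_features <- function(posture = "prone", movement = "still") {
  compute_distributions(rep(posture, 100), rep(movement, 100))
}

test_that("distributions of a pure prone/still recording are degenerate", {
  f <- const_features("prone", "still")
  expect_equal(unname(f$posture),
               as.numeric(fused_posture_classes() == "prone"))
  expect_equal(unname(f$movement$prone),
               as.numeric(fused_movement_classes() == "still"))
  expect_false(f$supported[["standing"]])
  expect_equal(sum(f$movement$standing), 0)
})

test_that("the carrying mask restricts fractions to retained frames", {
  posture <- c(rep("prone", 50), rep("sitting", 50))
  movement <- rep("still", 100)
  mask <- c(rep(TRUE, 50), rep(FALSE, 50))
  f <- compute_distributions(posture, movement, mask)
  expect_equal(f$n_frames, 50)
  expect_equal(unname(f$posture[["prone"]]), 1)
  expect_error(compute_distributions(posture, movement, rep(FALSE, 100)),
               "no retained frames")
})

test_that("ground-truth label distributions equal simulator occupancy", {
  cfg <- sim_config(10, 2000, seed = 13)
  s <- simulate_state_sequence(cfg)
  f <- compute_distributions(s$posture, s$movement)
  occ <- table(factor(fuse_lr(s$posture), fused_posture_classes())) / nrow(s)
  expect_equal(unname(f$posture), as.numeric(occ), tolerance = 1e-12)
})

test_that("BIMS rescaling has the exact anchor points", {
  expect_equal(bims_rescale(16), 100)
  expect_equal(bims_rescale(4), 0)
  expect_equal(bims_rescale(10), 50)
})

test_that("the sigma floor engages for identical member vectors", {
  cohort <- lapply(1:3, function(i)
    list(subject = paste0("S", i), age = 10, features = const_features()))
  fit <- fit_age_bins(cohort)
  expect_true(all(fit$bins[["10"]]$sigma == 1e-4))
})

test_that("recordings over 16 months pool into the 16-month bin", {
  cohort <- c(
    lapply(1:4, function(i)
      list(subject = paste0("A", i), age = 5 + i,
           features = const_features())),
    list(list(subject = "old", age = 30, features = const_features())))
  fit <- fit_age_bins(cohort)
  expect_true(5 %in% fit$bins[["16"]]$members)
  expect_false(5 %in% fit$bins[["14"]]$members)
})

test_that("bins short of 3 members absorb the nearest-age recordings", {
  ages <- c(4.2, 4.5, 8, 12.4, 12.6)
  cohort <- lapply(seq_along(ages), function(i)
    list(subject = paste0("S", i), age = ages[i],
         features = const_features()))
  fit <- fit_age_bins(cohort)
  b8 <- fit$bins[["8"]]
  expect_equal(length(b8$members), 3)
  expect_true(3 %in% b8$members)               # the in-window recording
  expect_setequal(b8$members, c(3, 2, 1))      # nearest-age fill
  expect_error(fit_age_bins(cohort[1:2]), "at least 3")
  # equidistant fill candidates resolve toward the younger recording
  ages2 <- c(6, 10, 8, 3, 13)
  cohort2 <- lapply(seq_along(ages2), function(i)
    list(subject = paste0("T", i), age = ages2[i],
         features = const_features()))
  fit2 <- fit_age_bins(cohort2, min_members = 2L)
  expect_setequal(fit2$bins[["8"]]$members, c(3, 1))
})

test_that("age prediction is the likelihood-weighted bin-centre average", {
  f10 <- const_features()
  cohort <- lapply(1:3, function(i)
    list(subject = paste0("S", i), age = 10, features = f10))
  fit <- fit_age_bins(cohort, centers = 10)
  p <- predict_age(fit, f10)
  expect_equal(p$predicted_age, 10)
  expect_equal(p$bims, 50)
  expect_equal(sum(p$weights), 1)
  # equal likelihoods across 4..16 average to the centre of the range
  fit2 <- fit_age_bins(cohort, centers = 4:16)
  for (b in names(fit2$bins)) {
    fit2$bins[[b]]$mu <- fit2$bins[["10"]]$mu
    fit2$bins[[b]]$sigma <- fit2$bins[["10"]]$sigma
  }
  p2 <- predict_age(fit2, f10)
  expect_equal(p2$predicted_age, 10)
  expect_equal(unname(p2$weights), rep(1 / 13, 13), tolerance = 1e-12)
})

test_that("a dominant-likelihood bin pulls the prediction to its age", {
  co <- generate_age_cohort(80, c(4, 16), concentration = 200, seed = 14)
  fit <- fit_age_bins(co)
  x <- fit$bins[["14"]]$mu
  attr(x, "active") <- rep(TRUE, length(x))
  p <- predict_age(fit, x)
  expect_lt(abs(p$predicted_age - 14), 0.1)
})

test_that("weights are invariant to a constant log-likelihood shift", {
  co <- generate_age_cohort(20, c(4, 16), seed = 15)
  fit <- fit_age_bins(co)
  p <- predict_age(fit, co[[5]]$features)
  w_direct <- exp(p$log_lik + 500 - max(p$log_lik + 500))
  expect_equal(unname(p$weights), unname(w_direct / sum(w_direct)),
               tolerance = 1e-12)
  expect_true(p$predicted_age >= 4 && p$predicted_age <= 16)
  expect_true(p$bims >= 0 && p$bims <= 100)
})

test_that("LOSO holds out whole subjects and is exact on constant cohorts", {
  f <- const_features()
  cohort <- lapply(1:8, function(i)
    list(subject = paste0("S", ceiling(i / 2)), age = 10, features = f))
  r <- loso_evaluate(cohort, centers = 10)
  expect_equal(r$mae, 0, tolerance = 1e-9)
  expect_equal(nrow(r$predictions), 8)
  expect_error(loso_evaluate(cohort[1:2]), "at least 4")
})

test_that("robustness segments shorter than the source reuse its labels", {
  cfg <- sim_config(10, 7500, seed = 16)
  s <- simulate_state_sequence(cfg)
  long <- list(list(subject = "L1", age = 10, posture = s$posture,
                    movement = s$movement, mask = NULL))
  co <- generate_age_cohort(30, c(4, 16), seed = 17)
  co <- c(co, list(list(subject = "L1", age = 10,
                        features = compute_distributions(s$posture,
                                                         s$movement))))
  rb <- length_robustness(long, co, lengths_min = c(10, 60),
                          n_iterations = 20, seed = 1)
  expect_equal(nrow(rb), 2)
  expect_true(all(rb$median_mae >= 0))
  rb2 <- length_robustness(long, co, lengths_min = c(10, 60),
                           n_iterations = 20, seed = 1)
  expect_equal(rb, rb2)     # fixed seed -> identical summaries
})

test_that("the AIMS predictor recovers an affine age-AIMS relation", {
  co <- generate_age_cohort(40, c(4, 16), concentration = 150, seed = 18)
  co <- lapply(co, function(e) { e$aims = 3 * e$age + 5; e })
  r <- aims_predict(co, bin_width = 3)
  expect_equal(nrow(r$predictions), 40)
  expect_gt(r$pearson_r, 0.9)
  expect_error(aims_predict(co[1:2]), "at least 3")
})

test_that("a single-bin AIMS model predicts a constant", {
  f <- const_features()
  co <- lapply(1:5, function(i)
    list(subject = paste0("S", i), age = 10, features = f, aims = 20))
  r <- aims_predict(co, bin_width = 5)
  expect_true(all(abs(r$predictions$predicted_aims - 20) < 1e-9))
})
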