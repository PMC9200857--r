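test_that("model outputs are row-stochastic with the contracted shapes", {
  m <- build_model(encoder_spec(), temporal_spec(7), posture_classes(),
                   seed = 1)
  X <- array(stats::rnorm(3 * 120 * 24), c(3, 120, 24))
  p <- predict(m, X)
  expect_equal(dim(p$probs), c(3, 7))
  expect_equal(unname(rowSums(p$probs)), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p$probs >= 0 & p$probs <= 1))
  expect_equal(ncol(p$latent), 160)          # encoder latent width
  # deterministic init and inference
  m2 <- build_model(encoder_spec(), temporal_spec(7), posture_classes(),
                    seed = 1)
  expect_equal(predict(m2, X)$probs, p$probs)
  expect_error(predict(m, array(0, c(2, 60, 24))), "shape mismatch")
})

test_that("inference is deterministic and position-invariant away from edges", {
  m <- build_model(encoder_spec(latent_dim = 32, channels = c(8, 8),
                                filter_widths = c(7, 5), strides = c(4, 3)),
                   temporal_spec(3, hidden = 8, dilations = c(1, 2)),
                   c("a", "b", "c"), seed = 2)
  fr <- array(stats::rnorm(120 * 24), c(1, 120, 24))
  X <- array(0, c(60, 120, 24))
  for (i in 1:60) X[i, , ] <- fr[1, , ]
  p1 <- predict(m, X)
  p2 <- predict(m, X)
  expect_identical(p1$probs, p2$probs)       # no dropout at inference
  # identical frames map to identical encoder latents
  expect_equal(p1$latent[10, ], p1$latent[50, ])
  # interior positions (outside the temporal receptive field of the
  # sequence edges) are position-invariant
  expect_equal(p1$probs[25, ], p1$probs[35, ], tolerance = 1e-9)
})

test_that("class weights are inverse-frequency, mean-normalized", {
  lab <- c(rep("a", 80), rep("b", 20))
  w <- class_weights(lab, c("a", "b"))
  expect_equal(unname(w), c(0.4, 1.6))
  expect_equal(w, class_weights(rep(lab, 5), c("a", "b")))
  lab2 <- rep(c("a", "b", "c"), 10)
  expect_equal(unname(class_weights(lab2, c("a", "b", "c"))), rep(1, 3))
  w3 <- class_weights(lab, c("a", "b", "missing"))
  expect_true(is.na(w3[["missing"]]))
})

test_that("zero-epoch training returns the initialized model", {
  m <- build_model(encoder_spec(latent_dim = 16, channels = c(4),
                                filter_widths = c(7), strides = c(4)),
                   temporal_spec(2, hidden = 4, dilations = 1),
                   c("a", "b"), seed = 3)
  X <- array(stats::rnorm(40 * 120 * 24), c(40, 120, 24))
  y <- rep(c("a", "b"), 20)
  p0 <- predict(m, X)
  mt <- train_classifier(m, X, y, train_config(epochs = 0, seed = 1))
  expect_false(mt$trained)
  mt$norm <- NULL
  p1 <- predict(mt, X)
  expect_equal(p1$probs, p0$probs)
  expect_error(train_classifier(m, X, rep("a", 40),
                                train_config(epochs = 1)), "single class")
})

test_that("a separable three-posture task is learnable", {
  cfg <- sim_config(10, 420, seed = 31,
                    posture_prior = c(supine = 0.4, sitting = 0.3,
                                      standing = 0.3))
  s <- simulate_state_sequence(cfg)
  rec <- synthesize_imu(s, cfg)
  fa <- preprocess_recording(rec)
  lab <- s$posture[pmin(floor(fa$frame_times) + 1, nrow(s))]
  cls <- c("supine", "sitting", "standing")
  m <- build_model(encoder_spec(), temporal_spec(3), cls, seed = 1)
  m <- train_classifier(m, fa, lab,
                        train_config(epochs = 20, lr = 1e-3, seed = 1))
  expect_gt(max(m$log$val_f1), 0.95)
  expect_equal(m$selected_epoch, which.max(m$log$val_f1))
  expect_gte(max(m$log$val_f1), m$log$val_f1[1])
})

test_that("fold assignment partitions recordings at the subject level", {
  recs <- lapply(1:12, function(i)
    list(frames = NULL, labels = NULL,
         subject = sprintf("S%d", ceiling(i / 2))))   # 2 recordings/subject
  subjects <- vapply(recs, function(r) r$subject, character(1))
  set.seed(4)
  uniq <- sample(unique(subjects))
  fold_of <- unname(stats::setNames(rep_len(1:10, length(uniq)),
                                    uniq)[subjects])
  expect_equal(length(fold_of), 12)
  for (s in unique(subjects))
    expect_equal(length(unique(fold_of[subjects == s])), 1)
  expect_error(crossvalidate_tenfold(recs[1:5], posture_classes()),
               "LOSO")
})

test_that("the ACD label collapse and filter mask behave as specified", {
  lab <- c("independent", "active_carry", "passive_carry", "active_carry",
           "passive_support")
  mask <- acd_filter(lab)
  expect_equal(as.logical(mask), c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(attr(mask, "retained_fraction"), 0.6)
  expect_equal(length(mask), length(lab))
  expect_true(all(acd_filter(rep("independent", 4))))
  expect_warning(m0 <- acd_filter(rep("active_carry", 3)), "no frames")
  expect_false(any(m0))
})

test_that("total sensor dropout reduces a single-sensor task to chance", {
  # class signal lives only in sensor 1 (channels 1:6)
  set.seed(6)
  n <- 200
  y <- rep(c("a", "b"), n / 2)
  X <- array(stats::rnorm(n * 120 * 24, 0, 0.1), c(n, 120, 24))
  X[y == "a", , 1:6] <- X[y == "a", , 1:6] + 3
  cls <- c("a", "b")
  enc <- encoder_spec(latent_dim = 16, channels = c(8),
                      filter_widths = c(7), strides = c(4))
  tmp <- temporal_spec(2, hidden = 8, dilations = 1)
  m_ok <- train_classifier(build_model(enc, tmp, cls, seed = 1), X, y,
                           train_config(epochs = 40, lr = 1e-3, seed = 1,
                                        sensor_dropout_p = 0))
  acc_ok <- mean(predict(m_ok, X)$labels == y)
  # dropping the informative sensor entirely leaves only noise channels
  m_dr <- train_classifier(build_model(enc, tmp, cls, seed = 1),
                           {
                             X0 <- X; X0[, , 1:6] <- 0; X0
                           }, y,
                           train_config(epochs = 40, lr = 1e-3, seed = 1))
  acc_dr <- mean(predict(m_dr, {
    X0 <- X; X0[, , 1:6] <- 0; X0
  })$labels == y)
  expect_gt(acc_ok, 0.9)
  expect_lt(acc_dr, 0.65)
})
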