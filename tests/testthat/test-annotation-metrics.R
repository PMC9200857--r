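make_signal <- function(n_sec, rate = 52) {
  structure(list(x = matrix(0, n_sec * rate, 24), t0 = 0, rate = rate),
            class = "uniform_signal")
}

make_ann <- function(labels_by_rater, track = "posture") {
  n <- length(labels_by_rater[[1]])
  m <- do.call(cbind, labels_by_rater)
  colnames(m) <- paste0("rater", seq_along(labels_by_rater))
  structure(list(raters = colnames(m), n_seconds = n,
                 tracks = stats::setNames(list(m), track)),
            class = "annotation_set")
}

test_that("unanimous constant annotations give unambiguous frame labels", {
  fa <- make_frames(make_signal(20))
  ann <- make_ann(list(rep("sitting", 20), rep("sitting", 20),
                       rep("sitting", 20)))
  fl <- frames_from_annotations(ann, fa)
  expect_true(all(fl$tracks$posture$hard == "sitting"))
  expect_false(any(fl$tracks$posture$ambiguous))
  expect_equal(unname(fl$tracks$posture$dist[, "sitting"]),
               rep(1, length(fl$tracks$posture$hard)))
})

test_that("plurality-time assignment picks the majority-share label", {
  # label changes at t = 1 s; first frame spans [0, 2.308): 43% / 57%
  fa <- make_frames(make_signal(12))
  lab <- c("supine", rep("prone", 11))
  ann <- make_ann(list(lab, lab))
  fl <- frames_from_annotations(ann, fa)
  expect_equal(fl$tracks$posture$hard[1], "prone")
})

test_that("a 2/1 rater split compounds into a (2/3, 1/3) distribution", {
  fa <- make_frames(make_signal(10))
  ann <- make_ann(list(rep("supine", 10), rep("supine", 10),
                       rep("prone", 10)))
  fl <- frames_from_annotations(ann, fa)
  expect_equal(unname(fl$tracks$posture$dist[1, "supine"]), 2 / 3)
  expect_equal(unname(fl$tracks$posture$dist[1, "prone"]), 1 / 3)
  expect_equal(fl$tracks$posture$hard[1], "supine")
  expect_true(all(fl$tracks$posture$ambiguous))
})

test_that("frames outside the annotation span are marked excluded", {
  fa <- make_frames(make_signal(20))
  ann <- make_ann(list(rep("supine", 10), rep("supine", 10)))
  ann$n_seconds <- 10
  ann$tracks$posture <- ann$tracks$posture[1:10, ]
  fl <- frames_from_annotations(ann, fa)
  expect_true(any(fl$excluded))
  expect_false(fl$excluded[1])
})

test_that("confusion compounding is additive and matches a manual tally", {
  a <- list(target = c("a", "a", "b", "b", "a"),
            predicted = c("a", "b", "b", "b", "a"))
  b <- list(target = c("b", "b", "a", "a", "a"),
            predicted = c("b", "a", "a", "a", "b"))
  cm_a <- compound_confusion(list(a), c("a", "b"))
  cm_b <- compound_confusion(list(b), c("a", "b"))
  cm_ab <- compound_confusion(list(a, b), c("a", "b"))
  expect_equal(unclass(cm_ab), unclass(cm_a) + unclass(cm_b),
               ignore_attr = TRUE)
  # manual tally of pair list a
  expect_equal(unname(unclass(cm_a)), matrix(c(2, 1, 0, 2), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_error(compound_confusion(list(list(target = "z", predicted = "a")),
                                  c("a", "b")), "unknown class")
})

test_that("identical sequences give a diagonal confusion matrix", {
  x <- sample(c("a", "b", "c"), 30, TRUE)
  cm <- compound_confusion(list(list(target = x, predicted = x)),
                           c("a", "b", "c"))
  expect_equal(sum(unclass(cm)) , sum(diag(unclass(cm))))
})

test_that("Fleiss' kappa matches a hand-computed worked table", {
  # 3 raters x 6 items, 2 categories; hand calculation gives 23/77
  counts <- rbind(c(3, 0), c(2, 1), c(1, 2), c(0, 3), c(3, 0), c(2, 1))
  expect_equal(fleiss_kappa_counts(counts), 23 / 77, tolerance = 1e-12)
})

test_that("two-rater kappa from a confusion matrix matches hand arithmetic", {
  cm <- matrix(c(20, 5, 10, 15), 2, byrow = TRUE)
  # po = 0.7, pe = 0.5 -> kappa = 0.4
  expect_equal(fleiss_kappa(cm), 0.4, tolerance = 1e-12)
})

test_that("kappa is 1 under perfect agreement and errors when degenerate", {
  counts <- rbind(c(3, 0), c(0, 3), c(3, 0))
  expect_equal(fleiss_kappa_counts(counts), 1)
  expect_error(fleiss_kappa_counts(rbind(c(3, 0), c(3, 0))), "undefined")
  expect_error(fleiss_kappa(matrix(c(5, 0, 0, 0), 2)), "undefined")
})

test_that("independent uniform raters have chance-level kappa", {
  set.seed(8)
  counts <- t(stats::rmultinom(1e4, 3, rep(1 / 4, 4)))
  expect_lt(abs(fleiss_kappa_counts(counts)), 0.05)
})

test_that("multi-rater Fleiss agrees with the two-rater form at n_raters = 2", {
  set.seed(3)
  a <- sample(c("x", "y", "z"), 500, TRUE)
  b <- ifelse(stats::runif(500) < 0.8, a, sample(c("x", "y", "z"), 500, TRUE))
  counts <- t(vapply(seq_along(a), function(i)
    tabulate(match(c(a[i], b[i]), c("x", "y", "z")), 3), integer(3)))
  cm <- table(factor(a, c("x", "y", "z")), factor(b, c("x", "y", "z")))
  # Fleiss with 2 raters uses mean-marginal chance; Cohen uses per-rater
  # marginals: close but not identical on unbalanced data
  expect_equal(fleiss_kappa_counts(counts), fleiss_kappa(as.matrix(cm)),
               tolerance = 0.02)
})

test_that("per-class metrics match arithmetic on a 2x2 example", {
  cm <- matrix(c(8, 2, 3, 7), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  m <- per_class_metrics(cm)
  expect_equal(m$per_class$recall[1], 0.8)
  expect_equal(m$per_class$precision[1], 8 / 11)
  expect_equal(m$accuracy, 0.75)
  diag_cm <- diag(c(5, 3, 2))
  dimnames(diag_cm) <- list(c("a", "b", "c"), c("a", "b", "c"))
  md <- per_class_metrics(diag_cm)
  expect_true(all(md$per_class$recall == 1 & md$per_class$f1 == 1))
  expect_equal(md$accuracy, 1)
})

test_that("permuting class order permutes per-class metrics only", {
  cm <- matrix(c(8, 2, 1, 3, 7, 0, 2, 2, 6), 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  perm <- c(3, 1, 2)
  cm_p <- cm[perm, perm]
  m <- per_class_metrics(cm)
  mp <- per_class_metrics(cm_p)
  expect_equal(mp$accuracy, m$accuracy)
  expect_equal(mp$per_class$f1, m$per_class$f1[perm])
})

test_that("empty classes report undefined metrics, not zero", {
  cm <- matrix(c(5, 0, 0, 0), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  m <- per_class_metrics(cm)
  expect_true(is.na(m$per_class$recall[2]))
  expect_true(is.na(m$per_class$precision[2]))
})

test_that("IAR is the identity at alpha 0 and conserves consensus", {
  set.seed(5)
  dist <- rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(0, 1, 0), c(1 / 3, 1 / 3, 1 / 3))
  train_const <- function(targets) matrix(1 / 3, nrow(targets), 3)
  r0 <- iar_refine(dist, train_const, alpha = 0)
  expect_equal(r0$targets, dist)
  expect_equal(r0$iterations, 0L)
  # all frames uncontested: classifier has no influence
  oh <- diag(3)[c(1, 2, 3, 1), ]
  r1 <- iar_refine(oh, function(t) matrix(c(0, 0, 1), 4, 3, byrow = TRUE),
                   alpha = 0.9)
  expect_equal(r1$targets, oh)
  expect_equal(r1$iterations, 0L)
  # contested rows move toward the classifier posterior; consensus rows fixed
  post <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 0, 0))
  r2 <- iar_refine(dist, function(t) post, alpha = 0.5, max_iter = 1)
  expect_equal(r2$targets[1, ], dist[1, ])
  expect_gt(r2$targets[2, 1], dist[2, 1])
  expect_error(iar_refine(dist, train_const, alpha = 1.5), "alpha")
})
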