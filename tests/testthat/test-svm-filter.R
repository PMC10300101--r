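# A linearly separable 22-feature toy problem: one informative column,
# the rest standard-normal noise.
toy_problem <- function(n = 60, gap = 4, seed = 1) {
  set.seed(seed)
  labels <- rep(c(TRUE, FALSE), length.out = n)
  x <- matrix(rnorm(n * 22), n, 22, dimnames = list(NULL, feature_names()))
  x[, "qual"] <- ifelse(labels, gap, -gap) + rnorm(n, 0, 0.2)
  list(x = x, labels = labels)
}

test_that("the hyperparameter grid has 11 linear + 121 RBF configurations", {
  g <- svm_config_grid()
  expect_equal(nrow(g), 132)
  expect_equal(sum(g$kernel == "linear"), 11)
  expect_equal(sum(g$kernel == "radial"), 121)
  expect_true(all(is.na(g$gamma[g$kernel == "linear"])))
  expect_equal(g$cost[1:11], c(1e-4, 1e-3, 1e-2, 0.1, 0.5, 1, 2, 5, 10, 20, 50))
  expect_equal(nrow(unique(g)), 132)
})

test_that("tuning reaches mean F1 = 1 on a separable problem", {
  tp <- toy_problem()
  cfg <- tune_hyperparameters(tp$x, tp$labels, seed = 2, grid = small_svm_grid())
  expect_equal(attr(cfg, "mean_f1"), 1)
  # ties on perfect F1 resolve to the first configuration in grid order
  cv <- attr(cfg, "cv_f1")
  expect_equal(which.max(cv), match(1, cv))
})

test_that("training is deterministic and separates the training set", {
  tp <- toy_problem()
  cfg <- data.frame(kernel = "linear", cost = 1, gamma = NA_real_)
  m1 <- svm_train(tp$x, tp$labels, cfg, seed = 5)
  m2 <- svm_train(tp$x, tp$labels, cfg, seed = 5)
  p1 <- svm_predict(m1, tp$x)
  p2 <- svm_predict(m2, tp$x)
  expect_identical(p1$score, p2$score)
  expect_equal(p1$keep, tp$labels)  # 100% training accuracy when separable
})

test_that("decision scores are oriented so positives score high", {
  tp <- toy_problem()
  # flip label order in the data; orientation must still hold
  ord <- order(tp$labels)
  m <- svm_train(tp$x[ord, ], tp$labels[ord],
                 data.frame(kernel = "linear", cost = 1, gamma = NA_real_))
  p <- svm_predict(m, tp$x)
  expect_gt(mean(p$score[tp$labels]), mean(p$score[!tp$labels]))
})

test_that("the decision threshold trades recall against precision monotonically", {
  set.seed(3)
  n <- 200
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  x <- matrix(rnorm(n * 22), n, 22, dimnames = list(NULL, feature_names()))
  x[, "vaf"] <- ifelse(labels, 1.5, -1.5) + rnorm(n)  # noisy separation
  m <- svm_train(x, labels, data.frame(kernel = "linear", cost = 1,
                                       gamma = NA_real_))
  sc <- svm_predict(m, x)$score
  expect_equal(sum(sc >= Inf), 0)
  expect_equal(sum(sc >= -Inf), n)
  thresholds <- quantile(sc, seq(0.05, 0.95, by = 0.1))
  stats <- t(vapply(thresholds, function(t) {
    m <- metrics_from_decisions(labels, sc >= t)
    c(rc = m$recall, pr = m$precision)
  }, numeric(2)))
  expect_true(all(diff(stats[, "rc"]) <= 1e-12))       # recall never rises
  expect_true(all(diff(stats[, "pr"]) >= -1e-12))      # precision never falls
})

test_that("wrong feature dimensionality is rejected at prediction", {
  tp <- toy_problem()
  m <- svm_train(tp$x, tp$labels,
                 data.frame(kernel = "linear", cost = 1, gamma = NA_real_))
  expect_error(svm_predict(m, tp$x[, 1:10]), "expected 22")
})

test_that("serialized models reload with identical scores and feature order", {
  tp <- toy_problem()
  m <- svm_train(tp$x, tp$labels,
                 data.frame(kernel = "radial", cost = 2, gamma = 0.1))
  f <- tempfile(fileext = ".rds")
  write_model(m, f)
  m2 <- read_model(f)
  expect_identical(m2$feature_names, feature_names())
  expect_identical(svm_predict(m2, tp$x)$score, svm_predict(m, tp$x)$score)
})

test_that("duplicating training rows preserves the decision sign pattern", {
  tp <- toy_problem(n = 40)
  cfg <- data.frame(kernel = "linear", cost = 1, gamma = NA_real_)
  m1 <- svm_train(tp$x, tp$labels, cfg)
  m2 <- svm_train(rbind(tp$x, tp$x), c(tp$labels, tp$labels), cfg)
  probe <- toy_problem(n = 20, seed = 99)$x
  expect_equal(sign(svm_predict(m1, probe)$score),
               sign(svm_predict(m2, probe)$score))
})

test_that("leave-one-patient-out separates a well-separated synthetic cohort", {
  td <- separable_cohort()$td
  res <- lopo_evaluate(td$calls, td$features, td$labels, td$patients,
                       strategies = c("none", "svm"), seed = 7,
                       grid = small_svm_grid())
  svm <- res$strategies$svm
  expect_equal(svm$pooled$f1, 1)
  # pooled counts equal the sum of per-patient counts
  expect_equal(svm$pooled$tp + svm$pooled$fp + svm$pooled$tn + svm$pooled$fn,
               sum(svm$counts[, c("tp", "fp", "tn", "fn")]))
  # no filtering: recall 1, MCC 0, J 0
  none <- res$strategies$none$pooled
  expect_equal(none$recall, 1)
  expect_equal(none$mcc, 0)
  expect_equal(none$youden_j, 0)
  # no leakage: the held-out patient is never among the training patients
  for (i in seq_along(res$patients))
    expect_false(res$patients[i] %in% svm$train_patients[[i]])
})

test_that("pooled performance grows with the class-separation of the cohort", {
  f1_at <- function(sep) {
    co <- make_cohort(n_patients = 4, separation = sep, seed = 31)
    td <- suppressMessages(cohort_training_data(co))
    res <- lopo_evaluate(td$calls, td$features, td$labels, td$patients,
                         strategies = "svm", seed = 5,
                         grid = small_svm_grid())
    res$strategies$svm$pooled$f1
  }
  f1s <- vapply(c(0.25, 1.5, 4), f1_at, numeric(1))
  expect_true(all(diff(f1s) >= -0.05))  # monotone up to sampling noise
  expect_gte(f1s[3], 0.95)
})

test_that("label-only missed variants count against recall in LOPO", {
  td <- separable_cohort()$td
  missed <- setNames(rep(1L, 6), unique(td$patients))
  res <- lopo_evaluate(td$calls, td$features, td$labels, td$patients,
                       strategies = "none", missed = missed)
  none <- res$strategies$none$pooled
  expect_equal(none$fn, 6)
  expect_lt(none$recall, 1)
})

test_that("the final model matches its tuned inner-CV performance on the cohort", {
  td <- separable_cohort()$td
  model <- train_final(td$features, td$labels, seed = 4,
                       grid = small_svm_grid())
  pred <- svm_predict(model, td$features)
  m <- metrics_from_decisions(td$labels, pred$keep)
  expect_gte(m$f1, attr(attr(model, "tuning"), "mean_f1"))
})
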