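toy_separable <- function(n = 40) {
  set.seed(3)
  tibble::tibble(
    x1 = c(rnorm(n, -2, 0.3), rnorm(n, 2, 0.3)),
    x2 = c(rnorm(n, -2, 0.3), rnorm(n, 2, 0.3)),
    label = factor(rep(c("a", "b"), each = n))
  )
}

xor_data <- function(n = 30) {
  set.seed(5)
  q <- rep(1:4, each = n)
  tibble::tibble(
    x1 = c(-1, 1, -1, 1)[q] + rnorm(4 * n, 0, 0.1),
    x2 = c(-1, -1, 1, 1)[q] + rnorm(4 * n, 0, 0.1),
    label = factor(ifelse(q %in% c(1, 4), "a", "b"))
  )
}

test_that("both classifier families fit separable data perfectly", {
  d <- toy_separable()
  for (kind in c("bdt", "svm")) {
    fit <- fit_classifier(d, kind)
    expect_equal(as.character(predict(fit, d)), as.character(d$label))
  }
  expect_error(fit_classifier(dplyr::mutate(d, label = factor("a")), "bdt"),
               class = "ecgkit_config")
})

test_that("the tree solves XOR but the linear SVM cannot", {
  d <- xor_data()
  # XOR has zero first-split impurity gain, so growing past the default
  # pruning needs the exposed control knob
  bdt <- fit_classifier(d, "bdt",
                        control = rpart::rpart.control(minsplit = 2L,
                                                       minbucket = 1L,
                                                       cp = 0, xval = 0L))
  expect_equal(mean(predict(bdt, d) == d$label), 1)
  svm <- fit_classifier(d, "svm")
  expect_lt(mean(predict(svm, d) == d$label), 1)
})

test_that("metrics follow their confusion-matrix definitions", {
  perfect <- evaluate_predictions(c(1, 1, 0, 0), c(1, 1, 0, 0), positive = 1)
  expect_equal(unlist(perfect[, 1:3]), c(accuracy = 100, sensitivity = 100,
                                         specificity = 100))
  # TP 9, FN 1, TN 8, FP 2
  truth <- rep(c("p", "n"), each = 10)
  pred <- c(rep("p", 9), "n", rep("n", 8), rep("p", 2))
  m <- evaluate_predictions(pred, truth, positive = "p")
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 80)
  expect_equal(m$accuracy, 85)

  allneg <- evaluate_predictions(rep("n", 20), truth, positive = "p")
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 100)
  expect_equal(allneg$accuracy, 50)

  expect_error(evaluate_predictions(1:3, 1:4, positive = 1),
               class = "ecgkit_config")
})

test_that("evaluation is invariant to joint permutation of pred and truth", {
  set.seed(61)
  pred <- sample(c("p", "n"), 50, replace = TRUE)
  truth <- sample(c("p", "n"), 50, replace = TRUE)
  base <- evaluate_predictions(pred, truth, "p")
  for (i in 1:5) {
    o <- sample(50)
    expect_equal(evaluate_predictions(pred[o], truth[o], "p"), base)
  }
})

test_that("the unbalanced protocol makes half/half splits and is seed-stable", {
  d <- toy_separable(50)  # N = 100
  ev <- protocol_unbalanced(d, "bdt", seed = 9, positive = "b")
  expect_equal(nrow(tidy(ev)), 5)
  trials <- tidy(ev)
  expect_true(all(trials$tp + trials$fn + trials$tn + trials$fp == 50))
  ev2 <- protocol_unbalanced(d, "bdt", seed = 9, positive = "b")
  expect_identical(glance(ev), glance(ev2))
  ev3 <- protocol_unbalanced(d, "bdt", seed = 10, positive = "b")
  expect_false(identical(tidy(ev), tidy(ev3)))
})

test_that("the balanced protocol yields 25 trials of B/B splits", {
  set.seed(71)
  d <- tibble::tibble(
    x1 = c(rnorm(200, 0, 1), rnorm(20, 4, 1)),
    label = factor(rep(c("neg", "pos"), c(200, 20)))
  )
  ev <- protocol_balanced(d, "bdt", seed = 11)
  trials <- tidy(ev)
  expect_equal(nrow(trials), 25)
  # every test fold holds the B = 20 samples left out of the 2B pool
  expect_true(all(trials$tp + trials$fn + trials$tn + trials$fp == 20))
  expect_identical(glance(protocol_balanced(d, "bdt", seed = 11)), glance(ev))
})

test_that("balancing recovers sensitivity lost to class imbalance", {
  set.seed(73)
  # overlapping classes, heavily majority-negative
  d <- tibble::tibble(
    x1 = c(rnorm(400, 0, 1.3), rnorm(24, 1.8, 1.3)),
    label = factor(rep(c("neg", "pos"), c(400, 24)))
  )
  g_unb <- glance(protocol_unbalanced(d, "bdt", seed = 13))
  g_bal <- glance(protocol_balanced(d, "bdt", seed = 13))
  expect_gte(g_bal$sensitivity, g_unb$sensitivity)
})
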