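#' Fit a stage classifier (binary decision tree or linear SVM)
#'
#' The two classifier families used at every decision stage: a binary
#' decision tree (Gini impurity, effectively unlimited depth, with rpart's
#' standard complexity pruning - fully grown trees tend to sprout
#' single-sample leaves that flip downstream episode labels on one noisy
#' beat) and a linear support vector machine with cost parameter C = 1.
#' SVM features are standardized internally using the training data only;
#' trees are fit on raw features.
#'
#' @param data Data frame with a two-level factor column `label` and numeric
#'   feature columns. Both classes must be present.
#' @param kind `"bdt"` (decision tree) or `"svm"` (linear SVM).
#' @param control [rpart::rpart.control()] overrides for the tree.
#' @return An object of class `ecg_classifier`.
#' @examples
#' d <- synth_dataset("pvc", n_per_class = 20, seed = 1)
#' fit_classifier(d, "bdt")
#' @export
fit_classifier <- function(data, kind = c("bdt", "svm"),
                           control = rpart::rpart.control(maxdepth = 30L,
                                                          xval = 0L)) {
  kind <- match.arg(kind)
  data <- as.data.frame(data)
  if (!"label" %in% names(data)) ecg_abort("`data` needs a `label` column.", "config")
  data$label <- as.factor(data$label)
  if (nlevels(droplevels(data$label)) < 2L) {
    ecg_abort("training data must contain both classes.", "config")
  }
  features <- setdiff(names(data), "label")
  model <- if (kind == "bdt") {
    rpart::rpart(label ~ ., data = data, method = "class",
                 parms = list(split = "gini"), control = control)
  } else {
    e1071::svm(label ~ ., data = data, kernel = "linear", cost = 1, scale = TRUE)
  }
  structure(list(kind = kind, model = model, features = features,
                 levels = levels(data$label)),
            class = "ecg_classifier")
}

#' @export
print.ecg_classifier <- function(x, ...) {
  cat(sprintf("<ecg_classifier> %s on %d features (%s) | classes: %s\n",
              if (x$kind == "bdt") "decision tree" else "linear SVM (C = 1)",
              length(x$features), paste(x$features, collapse = ", "),
              paste(x$levels, collapse = " vs ")))
  invisible(x)
}

#' Predict class labels
#'
#' @param object An `ecg_classifier`.
#' @param newdata Data frame containing the training feature columns.
#' @param ... Unused.
#' @return Factor of predicted labels with the training levels.
#' @export
predict.ecg_classifier <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[, object$features, drop = FALSE]
  if (object$kind == "bdt") {
    factor(predict(object$model, newdata, type = "class"),
           levels = object$levels)
  } else {
    factor(predict(object$model, newdata), levels = object$levels)
  }
}

#' Accuracy, sensitivity and specificity of a prediction
#'
#' Percentages: sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
#' accuracy = (TP + TN) / N, each times 100.
#'
#' @param pred,truth Vectors of equal length (factors or labels).
#' @param positive The positive-class label.
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`, `tp`,
#'   `fn`, `tn`, `fp`.
#' @examples
#' evaluate_predictions(rep(c(1, 0), c(11, 9)), rep(c(1, 0), c(10, 10)), positive = 1)
#' @export
evaluate_predictions <- function(pred, truth, positive) {
  if (length(pred) != length(truth)) {
    ecg_abort("`pred` and `truth` must have equal length.", "config")
  }
  p <- as.character(pred) == as.character(positive)
  t <- as.character(truth) == as.character(positive)
  tp <- sum(p & t); fn <- sum(!p & t); tn <- sum(!p & !t); fp <- sum(p & !t)
  tibble(
    accuracy = 100 * (tp + tn) / length(pred),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    tp = tp, fn = fn, tn = tn, fp = fp
  )
}

# draw a train index set until both train and test contain both classes
draw_split <- function(labels, n_train, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    tr <- sample(length(labels), n_train)
    if (nlevels(droplevels(labels[tr])) == 2L &&
        nlevels(droplevels(labels[-tr])) == 2L) {
      return(tr)
    }
  }
  ecg_abort("could not draw a split with both classes on each side.", "config")
}

#' Unbalanced evaluation protocol: five random half/half splits
#'
#' All samples are randomly split in half into training and testing sets
#' (unstratified); the classifier is trained and evaluated, and the
#' procedure is repeated `n_trials` times. Degenerate single-class splits
#' are re-drawn. Reported as mean and standard deviation over trials.
#'
#' @param data Data frame with `label` factor column plus features.
#' @param kind `"bdt"` or `"svm"`.
#' @param n_trials Number of random splits.
#' @param seed Integer seed; the whole protocol is deterministic given it.
#' @param positive Positive-class label; defaults to the last factor level.
#' @return An `ecg_eval` object; see [tidy.ecg_eval()] / [glance.ecg_eval()].
#' @examples
#' d <- synth_dataset("pvc", n_per_class = 30, seed = 1)
#' protocol_unbalanced(d, "bdt", seed = 1)
#' @export
protocol_unbalanced <- function(data, kind = c("bdt", "svm"), n_trials = 5L,
                                seed = 1L, positive = NULL) {
  kind <- match.arg(kind)
  data <- as.data.frame(data)
  data$label <- as.factor(data$label)
  if (nrow(data) < 4L) ecg_abort("need at least 4 samples.", "config")
  positive <- positive %||% levels(data$label)[nlevels(data$label)]
  trials <- withr::with_seed(seed, {
    map(seq_len(n_trials), function(trial) {
      tr <- draw_split(data$label, nrow(data) %/% 2L)
      fit <- fit_classifier(data[tr, ], kind)
      test <- data[-tr, ]
      mutate(evaluate_predictions(predict(fit, test), test$label, positive),
             trial = trial, .before = 1L)
    })
  })
  new_ecg_eval(bind_rows(trials), protocol = "unbalanced", kind = kind,
               positive = positive, n = nrow(data), seed = seed)
}

#' Balanced evaluation protocol: 5 x 5 subsampled splits
#'
#' The majority class is randomly subsampled to the minority-class size B
#' (outer loop, 5 times); each balanced pool of 2B samples is then randomly
#' split into B training and B testing samples (inner loop, 5 times),
#' yielding 25 trials whose metrics are averaged.
#'
#' @inheritParams protocol_unbalanced
#' @param n_outer,n_inner Repetitions of the subsample and split loops.
#' @return An `ecg_eval` object.
#' @export
protocol_balanced <- function(data, kind = c("bdt", "svm"), seed = 1L,
                              n_outer = 5L, n_inner = 5L, positive = NULL) {
  kind <- match.arg(kind)
  data <- as.data.frame(data)
  data$label <- as.factor(data$label)
  counts <- table(data$label)
  if (min(counts) < 4L) ecg_abort("minority class needs at least 4 samples.", "config")
  positive <- positive %||% levels(data$label)[nlevels(data$label)]
  minority <- names(counts)[which.min(counts)]
  b <- min(counts)
  trials <- withr::with_seed(seed, {
    out <- list()
    for (outer in seq_len(n_outer)) {
      keep_major <- sample(which(data$label != minority), b)
      pool <- data[c(which(data$label == minority), keep_major), ]
      for (inner in seq_len(n_inner)) {
        tr <- draw_split(pool$label, b)
        fit <- fit_classifier(pool[tr, ], kind)
        test <- pool[-tr, ]
        out[[length(out) + 1L]] <-
          mutate(evaluate_predictions(predict(fit, test), test$label, positive),
                 trial = length(out) + 1L, .before = 1L)
      }
    }
    out
  })
  new_ecg_eval(bind_rows(trials), protocol = "balanced", kind = kind,
               positive = positive, n = nrow(data), seed = seed)
}

new_ecg_eval <- function(trials, protocol, kind, positive, n, seed) {
  structure(list(trials = trials, protocol = protocol, kind = kind,
                 positive = positive, n = n, seed = seed),
            class = "ecg_eval")
}

#' @export
print.ecg_eval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<ecg_eval> %s protocol, %s, %d trials (n = %d, positive = %s)\n",
              x$protocol, x$kind, nrow(x$trials), x$n, x$positive))
  cat(sprintf("  accuracy    %5.1f +/- %.1f %%\n", g$accuracy, g$accuracy_sd))
  cat(sprintf("  sensitivity %5.1f +/- %.1f %%\n", g$sensitivity, g$sensitivity_sd))
  cat(sprintf("  specificity %5.1f +/- %.1f %%\n", g$specificity, g$specificity_sd))
  invisible(x)
}

#' Per-trial metrics of an evaluation
#'
#' @param x An `ecg_eval` from [protocol_unbalanced()] or
#'   [protocol_balanced()].
#' @param ... Unused.
#' @return Tibble with one row per trial.
#' @export
tidy.ecg_eval <- function(x, ...) {
  x$trials
}

#' One-row summary of an evaluation
#'
#' @inheritParams tidy.ecg_eval
#' @return One-row tibble with mean and standard deviation of accuracy,
#'   sensitivity and specificity (percent) over trials.
#' @export
glance.ecg_eval <- function(x, ...) {
  tr <- x$trials
  tibble(
    protocol = x$protocol, kind = x$kind, n_trials = nrow(tr),
    accuracy = mean(tr$accuracy), accuracy_sd = sd(tr$accuracy),
    sensitivity = mean(tr$sensitivity, na.rm = TRUE),
    sensitivity_sd = sd(tr$sensitivity, na.rm = TRUE),
    specificity = mean(tr$specificity, na.rm = TRUE),
    specificity_sd = sd(tr$specificity, na.rm = TRUE)
  )
}

#' Bar chart of evaluation metrics with trial spread
#'
#' @param object An `ecg_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_eval <- function(object, ...) {
  g <- glance(object)
  d <- tibble(
    metric = factor(c("accuracy", "sensitivity", "specificity"),
                    levels = c("accuracy", "sensitivity", "specificity")),
    mean = c(g$accuracy, g$sensitivity, g$specificity),
    sd = c(g$accuracy_sd, g$sensitivity_sd, g$specificity_sd)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(y = "percent", x = NULL,
                  title = sprintf("%s protocol, %s classifier",
                                  object$protocol, object$kind)) +
    ggplot2::theme_minimal()
}
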