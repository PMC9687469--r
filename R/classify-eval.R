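#' Fidelity kernel classifier
#'
#' Embeds the training samples of each class once and caches the states.
#' The decision value for a test sample `x` is the difference between its
#' mean overlap with the class-A and class-B training ensembles,
#' `f(x) = mean_a |<a|x>|^2 - mean_b |<b|x>|^2 = <x| rho - sigma |x>`;
#' the predicted class is `sign(f)`. Class A is the lexicographically
#' second label (the internal `+1` class), class B the first.
#'
#' @param train_table a [labeled_table()] with both classes.
#' @param params trained [hybrid_params()].
#' @param config an [embedding_config()].
#' @param tie_class label predicted when `f(x)` is exactly 0; defaults to
#'   class B (the negative class).
#' @return An object of class `fidelity_classifier`.
#' @export
fidelity_classifier <- function(train_table, params,
                                config = embedding_config(),
                                tie_class = NULL) {
  levels <- class_levels(train_table)
  if (length(levels) != 2L) {
    stop("classifier requires both classes in the training table",
         call. = FALSE)
  }
  if (is.null(tie_class)) tie_class <- levels[1]
  if (!tie_class %in% levels) {
    stop("`tie_class` must be one of the class labels", call. = FALSE)
  }
  states <- embed_table(train_table, params, config)
  structure(list(
    states_a = states[, train_table$labels == levels[2], drop = FALSE],
    states_b = states[, train_table$labels == levels[1], drop = FALSE],
    class_a = levels[2], class_b = levels[1],
    tie_class = tie_class, params = params, config = config
  ), class = "fidelity_classifier")
}

#' @export
print.fidelity_classifier <- function(x, ...) {
  cat(sprintf("<fidelity_classifier> A = '%s' (%d states), B = '%s' (%d states)\n",
              x$class_a, ncol(x$states_a), x$class_b, ncol(x$states_b)))
  invisible(x)
}

#' Decision values of the fidelity classifier
#'
#' @param x a feature vector, feature matrix (rows = samples) or
#'   [labeled_table()].
#' @param clf a [fidelity_classifier()].
#' @return Numeric vector of decision values `f(x)` in `[-1, 1]`; positive
#'   values favor class A.
#' @export
decision_value <- function(x, clf) {
  feats <- if (inherits(x, "labeled_table")) x$features
           else if (is.matrix(x)) x
           else matrix(x, nrow = 1)
  states <- embed_batch(project_features(feats, clf$params$weights),
                        clf$params$thetas, clf$config)
  colMeans(overlap_matrix(clf$states_a, states)) -
    colMeans(overlap_matrix(clf$states_b, states))
}

#' @rdname decision_value
#' @param object a [fidelity_classifier()].
#' @param newdata samples to classify (as in `x`).
#' @param ... unused.
#' @return For `predict`: character vector of predicted class labels
#'   (`sign(f)`; exact ties go to the classifier's `tie_class`).
#' @export
predict.fidelity_classifier <- function(object, newdata, ...) {
  f <- decision_value(newdata, object)
  out <- ifelse(f > 0, object$class_a,
                ifelse(f < 0, object$class_b, object$tie_class))
  as.character(out)
}

#' Precision, recall and F1 of a prediction vector
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 P R / (P + R)`; a zero denominator yields 0 with a warning.
#'
#' @param predictions predicted class labels.
#' @param truth true class labels (same length, non-empty).
#' @param positive_label label counted as positive.
#' @return List with `precision`, `recall` and `f1`.
#' @export
compute_metrics <- function(predictions, truth, positive_label) {
  if (length(predictions) != length(truth) || length(truth) == 0L) {
    stop("`predictions` and `truth` must be non-empty and of equal length",
         call. = FALSE)
  }
  tp <- sum(predictions == positive_label & truth == positive_label)
  fp <- sum(predictions == positive_label & truth != positive_label)
  fn <- sum(predictions != positive_label & truth == positive_label)
  div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reporting 0", what),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  precision <- div(tp, tp + fp, "precision")
  recall <- div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, f1 = f1)
}

#' Gram matrix of pairwise state overlaps
#'
#' Symmetric matrix of `|<x_i|x_j>|^2` with unit diagonal — the Hilbert
#' space "mutual data overlap" picture used to visualize class separation.
#'
#' @param states a `4 x M` amplitude matrix, list of states, or
#'   [class_ensemble()].
#' @return An `M x M` numeric matrix with entries in `[0, 1]`.
#' @export
gram_matrix <- function(states) {
  s <- as_state_matrix(if (inherits(states, "class_ensemble"))
    states$states else states)
  overlap_matrix(s, s)
}

#' Evaluate a trained embedding on a train/test split
#'
#' Embeds both splits once, computes the full-split training and test costs
#' from the class-ensemble overlaps, classifies the test rows against the
#' training ensembles, and assembles one result row in the layout of the
#' published tables.
#'
#' @param train,test [labeled_table()]s sharing the same feature space.
#' @param params trained [hybrid_params()].
#' @param config an [embedding_config()].
#' @param positive_label class scored as positive for precision/recall;
#'   defaults to the lexicographically second label.
#' @param used_pca logical bookkeeping flag for the output record.
#' @param tie_class see [fidelity_classifier()].
#' @return A one-row data.frame (`metrics_record`) with columns
#'   `n_features_used`, `used_pca`, `training_cost`, `test_cost`,
#'   `precision`, `recall`, `f1`.
#' @export
evaluate_split <- function(train, test, params,
                           config = embedding_config(),
                           positive_label = NULL, used_pca = FALSE,
                           tie_class = NULL) {
  levels <- class_levels(train)
  if (length(levels) != 2L) {
    stop("evaluation requires both classes in the training split",
         call. = FALSE)
  }
  if (is.null(positive_label)) positive_label <- levels[2]
  clf <- fidelity_classifier(train, params, config, tie_class = tie_class)

  test_states <- embed_table(test, params, config)
  test_a <- test_states[, test$labels == clf$class_a, drop = FALSE]
  test_b <- test_states[, test$labels == clf$class_b, drop = FALSE]
  if (ncol(test_a) == 0L || ncol(test_b) == 0L) {
    stop("test split must contain both classes", call. = FALSE)
  }

  preds <- predict(clf, test)
  met <- compute_metrics(preds, test$labels, positive_label)
  record <- data.frame(
    n_features_used = n_features(train),
    used_pca = used_pca,
    training_cost = ensemble_cost(clf$states_a, clf$states_b),
    test_cost = ensemble_cost(test_a, test_b),
    precision = met$precision, recall = met$recall, f1 = met$f1
  )
  class(record) <- c("metrics_record", class(record))
  record
}
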