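#' Classifier specification
#'
#' Names one of the four classifier families with its hyperparameters.
#' Defaults follow the common library defaults of each family and are
#' recorded in the object so a run log can print them verbatim:
#' * `RF` — [randomForest::randomForest] with 100 trees, no depth
#'   restriction, Gini impurity;
#' * `DT` — [rpart::rpart] with its standard complexity defaults;
#' * `NN` — [nnet::nnet] multi-layer perceptron with one hidden layer of
#'   100 units, weight decay 1e-4, 200 iterations;
#' * `SVM` — [e1071::svm] radial kernel with internal cross-validated
#'   probability calibration (`probability = TRUE`), required by the
#'   decision-threshold rule.
#'
#' @param kind One of `"RF"`, `"DT"`, `"NN"`, `"SVM"`.
#' @param ... Overrides of the family's defaults.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("RF", "DT", "NN", "SVM"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    RF = list(ntree = 100),
    DT = list(),
    NN = list(size = 100, decay = 1e-4, maxit = 200, MaxNWts = 20000),
    SVM = list(kernel = "radial", cost = 1))
  params <- utils::modifyList(defaults, list(...))
  structure(list(kind = kind, params = params), class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  ps <- paste(names(x$params), vapply(x$params, format, character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("<classifier_spec %s (%s)>\n", x$kind,
              if (nzchar(ps)) ps else "library defaults"))
  invisible(x)
}

#' Train a binary probabilistic classifier
#'
#' Fits the classifier named by `spec` on a (masked, normalised) feature
#' matrix against binary labels coded 0/1 (1 is the positive,
#' recall-critical class). The fitted model exposes `P(1 | sample)` via
#' [predict_prob()].
#'
#' @param spec A [classifier_spec].
#' @param X Numeric feature matrix.
#' @param y Binary vector (0/1) with both classes present.
#' @param seed Integer seed applied before fitting (RF bootstrap, NN init,
#'   SVM calibration folds are stochastic).
#' @return An object of class `fitted_classifier`.
#' @export
train_classifier <- function(spec, X, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in training labels")
  stopifnot(all(y %in% c(0L, 1L)), nrow(X) == length(y))
  df <- as.data.frame(X)
  df$.class <- factor(y, levels = c(0L, 1L))
  set.seed(seed)
  p <- spec$params
  fit <- switch(spec$kind,
    RF = do.call(randomForest::randomForest,
                 c(list(.class ~ ., data = df), p)),
    DT = do.call(rpart::rpart,
                 c(list(.class ~ ., data = df, method = "class"), p)),
    NN = do.call(nnet::nnet,
                 c(list(.class ~ ., data = df, trace = FALSE), p)),
    SVM = do.call(e1071::svm,
                  c(list(.class ~ ., data = df, probability = TRUE), p)))
  structure(list(spec = spec, fit = fit, features = colnames(X)),
            class = "fitted_classifier")
}

#' Positive-class probability
#'
#' @param model A `fitted_classifier`.
#' @param X Feature matrix with the training columns.
#' @return Numeric vector of `P(class 1 | sample)`.
#' @export
predict_prob <- function(model, X) {
  stopifnot(inherits(model, "fitted_classifier"))
  df <- as.data.frame(X)[model$features]
  switch(model$spec$kind,
    RF = unname(predict(model$fit, df, type = "prob")[, "1"]),
    DT = unname(predict(model$fit, df, type = "prob")[, "1"]),
    NN = as.numeric(predict(model$fit, df, type = "raw")),
    SVM = {
      pr <- predict(model$fit, df, probability = TRUE)
      unname(attr(pr, "probabilities")[, "1"])
    })
}

#' Decision-threshold classification rule
#'
#' A sample is assigned the positive class 1 exactly when
#' `P(1 | sample) >= threshold` (inclusive). The default 0.5 reproduces the
#' usual argmax rule; lowering the threshold trades accuracy for recall on
#' the positive (bird / big-raptor) class. The rule only affects prediction,
#' never training.
#'
#' @param model A `fitted_classifier`.
#' @param X Feature matrix.
#' @param threshold Probability cutoff in `[0, 1]`.
#' @return Integer vector of 0/1 predictions.
#' @export
predict_with_threshold <- function(model, X, threshold = 0.5) {
  threshold_rule(predict_prob(model, X), threshold)
}

#' @rdname predict_with_threshold
#' @param prob Vector of positive-class probabilities.
#' @export
threshold_rule <- function(prob, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  as.integer(prob >= threshold)
}

#' Binary confusion matrix
#'
#' Counts with class 1 as positive: `TP` (true 1 predicted 1), `FP` (true 0
#' predicted 1), `TN`, `FN`.
#'
#' @param y_true,y_pred Equal-length binary vectors.
#' @return An object of class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  structure(list(TP = sum(y_true == 1L & y_pred == 1L),
                 FP = sum(y_true == 0L & y_pred == 1L),
                 TN = sum(y_true == 0L & y_pred == 0L),
                 FN = sum(y_true == 1L & y_pred == 0L)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion: TP=%d FP=%d TN=%d FN=%d>\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Accuracy and recall of a confusion matrix
#'
#' `accuracy = (TP + TN) / (TP + FP + TN + FN)`; `recall = TP / (TP + FN)`.
#' Recall is the probability that a true positive (a bird, or a big raptor)
#' is flagged, the safety-critical quantity of the application; it is an
#' error to request it when the truth contains no positives.
#'
#' @param cm A `confusion_matrix`.
#' @return Named list with `accuracy` and `recall`, both in `[0, 1]`.
#' @export
cm_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$FP + cm$TN + cm$FN
  if (total == 0L) stop("empty confusion matrix")
  if (cm$TP + cm$FN == 0L)
    stop("recall undefined: no positive samples in truth")
  list(accuracy = (cm$TP + cm$TN) / total, recall = cm$TP / (cm$TP + cm$FN))
}

#' Train the two-stage cascade
#'
#' Stage 1 separates birds (positive class 1) from aeroplanes on all tracks;
#' stage 2 separates big raptors (positive class 1) from other birds on the
#' bird tracks only. Each stage carries its own feature mask, normalisation
#' model (fitted on that stage's training rows) and decision threshold.
#'
#' @param trajs List of labelled [trajectory] objects (all three classes).
#' @param spec1,spec2 [classifier_spec] for each stage.
#' @param threshold1,threshold2 Decision thresholds in `[0, 1]`.
#' @param mask1,mask2 Binary feature masks of length 78 (`NULL` = all 78).
#' @param edges Distance-interval edges for feature extraction.
#' @param seed Integer seed.
#' @return An object of class `cascade_model`.
#' @export
train_cascade <- function(trajs, spec1 = classifier_spec("RF"),
                          spec2 = classifier_spec("RF"),
                          threshold1 = 0.4, threshold2 = 0.125,
                          mask1 = NULL, mask2 = NULL,
                          edges = default_distance_edges(), seed = 1L) {
  fm <- extract_feature_matrix(trajs, edges = edges)
  if (is.null(mask1)) mask1 <- rep(1L, ncol(fm$X))
  if (is.null(mask2)) mask2 <- rep(1L, ncol(fm$X))
  fit_stage <- function(X, y, spec, mask, threshold, seed) {
    norm <- fit_normalization(X)
    Xn <- apply_normalization(norm, X)[, mask == 1L, drop = FALSE]
    list(model = train_classifier(spec, Xn, y, seed), norm = norm,
         mask = as.integer(mask), threshold = threshold)
  }
  y1 <- as.integer(fm$label != "aeroplane")
  stage1 <- fit_stage(fm$X, y1, spec1, mask1, threshold1, seed)
  birds <- fm$label != "aeroplane"
  y2 <- as.integer(fm$label[birds] == "big_raptor")
  stage2 <- fit_stage(fm$X[birds, , drop = FALSE], y2, spec2, mask2,
                      threshold2, seed + 1L)
  structure(list(stage1 = stage1, stage2 = stage2, edges = edges),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf(
    "<cascade_model: stage1 %s th=%.3g (%d features), stage2 %s th=%.3g (%d features)>\n",
    x$stage1$model$spec$kind, x$stage1$threshold, sum(x$stage1$mask),
    x$stage2$model$spec$kind, x$stage2$threshold, sum(x$stage2$mask)))
  invisible(x)
}

stage_predict <- function(stage, X) {
  Xn <- apply_normalization(stage$norm, X)[, stage$mask == 1L, drop = FALSE]
  predict_with_threshold(stage$model, Xn, stage$threshold)
}

#' Three-class cascade prediction
#'
#' Features are extracted once per track. Stage 1 decides aeroplane (0,
#' stop) vs bird (1, continue); stage 2 decides big raptor (1) vs other
#' bird (0). Every track receives exactly one of the three labels.
#'
#' @param cascade A `cascade_model`.
#' @param trajs A single [trajectory] or a list of them.
#' @return Factor of predicted labels
#'   (`aeroplane` / `big_raptor` / `other_bird`).
#' @export
cascade_predict <- function(cascade, trajs) {
  stopifnot(inherits(cascade, "cascade_model"))
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  X <- extract_feature_matrix(trajs, edges = cascade$edges)$X
  out <- rep("aeroplane", nrow(X))
  is_bird <- stage_predict(cascade$stage1, X) == 1L
  if (any(is_bird)) {
    raptor <- stage_predict(cascade$stage2, X[is_bird, , drop = FALSE]) == 1L
    out[is_bird] <- ifelse(raptor, "big_raptor", "other_bird")
  }
  factor(out, levels = TRACK_LABELS)
}

#' Evaluate a cascade on labelled tracks
#'
#' @param cascade A `cascade_model`.
#' @param trajs List of labelled trajectories.
#' @return List with the 3-class `table` (truth x prediction), overall
#'   3-class `accuracy`, and per-stage binary accuracy/recall (stage 2
#'   evaluated on the true birds).
#' @export
evaluate_cascade <- function(cascade, trajs) {
  truth <- factor(vapply(trajs, `[[`, character(1), "label"),
                  levels = TRACK_LABELS)
  pred <- cascade_predict(cascade, trajs)
  X <- extract_feature_matrix(trajs, edges = cascade$edges)$X
  m1 <- cm_metrics(confusion(as.integer(truth != "aeroplane"),
                             stage_predict(cascade$stage1, X)))
  birds <- truth != "aeroplane"
  m2 <- cm_metrics(confusion(as.integer(truth[birds] == "big_raptor"),
                             stage_predict(cascade$stage2,
                                           X[birds, , drop = FALSE])))
  list(table = table(truth = truth, pred = pred),
       accuracy = mean(truth == pred), stage1 = m1, stage2 = m2)
}
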