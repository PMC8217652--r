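## Classification stage: SMOTE oversampling, random forest / k-NN / bagging
## learners, participant-aware train/test split, leave-one-person-out
## cross-validation, and WEKA-style weighted metrics.

#' Build a frame-level dataset from a cohort
#'
#' Stacks the per-frame fear feature vectors of all clips, with a class
#' label (`lie`/`truth`) and the participant id of every frame.
#'
#' @param clips list of `clip_ts` objects.
#' @param au_set AU ids forming the feature vector.
#' @return Object of class `frame_dataset`: `features` (frames x AUs
#'   matrix), `labels` (factor `lie`/`truth`), `groups` (participant ids).
#' @export
frame_dataset <- function(clips, au_set = FEAR_AUS_7) {
  feats <- lapply(clips, fear_matrix, au_set = au_set)
  features <- do.call(rbind, feats)
  labels <- factor(rep(vapply(clips, `[[`, "", "condition"),
                       vapply(feats, nrow, 0L)), levels = c("lie", "truth"))
  groups <- rep(vapply(clips, `[[`, "", "participant_id"),
                vapply(feats, nrow, 0L))
  new_frame_dataset(features, labels, groups)
}

new_frame_dataset <- function(features, labels, groups) {
  stopifnot(nrow(features) == length(labels), length(labels) == length(groups))
  structure(list(features = features, labels = labels,
                 groups = as.character(groups)), class = "frame_dataset")
}

#' @export
print.frame_dataset <- function(x, ...) {
  cat(sprintf("<frame_dataset> %d frames x %d features, %d participants (%s)\n",
              nrow(x$features), ncol(x$features), length(unique(x$groups)),
              paste(sprintf("%s: %d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

subset_dataset <- function(ds, idx) {
  new_frame_dataset(ds$features[idx, , drop = FALSE],
                    factor(ds$labels[idx], levels = levels(ds$labels)),
                    ds$groups[idx])
}

#' SMOTE minority oversampling
#'
#' Upsamples the minority class to the majority count. Each synthetic row
#' is a convex combination of a minority row and one of its k nearest
#' minority neighbours (Euclidean metric): `parent + u * (neighbour -
#' parent)` with `u ~ U(0, 1)`. Majority rows are untouched; synthetic rows
#' inherit their parent's participant id.
#'
#' @param dataset a [frame_dataset()].
#' @param k number of minority nearest neighbours (default 5).
#' @param seed integer seed.
#' @return A balanced `frame_dataset` (original rows first).
#' @export
smote_oversample <- function(dataset, k = 5, seed = 1L) {
  stopifnot(inherits(dataset, "frame_dataset"))
  counts <- table(dataset$labels)
  if (length(counts) < 2L || min(counts) == max(counts)) return(dataset)
  minority <- names(counts)[which.min(counts)]
  n_min <- min(counts)
  if (n_min <= k)
    fl_stop("TooFewMinority", "minority class has %d <= k = %d instances",
            n_min, k)
  n_new <- max(counts) - n_min
  idx_min <- which(dataset$labels == minority)
  Xm <- dataset$features[idx_min, , drop = FALSE]
  nn <- FNN::get.knn(Xm, k = k)$nn.index
  set.seed(seed)
  parent <- sample.int(n_min, n_new, replace = TRUE)
  nb <- nn[cbind(parent, sample.int(k, n_new, replace = TRUE))]
  u <- runif(n_new)
  synth <- Xm[parent, , drop = FALSE] +
    u * (Xm[nb, , drop = FALSE] - Xm[parent, , drop = FALSE])
  new_frame_dataset(rbind(dataset$features, synth),
                    factor(c(as.character(dataset$labels),
                             rep(minority, n_new)),
                           levels = levels(dataset$labels)),
                    c(dataset$groups, dataset$groups[idx_min][parent]))
}

## ---- classifiers ---------------------------------------------------------

#' Fit a deception classifier
#'
#' Three learners mirroring the cited tool's defaults: `random_forest`
#' (100 CART trees, mtry = floor(log2(p) + 1)), `knn` (k = 1, the IBk
#' default), `bagging` (10 bagged full CART trees).
#'
#' @param dataset a [frame_dataset()] with both classes present.
#' @param classifier `"random_forest"`, `"knn"` or `"bagging"`.
#' @param seed integer seed.
#' @param n_trees override the ensemble size.
#' @param knn_k neighbours for the k-NN learner.
#' @param max_depth CART depth cap.
#' @return Object of class `fl_model`.
#' @export
fit_classifier <- function(dataset, classifier = c("random_forest", "knn",
                                                   "bagging"),
                           seed = 1L, n_trees = NULL, knn_k = 1,
                           max_depth = 25) {
  classifier <- match.arg(classifier)
  X <- dataset$features
  y <- dataset$labels
  if (nlevels(droplevels(y)) < 2L)
    fl_stop("DegenerateGroups", "training data holds a single class")
  y01 <- as.integer(y == levels(y)[1L])  # class 1 = "lie"
  set.seed(seed)
  model <- switch(classifier,
    knn = list(train = X, y = y, k = knn_k),
    random_forest = ,
    bagging = {
      p <- ncol(X)
      mtry <- if (classifier == "random_forest") max(1L, floor(log2(p) + 1))
              else p
      nt <- if (!is.null(n_trees)) n_trees
            else if (classifier == "random_forest") 100L else 10L
      n <- nrow(X)
      lapply(seq_len(nt), function(b) {
        rows <- sample.int(n, n, replace = TRUE)
        cart_fit(X, y01, rows, mtry, max_depth, 2L)
      })
    })
  structure(list(type = classifier, model = model,
                 levels = levels(y)), class = "fl_model")
}

#' Predict classes and class scores
#'
#' @param object an `fl_model`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return List: `class` (factor) and `scores` (matrix of class
#'   probabilities, one column per class).
#' @export
predict.fl_model <- function(object, newdata, ...) {
  lv <- object$levels
  p_lie <- switch(object$type,
    knn = {
      pr <- FNN::knn(object$model$train, newdata, object$model$y,
                     k = object$model$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == lv[1L], win, 1 - win)
    },
    rowMeans(vapply(object$model, function(tree)
      cart_predict(tree, newdata), numeric(nrow(newdata)))))
  scores <- cbind(p_lie, 1 - p_lie)
  colnames(scores) <- lv
  cls <- factor(ifelse(p_lie >= 0.5, lv[1L], lv[2L]), levels = lv)
  list(class = cls, scores = scores)
}

## ---- metrics -------------------------------------------------------------

## average precision (area under the precision-recall curve)
average_precision <- function(truth, score) {
  P <- sum(truth)
  if (P == 0L) return(0)
  ord <- order(score, decreasing = TRUE)
  hit <- truth[ord]
  prec_at <- cumsum(hit) / seq_along(hit)
  sum(prec_at[hit == 1L]) / P
}

#' WEKA-style classification report
#'
#' Per-class TP rate, FP rate, precision, recall, F-measure and PRC area
#' (average precision), combined by class-frequency weighting; overall
#' accuracy (%) and Cohen's kappa. Undefined ratios (zero denominators)
#' contribute 0.
#'
#' @param y_true,y_pred factors over the same levels.
#' @param y_scores matrix of class scores (columns named by level), used
#'   for the PRC area; omit to skip it (reported as `NA`).
#' @return One-row data.frame of class `classifier_report`.
#' @export
classification_metrics <- function(y_true, y_pred, y_scores = NULL) {
  if (length(y_true) != length(y_pred))
    fl_stop("LengthMismatch", "y_true and y_pred differ in length")
  lv <- levels(y_true)
  y_pred <- factor(y_pred, levels = lv)
  n <- length(y_true)
  wt <- as.numeric(table(y_true)[lv]) / n
  per <- lapply(lv, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    tn <- n - tp - fn - fp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    data.frame(tp_rate = rec,
               fp_rate = if (fp + tn > 0) fp / (fp + tn) else 0,
               precision = prec, recall = rec,
               f_measure = if (prec + rec > 0)
                 2 * prec * rec / (prec + rec) else 0,
               prc_area = if (is.null(y_scores)) NA_real_
                          else average_precision(as.integer(y_true == cl),
                                                 y_scores[, cl]))
  })
  per <- do.call(rbind, per)
  w <- function(col) sum(wt * per[[col]])
  po <- mean(y_true == y_pred)
  pe <- sum((table(y_true)[lv] / n) * (table(y_pred)[lv] / n))
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0
  structure(data.frame(accuracy = 100 * po, tp_rate = w("tp_rate"),
                       fp_rate = w("fp_rate"), precision = w("precision"),
                       recall = w("recall"), f_measure = w("f_measure"),
                       prc_area = if (is.null(y_scores)) NA_real_
                                  else w("prc_area"),
                       kappa = kappa),
            class = c("classifier_report", "data.frame"))
}

## ---- evaluation protocols ------------------------------------------------

#' Train on some participants, evaluate on the rest
#'
#' Fits a classifier on the frames of `train_participants` (optionally
#' SMOTE-balanced) and evaluates on the untouched frames of the remaining
#' participants, as in a 12-of-16 train / 4-of-16 test design.
#'
#' @param dataset a [frame_dataset()].
#' @param train_participants participant ids used for training.
#' @param classifier learner name (see [fit_classifier()]).
#' @param seed integer seed.
#' @param smote apply [smote_oversample()] to the training frames.
#' @param k SMOTE neighbour count.
#' @param ... passed to [fit_classifier()].
#' @return A `classifier_report` with attribute `n_test`.
#' @export
train_eval_split <- function(dataset, train_participants, classifier,
                             seed = 1L, smote = TRUE, k = 5, ...) {
  all_ids <- unique(dataset$groups)
  test_participants <- setdiff(all_ids, train_participants)
  if (!length(test_participants))
    fl_stop("ParticipantOverlap", "no participants left for testing")
  if (any(!train_participants %in% all_ids))
    fl_stop("ParticipantOverlap", "unknown training participant id")
  tr <- dataset$groups %in% train_participants
  train <- subset_dataset(dataset, which(tr))
  test <- subset_dataset(dataset, which(!tr))
  if (smote) train <- smote_oversample(train, k = k, seed = seed)
  model <- fit_classifier(train, classifier, seed = seed, ...)
  pred <- predict(model, test$features)
  rep <- classification_metrics(test$labels, pred$class, pred$scores)
  attr(rep, "n_test") <- nrow(test$features)
  rep
}

#' Leave-one-person-out cross-validation
#'
#' One fold per participant: that participant's frames form the test set,
#' everyone else's the training set, so no person contributes to both
#' sides of a fold.
#'
#' @inheritParams train_eval_split
#' @return List: `per_fold` (data.frame `participant`, `n_frames`,
#'   `accuracy`) and `mean_accuracy`.
#' @export
leave_one_person_out <- function(dataset, classifier = "random_forest",
                                 seed = 1L, smote = TRUE, k = 5, ...) {
  ids <- unique(dataset$groups)
  if (length(ids) < 2L) fl_stop("SingleParticipant", "need >= 2 participants")
  folds <- lapply(seq_along(ids), function(i) {
    te <- dataset$groups == ids[i]
    train <- subset_dataset(dataset, which(!te))
    test <- subset_dataset(dataset, which(te))
    if (smote) train <- smote_oversample(train, k = k, seed = seed + i)
    model <- fit_classifier(train, classifier, seed = seed + i, ...)
    pred <- predict(model, test$features)
    data.frame(participant = ids[i], n_frames = nrow(test$features),
               accuracy = 100 * mean(pred$class == test$labels),
               stringsAsFactors = FALSE)
  })
  per_fold <- do.call(rbind, folds)
  list(per_fold = per_fold, mean_accuracy = mean(per_fold$accuracy))
}

#' Frame-level k-fold cross-validation
#'
#' The protocol used when building the model on the training pool: frames
#' are shuffled into `folds` folds regardless of participant. In
#' `mode = "paper"` SMOTE is applied to the whole pool before splitting
#' (faithful to the original analysis, but lets resampled minority frames
#' straddle folds); `mode = "leak_safe"` applies SMOTE inside each
#' training fold only.
#'
#' @inheritParams train_eval_split
#' @param folds number of folds (default 10).
#' @param mode `"paper"` or `"leak_safe"`.
#' @return A `classifier_report` computed on the pooled out-of-fold
#'   predictions.
#' @export
frame_cv <- function(dataset, classifier, folds = 10, seed = 1L,
                     mode = c("paper", "leak_safe"), k = 5, ...) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (mode == "paper") dataset <- smote_oversample(dataset, k = k, seed = seed)
  n <- nrow(dataset$features)
  fold_of <- sample(rep(seq_len(folds), length.out = n))
  pred <- factor(rep(levels(dataset$labels)[1], n),
                 levels = levels(dataset$labels))
  scores <- matrix(NA_real_, n, 2,
                   dimnames = list(NULL, levels(dataset$labels)))
  for (f in seq_len(folds)) {
    te <- fold_of == f
    train <- subset_dataset(dataset, which(!te))
    if (mode == "leak_safe")
      train <- smote_oversample(train, k = k, seed = seed + f)
    model <- fit_classifier(train, classifier, seed = seed + f, ...)
    pr <- predict(model, dataset$features[te, , drop = FALSE])
    pred[te] <- pr$class
    scores[te, ] <- pr$scores
  }
  classification_metrics(dataset$labels, pred, scores)
}
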