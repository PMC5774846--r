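# Learners: KNN regression over barcode-space distances, tree ensembles
# (gradient boosting via xgboost, random forest and extremely randomized
# trees via ranger) with the registered default hyperparameters, and
# consensus combination.

#' Model configuration
#'
#' Registered defaults reproduce the reference settings: regression GBT
#' (20000 estimators, depth 8, learning rate 0.005, subsample 0.7,
#' square-root feature fraction), screening GBT (2000 estimators, subsample
#' 0.5, learning rate 0.01, positive:negative class weight 100:1,
#' square-root feature fraction), screening RF/ET (2000 trees, balanced
#' class weights) and KNN with k = 3.
#'
#' @param family `"gbt"`, `"rf"`, `"et"` or `"knn"`.
#' @param task `"regression"` or `"classification"`.
#' @param params named list overriding individual hyperparameters
#'   (`n_estimators`, `max_depth`, `learning_rate`, `subsample`,
#'   `class_weight_ratio`, `k`, ...).
#' @param seed integer seed for the stochastic learners.
#' @return object of class `ModelConfig`.
#' @export
model_config <- function(family = c("gbt", "rf", "et", "knn"),
                         task = c("regression", "classification"),
                         params = list(), seed = 1L) {
  family <- match.arg(family)
  task <- match.arg(task)
  defaults <- switch(family,
    gbt = if (task == "regression")
      list(n_estimators = 20000, max_depth = 8, learning_rate = 0.005,
           subsample = 0.7, max_features = "sqrt")
    else
      list(n_estimators = 2000, max_depth = 3, learning_rate = 0.01,
           subsample = 0.5, max_features = "sqrt",
           class_weight_ratio = 100),
    rf = list(n_estimators = 2000, class_weight = "balanced"),
    et = list(n_estimators = 2000, class_weight = "balanced"),
    knn = list(k = 3))
  defaults[names(params)] <- params
  structure(list(family = family, task = task, params = defaults,
                 seed = as.integer(seed)), class = "ModelConfig")
}

#' K-nearest-neighbour prediction over a precomputed distance matrix
#'
#' Predicts each test case as the unweighted mean of the targets of its k
#' nearest training cases (ascending distance, ties broken by stable
#' training order).  With `loo = TRUE` the matrix is square
#' (train x train) and each case's own column is excluded.
#'
#' @param distances matrix, rows = test cases, columns = training cases.
#' @param train_values numeric targets, one per training case.
#' @param k number of neighbours (default 3).
#' @param loo leave-one-out mode.
#' @return numeric predictions, one per row.
#' @export
knn_predict <- function(distances, train_values, k = 3, loo = FALSE) {
  distances <- as.matrix(distances)
  if (k < 1) stop("k must be at least 1")
  n_train <- ncol(distances)
  if (loo && nrow(distances) != n_train)
    stop("leave-one-out mode needs a square distance matrix")
  if (k > n_train - loo) stop("k exceeds the training-set size")
  vapply(seq_len(nrow(distances)), function(i) {
    d <- distances[i, ]
    cand <- seq_len(n_train)
    if (loo) cand <- cand[-i]
    ord <- cand[order(d[cand])]         # order() is stable: ties by index
    mean(train_values[ord[seq_len(k)]])
  }, numeric(1))
}

#' Fit a tree ensemble and predict
#'
#' Dispatches on the config family: gradient boosting through
#' \pkg{xgboost}, random forest and extremely randomized trees through
#' \pkg{ranger}.  Classification returns positive-class probabilities.
#' Single-threaded with a fixed seed, so identical inputs give identical
#' predictions.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y targets: numeric (regression) or 0/1 (classification).
#' @param cfg a [model_config()].
#' @param newx optional matrix to predict on (defaults to `x`).
#' @return list with `model`, `predictions` (on `newx`) and `predict`
#'   (closure for later matrices).
#' @export
fit_predict_trees <- function(x, y, cfg, newx = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite feature values")
  if (nrow(x) != length(y)) stop("feature rows and targets misaligned")
  if (is.null(newx)) newx <- x
  p <- cfg$params
  classify <- cfg$task == "classification"
  set.seed(cfg$seed)
  if (cfg$family == "gbt") {
    colsample <- if (identical(p$max_features, "sqrt"))
      max(1e-3, min(1, sqrt(ncol(x)) / ncol(x))) else 1
    xp <- list(objective = if (classify) "binary:logistic" else
                 "reg:squarederror",
               max_depth = p$max_depth, eta = p$learning_rate,
               subsample = p$subsample %||% 1,
               colsample_bytree = colsample, nthread = 1)
    if (classify && !is.null(p$class_weight_ratio))
      xp$scale_pos_weight <- p$class_weight_ratio
    dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y))
    model <- xgboost::xgb.train(params = xp, data = dtrain,
                                nrounds = p$n_estimators, verbose = 0)
    pred_fun <- function(m) predict(model, as.matrix(m))
  } else if (cfg$family %in% c("rf", "et")) {
    df <- as.data.frame(x)
    names(df) <- paste0("f", seq_len(ncol(df)))
    if (classify) {
      df$.y <- factor(y, levels = c(0, 1))
      cw <- NULL
      if (identical(p$class_weight, "balanced")) {
        tab <- table(df$.y)
        cw <- as.numeric(sum(tab) / (2 * pmax(tab, 1)))
      }
      model <- ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = p$n_estimators, probability = TRUE,
        splitrule = if (cfg$family == "et") "extratrees" else "gini",
        class.weights = cw, seed = cfg$seed, num.threads = 1)
      pred_fun <- function(m) {
        nd <- as.data.frame(as.matrix(m))
        names(nd) <- paste0("f", seq_len(ncol(nd)))
        predict(model, data = nd, num.threads = 1)$predictions[, "1"]
      }
    } else {
      df$.y <- as.numeric(y)
      model <- ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = p$n_estimators,
        splitrule = if (cfg$family == "et") "extratrees" else "variance",
        seed = cfg$seed, num.threads = 1)
      pred_fun <- function(m) {
        nd <- as.data.frame(as.matrix(m))
        names(nd) <- paste0("f", seq_len(ncol(nd)))
        predict(model, data = nd, num.threads = 1)$predictions
      }
    }
  } else stop("fit_predict_trees handles gbt, rf and et families")
  list(model = model, predictions = pred_fun(newx), predict = pred_fun)
}

#' Average class probabilities over voting classifiers
#'
#' @param probs list of numeric probability vectors (equal length), one per
#'   trained voter.
#' @return arithmetic mean vector.
#' @export
vote_classifiers <- function(probs) {
  if (length(probs) < 1) stop("need at least one voter")
  len <- unique(vapply(probs, length, integer(1)))
  if (length(len) != 1) stop("voter outputs have mismatched lengths")
  Reduce(`+`, probs) / length(probs)
}

#' Element-wise consensus average of prediction vectors
#'
#' @param predictions list of equal-length numeric vectors.
#' @return mean vector.
#' @export
consensus_average <- function(predictions) {
  if (length(predictions) < 1) stop("need at least one prediction vector")
  len <- unique(vapply(predictions, length, integer(1)))
  if (length(len) != 1) stop("prediction vectors have mismatched lengths")
  Reduce(`+`, predictions) / length(predictions)
}

#' Train the screening voter ensemble and predict probabilities
#'
#' Trains the gradient-boosting, random-forest and extra-trees classifiers
#' with the registered screening defaults and averages their positive-class
#' probabilities.
#'
#' @param x,y training features and 0/1 labels.
#' @param newx matrix to score.
#' @param seed integer seed.
#' @param n_estimators tree count override for all three voters (the
#'   registered default is 2000).
#' @return numeric vector of averaged probabilities for `newx`.
#' @export
screen_voters_predict <- function(x, y, newx, seed = 1,
                                  n_estimators = NULL) {
  ov <- if (is.null(n_estimators)) list() else
    list(n_estimators = n_estimators)
  probs <- lapply(c("gbt", "rf", "et"), function(fam) {
    cfg <- model_config(fam, "classification", params = ov, seed = seed)
    fit_predict_trees(x, y, cfg, newx)$predictions
  })
  vote_classifiers(probs)
}
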