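#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the balanced
#' binary-classification metric of choice when one class is rare: it ranges
#' over \[-1, 1\], with +1 a perfect prediction and 0 an average random one.
#' By the usual convention the value is 0 whenever a factor under the root is
#' 0.
#'
#' @param tp,tn,fp,fn confusion counts; alternatively pass a single named
#'   vector/list with elements `TP`, `TN`, `FP`, `FN` as `tp`.
#' @return numeric in \[-1, 1\].
#' @examples
#' mcc(3, 4, 1, 2)  # 10 / sqrt(600)
#' @export
mcc <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(tn)) {
    cc <- unlist(tp)
    tp <- cc[["TP"]]; tn <- cc[["TN"]]; fp <- cc[["FP"]]; fn <- cc[["FN"]]
  }
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

confusion_counts <- function(y, prob, threshold) {
  pred <- as.integer(prob >= threshold)
  c(TP = sum(pred == 1 & y == 1), TN = sum(pred == 0 & y == 0),
    FP = sum(pred == 1 & y == 0), FN = sum(pred == 0 & y == 1))
}

safe_auc <- function(y, prob) {
  if (length(unique(y)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = prob,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

classification_metrics <- function(y, prob, threshold) {
  cc <- confusion_counts(y, prob, threshold)
  prec <- if (cc[["TP"]] + cc[["FP"]] == 0) 0 else
    cc[["TP"]] / (cc[["TP"]] + cc[["FP"]])
  rec <- if (cc[["TP"]] + cc[["FN"]] == 0) 0 else
    cc[["TP"]] / (cc[["TP"]] + cc[["FN"]])
  c(mcc = mcc(cc), precision = prec, recall = rec, auc = safe_auc(y, prob))
}

#' Specify a classification model
#'
#' Bundles the estimator kind, its hyperparameters, the feature transform and
#' the decision threshold. The default pairing follows standard practice:
#' standardization for the RBF-kernel SVM (kernel distances are
#' scale-sensitive), no transform for tree ensembles.
#'
#' @param estimator `"rbf_svm"` (via \pkg{e1071}), `"xgboost"` or
#'   `"random_forest"` (via the suggested \pkg{xgboost} / \pkg{ranger}).
#' @param C,gamma RBF-SVM cost and kernel width (both > 0); `gamma = NULL`
#'   uses `1 / n_features`.
#' @param transform feature transform method, see [fit_transform()]; `NULL`
#'   picks the estimator's default.
#' @param threshold decision threshold on the predicted positive-class
#'   probability, in (0, 1).
#' @param seed integer seed used when fitting (probability calibration and
#'   tree growing are stochastic).
#' @param ... extra estimator arguments (e.g. `nrounds`, `max_depth` for
#'   xgboost; `num.trees` for ranger).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(estimator = c("rbf_svm", "xgboost", "random_forest"),
                       C = 1, gamma = NULL, transform = NULL,
                       threshold = 0.5, seed = 1L, ...) {
  estimator <- match.arg(estimator)
  if (!is.numeric(C) || C <= 0) stop("C must be > 0", call. = FALSE)
  if (!is.null(gamma) && (!is.numeric(gamma) || gamma <= 0)) {
    stop("gamma must be > 0", call. = FALSE)
  }
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)", call. = FALSE)
  }
  if (is.null(transform)) {
    transform <- if (estimator == "rbf_svm") "standardize" else "none"
  }
  structure(list(estimator = estimator, C = C, gamma = gamma,
                 transform = transform, threshold = threshold,
                 seed = as.integer(seed), extra = list(...)),
            class = "model_spec")
}

#' Fit a model on a training set
#'
#' Fits the spec's transform on the training features, then the estimator on
#' the transformed matrix. The returned object carries the frozen transform,
#' so [predict_prob()] can be applied to raw held-out features without
#' leakage.
#'
#' @param spec a [model_spec()].
#' @param x numeric training feature matrix (named columns).
#' @param y 0/1 labels.
#' @return list of class `pv_model`.
#' @export
train_model <- function(spec, x, y) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  ft <- fit_transform(x, spec$transform)
  set.seed(spec$seed)
  fit <- switch(spec$estimator,
    rbf_svm = {
      gamma <- if (is.null(spec$gamma)) 1 / ncol(x) else spec$gamma
      e1071::svm(ft$x, factor(y, levels = c(0, 1)), kernel = "radial",
                 cost = spec$C, gamma = gamma, probability = TRUE,
                 scale = FALSE)
    },
    xgboost = {
      if (!requireNamespace("xgboost", quietly = TRUE)) {
        stop("estimator 'xgboost' needs the xgboost package", call. = FALSE)
      }
      args <- utils::modifyList(
        list(max_depth = 3L, eta = 0.3, nrounds = 100L), spec$extra)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = args$max_depth, eta = args$eta,
                      nthread = 1L, seed = spec$seed),
        data = xgboost::xgb.DMatrix(ft$x, label = y, nthread = 1L),
        nrounds = args$nrounds, verbose = 0)
    },
    random_forest = {
      if (!requireNamespace("ranger", quietly = TRUE)) {
        stop("estimator 'random_forest' needs the ranger package",
             call. = FALSE)
      }
      args <- utils::modifyList(list(num.trees = 500L), spec$extra)
      ranger::ranger(x = ft$x, y = factor(y, levels = c(0, 1)),
                     probability = TRUE, num.trees = args$num.trees,
                     seed = spec$seed, num.threads = 1L)
    })
  structure(list(spec = spec, transform = ft$spec, fit = fit,
                 features = colnames(x)),
            class = "pv_model")
}

#' Predicted positive-class probabilities
#'
#' @param model a `pv_model` from [train_model()].
#' @param x raw (untransformed) feature matrix with the training columns.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_prob <- function(model, x) {
  stopifnot(inherits(model, "pv_model"))
  x <- as.matrix(x)
  if (!is.null(model$features) && !is.null(colnames(x))) {
    x <- x[, model$features, drop = FALSE]
  }
  xt <- apply_transform(model$transform, x)
  switch(model$spec$estimator,
    rbf_svm = {
      p <- stats::predict(model$fit, xt, probability = TRUE)
      attr(p, "probabilities")[, "1"]
    },
    xgboost = stats::predict(model$fit,
                             xgboost::xgb.DMatrix(xt, nthread = 1L)),
    random_forest = stats::predict(model$fit, data = xt)$predictions[, "1"])
}

#' Stratified train/test split
#'
#' Splits by label so that the training fraction holds within rounding in each
#' class separately.
#'
#' @param data a list with feature matrix `x` and 0/1 labels `y` (e.g. from
#'   [prepare_model_matrix()]), or a `pair_features` data frame with a
#'   `label` column.
#' @param ratio training fraction, in (0, 1).
#' @param seed integer seed; the split is deterministic given it.
#' @return list with `train` and `test`, each a list `x`, `y` (and `meta` row
#'   indices `idx` into the input).
#' @export
split_dataset <- function(data, ratio = 0.7, seed = 1L) {
  if (is.data.frame(data)) data <- prepare_model_matrix(data)
  y <- as.integer(data$y)
  if (is.null(y) || length(unique(y)) < 2) {
    stop("both classes must be present to split", call. = FALSE)
  }
  if (ratio <= 0 || ratio >= 1) {
    stop("ratio must be strictly between 0 and 1 (both sets must be ",
         "non-empty)", call. = FALSE)
  }
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in sort(unique(y))) {
    ids <- which(y == cl)
    n_tr <- round(ratio * length(ids))
    n_tr <- min(max(n_tr, 1L), length(ids) - 1L)  # keep both sets populated
    train_idx <- c(train_idx, sort(sample(ids, n_tr)))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(y), train_idx)
  list(train = list(x = data$x[train_idx, , drop = FALSE], y = y[train_idx],
                    idx = train_idx),
       test = list(x = data$x[test_idx, , drop = FALSE], y = y[test_idx],
                   idx = test_idx))
}

stratified_folds <- function(y, k, seed) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (min(table(y)) < k) {
    stop("a fold would lack positives or negatives; use a smaller k (minority",
         " class has ", min(table(y)), " samples)", call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in sort(unique(y))) {
    ids <- sample(which(y == cl))
    fold[ids] <- rep_len(seq_len(k), length(ids))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' For each fold, the transform and estimator are fitted on the other k-1
#' folds only and evaluated on the held-out fold at the spec's decision
#' threshold.
#'
#' @param spec a [model_spec()].
#' @param x,y training features and 0/1 labels.
#' @param k number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @return list with `folds` (per-fold metric data frame: mcc, precision,
#'   recall, auc), `mean` and `sd` (named numeric vectors).
#' @export
cross_validate <- function(spec, x, y, k = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  fold <- stratified_folds(y, k, seed)
  rows <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    m <- train_model(spec, x[tr, , drop = FALSE], y[tr])
    prob <- predict_prob(m, x[!tr, , drop = FALSE])
    classification_metrics(y[!tr], prob, spec$threshold)
  })
  folds <- as.data.frame(do.call(rbind, rows))
  list(folds = folds,
       mean = colMeans(folds, na.rm = TRUE),
       sd = apply(folds, 2, stats::sd, na.rm = TRUE))
}

#' Exhaustive feature selection
#'
#' Brute-force wrapper selection: every feature subset of each requested size
#' is scored by stratified cross-validated mean MCC, and the best subset wins.
#' Ties are broken in favor of the smaller subset, then by alphabetical
#' feature order, so the result is deterministic. The total number of subsets
#' is bounded by `budget`; exceeding it is an error rather than a silent
#' truncation.
#'
#' @param x,y training features and 0/1 labels.
#' @param spec a [model_spec()] used to score each subset.
#' @param subset_sizes integer vector of subset sizes to enumerate (all >= 1).
#' @param k,seed cross-validation folds and seed (shared across subsets, so
#'   every subset sees identical folds).
#' @param features candidate feature names (default: all columns of `x`).
#' @param budget maximum number of subsets to evaluate.
#' @return list with `best` (character vector of selected features), `score`
#'   (its cv mean MCC) and `results` (one row per subset: features, size,
#'   mean_mcc, sd_mcc).
#' @export
efs <- function(x, y, spec, subset_sizes = 1:2, k = 5L, seed = 1L,
                features = colnames(x), budget = 10000L) {
  x <- as.matrix(x)
  subset_sizes <- unique(as.integer(subset_sizes))
  if (any(subset_sizes < 1)) {
    stop("subset sizes must be >= 1 (the empty subset is not a model)",
         call. = FALSE)
  }
  if (any(subset_sizes > length(features))) {
    stop("subset size exceeds the number of candidate features", call. = FALSE)
  }
  n_subsets <- sum(choose(length(features), subset_sizes))
  if (n_subsets > budget) {
    stop("exhaustive search over ", n_subsets, " subsets exceeds the budget ",
         "of ", budget, "; reduce subset_sizes or the candidate features",
         call. = FALSE)
  }
  subsets <- unlist(lapply(sort(subset_sizes), function(s) {
    utils::combn(sort(features), s, simplify = FALSE)
  }), recursive = FALSE)
  scores <- vapply(subsets, function(fs) {
    cv <- cross_validate(spec, x[, fs, drop = FALSE], y, k = k, seed = seed)
    c(cv$mean[["mcc"]], cv$sd[["mcc"]])
  }, c(0, 0))
  results <- data.frame(
    features = vapply(subsets, paste, "", collapse = "+"),
    size = lengths(subsets), mean_mcc = scores[1, ], sd_mcc = scores[2, ],
    stringsAsFactors = FALSE)
  # best mean MCC; ties -> smaller subset, then lexicographic feature order
  ord <- order(-results$mean_mcc, results$size, results$features)
  best <- subsets[[ord[1L]]]
  list(best = best, score = results$mean_mcc[ord[1L]], results = results)
}

#' Hyperparameter search for the RBF-SVM
#'
#' Seeded random search over the log-uniform box `space`, scoring each
#' candidate by stratified cross-validated mean MCC. The default box is
#' C in \[0.01, 3000\] and gamma in \[0.001, 1000\].
#'
#' @param x,y training features and 0/1 labels.
#' @param spec base [model_spec()] (estimator, transform, threshold are kept).
#' @param space named list of `c(min, max)` ranges for `C` and `gamma`.
#' @param iterations number of sampled candidates (>= 1).
#' @param k,seed cross-validation folds and the search seed.
#' @return list with `spec` (best candidate as a `model_spec`), `score` (its
#'   cv mean MCC) and `results` (per-candidate data frame).
#' @export
tune_hyperparams <- function(x, y, spec,
                             space = list(C = c(0.01, 3000),
                                          gamma = c(0.001, 1000)),
                             iterations = 50L, k = 5L, seed = 1L) {
  if (length(space) == 0) stop("empty search space", call. = FALSE)
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  for (nm in names(space)) {
    rg <- space[[nm]]
    if (length(rg) != 2 || any(rg <= 0) || rg[1] > rg[2]) {
      stop("search range for '", nm, "' must be 0 < min <= max", call. = FALSE)
    }
  }
  set.seed(seed)
  draw <- function(rg, n) exp(stats::runif(n, log(rg[1]), log(rg[2])))
  cand <- data.frame(
    C = if ("C" %in% names(space)) draw(space$C, iterations) else spec$C,
    gamma = if ("gamma" %in% names(space)) draw(space$gamma, iterations)
            else spec$gamma %||% 1 / ncol(x))
  score <- numeric(iterations)
  for (i in seq_len(iterations)) {
    si <- model_spec(spec$estimator, C = cand$C[i], gamma = cand$gamma[i],
                     transform = spec$transform, threshold = spec$threshold,
                     seed = spec$seed)
    score[i] <- cross_validate(si, x, y, k = k, seed = seed)$mean[["mcc"]]
  }
  best <- which.max(score)
  list(spec = model_spec(spec$estimator, C = cand$C[best],
                         gamma = cand$gamma[best], transform = spec$transform,
                         threshold = spec$threshold, seed = spec$seed),
       score = score[best],
       results = cbind(cand, mean_mcc = score))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation feature importance
#'
#' A feature matters if shuffling its values degrades the model: importance
#' is the mean drop in the metric (MCC at the model's threshold, or AUC) over
#' `n_repeats` seeded permutations of that column, all other columns intact.
#'
#' @param model a fitted `pv_model`.
#' @param x,y evaluation features and labels.
#' @param metric `"mcc"` or `"auc"`.
#' @param n_repeats permutations per feature (>= 1).
#' @param seed permutation seed.
#' @return data frame: `feature`, `importance` (mean metric drop), `sd`.
#' @export
permutation_importance <- function(model, x, y, metric = c("mcc", "auc"),
                                   n_repeats = 5L, seed = 1L) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  score <- function(xx) {
    m <- classification_metrics(y, predict_prob(model, xx),
                                model$spec$threshold)
    m[[metric]]
  }
  base <- score(x)
  set.seed(seed)
  feats <- model$features %||% colnames(x)
  rows <- lapply(feats, function(f) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[, f] <- sample(xp[, f])
      base - score(xp)
    }, 0)
    c(importance = mean(drops), sd = stats::sd(drops))
  })
  out <- data.frame(feature = feats, do.call(rbind, rows),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), ]
}

#' Sweep the decision threshold
#'
#' Re-scores fixed predicted probabilities at each threshold. With imbalanced
#' cohorts the positive-class probabilities of true negatives concentrate near
#' 0, so lowering the threshold (the default grid pairs the conventional 0.5
#' with 0.1) can trade precision for recall without refitting.
#'
#' @param model a fitted `pv_model`.
#' @param x,y evaluation features and labels.
#' @param thresholds numeric vector of thresholds, each in (0, 1).
#' @return data frame: threshold, TP, TN, FP, FN, mcc, precision, recall.
#' @export
threshold_sweep <- function(model, x, y, thresholds = c(0.1, 0.5)) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  }
  prob <- predict_prob(model, as.matrix(x))
  y <- as.integer(y)
  rows <- lapply(thresholds, function(th) {
    cc <- confusion_counts(y, prob, th)
    m <- classification_metrics(y, prob, th)
    data.frame(threshold = th, TP = cc[["TP"]], TN = cc[["TN"]],
               FP = cc[["FP"]], FN = cc[["FN"]], mcc = m[["mcc"]],
               precision = m[["precision"]], recall = m[["recall"]])
  })
  do.call(rbind, rows)
}

#' Evaluate a fitted model on held-out data
#'
#' @param model a fitted `pv_model`.
#' @param x,y held-out features and labels.
#' @return list with `metrics` (mcc, precision, recall, auc at the model's
#'   threshold) and `confusion` (TP/TN/FP/FN).
#' @export
evaluate_model <- function(model, x, y) {
  prob <- predict_prob(model, as.matrix(x))
  y <- as.integer(y)
  list(metrics = classification_metrics(y, prob, model$spec$threshold),
       confusion = confusion_counts(y, prob, model$spec$threshold))
}
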