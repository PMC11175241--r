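#' Default hyperparameters for the six classifier families
#'
#' The tuned values used by the benchmark grid search: linear SVM
#' (C = 0.05, probability estimates on), LDA (SVD solver, no shrinkage),
#' Gaussian naive Bayes, Gaussian-process classifier with an RBF kernel of
#' unit length scale, kNN (k = 5, Euclidean, uniform weights) and random
#' forest (50 trees, minimum leaf size 4). Each entry is a one-point grid;
#' supply longer lists to [loocv_grid_search()] for wider searches.
#'
#' @return Named list: for each family, a list of hyperparameter lists.
#' @export
default_grids <- function() {
  list(
    svm = list(list(C = 0.05)),
    lda = list(list()),
    nb = list(list()),
    gpc = list(list(length_scale = 1.0)),
    knn = list(list(k = 5)),
    rf = list(list(ntree = 50, nodesize = 4))
  )
}

ML_FAMILIES <- c("svm", "lda", "nb", "gpc", "knn", "rf")
POSITIVE_CLASS <- "amci"

fit_classifier <- function(family, X, y, params = list()) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("both classes must be present", call. = FALSE)
  fit <- switch(family,
    svm = e1071::svm(X, y, kernel = "linear", cost = params$C %||% 0.05,
                     probability = TRUE, scale = FALSE),
    lda = MASS::lda(X, grouping = y),
    nb = e1071::naiveBayes(X, y),
    gpc = {
      sigma <- 1 / (2 * (params$length_scale %||% 1.0)^2)
      kernlab::gausspr(X, y, kernel = "rbfdot", kpar = list(sigma = sigma),
                       type = "classification", scaled = FALSE)
    },
    knn = list(train = X, cl = y, k = params$k %||% 5),
    rf = randomForest::randomForest(X, y,
                                    ntree = params$ntree %||% 50,
                                    nodesize = params$nodesize %||% 4),
    stop("unknown classifier family: ", family, call. = FALSE)
  )
  structure(list(family = family, fit = fit, levels = levels(y),
                 params = params), class = "ssvepkiosk_model")
}

# Predicted class and a continuous score for the positive (aMCI) class.
predict_classifier <- function(model, X) {
  fit <- model$fit
  pos <- POSITIVE_CLASS
  switch(model$family,
    svm = {
      pr <- predict(fit, X, probability = TRUE)
      prob <- attr(pr, "probabilities")
      list(class = pr, score = prob[, pos])
    },
    lda = {
      pr <- predict(fit, X)
      list(class = pr$class, score = pr$posterior[, pos])
    },
    nb = {
      prob <- predict(fit, X, type = "raw")
      cls <- factor(model$levels[max.col(prob)], levels = model$levels)
      list(class = cls, score = prob[, pos])
    },
    gpc = {
      prob <- kernlab::predict(fit, X, type = "probabilities")
      colnames(prob) <- fit@lev
      cls <- factor(colnames(prob)[max.col(prob)], levels = model$levels)
      list(class = cls, score = prob[, pos])
    },
    knn = {
      pr <- class::knn(fit$train, X, fit$cl, k = fit$k, prob = TRUE)
      p_win <- attr(pr, "prob")
      score <- ifelse(pr == pos, p_win, 1 - p_win)
      list(class = pr, score = score)
    },
    rf = {
      prob <- predict(fit, X, type = "prob")
      cls <- predict(fit, X)
      list(class = cls, score = prob[, pos])
    }
  )
}

#' Embedded linear-SVM feature selection
#'
#' Fits a linear SVM (L2 regularization, `C = 0.05`) on standardized
#' features and scores each feature by the absolute value of its weight in
#' the separating hyperplane. Features whose importance is strictly
#' greater than the mean importance are kept ("lower importance relative
#' to the average" is filtered out; a feature exactly at the mean is
#' dropped).
#'
#' @param X Numeric matrix of standardized features (columns named).
#' @param y Two-level factor of group labels.
#' @param C SVM regularization constant, default 0.05.
#' @return List with `selected` (character), `importance` (named numeric).
#' @export
embedded_select <- function(X, y, C = 0.05) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("both classes must be present", call. = FALSE)
  if (ncol(X) < 2) stop("need at least two features", call. = FALSE)
  fit <- e1071::svm(X, y, kernel = "linear", cost = C, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  importance <- abs(w)[colnames(X)]
  names(importance) <- colnames(X)
  list(selected = names(importance)[importance > mean(importance)],
       importance = importance)
}

#' Stratified train/test split
#'
#' Splits a feature table into train and test sets preserving class
#' proportions: a 24 + 24 cohort at the default 0.7 fraction yields
#' 17 + 17 training and 7 + 7 test subjects.
#'
#' @param table Feature table with a `group` column.
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed Integer seed.
#' @return List with data frames `train` and `test`.
#' @export
stratified_split <- function(table, train_fraction = 0.7, seed) {
  stopifnot("group" %in% names(table))
  groups <- split(seq_len(nrow(table)), table$group)
  if (any(lengths(groups) < 2)) {
    stop("each class needs at least 2 subjects to stratify", call. = FALSE)
  }
  with_seed(seed, {
    train_idx <- unlist(lapply(groups, function(ix) {
      sample(ix, round(train_fraction * length(ix)))
    }))
    list(train = table[sort(train_idx), , drop = FALSE],
         test = table[sort(setdiff(seq_len(nrow(table)), train_idx)), ,
                      drop = FALSE])
  })
}

#' Leave-one-out cross-validated grid search
#'
#' For each hyperparameter point, computes the leave-one-out
#' cross-validation accuracy over the training set and returns the best
#' point (ties broken toward the earlier grid entry).
#'
#' @param X Training feature matrix (standardized).
#' @param y Training labels (two-level factor).
#' @param family One of `"svm"`, `"lda"`, `"nb"`, `"gpc"`, `"knn"`,
#'   `"rf"`.
#' @param grid List of hyperparameter lists; defaults to the family's
#'   entry in [default_grids()].
#' @return List with `params` (best point), `cv_accuracy` (fraction) and
#'   `accuracies` (per grid point).
#' @export
loocv_grid_search <- function(X, y, family, grid = NULL) {
  if (is.null(grid)) grid <- default_grids()[[family]]
  if (length(grid) == 0) stop("empty grid", call. = FALSE)
  if (nrow(X) < 2) stop("training set too small", call. = FALSE)
  y <- droplevels(factor(y))
  acc <- vapply(grid, function(params) {
    correct <- vapply(seq_len(nrow(X)), function(i) {
      m <- fit_classifier(family, X[-i, , drop = FALSE], y[-i], params)
      pr <- predict_classifier(m, X[i, , drop = FALSE])
      as.character(pr$class) == as.character(y[i])
    }, logical(1))
    mean(correct)
  }, numeric(1))
  best <- which.max(acc)
  list(params = grid[[best]], cv_accuracy = acc[best], accuracies = acc)
}

#' Held-out evaluation metrics
#'
#' Confusion counts and the derived metrics, with aMCI as the positive
#' class: accuracy = (TP + TN) / (TP + TN + FP + FN), sensitivity =
#' TP / (TP + FN), specificity = TN / (TN + FP), all in percent, and AUC
#' (percent) as the trapezoidal area under the ROC of the model's
#' continuous scores (ties handled by rank averaging). If the test set
#' lacks a class the undefined metrics are `NA` and `flagged` is `TRUE`.
#'
#' @param model Fitted classifier from an internal fit or via
#'   [loocv_grid_search()] + refit.
#' @param X Test feature matrix (standardized with training statistics).
#' @param y True test labels.
#' @return One-row data frame: `TP`, `TN`, `FP`, `FN`, `accuracy`,
#'   `sensitivity`, `specificity`, `auc`, `flagged`.
#' @export
evaluate <- function(model, X, y) {
  if (nrow(X) == 0) stop("empty test set", call. = FALSE)
  pr <- predict_classifier(model, X)
  truth <- factor(y, levels = model$levels)
  pos <- truth == POSITIVE_CLASS
  pred_pos <- pr$class == POSITIVE_CLASS
  TP <- sum(pos & pred_pos); FN <- sum(pos & !pred_pos)
  TN <- sum(!pos & !pred_pos); FP <- sum(!pos & pred_pos)
  sens <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_
  auc <- if (TP + FN > 0 && TN + FP > 0) {
    100 * auc_trapezoid(pr$score, pos)
  } else NA_real_
  data.frame(TP = TP, TN = TN, FP = FP, FN = FN,
             accuracy = 100 * (TP + TN) / (TP + TN + FP + FN),
             sensitivity = sens, specificity = spec, auc = auc,
             flagged = is.na(sens) || is.na(spec))
}

# Trapezoidal ROC area via the rank (Mann-Whitney) identity; average
# ranks make tied scores contribute the trapezoid's half-height.
auc_trapezoid <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  list(apply = function(M) sweep(sweep(M, 2, ctr), 2, scl, `/`))
}

feature_matrix <- function(table, features) {
  as.matrix(table[, features, drop = FALSE])
}

# Standardize on train, optionally embed-select, grid-search, refit.
# Everything is fit on the training table only.
fit_pipeline <- function(train, features, family, grid = NULL,
                         select = TRUE, C = 0.05) {
  Xtr_raw <- feature_matrix(train, features)
  std <- standardizer(Xtr_raw)
  Xtr <- std$apply(Xtr_raw)
  y <- droplevels(factor(train$group))
  sel <- NULL
  used <- features
  if (select && length(features) >= 2) {
    sel <- embedded_select(Xtr, y, C = C)
    if (length(sel$selected) > 0) used <- sel$selected
  }
  gs <- loocv_grid_search(Xtr[, used, drop = FALSE], y, family, grid)
  model <- fit_classifier(family, Xtr[, used, drop = FALSE], y, gs$params)
  list(model = model, std = std, features = used, selection = sel,
       cv_accuracy = gs$cv_accuracy)
}

#' Repeated-split benchmark of the six classifiers and three modalities
#'
#' For each of `n_repeats` seeded stratified 7:3 splits and each feature
#' condition (`vr` = behavioral features only, `eeg` = neurological
#' features only, `combined` = both): standardizes with training
#' statistics, runs embedded linear-SVM feature selection on the training
#' set, LOOCV grid search per classifier family, refits on the full
#' training set and evaluates on the held-out test set. Reports mean and
#' SD of accuracy, sensitivity, specificity and AUC over repeats plus
#' per-repeat confusion counts, selection frequencies and mean importance
#' scores.
#'
#' @param table Feature table with `group` plus feature columns.
#' @param n_repeats Number of independent splits (default 30).
#' @param seed Integer seed.
#' @param families Subset of `c("svm","lda","nb","gpc","knn","rf")`.
#' @param conditions Subset of `c("vr","eeg","combined")`.
#' @param select Run embedded selection per split (default `TRUE`); with
#'   `select = "global"` selection is done once on the full table before
#'   splitting (literal but leakage-prone).
#' @param train_fraction Training fraction (default 0.7).
#' @param grids Hyperparameter grids; see [default_grids()].
#' @return Object of class `evaluation_report`: list with `summary` (mean
#'   and SD per condition x family x metric), `per_repeat` (confusion
#'   counts and metrics), `selected` (selection frequency per feature),
#'   `importances` (mean importance per feature).
#' @export
run_benchmark <- function(table, n_repeats = 30, seed,
                          families = ML_FAMILIES,
                          conditions = c("vr", "eeg", "combined"),
                          select = TRUE, train_fraction = 0.7,
                          grids = default_grids()) {
  feats_all <- setdiff(
    names(table)[vapply(table, is.numeric, logical(1))], "subject_id")
  feats_vr <- intersect(BEHAVIORAL_FEATURES, feats_all)
  feats_eeg <- setdiff(feats_all, feats_vr)
  cond_feats <- list(vr = feats_vr, eeg = feats_eeg, combined = feats_all)

  global_sel <- NULL
  if (identical(select, "global")) {
    X <- standardizer(feature_matrix(table, feats_all))$apply(
      feature_matrix(table, feats_all))
    global_sel <- embedded_select(X, table$group)$selected
  }

  split_seeds <- with_seed(seed, sample.int(.Machine$integer.max,
                                            n_repeats))
  per_repeat <- list()
  sel_count <- structure(numeric(length(feats_all)), names = feats_all)
  imp_sum <- structure(numeric(length(feats_all)), names = feats_all)
  imp_n <- 0

  for (r in seq_len(n_repeats)) {
    sp <- stratified_split(table, train_fraction, seed = split_seeds[r])
    for (cond in conditions) {
      features <- cond_feats[[cond]]
      if (length(features) == 0) next
      if (identical(select, "global")) {
        features <- intersect(features, global_sel)
        if (length(features) == 0) features <- cond_feats[[cond]]
      }
      for (fam in families) {
        fitted <- with_seed(split_seeds[r] %% 1000000L + r, {
          fit_pipeline(sp$train, features, fam,
                       grid = grids[[fam]],
                       select = isTRUE(select))
        })
        Xte <- fitted$std$apply(feature_matrix(sp$test,
                                               cond_feats[[cond]]))
        res <- evaluate(fitted$model,
                        Xte[, fitted$features, drop = FALSE],
                        sp$test$group)
        per_repeat[[length(per_repeat) + 1L]] <-
          cbind(data.frame(condition = cond, family = fam, rep = r,
                           cv_accuracy = 100 * fitted$cv_accuracy), res)
        if (cond == "combined" && fam == families[1] &&
            !is.null(fitted$selection)) {
          sel_count[fitted$features] <- sel_count[fitted$features] + 1
          imp <- fitted$selection$importance
          imp_sum[names(imp)] <- imp_sum[names(imp)] + imp
          imp_n <- imp_n + 1
        }
      }
    }
  }
  per_repeat <- do.call(rbind, per_repeat)

  agg <- function(metric) {
    m <- aggregate(per_repeat[[metric]],
                   per_repeat[c("condition", "family")],
                   function(v) c(mean = mean(v, na.rm = TRUE),
                                 sd = sd(v, na.rm = TRUE)))
    data.frame(condition = m$condition, family = m$family,
               metric = metric, mean = m$x[, "mean"], sd = m$x[, "sd"])
  }
  summary <- do.call(rbind, lapply(c("accuracy", "sensitivity",
                                     "specificity", "auc"), agg))
  structure(
    list(summary = summary, per_repeat = per_repeat,
         selected = sel_count / max(imp_n, 1),
         importances = imp_sum / max(imp_n, 1),
         n_repeats = n_repeats, conditions = conditions,
         families = families),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$n_repeats, " repeats\n", sep = "")
  acc <- x$summary[x$summary$metric == "accuracy", ]
  print(acc[order(acc$condition, -acc$mean), ], row.names = FALSE)
  invisible(x)
}

#' Two-dimensional PCA projection of a feature subset
#'
#' First two principal-component scores of the standardized feature
#' columns, for visualizing group separation.
#'
#' @param table Feature table with a `group` column.
#' @param feature_subset Character vector of >= 2 feature columns.
#' @return Data frame `PC1`, `PC2`, `group`, with attribute
#'   `explained_variance` (fractions for the two components).
#' @export
pca_project <- function(table, feature_subset) {
  if (length(feature_subset) < 2) {
    stop("need at least two features", call. = FALSE)
  }
  X <- feature_matrix(table, feature_subset)
  if (any(apply(X, 2, sd) == 0)) {
    stop("fewer than 2 non-degenerate features", call. = FALSE)
  }
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  out <- data.frame(PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                    group = table$group)
  attr(out, "explained_variance") <-
    (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  out
}
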