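informative_table <- function(n_per_group = 24, d = 3, p_noise = 9,
                              seed = 51) {
  set.seed(seed)
  n <- 2 * n_per_group
  X <- matrix(rnorm(n * (p_noise + 1)), n)
  colnames(X) <- c("signal", paste0("noise", seq_len(p_noise)))
  grp <- factor(rep(c("hc", "amci"), each = n_per_group),
                levels = c("hc", "amci"))
  X[grp == "amci", "signal"] <- X[grp == "amci", "signal"] + d
  data.frame(subject_id = sprintf("S%02d", 1:n), group = grp, X)
}

test_that("embedded selection keeps the informative feature", {
  tab <- informative_table()
  X <- scale(as.matrix(tab[, -(1:2)]))
  sel <- embedded_select(X, tab$group)
  expect_true("signal" %in% sel$selected)
  expect_equal(which.max(sel$importance), c(signal = 1))

  # duplicated informative feature receives symmetric importance
  X2 <- cbind(X, signal_copy = X[, "signal"])
  sel2 <- embedded_select(X2, tab$group)
  expect_equal(unname(sel2$importance["signal"]),
               unname(sel2$importance["signal_copy"]), tolerance = 1e-6)

  expect_error(embedded_select(X[tab$group == "hc", ],
                               tab$group[tab$group == "hc"]),
               "both classes")
  expect_error(embedded_select(X[, 1, drop = FALSE], tab$group),
               "two features")
})

test_that("stratified split preserves class balance and partitions", {
  tab <- informative_table(24)
  sp <- stratified_split(tab, 0.7, seed = 52)
  expect_equal(nrow(sp$train), 34)
  expect_equal(nrow(sp$test), 14)
  expect_equal(as.vector(table(sp$train$group)), c(17, 17))
  expect_equal(as.vector(table(sp$test$group)), c(7, 7))
  expect_setequal(c(sp$train$subject_id, sp$test$subject_id),
                  tab$subject_id)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  expect_identical(stratified_split(tab, 0.7, seed = 53)$train$subject_id,
                   stratified_split(tab, 0.7, seed = 53)$train$subject_id)
})

test_that("LOOCV grid search scores separable data perfectly", {
  tab <- informative_table(12, d = 6, p_noise = 1)
  X <- scale(as.matrix(tab[, -(1:2)]))
  gs <- loocv_grid_search(X, tab$group, "svm")
  expect_equal(gs$cv_accuracy, 1)
  expect_equal(gs$params, list(C = 0.05))     # one-point grid returns it
  expect_error(loocv_grid_search(X, tab$group, "svm", grid = list()),
               "empty grid")
})

test_that("evaluation metrics follow the confusion-count identities", {
  # synthetic model wrapper with fixed predictions: TP=5 FN=2 TN=7 FP=0
  truth <- factor(rep(c("amci", "hc"), c(7, 7)), levels = c("hc", "amci"))
  pred <- factor(c(rep("amci", 5), rep("hc", 2), rep("hc", 7)),
                 levels = c("hc", "amci"))
  scores <- ifelse(pred == "amci", 0.9, 0.1)
  fake <- structure(list(family = "knn", levels = c("hc", "amci"),
                         fit = NULL), class = "ssvepkiosk_model")
  with_mocked_bindings(
    predict_classifier = function(model, X) list(class = pred,
                                                 score = scores),
    .package = "ssvepkiosk",
    {
      res <- evaluate(fake, matrix(0, 14, 2), truth)
      expect_equal(res$sensitivity, 100 * 5 / 7, tolerance = 1e-12)
      expect_equal(res$specificity, 100)
      expect_equal(res$accuracy, 100 * 12 / 14, tolerance = 1e-12)
      expect_equal(c(res$TP, res$FN, res$TN, res$FP), c(5, 2, 7, 0))
    }
  )
})

test_that("trapezoidal AUC matches pROC and is 50% under the null", {
  set.seed(54)
  y <- rep(c(TRUE, FALSE), each = 500)
  s <- rnorm(1000)
  expect_equal(ssvepkiosk:::auc_trapezoid(s, y), 0.5, tolerance = 0.06)
  s2 <- rnorm(1000) + y * 1.5
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s2,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ssvepkiosk:::auc_trapezoid(s2, y), ref, tolerance = 1e-12)
})

test_that("every classifier family trains, predicts and scores", {
  tab <- informative_table(15, d = 2.5, p_noise = 3)
  sp <- stratified_split(tab, 0.7, seed = 55)
  feats <- setdiff(names(tab), c("subject_id", "group"))
  for (fam in c("svm", "lda", "nb", "gpc", "knn", "rf")) {
    set.seed(56)
    fit <- ssvepkiosk:::fit_pipeline(sp$train, feats, fam, select = FALSE)
    Xte <- fit$std$apply(as.matrix(sp$test[, feats]))
    res <- evaluate(fit$model, Xte[, fit$features, drop = FALSE],
                    sp$test$group)
    expect_false(res$flagged)
    expect_gt(res$accuracy, 50)
    expect_true(res$auc >= 0 && res$auc <= 100)
  }
})

test_that("the fitted pipeline never sees the test set", {
  tab <- informative_table(20)
  sp <- stratified_split(tab, 0.7, seed = 57)
  feats <- setdiff(names(tab), c("subject_id", "group"))
  set.seed(58)
  f1 <- ssvepkiosk:::fit_pipeline(sp$train, feats, "svm")
  set.seed(58)
  f2 <- ssvepkiosk:::fit_pipeline(sp$train, feats, "svm")
  # identical training data -> identical model irrespective of any test
  # labels (which never enter the pipeline)
  expect_identical(f1$features, f2$features)
  expect_equal(f1$model$fit$coefs, f2$model$fit$coefs, tolerance = 1e-12)
  corrupted <- sp$test
  corrupted$group <- rev(corrupted$group)
  Xte <- f1$std$apply(as.matrix(sp$test[, feats]))
  r1 <- evaluate(f1$model, Xte[, f1$features, drop = FALSE],
                 sp$test$group)
  r2 <- evaluate(f2$model, Xte[, f2$features, drop = FALSE],
                 corrupted$group)
  # scores identical; only the truth labels differ
  expect_equal(r1$TP + r1$FN, r2$TP + r2$FN)
})

test_that("benchmark report is deterministic and internally consistent", {
  tab <- simulate_cohort(cohort_spec(n_per_group = 24, seed = 59))
  rep1 <- run_benchmark(tab, n_repeats = 2, seed = 60, families = "svm")
  rep2 <- run_benchmark(tab, n_repeats = 2, seed = 60, families = "svm")
  expect_equal(rep1$per_repeat, rep2$per_repeat)
  pr <- rep1$per_repeat
  expect_equal(pr$accuracy,
               100 * (pr$TP + pr$TN) / (pr$TP + pr$TN + pr$FP + pr$FN),
               tolerance = 1e-12)
  expect_equal(pr$sensitivity, 100 * pr$TP / (pr$TP + pr$FN),
               tolerance = 1e-12)
  expect_equal(pr$specificity, 100 * pr$TN / (pr$TN + pr$FP),
               tolerance = 1e-12)
})

test_that("shuffled labels give chance-level LOOCV accuracy", {
  set.seed(61)
  accs <- replicate(30, {
    tab <- informative_table(17, d = 0, p_noise = 4,
                             seed = sample.int(1e6, 1))
    X <- scale(as.matrix(tab[, -(1:2)]))
    loocv_grid_search(X, sample(tab$group), "lda")$cv_accuracy
  })
  # leave-one-out with balanced classes is pessimistically biased under
  # the null (the held-out sample's class is under-represented in
  # training), so the mean sits slightly below 0.5
  expect_lt(abs(mean(accs) - 0.5), 0.08)
  expect_lt(max(accs), 0.85)
})

test_that("PCA projection separates a planted group difference", {
  tab <- informative_table(20, d = 4, p_noise = 2)
  pc <- pca_project(tab, c("signal", "noise1", "noise2"))
  expect_equal(names(pc)[1:2], c("PC1", "PC2"))
  # silhouette of the grouping along PC1 must be positive
  x <- pc$PC1
  g <- pc$group
  m1 <- mean(x[g == "hc"]); m2 <- mean(x[g == "amci"])
  expect_gt(abs(m1 - m2),
            max(sd(x[g == "hc"]), sd(x[g == "amci"])))

  # order permutation changes components at most by sign
  pc2 <- pca_project(tab, c("noise2", "signal", "noise1"))
  expect_equal(abs(cor(pc$PC1, pc2$PC1)), 1, tolerance = 1e-9)

  # two uncorrelated unit-variance features split variance evenly
  set.seed(62)
  t2 <- data.frame(group = factor(rep(c("hc", "amci"), each = 300)),
                   a = rnorm(600), b = rnorm(600))
  pc3 <- pca_project(t2, c("a", "b"))
  expect_equal(attr(pc3, "explained_variance")[1], 0.5, tolerance = 0.1)
  expect_error(pca_project(t2, "a"), "two features")
})
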