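test_that("the registry holds the nine configurations", {
  reg <- classifier_registry()
  expect_length(reg, 9L)
  expect_setequal(names(reg),
                  c("decision_tree", "lda", "qda", "knn1", "knn10",
                    "svm_linear", "svm_quadratic", "naive_bayes",
                    "bagged_trees"))
  expect_equal(reg$knn1$k, 1L)
  expect_equal(reg$knn10$k, 10L)
  expect_equal(reg$svm_quadratic$kernel, "quadratic")
  expect_equal(reg$bagged_trees$n_learners, 30L)
  # only distance/kernel families standardize
  std <- vapply(reg, function(cc) cc$standardize, logical(1))
  expect_setequal(names(std)[std],
                  c("knn1", "knn10", "svm_linear", "svm_quadratic"))
})

test_that("every family separates well-separated blobs", {
  blobs <- make_blobs(60, p = 3, sep = 5, seed = 10)
  for (nm in names(classifier_registry())) {
    cfg <- classifier_registry()[[nm]]
    m <- train_classifier(cfg, blobs$x, blobs$y, seed = 1)
    pred <- predict(m, blobs$x, type = "class")
    expect_gte(mean(pred == blobs$y), 0.95)
    pr <- predict(m, blobs$x, type = "prob")
    expect_equal(colnames(pr), levels(blobs$y))
    expect_true(all(pr >= -1e-9 & pr <= 1 + 1e-9))
    expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-6)
  }
})

test_that("training validates inputs", {
  blobs <- make_blobs(20, seed = 2)
  cfg <- classifier_config("lda")
  expect_error(train_classifier(cfg, blobs$x, rep("low", 40)), "2 classes")
  xna <- blobs$x
  xna[1, 1] <- NA
  expect_error(train_classifier(cfg, xna, blobs$y), "missing values")
  # QDA names its degeneracy: a constant feature within a class
  xdeg <- blobs$x
  xdeg$f2 <- rep(c(0, 1), each = 20)
  expect_error(train_classifier(classifier_config("qda"), xdeg, blobs$y),
               "degenerate class covariance")
})

test_that("1-NN memorizes its training set exactly", {
  blobs <- make_blobs(30, sep = 1, seed = 3)  # heavy overlap
  m <- train_classifier(classifier_config("knn", k = 1), blobs$x, blobs$y)
  expect_equal(mean(predict(m, blobs$x) == blobs$y), 1)
})

test_that("standardization is fitted on training data and applied to new data", {
  blobs <- make_blobs(50, sep = 4, seed = 4)
  # wildly different feature scales must not hurt the scaled families
  x <- blobs$x
  x$f2 <- x$f2 * 1e6
  for (fam in c("knn10", "svm_linear")) {
    cfg <- classifier_registry()[[fam]]
    m <- train_classifier(cfg, x, blobs$y, seed = 1)
    expect_equal(unname(m$scaling$mean), unname(colMeans(x)))
    expect_gte(mean(predict(m, x) == blobs$y), 0.9)
  }
})

test_that("cohens_kappa reproduces the worked example and identities", {
  cm <- matrix(c(45, 10, 5, 40), 2, 2)  # rows true: [[45,5],[10,40]]
  k <- cohens_kappa(cm)
  expect_equal(k$kappa, 0.70, tolerance = 1e-12)
  expect_equal(k$band, "substantial")
  expect_equal(k$kappa, o_kappa(cm), tolerance = 1e-12)
  # perfect diagonal -> 1
  expect_equal(cohens_kappa(diag(c(30, 20, 10)))$kappa, 1)
  # uniform matrix -> 0
  expect_equal(cohens_kappa(matrix(5, 3, 3))$kappa, 0)
  # label-independent predictions -> ~0 (outer product of the marginals)
  expect_equal(cohens_kappa(outer(c(30, 70), c(40, 60)))$kappa, 0,
               tolerance = 1e-12)
  # degenerate single-cell matrix: kappa 0 with a warning
  expect_warning(k0 <- cohens_kappa(matrix(c(10, 0, 0, 0), 2, 2)),
                 "degenerate")
  expect_equal(k0$kappa, 0)
  # random matrices agree with the loop oracle
  set.seed(8)
  for (rep in 1:50) {
    cm <- matrix(rpois(9, 20) + 1, 3, 3)
    expect_equal(cohens_kappa(cm)$kappa, o_kappa(cm), tolerance = 1e-12)
  }
})

test_that("Landis-Koch bands are left-open at each boundary", {
  expect_equal(landis_koch_band(-0.2), "no agreement")
  expect_equal(landis_koch_band(0), "slight")
  expect_equal(landis_koch_band(0.20), "slight")
  expect_equal(landis_koch_band(0.21), "fair")
  expect_equal(landis_koch_band(0.40), "fair")
  expect_equal(landis_koch_band(0.41), "moderate")
  expect_equal(landis_koch_band(0.60), "moderate")
  expect_equal(landis_koch_band(0.61), "substantial")
  expect_equal(landis_koch_band(0.80), "substantial")
  expect_equal(landis_koch_band(0.81), "almost perfect")
  expect_equal(landis_koch_band(1), "almost perfect")
  expect_error(landis_koch_band(1.5))
})

test_that("per-class rates are recall; empty classes give NA", {
  cm <- matrix(c(8, 2, 0, 4, 6, 0, 0, 0, 0), 3, 3, byrow = TRUE,
               dimnames = list(c("low", "medium", "high"),
                               c("low", "medium", "high")))
  r <- per_class_rates(cm)
  expect_equal(r[["low"]], 0.8)
  expect_equal(r[["medium"]], 0.6)
  expect_true(is.na(r[["high"]]))  # empty true class
  p <- per_class_precision(cm)
  expect_equal(p[["low"]], 8 / 12)
  expect_equal(p[["medium"]], 6 / 8)
  expect_true(is.na(p[["high"]]))  # never predicted
})

test_that("ROC/AUC behaves at the extremes", {
  set.seed(5)
  y <- factor(rep(c("low", "high"), each = 50), levels = c("low", "high"))
  # perfectly separating scores -> AUC 1 for both one-vs-rest curves
  s_high <- c(runif(50, 0, 0.4), runif(50, 0.6, 1))
  scores <- cbind(low = 1 - s_high, high = s_high)
  rc <- roc_curves(y, scores)
  expect_equal(rc$high$auc, 1)
  expect_equal(rc$low$auc, 1)
  # label-independent scores -> AUC ~ 0.5 on average
  aucs <- replicate(20, {
    sc <- runif(100)
    roc_curves(y, cbind(low = 1 - sc, high = sc))$high$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # operating point matches the confusion-matrix rates
  pred <- factor(ifelse(s_high > 0.5, "high", "low"), levels = levels(y))
  rc2 <- roc_curves(y, scores, y_pred = pred)
  expect_equal(unname(rc2$high$operating_point["tpr"]), 1)
  expect_equal(unname(rc2$high$operating_point["fpr"]), 0)
})

test_that("evaluation_report assembles consistent metrics", {
  y <- factor(c("low", "low", "high", "high", "medium", "medium"),
              levels = c("low", "medium", "high"))
  p <- factor(c("low", "high", "high", "high", "medium", "low"),
              levels = c("low", "medium", "high"))
  rep_ <- evaluation_report(y, p)
  expect_equal(rep_$accuracy, 4 / 6)
  expect_equal(sum(rep_$confusion), 6)
  expect_equal(unname(rep_$per_class["high"]), 1)
  expect_equal(rep_$kappa_band, landis_koch_band(rep_$kappa))
  # JSON export round-trips the headline numbers
  pth <- file.path(tempdir(), "report.json")
  export_report_json(rep_, pth)
  got <- jsonlite::read_json(pth, simplifyVector = TRUE)
  expect_equal(got$accuracy, rep_$accuracy, tolerance = 1e-12)
  expect_equal(got$kappa, rep_$kappa, tolerance = 1e-12)
  unlink(pth)
})

test_that("k-fold CV is stratified, deterministic and near-perfect on blobs", {
  blobs <- make_blobs(50, sep = 6, seed = 11)
  cfg <- classifier_config("lda")
  r1 <- kfold_cv(cfg, blobs$x, blobs$y, k = 10, seed = 7)
  r2 <- kfold_cv(cfg, blobs$x, blobs$y, k = 10, seed = 7)
  expect_identical(r1$confusion, r2$confusion)
  expect_gte(r1$accuracy, 0.97)
  expect_gte(r1$kappa, 0.94)
  expect_gte(min(r1$auc), 0.99)
  # fold balance: every fold holds both classes
  fold <- anxiodetect:::make_folds(blobs$y, 10, seed = 7)
  tab <- table(fold, blobs$y)
  expect_true(all(tab > 0))
  expect_equal(length(unique(fold)), 10L)
})

test_that("n = k gives leave-one-out singleton folds", {
  y <- factor(rep(c("low", "high"), each = 5))
  fold <- anxiodetect:::make_folds(y, 10, seed = 1)
  expect_setequal(fold, 1:10)
  blobs <- make_blobs(5, sep = 6, seed = 12)
  r <- kfold_cv(classifier_config("lda"), blobs$x, blobs$y, k = 10, seed = 2)
  expect_equal(sum(r$confusion), 10)
  expect_error(kfold_cv(classifier_config("lda"), blobs$x[1:5, ],
                        blobs$y[1:5], k = 10), "at least k")
})

test_that("grouped folds hold out whole groups together", {
  blobs <- make_blobs(40, sep = 5, seed = 13)
  group <- rep(paste0("g", 1:8), each = 10)
  fold <- anxiodetect:::make_folds(blobs$y, 4, seed = 3, group = group)
  for (g in unique(group)) {
    expect_length(unique(fold[group == g]), 1L)
  }
})

test_that("CV on pure noise stays at chance; permuted labels give kappa ~ 0", {
  set.seed(19)
  n <- 100
  x <- as.data.frame(matrix(rnorm(n * 3), n, 3))
  names(x) <- paste0("f", 1:3)
  y <- factor(rep(c("low", "high"), each = n / 2))
  accs <- kappas <- numeric(20)
  for (i in 1:20) {
    yp <- sample(y)
    r <- kfold_cv(classifier_config("bagged_trees"), x, yp, k = 10, seed = i)
    accs[i] <- r$accuracy
    kappas[i] <- r$kappa
  }
  expect_lt(abs(mean(kappas)), 0.1)
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("forward selection finds the informative feature first and stops", {
  set.seed(23)
  n <- 120
  y <- factor(rep(c("low", "high"), each = n / 2))
  x <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(x) <- paste0("f", 1:6)
  x$f4 <- x$f4 + ifelse(y == "high", 3, 0)  # the informative one
  cfg <- classifier_config("lda")
  sel <- sequential_forward_selection(cfg, x, y, seed = 5)
  expect_equal(sel[1L], "f4")
  expect_lte(length(sel), 3L)
  # a duplicated informative feature is added only once (lda warns about the
  # collinear candidate while probing it; that is expected)
  x$f5 <- x$f4
  sel2 <- suppressWarnings(sequential_forward_selection(cfg, x, y, seed = 5))
  expect_equal(sel2[1L], "f4")  # ties go to the earlier column
  expect_false(all(c("f4", "f5") %in% sel2))
  # all-noise features: greedy selection stays small (CV noise can admit the
  # odd feature, but it must never sweep up the whole set)
  lens <- vapply(1:5, function(s) {
    xn <- as.data.frame(matrix(rnorm(n * 4), n, 4))
    names(xn) <- paste0("n", 1:4)
    length(sequential_forward_selection(cfg, xn, y, seed = s))
  }, numeric(1))
  expect_lte(mean(lens), 1.5)
  expect_lt(max(lens), 4)
})

test_that("select_models filters unbalanced candidates and ranks the rest", {
  mk <- function(name, acc_by_class, n_feat) {
    n <- 50
    y <- factor(rep(names(acc_by_class), each = n),
                levels = names(acc_by_class))
    pred <- y
    for (cls in names(acc_by_class)) {
      idx <- which(y == cls)
      nwrong <- round((1 - acc_by_class[[cls]]) * n)
      if (nwrong > 0) {
        other <- setdiff(names(acc_by_class), cls)[1L]
        pred[idx[seq_len(nwrong)]] <- other
      }
    }
    list(name = name, features = paste0("f", seq_len(n_feat)),
         report = evaluation_report(y, pred))
  }
  # A: 90% overall but 100/80 split (spread 0.2, kept)
  a <- mk("A", c(low = 1, high = 0.8), 3)
  # B: 92% overall but 100/84... make spread > 0.25 to be filtered
  b <- mk("B", c(low = 1, high = 0.7), 2)
  # C: same accuracy as A with fewer features -> ranked above A
  c_ <- mk("C", c(low = 0.9, high = 0.9), 2)
  got <- select_models(list(a, b, c_), balance_threshold = 0.25)
  expect_false("B" %in% got$name)
  expect_equal(got$name, c("C", "A"))  # tie on accuracy, C has fewer features
  expect_equal(nrow(select_models(list())), 0L)
})
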