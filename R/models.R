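#' Classifier configuration
#'
#' The classifier families compared for anxiety-level detection with their
#' fixed hyperparameters: decision tree (at most 100 splits, Gini index),
#' linear and quadratic discriminant analysis, k-nearest neighbors (Euclidean,
#' k = 1 or 10), support vector machines (linear or quadratic kernel, box
#' constraint 1), naive Bayes (Gaussian class-conditionals) and bagged trees
#' (30 learners, trees grown to up to n-1 splits). Distance- and kernel-based
#' families (kNN, SVM) receive per-feature standardization fitted on training
#' folds only.
#'
#' @param family One of `"decision_tree"`, `"lda"`, `"qda"`, `"knn"`,
#'   `"svm"`, `"naive_bayes"`, `"bagged_trees"`.
#' @param k Neighbors for kNN (1 or 10).
#' @param kernel SVM kernel, `"linear"` or `"quadratic"`.
#' @param max_splits Split cap for the decision tree.
#' @param n_learners Trees in the bagged ensemble.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(family, k = 1, kernel = "linear",
                              max_splits = 100, n_learners = 30) {
  family <- match.arg(family, c("decision_tree", "lda", "qda", "knn", "svm",
                                "naive_bayes", "bagged_trees"))
  kernel <- match.arg(kernel, c("linear", "quadratic"))
  cfg <- list(family = family, max_splits = max_splits)
  if (family == "knn") cfg$k <- as.integer(k)
  if (family == "svm") {
    cfg$kernel <- kernel
    cfg$cost <- 1
  }
  if (family == "bagged_trees") {
    cfg$n_learners <- as.integer(n_learners)
    # printed alongside the ensemble options but inert for bagging
    cfg$inert <- list(learning_rate = 0.1, subspace_dimension = 1)
  }
  cfg$standardize <- family %in% c("knn", "svm")
  structure(cfg, class = "classifier_config")
}

#' The nine classifier configurations
#' @return Named list of `classifier_config`s.
#' @export
classifier_registry <- function() {
  list(
    decision_tree = classifier_config("decision_tree"),
    lda = classifier_config("lda"),
    qda = classifier_config("qda"),
    knn1 = classifier_config("knn", k = 1),
    knn10 = classifier_config("knn", k = 10),
    svm_linear = classifier_config("svm", kernel = "linear"),
    svm_quadratic = classifier_config("svm", kernel = "quadratic"),
    naive_bayes = classifier_config("naive_bayes"),
    bagged_trees = classifier_config("bagged_trees")
  )
}

#' @export
print.classifier_config <- function(x, ...) {
  extra <- switch(x$family,
                  knn = sprintf(" (k=%d)", x$k),
                  svm = sprintf(" (%s kernel, C=%g)", x$kernel, x$cost),
                  bagged_trees = sprintf(" (%d learners)", x$n_learners),
                  "")
  cat(sprintf("<classifier_config> %s%s\n", x$family, extra))
  invisible(x)
}

# prune an unconstrained rpart back to at most max_splits splits
cap_rpart_splits <- function(fit, max_splits) {
  ct <- fit$cptable
  ok <- ct[, "nsplit"] <= max_splits
  if (all(ok)) return(fit)
  rpart::prune(fit, cp = ct[max(which(ok)), "CP"] + 1e-12)
}

#' Train a classifier
#'
#' Deterministic given `seed`. Errors on single-class labels; QDA reports a
#' class-covariance degeneracy explicitly.
#'
#' @param config A `classifier_config`.
#' @param x Feature `data.frame` (complete, numeric).
#' @param y Label factor.
#' @param seed Integer seed.
#' @return Object of class `anx_model` with a [predict.anx_model()] method.
#' @export
train_classifier <- function(config, x, y, seed = 1) {
  stopifnot(inherits(config, "classifier_config"))
  x <- as.data.frame(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("training needs at least 2 classes")
  if (anyNA(x)) stop("missing values in features; impute upstream")
  set.seed(seed)
  scaling <- NULL
  if (isTRUE(config$standardize)) {
    mu <- vapply(x, mean, numeric(1))
    sg <- vapply(x, stats::sd, numeric(1))
    sg[sg == 0 | is.na(sg)] <- 1
    scaling <- list(mean = mu, sd = sg)
    x <- as.data.frame(scale(x, center = mu, scale = sg))
  }
  dat <- cbind(x, .label = y)
  fit <- switch(
    config$family,
    decision_tree = cap_rpart_splits(
      rpart::rpart(.label ~ ., data = dat, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(cp = 0, minsplit = 4,
                                                  xval = 0)),
      config$max_splits),
    lda = MASS::lda(x, grouping = y),
    qda = tryCatch(
      MASS::qda(x, grouping = y),
      error = function(e) {
        stop("QDA degenerate class covariance (", conditionMessage(e),
             "); drop collinear features or regularize")
      }),
    knn = caret::knn3(as.matrix(x), y, k = config$k),
    svm = e1071::svm(x, y, kernel = if (config$kernel == "linear") "linear"
                                    else "polynomial",
                     degree = 2, coef0 = 1, cost = config$cost,
                     scale = FALSE, probability = TRUE),
    naive_bayes = e1071::naiveBayes(x, y),
    bagged_trees = randomForest::randomForest(x, y,
                                              ntree = config$n_learners,
                                              mtry = ncol(x),
                                              replace = TRUE)
  )
  structure(list(config = config, fit = fit, scaling = scaling,
                 feature_names = colnames(x), classes = levels(y),
                 version = as.character(utils::packageVersion("anxiodetect"))),
            class = "anx_model")
}

#' @export
print.anx_model <- function(x, ...) {
  cat(sprintf("<anx_model> %s on %d features {%s}; classes {%s}\n",
              x$config$family, length(x$feature_names),
              paste(x$feature_names, collapse = ","),
              paste(x$classes, collapse = ",")))
  invisible(x)
}

#' Predict labels or class scores
#'
#' @param object An `anx_model`.
#' @param newdata Feature `data.frame` containing the model's features.
#' @param type `"class"` for hard labels, `"prob"` for a class-score matrix.
#' @param ... Unused.
#' @return Factor of labels or a numeric matrix with one column per class.
#' @export
predict.anx_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  nd <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  if (!is.null(object$scaling)) {
    nd <- as.data.frame(scale(nd, center = object$scaling$mean,
                              scale = object$scaling$sd))
  }
  fit <- object$fit
  fam <- object$config$family
  cls <- object$classes
  if (type == "prob") {
    p <- switch(fam,
      decision_tree = stats::predict(fit, nd, type = "prob"),
      lda = stats::predict(fit, nd)$posterior,
      qda = stats::predict(fit, nd)$posterior,
      knn = stats::predict(fit, as.matrix(nd), type = "prob"),
      svm = {
        pr <- stats::predict(fit, nd, probability = TRUE)
        attr(pr, "probabilities")
      },
      naive_bayes = stats::predict(fit, nd, type = "raw"),
      bagged_trees = stats::predict(fit, nd, type = "prob"))
    p <- as.matrix(p)
    miss <- setdiff(cls, colnames(p))
    if (length(miss)) {
      p <- cbind(p, matrix(0, nrow(p), length(miss),
                           dimnames = list(NULL, miss)))
    }
    return(p[, cls, drop = FALSE])
  }
  pred <- switch(fam,
    decision_tree = stats::predict(fit, nd, type = "class"),
    lda = stats::predict(fit, nd)$class,
    qda = stats::predict(fit, nd)$class,
    knn = stats::predict(fit, as.matrix(nd), type = "class"),
    svm = stats::predict(fit, nd),
    naive_bayes = stats::predict(fit, nd, type = "class"),
    bagged_trees = {
      # argmax of the vote fractions with ties to the first class:
      # predict(type = "response") breaks exact vote ties at random, which
      # would make predictions depend on RNG state and on whether rows are
      # scored in batch or one at a time
      pv <- stats::predict(fit, nd, type = "prob")
      colnames(pv)[max.col(pv, ties.method = "first")]
    })
  factor(as.character(pred), levels = cls)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement from the marginal products. A degenerate single-cell
#' matrix (`p_e = 1`) yields `kappa = 0` with a warning.
#'
#' @param cm Square non-negative confusion matrix, rows = true class.
#' @return List with `kappa` and Landis--Koch `band`.
#' @export
cohens_kappa <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0), sum(cm) > 0)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warning("degenerate confusion matrix (chance agreement 1); kappa set to 0")
    k <- 0
  } else {
    k <- (po - pe) / (1 - pe)
  }
  list(kappa = k, band = landis_koch_band(k))
}

#' Landis--Koch interpretation band for a kappa value
#'
#' Left-closed bands `[0, 0.20]` slight, `(0.20, 0.40]` fair, `(0.40, 0.60]`
#' moderate, `(0.60, 0.80]` substantial, `(0.80, 1]` almost perfect;
#' negative values indicate no agreement.
#'
#' @param kappa Numeric in `[-1, 1]`.
#' @return Character band label.
#' @export
landis_koch_band <- function(kappa) {
  stopifnot(is.finite(kappa), kappa >= -1 - 1e-9, kappa <= 1 + 1e-9)
  if (kappa < 0) return("no agreement")
  if (kappa <= 0.20) return("slight")
  if (kappa <= 0.40) return("fair")
  if (kappa <= 0.60) return("moderate")
  if (kappa <= 0.80) return("substantial")
  "almost perfect"
}

#' Per-class true detection rates
#'
#' Recall per class: the diagonal cell over its row sum (rows = true class).
#' An empty true class yields `NA`. For the anxiety classes these are the
#' true high/medium/low rates (THR/TMR/TLR).
#'
#' @param cm Confusion matrix, rows = true class.
#' @return Named numeric vector of per-class rates.
#' @export
per_class_rates <- function(cm) {
  cm <- as.matrix(cm)
  rs <- rowSums(cm)
  r <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  stats::setNames(r, rownames(cm))
}

#' Per-class precision
#' @param cm Confusion matrix, rows = true class.
#' @return Named numeric vector (diagonal over column sums; `NA` for 0/0).
#' @export
per_class_precision <- function(cm) {
  cm <- as.matrix(cm)
  cs <- colSums(cm)
  stats::setNames(ifelse(cs > 0, diag(cm) / cs, NA_real_), colnames(cm))
}

#' One-vs-rest ROC curves
#'
#' One curve per class from pooled class scores, with trapezoidal AUC; the
#' operating point of the hard classifier is attached when predictions are
#' supplied.
#'
#' @param y_true Label factor.
#' @param scores Numeric matrix of class scores, columns named by class.
#' @param y_pred Optional hard predictions for the operating point.
#' @param positive_class Restrict to one class; default all classes present.
#' @return Named list per class: `points` (`data.frame` of `fpr`, `tpr`),
#'   `auc`, and `operating_point` (or `NULL`).
#' @export
roc_curves <- function(y_true, scores, y_pred = NULL, positive_class = NULL) {
  y_true <- as.factor(y_true)
  classes <- if (is.null(positive_class)) {
    intersect(colnames(scores), levels(droplevels(y_true)))
  } else positive_class
  out <- list()
  for (cls in classes) {
    resp <- factor(ifelse(y_true == cls, "pos", "neg"),
                   levels = c("neg", "pos"))
    r <- pROC::roc(resp, scores[, cls], quiet = TRUE, direction = "<",
                   levels = c("neg", "pos"))
    pts <- data.frame(fpr = rev(1 - r$specificities),
                      tpr = rev(r$sensitivities))
    op <- NULL
    if (!is.null(y_pred)) {
      tp <- sum(y_pred == cls & y_true == cls)
      fp <- sum(y_pred == cls & y_true != cls)
      op <- c(fpr = fp / max(1, sum(y_true != cls)),
              tpr = tp / max(1, sum(y_true == cls)))
    }
    out[[cls]] <- list(points = pts, auc = as.numeric(pROC::auc(r)),
                       operating_point = op)
  }
  out
}

#' Build an evaluation report
#'
#' @param y_true,y_pred Label factors on the same levels.
#' @param scores Optional class-score matrix for ROC/AUC.
#' @return Object of class `evaluation_report`: confusion matrix (rows =
#'   true class), accuracy, per-class rates and precision, Cohen's kappa with
#'   its Landis--Koch band, and per-class ROC/AUC when scores are given.
#' @export
evaluation_report <- function(y_true, y_pred, scores = NULL) {
  y_true <- droplevels(as.factor(y_true))
  y_pred <- factor(as.character(y_pred), levels = levels(y_true))
  cm <- table(true = y_true, predicted = y_pred)
  kp <- cohens_kappa(cm)
  roc <- if (!is.null(scores)) roc_curves(y_true, scores, y_pred) else NULL
  structure(
    list(confusion = cm,
         accuracy = sum(diag(cm)) / sum(cm),
         per_class = per_class_rates(cm),
         per_class_precision = per_class_precision(cm),
         kappa = kp$kappa,
         kappa_band = kp$band,
         roc = roc,
         auc = if (!is.null(roc)) vapply(roc, `[[`, numeric(1), "auc")
               else NULL),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> accuracy %.3f, kappa %.3f (%s)\n",
              x$accuracy, x$kappa, x$kappa_band))
  cat("per-class rates: ",
      paste(sprintf("%s=%.3f", names(x$per_class), x$per_class),
            collapse = ", "), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Serialize a report to JSON
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_report_json <- function(report, path) {
  x <- list(confusion = as.data.frame.matrix(report$confusion),
            accuracy = report$accuracy,
            per_class = as.list(report$per_class),
            per_class_precision = as.list(report$per_class_precision),
            kappa = report$kappa, kappa_band = report$kappa_band,
            auc = as.list(report$auc))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

make_folds <- function(y, k, seed, group = NULL) {
  set.seed(seed)
  n <- length(y)
  fold <- integer(n)
  if (!is.null(group)) {
    g <- unique(group)
    gf <- stats::setNames(rep_len(sample(k), length(g))[sample(length(g))], g)
    fold <- gf[as.character(group)]
  } else if (n == k) {
    fold <- sample(n)  # leave-one-out
  } else {
    for (cls in levels(y)) {
      idx <- which(y == cls)
      if (length(idx) < k) {
        warning("class '", cls, "' has fewer members than folds; ",
                "fold-wise presence not guaranteed")
      }
      fold[idx] <- rep_len(sample(k), length(idx))[sample(length(idx))]
    }
  }
  as.integer(fold)
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by class and randomized by seed; out-of-fold
#' predictions are pooled into one confusion matrix from which all metrics
#' are computed. With `group` set (e.g. subject ids), whole groups are held
#' out together, preventing same-subject windows in train and test; the
#' default window-level folding mirrors common practice for these models.
#'
#' @param config A `classifier_config`.
#' @param x Feature `data.frame`.
#' @param y Label factor.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param group Optional grouping vector for leakage-safe grouped folds.
#' @return An `evaluation_report` (with ROC/AUC from pooled scores).
#' @export
kfold_cv <- function(config, x, y, k = 10, seed = 1, group = NULL) {
  x <- as.data.frame(x)
  y <- droplevels(as.factor(y))
  n <- nrow(x)
  if (n < k) stop("need at least k observations")
  fold <- make_folds(y, k, seed, group)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  scores <- matrix(NA_real_, n, nlevels(y),
                   dimnames = list(NULL, levels(y)))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < 2L) {
      stop("a training fold lost all but one class; use fewer folds")
    }
    m <- train_classifier(config, x[tr, , drop = FALSE], y[tr],
                          seed = seed + f)
    te <- x[!tr, , drop = FALSE]
    pred[!tr] <- predict(m, te, type = "class")
    p <- tryCatch(predict(m, te, type = "prob"), error = function(e) NULL)
    if (!is.null(p)) {
      scores[!tr, colnames(p)] <- p
    }
  }
  if (anyNA(scores)) {
    # fall back to one-hot scores where a family could not emit probabilities
    bad <- which(is.na(scores[, 1L]))
    scores[bad, ] <- 0
    scores[cbind(bad, as.integer(pred[bad]))] <- 1
  }
  evaluation_report(y, pred, scores)
}

#' Sequential forward feature selection
#'
#' Greedy wrapper: starts from the empty set and adds the candidate feature
#' with the best k-fold cross-validated accuracy, stopping when no candidate
#' strictly improves it. Fold assignments are fixed by the seed, so the
#' selection is deterministic; ties go to the earlier feature in column
#' order.
#'
#' @param config A `classifier_config`.
#' @param x Feature `data.frame` with at least 2 columns.
#' @param y Label factor.
#' @param seed Integer seed (also fixes the CV folds).
#' @param k CV folds per candidate evaluation.
#' @return Character vector of selected feature names in selection order
#'   (may be empty if nothing beats the empty model's majority accuracy).
#' @export
sequential_forward_selection <- function(config, x, y, seed = 1, k = 10) {
  x <- as.data.frame(x)
  y <- droplevels(as.factor(y))
  stopifnot(ncol(x) >= 2L)
  selected <- character(0)
  best <- max(table(y)) / length(y)  # empty model: majority class
  repeat {
    remaining <- setdiff(colnames(x), selected)
    if (!length(remaining)) break
    accs <- vapply(remaining, function(f) {
      kfold_cv(config, x[, c(selected, f), drop = FALSE], y,
               k = k, seed = seed)$accuracy
    }, numeric(1))
    j <- which.max(accs)  # first maximum wins ties
    if (accs[j] <= best + 1e-12) break
    selected <- c(selected, remaining[j])
    best <- accs[j]
  }
  selected
}

#' Rank candidate models
#'
#' Sorts candidates by overall accuracy, keeps those whose per-class true
#' rates are balanced (max spread at most `balance_threshold`), and breaks
#' ties by preferring fewer features.
#'
#' @param candidates List; each element a list with fields `name`,
#'   `features` (character) and `report` (`evaluation_report`).
#' @param balance_threshold Maximum allowed spread between per-class rates.
#' @return `data.frame` shortlist ordered best-first.
#' @export
select_models <- function(candidates, balance_threshold = 0.25) {
  if (!length(candidates)) {
    return(data.frame(name = character(0), accuracy = numeric(0),
                      spread = numeric(0), n_features = integer(0),
                      kappa = numeric(0)))
  }
  rows <- lapply(candidates, function(cc) {
    r <- cc$report
    rates <- r$per_class[!is.na(r$per_class)]
    data.frame(name = cc$name,
               accuracy = r$accuracy,
               spread = if (length(rates)) max(rates) - min(rates) else NA,
               n_features = length(cc$features),
               kappa = r$kappa)
  })
  df <- do.call(rbind, rows)
  df <- df[!is.na(df$spread) & df$spread <= balance_threshold, ,
           drop = FALSE]
  df <- df[order(-df$accuracy, df$n_features), , drop = FALSE]
  rownames(df) <- NULL
  df
}
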