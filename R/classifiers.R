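## Classifier suite behind the decoding protocol: three linear models (LDA,
## linear SVC, logistic regression), three non-linear (RBF SVC, 3-NN, decision
## tree) and three ensembles (random forest, AdaBoost, gradient boosting),
## each behind a common fit/score interface. Scores are oriented so that
## larger means more rare-like (positive class = rare = 1).

CLASSIFIER_NAMES <- c("lda", "logreg", "svc_lin", "svc_rbf", "knn", "tree",
                      "rf", "adaboost", "xgb")

#' Specify a classifier
#'
#' @param name one of `"lda"`, `"logreg"`, `"svc_lin"`, `"svc_rbf"`, `"knn"`,
#'   `"tree"`, `"rf"`, `"adaboost"`, `"xgb"`.
#' @param params named list of overrides. Defaults: `knn` uses `k = 3`;
#'   `rf`, `adaboost` and `xgb` use 100 estimators with maximum depth 4;
#'   everything else library defaults.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, params = list()) {
  name <- match.arg(name, CLASSIFIER_NAMES)
  defaults <- switch(name,
    knn = list(k = 3L),
    rf = list(n_estimators = 100L, max_depth = 4L),
    adaboost = list(n_estimators = 100L, max_depth = 4L),
    xgb = list(n_estimators = 100L, max_depth = 4L),
    list()
  )
  defaults[names(params)] <- params
  structure(list(name = name, params = defaults), class = "classifier_spec")
}

#' The full nine-classifier suite
#'
#' @param names subset of classifier names to include.
#' @return named list of [classifier_spec()] objects.
#' @export
default_classifier_specs <- function(names = CLASSIFIER_NAMES) {
  stats::setNames(lapply(names, classifier_spec), names)
}

#' Fit a classifier on a training set
#'
#' @param spec a [classifier_spec()].
#' @param x training feature matrix (rows = trials).
#' @param y binary training labels (0 = frequent, 1 = rare).
#' @param seed integer seed for stochastic learners.
#' @return object of class `erp_classifier`.
#' @export
fit_classifier <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.matrix(x)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) stop("training set needs both classes", call. = FALSE)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  p <- spec$params
  fit <- switch(spec$name,
    lda = {
      ## drop features that are (near-)constant within both classes, which
      ## would make the pooled covariance singular in a way MASS::lda rejects
      keep <- which(apply(x, 2, function(col) {
        stats::sd(col[y == 0]) > 1e-10 || stats::sd(col[y == 1]) > 1e-10
      }))
      if (!length(keep)) {
        list(kind = "constant")
      } else {
        list(kind = "lda", keep = keep,
             model = MASS::lda(x[, keep, drop = FALSE], grouping = factor(y)))
      }
    },
    logreg = {
      df <- data.frame(x, .y = y)
      model <- suppressWarnings(
        stats::glm(.y ~ ., family = stats::binomial(), data = df))
      list(kind = "logreg", model = model)
    },
    svc_lin = ,
    svc_rbf = {
      kernel <- if (spec$name == "svc_lin") "linear" else "radial"
      model <- with_seed(seed, e1071::svm(x, factor(y), kernel = kernel,
                                          scale = FALSE))
      list(kind = "svm", model = model)
    },
    knn = list(kind = "knn", train_x = x, train_y = y, k = p$k, seed = seed),
    tree = {
      df <- data.frame(x, .y = factor(y))
      list(kind = "tree", model = rpart::rpart(.y ~ ., data = df,
                                               method = "class"))
    },
    rf = {
      model <- ranger::ranger(x = x, y = factor(y),
                              num.trees = p$n_estimators,
                              max.depth = p$max_depth,
                              probability = TRUE, num.threads = 1,
                              seed = seed)
      list(kind = "rf", model = model)
    },
    adaboost = list(kind = "adaboost",
                    model = with_seed(seed, fit_adaboost(x, y,
                                                         p$n_estimators,
                                                         p$max_depth))),
    xgb = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      params <- list(objective = "binary:logistic", max_depth = p$max_depth,
                     nthread = 1)
      model <- xgboost::xgb.train(params = params, data = dtrain,
                                  nrounds = p$n_estimators, verbose = 0)
      list(kind = "xgb", model = model)
    }
  )
  structure(c(fit, list(spec = spec, n_features = ncol(x))),
            class = "erp_classifier")
}

#' Continuous rare-class scores of a fitted classifier
#'
#' Probability of the rare class where the model provides one, otherwise a
#' decision value oriented so larger means more rare-like.
#'
#' @param fit an `erp_classifier` from [fit_classifier()].
#' @param x feature matrix to score.
#' @return numeric vector of scores.
#' @export
predict_scores <- function(fit, x) {
  stopifnot(inherits(fit, "erp_classifier"))
  x <- as.matrix(x)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  switch(fit$kind,
    constant = rep(0.5, nrow(x)),
    lda = {
      pr <- stats::predict(fit$model, x[, fit$keep, drop = FALSE])
      unname(pr$posterior[, "1"])
    },
    logreg = {
      unname(stats::predict(fit$model, newdata = data.frame(x),
                            type = "response"))
    },
    svm = {
      pr <- stats::predict(fit$model, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      ## column name "A/B": positive decision values favour class A
      pos <- strsplit(colnames(dv)[1], "/")[[1]][1]
      if (pos == "1") as.numeric(dv[, 1]) else -as.numeric(dv[, 1])
    },
    knn = {
      pr <- with_seed(fit$seed,
                      class::knn(fit$train_x, x, factor(fit$train_y),
                                 k = fit$k, prob = TRUE))
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    tree = {
      pr <- stats::predict(fit$model, newdata = data.frame(x), type = "prob")
      unname(pr[, "1"])
    },
    rf = {
      pr <- stats::predict(fit$model, data = x, num.threads = 1)$predictions
      unname(pr[, "1"])
    },
    adaboost = predict_adaboost(fit$model, x),
    xgb = {
      as.numeric(stats::predict(fit$model, xgboost::xgb.DMatrix(x)))
    }
  )
}

#' Hard class predictions of a fitted classifier
#'
#' Thresholds the continuous score: 0.5 for probability-like scores, 0 for
#' decision values (linear and RBF SVC, AdaBoost margins).
#'
#' @inheritParams predict_scores
#' @return integer vector of 0/1 predictions.
#' @export
predict_class <- function(fit, x) {
  s <- predict_scores(fit, x)
  thr <- if (fit$kind %in% c("svm", "adaboost")) 0 else 0.5
  as.integer(s > thr)
}

## -- AdaBoost (discrete SAMME / AdaBoost.M1) over depth-limited CART trees --

fit_adaboost <- function(x, y, n_estimators, max_depth) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- data.frame(x)
  learners <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, xval = 0,
                               minsplit = 2, minbucket = 1)
  for (m in seq_len(n_estimators)) {
    df$.y <- factor(y, levels = c(0, 1))
    tree <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                         control = ctrl)
    pred <- as.integer(as.character(stats::predict(tree, type = "class")))
    wrong <- pred != y
    err <- sum(w[wrong])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    learners[[length(learners) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break     # perfect learner; further rounds add nothing
    w <- w * exp(alpha * ifelse(wrong, 1, -1))
    w <- w / sum(w)
  }
  list(learners = learners, alphas = alphas)
}

## Closed-form pooled-covariance linear discriminant. Kept as an in-package
## reference for the LDA backend: returns the discriminant score
## w'x + b with w = Sigma^-1 (mu1 - mu0) and the prior-adjusted intercept,
## which is a strictly monotone transform of the LDA posterior.
lda_discriminant_scores <- function(x_train, y_train, x_test) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  mu0 <- colMeans(x_train[y_train == 0, , drop = FALSE])
  mu1 <- colMeans(x_train[y_train == 1, , drop = FALSE])
  n0 <- sum(y_train == 0); n1 <- sum(y_train == 1)
  c0 <- stats::cov(x_train[y_train == 0, , drop = FALSE])
  c1 <- stats::cov(x_train[y_train == 1, , drop = FALSE])
  sigma <- ((n0 - 1) * c0 + (n1 - 1) * c1) / (n0 + n1 - 2)
  w <- solve(sigma, mu1 - mu0)
  b <- -0.5 * sum((mu1 + mu0) * w) + log(n1 / n0)
  as.numeric(x_test %*% w + b)
}

## weighted-vote margin; larger = more rare-like
predict_adaboost <- function(model, x) {
  if (!length(model$learners)) return(rep(0, nrow(x)))
  df <- data.frame(x)
  score <- rep(0, nrow(x))
  for (m in seq_along(model$learners)) {
    pred <- as.integer(as.character(
      stats::predict(model$learners[[m]], newdata = df, type = "class")))
    score <- score + model$alphas[m] * ifelse(pred == 1L, 1, -1)
  }
  score
}
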