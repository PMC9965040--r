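## Per-participant imbalance-aware classification protocol: stratified 10-fold
## CV; training folds balanced by random undersampling of the majority class
## and SMOTE-style oversampling of the minority class to the class-size mean;
## min-max scaling fitted on the balanced training data; metrics on the
## untouched (imbalanced) test fold with rare as the positive class.

#' Stratified k-fold plan
#'
#' Each class is shuffled and dealt round-robin into `k` folds, so each fold's
#' rare count differs by at most one from any other's; the test folds
#' partition the trials.
#'
#' @param labels binary 0/1 labels.
#' @param k number of folds (default 10, minimum 2).
#' @param seed integer seed; the plan is deterministic given the seed.
#' @return object of class `fold_plan`: list with `k`, `seed` and `folds`, a
#'   list of `k` lists with `train` and `test` index vectors.
#' @export
stratified_kfold <- function(labels, k = 10, seed = 1L) {
  labels <- as.integer(labels)
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  counts <- table(labels)
  if (length(counts) < 2L) stop("both classes must be present", call. = FALSE)
  if (min(counts) < k) {
    stop(sprintf("smallest class has %d trials, fewer than k = %d folds",
                 min(counts), k), call. = FALSE)
  }
  assignment <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      assignment[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  all_idx <- seq_along(labels)
  folds <- lapply(seq_len(k), function(f) {
    test <- which(assignment == f)
    list(train = setdiff(all_idx, test), test = test)
  })
  structure(list(k = k, seed = seed, folds = folds), class = "fold_plan")
}

#' Balance a training set (undersample majority, SMOTE the minority)
#'
#' Both classes are brought to the floor of the mean of the two training
#' class sizes: the majority class is randomly undersampled without
#' replacement; the minority class keeps its members and is augmented with
#' synthetic points, each generated by picking a random minority point `x`,
#' one of its `min(5, n_minority - 1)` nearest minority neighbours `z`
#' (Euclidean distance in the given, unscaled feature space), and emitting
#' `x + u * (z - x)` with `u ~ Uniform(0, 1)`. The balanced set is shuffled.
#'
#' @param x training feature matrix.
#' @param y binary training labels.
#' @param seed integer seed.
#' @param k_neighbors SMOTE neighbour count cap (default 5).
#' @return list with balanced `x` and `y`.
#' @export
balance_training <- function(x, y, seed = 1L, k_neighbors = 5) {
  x <- as.matrix(x)
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n0 == 0L || n1 == 0L) stop("both classes must be non-empty", call. = FALSE)
  minority <- if (n1 <= n0) 1L else 0L
  n_min <- min(n0, n1); n_maj <- max(n0, n1)
  if (n_min < 2L) {
    stop("minority class of size 1: SMOTE needs at least one neighbour",
         call. = FALSE)
  }
  target <- floor((n0 + n1) / 2)
  min_idx <- which(y == minority)
  maj_idx <- which(y != minority)
  xm <- x[min_idx, , drop = FALSE]
  kk <- min(k_neighbors, n_min - 1L)
  ## nearest minority neighbours of each minority point
  d2 <- as.matrix(stats::dist(xm))
  diag(d2) <- Inf
  nn <- apply(d2, 1, function(row) order(row)[seq_len(kk)])
  nn <- matrix(nn, ncol = n_min)            # kk x n_min
  with_seed(seed, {
    keep_maj <- sample(maj_idx, target)
    n_new <- target - n_min
    synth <- NULL
    if (n_new > 0) {
      base <- sample.int(n_min, n_new, replace = TRUE)
      pick <- vapply(base, function(b) nn[sample.int(kk, 1), b], integer(1))
      u <- stats::runif(n_new)
      synth <- xm[base, , drop = FALSE] +
        u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
    }
    bx <- rbind(x[min_idx, , drop = FALSE], synth, x[keep_maj, , drop = FALSE])
    by <- c(rep(minority, target), rep(1L - minority, target))
    ord <- sample.int(nrow(bx))
    list(x = bx[ord, , drop = FALSE], y = as.integer(by[ord]))
  })
}

#' Fit a min-max scaler on training features
#'
#' @param x training feature matrix.
#' @return object of class `minmax_scaler` (per-feature min and range).
#' @export
minmax_scale_fit <- function(x) {
  x <- as.matrix(x)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  structure(list(min = mins, range = maxs - mins), class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Maps each feature by `(x - min_train) / (max_train - min_train)`;
#' zero-range features map to 0; values outside the training range are not
#' clipped, so test values may fall outside `[0, 1]`.
#'
#' @param scaler a `minmax_scaler` from [minmax_scale_fit()].
#' @param x feature matrix to transform.
#' @return scaled matrix.
#' @export
minmax_scale_apply <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  x <- as.matrix(x)
  out <- sweep(x, 2, scaler$min, `-`)
  rng <- scaler$range
  rng[rng == 0] <- Inf                       # zero-range features -> 0
  sweep(out, 2, rng, `/`)
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney identity: `P(score_rare > score_frequent) + 0.5 P(tie)`,
#' computed from midranks, so it is invariant under strictly monotone
#' transformations of the scores.
#'
#' @param scores continuous scores, larger = more rare-like.
#' @param labels binary labels (1 = rare = positive).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute the AUROC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Classification metrics with rare as the positive class
#'
#' @param scores continuous scores (for the AUROC).
#' @param predicted hard 0/1 predictions.
#' @param labels true 0/1 labels.
#' @return one-row data.frame with accuracy, precision, recall, f1, auroc.
#'   Precision is `NA` when nothing is predicted positive; F1 is `NA` when
#'   either component is undefined or both are zero.
#' @export
classification_metrics <- function(scores, predicted, labels) {
  labels <- as.integer(labels); predicted <- as.integer(predicted)
  tp <- sum(predicted == 1L & labels == 1L)
  fp <- sum(predicted == 1L & labels == 0L)
  fn <- sum(predicted == 0L & labels == 1L)
  precision <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  data.frame(accuracy = mean(predicted == labels), precision = precision,
             recall = recall, f1 = f1, auroc = auroc(scores, labels))
}

#' Train and evaluate one classifier on one fold
#'
#' Expects an already balanced and scaled training set and an untouched (but
#' identically scaled) test set; fits the classifier and reports test-set
#' metrics with rare as the positive class. A single-class test fold yields
#' `NA` metrics with a warning.
#'
#' @param spec a [classifier_spec()].
#' @param train_x,train_y balanced, scaled training data.
#' @param test_x,test_y scaled test data with the session's class ratio.
#' @param seed integer seed for stochastic learners.
#' @return one-row data.frame of metrics (with `classifier` first).
#' @export
evaluate_fold <- function(spec, train_x, train_y, test_x, test_y, seed = 1L) {
  if (length(unique(as.integer(test_y))) < 2L) {
    warning(sprintf("single-class test fold for %s: metrics recorded as NA",
                    spec$name))
    return(data.frame(classifier = spec$name, accuracy = NA_real_,
                      precision = NA_real_, recall = NA_real_, f1 = NA_real_,
                      auroc = NA_real_))
  }
  fit <- fit_classifier(spec, train_x, train_y, seed = seed)
  m <- classification_metrics(predict_scores(fit, test_x),
                              predict_class(fit, test_x), test_y)
  cbind(data.frame(classifier = spec$name), m)
}

## Run the full per-fold protocol for one feature matrix; returns long records.
run_cv_protocol <- function(x, labels, specs, seed, k = 10,
                            keep_models = FALSE) {
  plan <- stratified_kfold(labels, k = k, seed = derive_seed(seed, 0L))
  records <- list()
  models <- if (keep_models) list() else NULL
  for (f in seq_len(plan$k)) {
    tr <- plan$folds[[f]]$train; te <- plan$folds[[f]]$test
    bal <- balance_training(x[tr, , drop = FALSE], labels[tr],
                            seed = derive_seed(seed, f, 1L))
    scaler <- minmax_scale_fit(bal$x)
    bx <- minmax_scale_apply(scaler, bal$x)
    tx <- minmax_scale_apply(scaler, x[te, , drop = FALSE])
    for (si in seq_along(specs)) {
      spec <- specs[[si]]
      rec <- evaluate_fold(spec, bx, bal$y, tx, labels[te],
                           seed = derive_seed(seed, f, 2L, si))
      rec$fold <- f
      records[[length(records) + 1L]] <- rec
      if (keep_models) {
        models[[length(models) + 1L]] <- list(
          classifier = spec$name, fold = f,
          fit = fit_classifier(spec, bx, bal$y,
                               seed = derive_seed(seed, f, 2L, si)),
          test_x = tx, test_y = labels[te])
      }
    }
  }
  out <- do.call(rbind, records)
  attr(out, "models") <- models
  out
}

#' Subset a feature object to the selected features
#'
#' @param features a `temporal_features` or `erp_features` object.
#' @param ranking a `feature_ranking` from [select_temporal()] or
#'   [select_erp()], or a character vector of feature names.
#' @return the same class of object restricted to the selected features.
#' @export
apply_selection <- function(features, ranking) {
  keep <- if (inherits(ranking, "feature_ranking")) {
    ranking$feature[ranking$selected]
  } else as.character(ranking)
  if (inherits(features, "temporal_features")) {
    idx <- match(keep, features$feature_names)
    if (anyNA(idx)) stop("unknown feature name in selection", call. = FALSE)
    features$values <- features$values[, , idx, drop = FALSE]
    features$feature_names <- keep
    features
  } else if (inherits(features, "erp_features")) {
    idx <- match(keep, colnames(features$values))
    if (anyNA(idx)) stop("unknown feature name in selection", call. = FALSE)
    features$values <- features$values[, idx, drop = FALSE]
    features
  } else {
    stop("`features` must be temporal_features or erp_features", call. = FALSE)
  }
}

new_decoding_result <- function(records, participant_id, group, static) {
  structure(records,
            participant_id = participant_id, group = group, static = static,
            class = c("decoding_result", "data.frame"))
}

#' Decode one participant's time-independent ERP features
#'
#' Full stratified-CV protocol (balancing, scaling, all classifiers) on the
#' static feature table; the per-participant score for a classifier is the
#' mean over folds.
#'
#' @param table an `erp_features` object (typically after [apply_selection()]).
#' @param specs list of [classifier_spec()] objects.
#' @param seed integer master seed; fold, balancing and classifier seeds are
#'   derived from it by a fixed counter scheme.
#' @param k folds (default 10).
#' @return a `decoding_result` data frame: classifier, accuracy, precision,
#'   recall, f1, auroc, fold, time_ms (`NA` for static).
#' @export
decode_static <- function(table, specs = default_classifier_specs(),
                          seed = 1L, k = 10) {
  stopifnot(inherits(table, "erp_features"))
  rec <- run_cv_protocol(table$values, table$labels, specs, seed, k = k)
  attr(rec, "models") <- NULL
  rec$time_ms <- NA_real_
  new_decoding_result(rec, table$participant_id, table$group, static = TRUE)
}

#' Decode one participant's temporal features per time point
#'
#' Repeats the complete CV + balancing + scaling protocol independently at
#' every requested time point, using the feature values at that time point.
#'
#' @param tensor a `temporal_features` object (typically after
#'   [apply_selection()]).
#' @param specs list of [classifier_spec()] objects.
#' @param seed integer master seed.
#' @param k folds (default 10).
#' @param time_indices which time points to decode (default all).
#' @return a `decoding_result` data frame with one block of fold records per
#'   time point (`time_ms` column).
#' @export
decode_timecourse <- function(tensor, specs = default_classifier_specs(),
                              seed = 1L, k = 10, time_indices = NULL) {
  stopifnot(inherits(tensor, "temporal_features"))
  nt <- dim(tensor$values)[2]
  if (is.null(time_indices)) time_indices <- seq_len(nt)
  out <- vector("list", length(time_indices))
  for (j in seq_along(time_indices)) {
    ti <- time_indices[j]
    x <- tensor$values[, ti, , drop = TRUE]
    x <- matrix(x, nrow = dim(tensor$values)[1])
    rec <- run_cv_protocol(x, tensor$labels, specs,
                           seed = derive_seed(seed, 1000L, ti), k = k)
    attr(rec, "models") <- NULL
    rec$time_ms <- tensor$times[ti]
    out[[j]] <- rec
  }
  new_decoding_result(do.call(rbind, out), tensor$participant_id,
                      tensor$group, static = FALSE)
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> participant %s (%s), %s: %d records\n",
              attr(x, "participant_id"), attr(x, "group"),
              if (attr(x, "static")) "static" else "timecourse", nrow(x)))
  invisible(x)
}

#' Summarise a decoding result
#'
#' @param object a `decoding_result`.
#' @param ... unused.
#' @return data.frame of fold-mean metrics per classifier (and per time point
#'   for timecourse results).
#' @export
summary.decoding_result <- function(object, ...) {
  df <- as.data.frame(object)
  by_cols <- if (attr(object, "static")) list(classifier = df$classifier) else
    list(classifier = df$classifier, time_ms = df$time_ms)
  out <- aggregate(df[c("accuracy", "precision", "recall", "f1", "auroc")],
                   by = by_cols, FUN = mean, na.rm = TRUE)
  out[order(out$classifier), , drop = FALSE]
}

#' Plot the AUROC timecourse of a decoding result
#'
#' @param x a timecourse `decoding_result`.
#' @param metric metric column to plot (default `"auroc"`).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.decoding_result <- function(x, metric = "auroc", ...) {
  s <- summary(x)
  if (attr(x, "static")) {
    graphics::barplot(s[[metric]], names.arg = s$classifier, las = 2,
                      ylab = metric, ...)
    return(invisible(x))
  }
  wide <- stats::reshape(s[c("classifier", "time_ms", metric)],
                         idvar = "time_ms", timevar = "classifier",
                         direction = "wide")
  wide <- wide[order(wide$time_ms), ]
  graphics::matplot(wide$time_ms, as.matrix(wide[, -1, drop = FALSE]),
                    type = "l", lty = 1, xlab = "time (ms)", ylab = metric, ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey")
  graphics::abline(v = 0, lty = 2, col = "grey")
  invisible(x)
}
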