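## Permutation-based feature importance, per classifier and age group, over
## time (temporal dataset) or once (statistical dataset).

#' Permutation importance of each feature for a fitted classifier
#'
#' For each feature column of the test set, the column is shuffled
#' `n_repeats` times (all other columns fixed); the importance is the
#' baseline metric minus the mean permuted metric. Negative values indicate
#' permutation noise.
#'
#' @param fit an `erp_classifier` from [fit_classifier()].
#' @param test_x,test_y test features and labels (both classes present).
#' @param metric function of `(scores, labels)` returning a scalar (default
#'   [auroc()]).
#' @param n_repeats shuffles per feature (default 10).
#' @param seed integer seed.
#' @param feature_names optional names for the output (default `f1..fp`).
#' @return data.frame with columns `feature`, `importance`, `n_repeats`; the
#'   baseline metric is attached as attribute `baseline`.
#' @export
permutation_importance <- function(fit, test_x, test_y, metric = auroc,
                                   n_repeats = 10, seed = 1L,
                                   feature_names = NULL) {
  test_x <- as.matrix(test_x)
  baseline <- metric(predict_scores(fit, test_x), test_y)
  p <- ncol(test_x)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(p))
  imp <- numeric(p)
  with_seed(seed, {
    for (j in seq_len(p)) {
      drop <- numeric(n_repeats)
      for (r in seq_len(n_repeats)) {
        xp <- test_x
        xp[, j] <- xp[sample.int(nrow(xp)), j]
        drop[r] <- metric(predict_scores(fit, xp), test_y)
      }
      imp[j] <- baseline - mean(drop)
    }
  })
  out <- data.frame(feature = feature_names, importance = imp,
                    n_repeats = n_repeats)
  attr(out, "baseline") <- baseline
  out
}

## per-participant importance for one feature matrix: CV protocol with models
## retained, importance computed on each (scaled, imbalanced) test fold and
## averaged over folds.
importance_one_matrix <- function(x, labels, spec, seed, k, n_repeats,
                                  feature_names) {
  rec <- run_cv_protocol(x, labels, list(spec), seed, k = k,
                         keep_models = TRUE)
  models <- attr(rec, "models")
  per_fold <- lapply(seq_along(models), function(mi) {
    m <- models[[mi]]
    permutation_importance(m$fit, m$test_x, m$test_y, n_repeats = n_repeats,
                           seed = derive_seed(seed, 5L, mi),
                           feature_names = feature_names)$importance
  })
  rowMeans(do.call(cbind, per_fold))
}

#' Group-averaged permutation importance profiles
#'
#' Runs the full CV protocol per participant with the given classifier,
#' computes permutation importance on every test fold, averages over folds
#' within participant and then (unweighted) over participants within each age
#' group. For temporal features this is repeated at each requested time
#' point; for static ERP features it is computed once.
#'
#' @param feature_sets list of `temporal_features` or `erp_features` objects
#'   (one per participant, same type, typically after [apply_selection()]).
#' @param spec a single [classifier_spec()].
#' @param seed integer master seed.
#' @param k CV folds (default 10).
#' @param n_repeats permutation repeats (default 10).
#' @param time_indices time points to profile (temporal input only; default
#'   all).
#' @return object of class `importance_profile`: long data.frame with columns
#'   `classifier`, `group`, `feature`, `time_ms` (`NA` for static),
#'   `importance`, `n_repeats`.
#' @export
importance_profile <- function(feature_sets, spec, seed = 1L, k = 10,
                               n_repeats = 10, time_indices = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  temporal <- inherits(feature_sets[[1]], "temporal_features")
  groups <- vapply(feature_sets, `[[`, character(1), "group")
  rows <- list()
  for (g in unique(groups)) {
    sets <- feature_sets[groups == g]
    if (temporal) {
      nt <- dim(sets[[1]]$values)[2]
      tidx <- if (is.null(time_indices)) seq_len(nt) else time_indices
      fn <- sets[[1]]$feature_names
      for (ti in tidx) {
        per_part <- lapply(seq_along(sets), function(pi) {
          s <- sets[[pi]]
          x <- matrix(s$values[, ti, , drop = TRUE], nrow = dim(s$values)[1])
          importance_one_matrix(x, s$labels, spec,
                                derive_seed(seed, 1000L, ti, pi), k,
                                n_repeats, fn)
        })
        imp <- rowMeans(do.call(cbind, per_part))
        rows[[length(rows) + 1L]] <- data.frame(
          classifier = spec$name, group = g, feature = fn,
          time_ms = sets[[1]]$times[ti], importance = imp,
          n_repeats = n_repeats)
      }
    } else {
      fn <- colnames(sets[[1]]$values)
      per_part <- lapply(seq_along(sets), function(pi) {
        s <- sets[[pi]]
        importance_one_matrix(s$values, s$labels, spec,
                              derive_seed(seed, 2000L, pi), k, n_repeats, fn)
      })
      imp <- rowMeans(do.call(cbind, per_part))
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = spec$name, group = g, feature = fn, time_ms = NA_real_,
        importance = imp, n_repeats = n_repeats)
    }
  }
  structure(do.call(rbind, rows),
            class = c("importance_profile", "data.frame"))
}

#' Plot importance profiles
#'
#' Temporal profiles as importance-versus-time lines per feature, one panel
#' per age group; static profiles as a bar chart.
#'
#' @param x an `importance_profile`.
#' @param ... unused.
#' @export
plot.importance_profile <- function(x, ...) {
  df <- as.data.frame(x)
  groups <- unique(df$group)
  if (all(is.na(df$time_ms))) {
    old <- graphics::par(mfrow = c(1, length(groups)), mar = c(8, 4, 2, 1))
    on.exit(graphics::par(old))
    for (g in groups) {
      sub <- df[df$group == g, ]
      graphics::barplot(sub$importance, names.arg = sub$feature, las = 2,
                        main = g, ylab = "AUROC drop", cex.names = 0.7)
    }
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(length(groups), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (g in groups) {
    sub <- df[df$group == g, ]
    wide <- stats::reshape(sub[c("feature", "time_ms", "importance")],
                           idvar = "time_ms", timevar = "feature",
                           direction = "wide")
    wide <- wide[order(wide$time_ms), ]
    graphics::matplot(wide$time_ms, as.matrix(wide[, -1, drop = FALSE]),
                      type = "l", lty = 1, xlab = "time (ms)",
                      ylab = "AUROC drop", main = g)
    graphics::abline(v = 0, lty = 2, col = "grey")
  }
  invisible(x)
}
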