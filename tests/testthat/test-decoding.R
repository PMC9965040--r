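# CV plan, balancing, scaling, AUROC and the decoding protocol.

test_that("stratified folds partition trials and spread the rare class evenly", {
  labels <- rep(c(0, 1), c(124, 23))
  plan <- stratified_kfold(labels, k = 10, seed = 3)
  test_sets <- lapply(plan$folds, `[[`, "test")
  expect_identical(sort(unlist(test_sets)), 1:147)
  rare_counts <- vapply(test_sets, function(i) sum(labels[i]), numeric(1))
  expect_true(all(rare_counts %in% c(2, 3)))
  # train/test are complementary
  for (f in plan$folds) expect_identical(sort(c(f$train, f$test)), 1:147)
  # deterministic under the seed
  expect_identical(plan, stratified_kfold(labels, k = 10, seed = 3))
  expect_false(identical(plan, stratified_kfold(labels, k = 10, seed = 4)))
})

test_that("degenerate fold requests are rejected", {
  labels <- rep(c(0, 1), c(124, 23))
  expect_error(stratified_kfold(labels, k = 1), "at least 2")
  expect_error(stratified_kfold(rep(c(0, 1), c(140, 7)), k = 10), "fewer than")
  expect_error(stratified_kfold(rep(0, 50), k = 5), "both classes")
})

test_that("balancing hits the class-size mean from both sides", {
  set.seed(8)
  x <- matrix(rnorm(132 * 5), 132, 5)
  y <- rep(c(0, 1), c(112, 20))
  bal <- balance_training(x, y, seed = 1)
  expect_identical(sum(bal$y == 0L), 66L)      # the study's balanced size
  expect_identical(sum(bal$y == 1L), 66L)
  # undersampled majority rows are original rows
  maj_rows <- bal$x[bal$y == 0L, ]
  expect_true(all(apply(maj_rows, 1, function(r) {
    any(colSums(abs(t(x[1:112, ]) - r)) < 1e-12)
  })))
  # already balanced input keeps its sizes
  y2 <- rep(c(0, 1), each = 30)
  bal2 <- balance_training(x[1:60, ], y2, seed = 2)
  expect_identical(as.vector(table(bal2$y)), c(30L, 30L))
})

test_that("SMOTE points interpolate between minority neighbours", {
  # identical minority points can only generate themselves
  x <- rbind(matrix(5, 4, 3), matrix(rnorm(60, sd = 0.1), 20, 3))
  y <- rep(c(1, 0), c(4, 20))
  bal <- balance_training(x, y, seed = 6)
  minority <- bal$x[bal$y == 1L, ]
  expect_true(all(abs(minority - 5) < 1e-12))
  # synthetic points lie on segments between minority members
  set.seed(12)
  xm <- matrix(runif(10 * 2), 10, 2)
  x2 <- rbind(xm, matrix(rnorm(80 * 2, mean = 4), 80, 2))
  y2 <- rep(c(1, 0), c(10, 80))
  bal2 <- balance_training(x2, y2, seed = 3)
  new_pts <- bal2$x[bal2$y == 1L, ]
  expect_true(all(new_pts[, 1] >= min(xm[, 1]) - 1e-9 &
                    new_pts[, 1] <= max(xm[, 1]) + 1e-9))
  # a singleton minority cannot be oversampled
  expect_error(balance_training(x2[c(1, 11:30), ], rep(c(1, 0), c(1, 20))),
               "minority")
})

test_that("min-max scaling follows the train-only contract", {
  train <- matrix(c(2, 4, 3, 1, 1, 1), ncol = 2)   # ranges [2,4] and {1}
  sc <- minmax_scale_fit(train)
  out <- minmax_scale_apply(sc, matrix(c(3, 5, 1, 9), ncol = 2))
  expect_equal(out[1, 1], 0.5)
  expect_equal(out[2, 1], 1.5)          # outside the training range: no clip
  expect_equal(out[, 2], c(0, 0))       # zero-range feature always maps to 0
  expect_equal(minmax_scale_apply(sc, train)[, 2], c(0, 0, 0))
})

test_that("the rank-based AUROC matches the exhaustive pairwise oracle", {
  oracle <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.3))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)   # forces ties
    expect_equal(auroc(s, y), oracle(s, y), tolerance = 1e-12)
  }
  expect_identical(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_identical(auroc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(15)
  s <- rnorm(60); y <- rbinom(60, 1, 0.25)
  expect_equal(auroc(exp(s), y), auroc(s, y))
  expect_equal(auroc(rank(s), y), auroc(s, y))
})

test_that("a majority-class predictor shows high accuracy but chance AUROC", {
  y <- rep(c(0, 1), c(124, 23))
  m <- classification_metrics(scores = rep(0.2, 147),
                              predicted = rep(0L, 147), labels = y)
  expect_equal(m$accuracy, 124 / 147)
  expect_equal(m$recall, 0)
  expect_identical(m$auroc, 0.5)
  expect_true(is.na(m$precision))
})

test_that("every classifier separates a linearly separable problem", {
  set.seed(16)
  train_x <- rbind(matrix(rnorm(120, mean = 0, sd = 0.3), ncol = 2),
                   matrix(rnorm(40, mean = 3, sd = 0.3), ncol = 2))
  train_y <- rep(c(0, 1), c(60, 20))
  test_x <- rbind(matrix(rnorm(40, 0, 0.3), ncol = 2),
                  matrix(rnorm(20, 3, 0.3), ncol = 2))
  test_y <- rep(c(0, 1), c(20, 10))
  for (nm in c("lda", "logreg", "svc_lin", "svc_rbf", "knn", "tree", "rf",
               "adaboost", "xgb")) {
    rec <- evaluate_fold(classifier_spec(nm), train_x, train_y,
                         test_x, test_y, seed = 5)
    expect_equal(rec$auroc, 1, tolerance = 1e-9, label = nm)
    expect_gt(rec$accuracy, 0.95)
  }
})

test_that("the LDA backend agrees with the closed-form pooled discriminant", {
  set.seed(17)
  train_x <- rbind(matrix(rnorm(200), ncol = 4),
                   matrix(rnorm(120, mean = 0.8), ncol = 4))
  train_y <- rep(c(0, 1), c(50, 30))
  test_x <- matrix(rnorm(80), ncol = 4)
  fit <- fit_classifier(classifier_spec("lda"), train_x, train_y)
  post <- predict_scores(fit, test_x)
  ref <- erpdecode:::lda_discriminant_scores(train_x, train_y, test_x)
  # the posterior is the logistic transform of the discriminant score
  expect_equal(post, plogis(ref), tolerance = 1e-6)
  yy <- rep(c(0, 1), 10)
  expect_equal(auroc(post, yy), auroc(ref, yy))
})

test_that("identical feature rows decode exactly at chance", {
  tab <- make_erp_features(matrix(1, 100, 4), rep(c(0, 1), c(80, 20)))
  res <- decode_static(tab, default_classifier_specs(c("lda", "tree")),
                       seed = 2, k = 5)
  s <- summary(res)
  expect_true(all(s$auroc == 0.5))
})

test_that("shuffled labels decode at chance on real simulated features", {
  cfg <- desk_config_sim(n_young = 1, n_older = 0, seed = 6)
  es <- simulate_participant(default_group_profiles()$young, cfg, 18)
  with_seed <- erpdecode:::with_seed
  es$labels <- with_seed(9L, sample(es$labels))
  tab <- build_erp_features(es)
  tab$values <- tab$values[, grepl("peak", colnames(tab$values))]
  res <- decode_static(tab, default_classifier_specs("lda"), seed = 3)
  fold_auc <- as.data.frame(res)$auroc
  se <- sd(fold_auc) / sqrt(length(fold_auc))
  expect_lt(abs(mean(fold_auc) - 0.5), 3 * se + 0.05)
})

test_that("a single decoded time point equals the static protocol on that slice", {
  cfg <- desk_config_sim(n_young = 1, n_older = 0,
                         trials_per_participant = 60, n_rare = 12, seed = 10)
  es <- simulate_participant(default_group_profiles()$young, cfg, 21)
  tf <- build_temporal_features(es)
  keep <- c("amp_occipital", "amp_central", "pow_4Hz_central")
  tf <- apply_selection(tf, keep)
  ti <- 30L
  specs <- default_classifier_specs(c("lda", "knn"))
  tc <- decode_timecourse(tf, specs, seed = 11, k = 5, time_indices = ti)
  slice <- matrix(tf$values[, ti, ], nrow = 60)
  colnames(slice) <- keep
  tab <- make_erp_features(slice, tf$labels)
  st <- decode_static(tab, specs, seed = erpdecode:::derive_seed(11L, 1000L, ti),
                      k = 5)
  expect_equal(as.data.frame(tc)[, c("classifier", "accuracy", "auroc")],
               as.data.frame(st)[, c("classifier", "accuracy", "auroc")],
               tolerance = 1e-12)
})

test_that("the protocol never balances or rescales the test fold", {
  labels <- rep(c(0, 1), c(124, 23))
  plan <- stratified_kfold(labels, k = 10, seed = 5)
  for (f in plan$folds) {
    # test-fold class ratio mirrors the session ratio (2 or 3 rare of ~15)
    expect_true(sum(labels[f$test]) %in% c(2, 3))
    expect_identical(length(f$test) + length(f$train), 147L)
  }
})
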