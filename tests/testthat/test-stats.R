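# Friedman/Wilcoxon/Nemenyi machinery, CD diagrams, age tests, intervals.

test_that("the Friedman statistic matches stats::friedman.test", {
  set.seed(19)
  for (rep in 1:30) {
    n <- sample(6:15, 1); k <- sample(3:9, 1)
    m <- matrix(rnorm(n * k), n, k)
    got <- friedman_rank_test(m)
    want <- friedman.test(m)
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
  }
  # with ties (duplicated columns partially)
  m <- matrix(rnorm(8 * 4), 8, 4)
  m[, 2] <- m[, 1]
  got <- friedman_rank_test(m)
  want <- friedman.test(m)
  expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-12)
})

test_that("degenerate and dominant score matrices behave as required", {
  # all classifiers identical per participant
  m <- matrix(rep(rnorm(10), 4), 10, 4)
  got <- friedman_rank_test(m)
  expect_identical(got$statistic, 0)
  expect_identical(got$p_value, 1)
  # strictly dominant ordering attains the distribution-free maximum N(k-1)
  n <- 12; k <- 5
  m2 <- t(replicate(n, sort(rnorm(k))))
  got2 <- friedman_rank_test(m2)
  expect_equal(got2$statistic, 12 * sum((1:k - (k + 1) / 2)^2) * n^2 /
                 (n * k * (k + 1)), tolerance = 1e-12)
  # mean ranks sum to k(k+1)/2
  expect_equal(sum(got2$mean_ranks), k * (k + 1) / 2)
})

test_that("Holm adjustment follows its step-down definition", {
  set.seed(20)
  m <- matrix(rnorm(12 * 4), 12, 4)
  colnames(m) <- paste0("c", 1:4)
  pw <- pairwise_wilcoxon_holm(m)
  praw <- pw$p_raw[upper.tri(pw$p_raw)]
  padj <- pw$p_adjusted[upper.tri(pw$p_adjusted)]
  expect_true(all(padj >= praw - 1e-12))
  # smallest raw p is multiplied by the number of hypotheses (capped at 1)
  expect_equal(min(padj), min(1, length(praw) * min(praw)))
  expect_equal(padj, p.adjust(praw, "holm"), ignore_attr = TRUE)
  # identical columns give p = 1
  m2 <- cbind(a = m[, 1], b = m[, 1], c = m[, 2])
  pw2 <- pairwise_wilcoxon_holm(m2)
  expect_identical(pw2$p_raw["a", "b"], 1)
  expect_identical(pw2$p_adjusted["a", "b"], 1)
})

test_that("the Nemenyi critical distance reproduces tabulated values and scaling", {
  # studentized-range constants (alpha = 0.05) from the standard table
  q05 <- c(`2` = 1.960, `3` = 2.343, `4` = 2.569, `5` = 2.728, `6` = 2.850,
           `7` = 2.949, `8` = 3.031, `9` = 3.102, `10` = 3.164)
  for (k in 2:10) {
    q <- qtukey(0.95, k, Inf) / sqrt(2)
    expect_equal(q, unname(q05[as.character(k)]), tolerance = 5e-4)
    expect_equal(nemenyi_cd(k, 50), q * sqrt(k * (k + 1) / (6 * 50)),
                 tolerance = 1e-9)
  }
  # the study geometry: 9 classifiers, 70 participants
  cd <- nemenyi_cd(9, 70)
  expect_gte(cd, 1.34)
  expect_lte(cd, 1.56)
  # k = 2 scales as 1/sqrt(N); quadrupling N halves the CD
  expect_equal(nemenyi_cd(2, 9) / nemenyi_cd(2, 36), 2, tolerance = 1e-12)
  expect_equal(nemenyi_cd(7, 40) / nemenyi_cd(7, 160), 2, tolerance = 1e-12)
  expect_error(nemenyi_cd(9, 70, alpha = 1.2), "alpha")
})

test_that("the CD diagram groups classifiers by non-significant differences", {
  set.seed(21)
  n <- 20
  # three well-separated performance tiers, two classifiers each
  tiers <- c(0, 0, 1, 1, 2, 2)
  m <- sapply(tiers, function(mu) mu + rnorm(n, sd = 0.05))
  colnames(m) <- paste0("clf", 1:6)
  cmp <- compare_classifiers(m)
  dg <- cd_diagram(cmp)
  expect_identical(length(dg$groups), 3L)
  sizes <- sort(vapply(dg$groups, length, integer(1)))
  expect_identical(sizes, c(2L, 2L, 2L))
  # nothing significant -> a single group containing everyone
  m2 <- matrix(rnorm(5 * 4, sd = 1e-3), 5, 4) + rnorm(5)
  colnames(m2) <- paste0("c", 1:4)
  dg2 <- cd_diagram(compare_classifiers(m2))
  expect_identical(length(dg2$groups), 1L)
  expect_length(dg2$groups[[1]], 4L)
})

test_that("time-resolved comparison marks clusters only when Friedman allows", {
  set.seed(22)
  n <- 25; k <- 5; nt <- 8
  nm <- c("lda", "logreg", "svc_lin", "rf", "tree")
  arr <- array(rnorm(n * k * nt, sd = 0.01) + 0.5, dim = c(n, k, nt),
               dimnames = list(NULL, nm, NULL))
  # chance-level first half: every classifier scores identically
  arr[, , 1:4] <- 0.5
  # in the second half, the linear trio jumps ahead
  for (ti in 5:8) {
    arr[, c("lda", "logreg", "svc_lin"), ti] <-
      arr[, c("lda", "logreg", "svc_lin"), ti] + 0.3
  }
  out <- cd_over_time(arr, times = seq(-100, 250, by = 50),
                      representatives = c("lda", "rf"))
  # chance-level first half: no Friedman significance, no markers
  expect_true(all(out$friedman_p[1:4] > 0.05))
  expect_false(any(out$membership[1:4, , ]))
  # second half: lda clusters with exactly the linear trio
  for (ti in 5:8) {
    expect_true(out$friedman_p[ti] <= 0.05)
    expect_identical(sort(nm[out$membership[ti, , "lda"]]),
                     sort(c("lda", "logreg", "svc_lin")))
    expect_identical(sort(nm[out$membership[ti, , "rf"]]),
                     sort(c("rf", "tree")))
  }
  # all-equal scores: no markers anywhere
  arr2 <- array(0.5, dim = c(n, k, nt), dimnames = list(NULL, nm, NULL))
  out2 <- cd_over_time(arr2, times = seq_len(nt), representatives = "lda")
  expect_false(any(out2$membership))
})

test_that("age comparison handles identity, label swap and real power", {
  scores <- data.frame(
    participant = c(paste0("y", 1:10), paste0("o", 1:10)),
    group = rep(c("young", "older"), each = 10),
    classifier = "lda", dataset = "statistical",
    score = rep(seq(0.5, 0.95, length.out = 10), 2))
  cmp <- age_compare(scores)
  tt <- cmp$lda$t_tests$statistical
  expect_equal(tt$p, 1, tolerance = 1e-12)
  expect_equal(tt$mean_young, tt$mean_older)

  set.seed(24)
  scores$score <- scores$score + rnorm(20, sd = 0.02)
  a <- age_compare(scores)$lda$t_tests$statistical
  swapped <- scores
  swapped$group <- ifelse(scores$group == "young", "older", "young")
  b <- age_compare(swapped)$lda$t_tests$statistical
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)

  # a 0.06 AUROC gap (sd 0.1) at n = 27/43: the empirical detection rate
  # matches the analytic noncentral-t power (about 0.67)
  ncp <- 0.06 / (0.1 * sqrt(1 / 27 + 1 / 43))
  crit <- qt(0.975, 68)
  power <- 1 - pt(crit, 68, ncp) + pt(-crit, 68, ncp)
  set.seed(25)
  hits <- 0
  for (rep in 1:200) {
    y <- rnorm(27, 0.80, 0.1); o <- rnorm(43, 0.74, 0.1)
    hits <- hits + (t.test(y, o, var.equal = TRUE)$p.value < 0.05)
  }
  expect_lt(abs(hits / 200 - power), 0.1)
  expect_gt(hits / 200, 0.5)
})

test_that("participant maxima and significance intervals follow their contracts", {
  s <- data.frame(classifier = "lda", time_ms = seq(-100, 300, by = 50),
                  auroc = 0.7)
  expect_identical(max_auroc_per_participant(s), 0.7)
  s$auroc <- seq(0.5, 0.9, length.out = nrow(s))
  expect_identical(max_auroc_per_participant(s), 0.9)
  expect_gte(max_auroc_per_participant(s), mean(s$auroc))
  # post-stimulus restriction
  s$auroc <- rev(seq(0.5, 0.9, length.out = nrow(s)))
  expect_identical(max_auroc_per_participant(s, post_stimulus_only = TRUE),
                   s$auroc[s$time_ms == 0])

  times <- seq(0, 90, by = 10)
  p <- rep(0.5, 10)
  expect_identical(nrow(significant_intervals(times, p)), 0L)
  p[4] <- 0.001
  one <- significant_intervals(times, p)
  expect_equal(one, data.frame(t_start = 30, t_end = 30))
  p <- c(0.001, 0.002, 0.5, 0.5, 0.003, 0.004, 0.002, 0.5, 0.5, 0.5)
  two <- significant_intervals(times, p)
  expect_equal(two, data.frame(t_start = c(0, 40), t_end = c(10, 60)))
})
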