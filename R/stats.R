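## Classifier comparison machinery: Friedman test, Holm-corrected pairwise
## Wilcoxon signed-rank tests, Nemenyi critical distance and the critical
## difference (CD) diagram, its time-resolved extension, and age-group tests.

#' Friedman test on a participants-by-classifiers score matrix
#'
#' Scores are ranked within each participant (average ranks for ties); the
#' chi-square-form statistic with the tie correction is referred to a
#' chi-square distribution with `k - 1` degrees of freedom. A matrix in which
#' every participant ranks all classifiers equally returns statistic 0 and
#' p-value 1.
#'
#' @param scores numeric matrix, rows = participants (N >= 2), columns =
#'   classifiers (k >= 3).
#' @return list with `statistic`, `p_value`, `mean_ranks` (rank 1 = best,
#'   i.e. ranks of the negated scores).
#' @export
friedman_rank_test <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  if (k < 3) stop("need at least 3 classifiers", call. = FALSE)
  r <- t(apply(scores, 1, rank))
  ## tie-corrected chi-square form
  tie_term <- sum(apply(r, 1, function(u) {
    t <- table(u); sum(t^3 - t)
  }))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  if (denom <= 0) {
    stat <- 0
  } else {
    stat <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2) / denom
  }
  mean_ranks <- colMeans(t(apply(-scores, 1, rank)))
  names(mean_ranks) <- colnames(scores)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
       mean_ranks = mean_ranks)
}

#' Holm-corrected pairwise Wilcoxon signed-rank tests
#'
#' One signed-rank test per classifier pair on the within-participant score
#' differences, Holm step-down adjusted over all `k (k - 1) / 2` pairs. A
#' pair with all-zero differences is recorded with p = 1.
#'
#' @param scores participants x classifiers matrix.
#' @param exact passed to [stats::wilcox.test()] (default FALSE: the normal
#'   approximation, appropriate at the study's N = 70).
#' @return list with `p_raw` and `p_adjusted`, symmetric k x k matrices
#'   (diagonal NA).
#' @export
pairwise_wilcoxon_holm <- function(scores, exact = FALSE) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  nm <- colnames(scores)
  if (is.null(nm)) nm <- paste0("clf", seq_len(k))
  p_raw <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  pairs <- utils::combn(k, 2)
  praw <- apply(pairs, 2, function(ij) {
    d <- scores[, ij[1]] - scores[, ij[2]]
    if (all(d == 0)) return(1)
    suppressWarnings(
      stats::wilcox.test(d, exact = exact, correct = TRUE)$p.value)
  })
  p_adj_vec <- stats::p.adjust(praw, method = "holm")
  p_adj <- p_raw
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    p_raw[i1, i2] <- p_raw[i2, i1] <- praw[j]
    p_adj[i1, i2] <- p_adj[i2, i1] <- p_adj_vec[j]
  }
  list(p_raw = p_raw, p_adjusted = p_adj)
}

#' Nemenyi critical distance
#'
#' `CD = q_alpha(k) * sqrt(k (k + 1) / (6 N))`, where `q_alpha(k)` is the
#' studentized-range quantile (infinite degrees of freedom) divided by
#' `sqrt(2)`. For the study's 9 classifiers and 70 participants at alpha
#' 0.05 the value is about 1.44 rank units.
#'
#' @param k number of classifiers (>= 2).
#' @param n_participants number of participants (>= 1).
#' @param alpha significance level in (0, 1), default 0.05.
#' @return critical distance in rank units.
#' @examples
#' nemenyi_cd(9, 70)
#' @export
nemenyi_cd <- function(k, n_participants, alpha = 0.05) {
  stopifnot_scalar_number(k, "k", lower = 2)
  stopifnot_scalar_number(n_participants, "n_participants", lower = 1)
  if (alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  q <- stats::qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2)
  q * sqrt(k * (k + 1) / (6 * n_participants))
}

#' Compare classifiers on a score matrix
#'
#' Runs the Friedman test, the Holm-corrected pairwise Wilcoxon tests and the
#' Nemenyi critical distance on one participants x classifiers AUROC matrix.
#'
#' @param scores participants x classifiers matrix (column names = classifier
#'   names).
#' @param alpha significance level (default 0.05).
#' @return object of class `classifier_comparison`: mean ranks, Friedman
#'   statistic and p, raw/adjusted pairwise p matrices, `cd_value`, `alpha`,
#'   `n_participants`.
#' @export
compare_classifiers <- function(scores, alpha = 0.05) {
  scores <- as.matrix(scores)
  fr <- friedman_rank_test(scores)
  pw <- pairwise_wilcoxon_holm(scores)
  structure(
    list(mean_ranks = fr$mean_ranks, friedman_stat = fr$statistic,
         friedman_p = fr$p_value, p_raw = pw$p_raw,
         p_adjusted = pw$p_adjusted,
         cd_value = nemenyi_cd(ncol(scores), nrow(scores), alpha),
         alpha = alpha, n_participants = nrow(scores)),
    class = "classifier_comparison"
  )
}

#' @export
print.classifier_comparison <- function(x, ...) {
  cat(sprintf(
    "<classifier_comparison> N = %d, k = %d: Friedman chi^2 = %.3f (p = %.3g), Nemenyi CD = %.3f\n",
    x$n_participants, length(x$mean_ranks), x$friedman_stat, x$friedman_p,
    x$cd_value))
  print(sort(x$mean_ranks))
  invisible(x)
}

#' Critical difference diagram structure
#'
#' Orders the classifiers by mean rank and groups together maximal sets,
#' contiguous in rank order, within which no pairwise difference is
#' significant (all Holm-adjusted p > alpha).
#'
#' @param comparison a `classifier_comparison` from [compare_classifiers()].
#' @return object of class `cd_diagram`: `order` (classifier names by
#'   increasing mean rank), `mean_ranks`, `cd_value`, `groups` (list of
#'   character vectors).
#' @export
cd_diagram <- function(comparison) {
  stopifnot(inherits(comparison, "classifier_comparison"))
  ranks <- sort(comparison$mean_ranks)
  nm <- names(ranks)
  k <- length(nm)
  alpha <- comparison$alpha
  padj <- comparison$p_adjusted[nm, nm]
  groups <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(padj[i:(j + 1), i:(j + 1)] > alpha, na.rm = TRUE)) {
      j <- j + 1
    }
    groups[[length(groups) + 1L]] <- nm[i:j]
  }
  ## drop groups contained in another
  keep <- vapply(seq_along(groups), function(a) {
    !any(vapply(seq_along(groups), function(b) {
      b != a && all(groups[[a]] %in% groups[[b]])
    }, logical(1)))
  }, logical(1))
  groups <- unique(groups[keep])
  structure(list(order = nm, mean_ranks = ranks,
                 cd_value = comparison$cd_value, groups = groups),
            class = "cd_diagram")
}

#' @export
print.cd_diagram <- function(x, ...) {
  cat(sprintf("<cd_diagram> CD = %.3f\n", x$cd_value))
  for (i in seq_along(x$order)) {
    cat(sprintf("  %5.2f  %s\n", x$mean_ranks[i], x$order[i]))
  }
  cat("groups:", paste(vapply(x$groups, paste, character(1), collapse = "+"),
                       collapse = " | "), "\n")
  invisible(x)
}

#' Plot a critical difference diagram
#'
#' Classifiers on a mean-rank axis; horizontal bars join groups whose
#' pairwise differences are not significant.
#'
#' @param x a `cd_diagram`.
#' @param ... unused.
#' @export
plot.cd_diagram <- function(x, ...) {
  k <- length(x$order)
  graphics::plot(NULL, xlim = range(x$mean_ranks) + c(-0.5, 0.5),
                 ylim = c(0, k + 1 + length(x$groups)), xlab = "mean rank",
                 ylab = "", yaxt = "n", main = sprintf("CD = %.2f", x$cd_value))
  graphics::points(x$mean_ranks, seq_len(k), pch = 19)
  graphics::text(x$mean_ranks, seq_len(k), labels = x$order, pos = 4, cex = 0.8)
  for (g in seq_along(x$groups)) {
    members <- x$groups[[g]]
    if (length(members) < 2) next
    r <- x$mean_ranks[members]
    graphics::segments(min(r), k + g, max(r), k + g, lwd = 3)
  }
  invisible(x)
}

#' Time-resolved critical difference comparison
#'
#' At each time point: a Friedman test over the per-participant AUROC scores;
#' only when it is significant (p <= alpha) are Holm-corrected pairwise
#' Wilcoxon tests computed, and classifier `j` joins representative `r`'s
#' cluster iff their adjusted p-value exceeds alpha (no significant
#' difference). At times where the Friedman test is not significant no
#' cluster markers are recorded.
#'
#' @param score_array participants x classifiers x time array of AUROC scores
#'   (dimnames on classifiers), or a list of participants x classifiers
#'   matrices, one per time point.
#' @param times time axis in ms (one per time point).
#' @param representatives classifier names anchoring the clusters (default
#'   `c("lda", "rf", "xgb", "knn")`).
#' @param alpha significance level (default 0.05).
#' @return object of class `cd_over_time`: `times`, `friedman_p`,
#'   `mean_ranks` (time x classifier), `membership` (time x classifier x
#'   representative logical array; all-FALSE slices where Friedman was not
#'   significant), `alpha`.
#' @export
cd_over_time <- function(score_array, times,
                         representatives = c("lda", "rf", "xgb", "knn"),
                         alpha = 0.05) {
  if (is.list(score_array)) {
    mats <- score_array
  } else {
    mats <- lapply(seq_len(dim(score_array)[3]), function(ti) {
      m <- score_array[, , ti, drop = TRUE]
      matrix(m, ncol = dim(score_array)[2],
             dimnames = list(NULL, dimnames(score_array)[[2]]))
    })
  }
  stopifnot(length(mats) == length(times))
  nm <- colnames(mats[[1]])
  representatives <- intersect(representatives, nm)
  if (!length(representatives)) {
    stop("no representative classifier present in the score matrix", call. = FALSE)
  }
  nt <- length(times)
  friedman_p <- numeric(nt)
  mean_ranks <- matrix(NA_real_, nt, length(nm), dimnames = list(NULL, nm))
  membership <- array(FALSE, dim = c(nt, length(nm), length(representatives)),
                      dimnames = list(NULL, nm, representatives))
  for (ti in seq_len(nt)) {
    fr <- friedman_rank_test(mats[[ti]])
    friedman_p[ti] <- fr$p_value
    mean_ranks[ti, ] <- fr$mean_ranks[nm]
    if (is.na(fr$p_value) || fr$p_value > alpha) next
    pw <- pairwise_wilcoxon_holm(mats[[ti]])
    for (r in representatives) {
      membership[ti, r, r] <- TRUE
      for (j in setdiff(nm, r)) {
        membership[ti, j, r] <- pw$p_adjusted[j, r] > alpha
      }
    }
  }
  structure(list(times = times, friedman_p = friedman_p,
                 mean_ranks = mean_ranks, membership = membership,
                 alpha = alpha),
            class = "cd_over_time")
}

#' Plot the time-resolved critical difference comparison
#'
#' Rank background as an image (darker = better rank) with cluster-membership
#' markers above for each representative classifier.
#'
#' @param x a `cd_over_time` object.
#' @param ... unused.
#' @export
plot.cd_over_time <- function(x, ...) {
  nm <- colnames(x$mean_ranks)
  k <- length(nm)
  nrep <- dim(x$membership)[3]
  graphics::image(x$times, seq_len(k), x$mean_ranks,
                  col = grDevices::grey.colors(64, start = 0.1, end = 0.95,
                                               rev = TRUE),
                  xlab = "time (ms)", ylab = "", yaxt = "n",
                  ylim = c(0.5, k + nrep + 0.5))
  graphics::axis(2, at = seq_len(k), labels = nm, las = 2, cex.axis = 0.7)
  cols <- grDevices::hcl.colors(nrep, "Dark 3")
  for (ri in seq_len(nrep)) {
    for (ji in seq_len(k)) {
      on <- x$membership[, ji, ri]
      if (any(on)) {
        graphics::points(x$times[on], rep(k + ri - 0.5 + ji / (k + 1), sum(on)),
                         pch = 15, cex = 0.3, col = cols[ri])
      }
    }
  }
  graphics::legend("topright", legend = dimnames(x$membership)[[3]],
                   col = cols, pch = 15, cex = 0.7, bg = "white")
  invisible(x)
}

#' Age-group comparison of classifier scores
#'
#' Per classifier: a one-way ANOVA across the group x dataset cells, followed
#' by pairwise independent two-sample t-tests (equal variance, two-sided)
#' between the young and older groups within each dataset.
#'
#' @param scores data.frame with columns `participant`, `group` (`young` /
#'   `older`), `classifier`, `dataset` and `score`.
#' @param var_equal use the pooled-variance t-test (default TRUE).
#' @return object of class `age_comparison`: per classifier the ANOVA p-value
#'   and per dataset the t-test results with group means and SDs.
#' @export
age_compare <- function(scores, var_equal = TRUE) {
  needed <- c("participant", "group", "classifier", "dataset", "score")
  if (!all(needed %in% names(scores))) {
    stop("`scores` must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(scores$group)) < 2) {
    stop("both age groups must be present", call. = FALSE)
  }
  tab <- table(scores$group)
  if (min(tab) < 2) stop("each group needs at least 2 observations", call. = FALSE)
  out <- list()
  for (clf in unique(scores$classifier)) {
    sub <- scores[scores$classifier == clf, ]
    cell <- interaction(sub$group, sub$dataset, drop = TRUE)
    anova_p <- if (nlevels(cell) > 1) {
      stats::anova(stats::aov(score ~ cell, data = sub))[["Pr(>F)"]][1]
    } else NA_real_
    tests <- list()
    for (ds in unique(sub$dataset)) {
      ss <- sub[sub$dataset == ds, ]
      y <- ss$score[ss$group == "young"]
      o <- ss$score[ss$group == "older"]
      if (length(y) < 2 || length(o) < 2) {
        stop("each group needs at least 2 participants per dataset", call. = FALSE)
      }
      tt <- stats::t.test(y, o, var.equal = var_equal)
      tests[[as.character(ds)]] <- list(
        t = unname(tt$statistic), p = tt$p.value,
        mean_young = mean(y), sd_young = stats::sd(y),
        mean_older = mean(o), sd_older = stats::sd(o))
    }
    out[[as.character(clf)]] <- list(anova_p = anova_p, t_tests = tests)
  }
  structure(out, class = "age_comparison")
}

#' @export
print.age_comparison <- function(x, ...) {
  for (clf in names(x)) {
    cat(sprintf("%s: ANOVA p = %.4g\n", clf, x[[clf]]$anova_p))
    for (ds in names(x[[clf]]$t_tests)) {
      t <- x[[clf]]$t_tests[[ds]]
      cat(sprintf(
        "  %s: young %.3f (%.3f) vs older %.3f (%.3f), t = %.2f, p = %.4g\n",
        ds, t$mean_young, t$sd_young, t$mean_older, t$sd_older, t$t, t$p))
    }
  }
  invisible(x)
}

#' Best AUROC over time per participant
#'
#' Maximum over time of a participant's fold-mean AUROC timecourse.
#'
#' @param result a timecourse `decoding_result` (one participant), or its
#'   [summary.decoding_result()] data.frame.
#' @param classifier classifier to extract (required when several present).
#' @param post_stimulus_only restrict to time points at or after 0 ms
#'   (default FALSE: all trimmed time points).
#' @return the participant's best fold-mean AUROC (scalar).
#' @export
max_auroc_per_participant <- function(result, classifier = NULL,
                                      post_stimulus_only = FALSE) {
  s <- if (inherits(result, "decoding_result")) summary(result) else result
  if (!is.null(classifier)) s <- s[s$classifier == classifier, ]
  if (length(unique(s$classifier)) > 1) {
    stop("several classifiers present; pass `classifier`", call. = FALSE)
  }
  if (post_stimulus_only) s <- s[s$time_ms >= 0, ]
  max(s$auroc, na.rm = TRUE)
}

#' Contiguous intervals of significant group differences
#'
#' Maximal runs of per-time p-values below `alpha`, reported in ms.
#'
#' @param times time axis in ms.
#' @param p_values per-time p-values (same length as `times`).
#' @param alpha threshold (default 0.01).
#' @return data.frame with columns `t_start`, `t_end` (one row per interval;
#'   zero rows when nothing is significant). A single significant time point
#'   yields a degenerate interval with `t_start == t_end`.
#' @export
significant_intervals <- function(times, p_values, alpha = 0.01) {
  stopifnot(length(times) == length(p_values))
  sig <- p_values < alpha
  sig[is.na(sig)] <- FALSE
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(t_start = times[starts[keep]], t_end = times[ends[keep]])
}
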