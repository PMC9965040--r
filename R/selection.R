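## Mutual-information feature ranking and the top-8 selection rules for the
## temporal and the statistical ERP datasets.

#' Mutual information between a continuous feature and a binary label
#'
#' Nearest-neighbour (Kozachenko-Leonenko style) continuous-discrete
#' estimator: for each trial, the distance to its k-th nearest neighbour
#' within the same class defines a radius; counting how many trials of either
#' class fall strictly inside that radius yields the estimate
#' `psi(N) - mean(psi(n_class)) + mean(psi(k)) - mean(psi(m))`,
#' clipped at zero. A constant feature has zero mutual information by
#' definition. To break exact ties, an imperceptible deterministic jitter
#' (1e-10 of the feature's scale) is added.
#'
#' @param x numeric feature values, one per trial.
#' @param y binary labels (two distinct values), one per trial.
#' @param k neighbour count (default 3).
#' @return estimated mutual information in nats (>= 0).
#' @export
mutual_information <- function(x, y, k = 3) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  y <- as.integer(factor(y))
  if (length(unique(y)) != 2L) stop("`y` must contain exactly two classes", call. = FALSE)
  if (min(tabulate(y)) < 2L) stop("each class needs at least 2 trials", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  ## deterministic tie-breaking jitter, far below measurement precision
  x <- x + s * 1e-10 * sin(seq_len(n) * 12.9898)

  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  radius <- numeric(n)
  kk <- integer(n)
  for (cl in 1:2) {
    pos <- which(ys == cl)
    xc <- xs[pos]
    nc <- length(xc)
    ki <- min(k, nc - 1L)
    ## k-th NN distance within class via sorted order: the k nearest
    ## neighbours of xc[i] lie among the 2*ki sorted neighbours around i
    for (i in seq_len(nc)) {
      lo <- max(1L, i - ki); hi <- min(nc, i + ki)
      d <- sort(abs(xc[lo:hi] - xc[i]))[ki + 1L]   # drop self-distance 0
      radius[pos[i]] <- d
      kk[pos[i]] <- ki
    }
  }
  ## m_i: points of either class strictly within the radius (self included)
  r <- radius * (1 - 1e-10)
  m <- findInterval(xs + r, xs) - findInterval(xs - r, xs, left.open = TRUE)
  n_class <- tabulate(ys)[ys]
  mi <- digamma(n) - mean(digamma(n_class)) + mean(digamma(kk)) -
    mean(digamma(pmax(m, 1L)))
  max(mi, 0)
}

new_feature_ranking <- function(feature_names, scores, selected) {
  structure(
    data.frame(feature = feature_names, score = scores,
               selected = selected, stringsAsFactors = FALSE),
    class = c("feature_ranking", "data.frame")
  )
}

#' Select the top-k temporal features by mutual information
#'
#' For every feature, mutual information with the stimulus label is computed
#' at each time point (trials pooled across participants) and aggregated by
#' the mean over time; the `k` features with the highest aggregate are
#' selected. Ties are broken by the fixed feature order.
#'
#' @param tensors a `temporal_features` object or a list of them (pooled).
#' @param k number of features to keep (default 8).
#' @param time_subsample optional integer: use every `time_subsample`-th time
#'   point when aggregating (1 = all time points).
#' @param mi_k neighbour count for [mutual_information()].
#' @return a `feature_ranking` data frame (feature, score, selected), in the
#'   fixed feature order.
#' @export
select_temporal <- function(tensors, k = 8, time_subsample = 1, mi_k = 3) {
  if (inherits(tensors, "temporal_features")) tensors <- list(tensors)
  feature_names <- tensors[[1]]$feature_names
  if (k > length(feature_names)) {
    stop(sprintf("`k` cannot exceed the %d available features",
                 length(feature_names)), call. = FALSE)
  }
  vals <- do.call(abind_trials, tensors)
  labels <- unlist(lapply(tensors, `[[`, "labels"))
  nt <- dim(vals)[2]
  t_idx <- seq(1, nt, by = time_subsample)
  scores <- vapply(seq_along(feature_names), function(f) {
    mean(vapply(t_idx, function(ti) {
      mutual_information(vals[, ti, f], labels, k = mi_k)
    }, numeric(1)))
  }, numeric(1))
  sel_order <- order(-scores, seq_along(scores))   # ties -> earlier feature
  selected <- seq_along(scores) %in% sel_order[seq_len(k)]
  new_feature_ranking(feature_names, scores, selected)
}

## bind trials of several temporal_features tensors along the first axis
abind_trials <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]]$values)
  total <- sum(vapply(parts, function(p) dim(p$values)[1], integer(1)))
  out <- array(NA_real_, dim = c(total, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    np <- dim(p$values)[1]
    out[at + seq_len(np), , ] <- p$values
    at <- at + np
  }
  out
}

#' Select the ERP measure families by mutual information
#'
#' The two amplitude measures (peak vs. mean amplitude) are ranked against
#' each other by mutual information summed across the four components, and
#' likewise the two latency measures (peak vs. fractional 50 percent peak
#' latency); the winning amplitude measure and the winning latency measure
#' are kept for all four components, yielding 8 selected features. Amplitude
#' ties prefer the peak amplitude and latency ties the fractional latency.
#'
#' @param tables an `erp_features` object or a list of them (trials pooled).
#' @param mi_k neighbour count for [mutual_information()].
#' @return a `feature_ranking` data frame over the 16 columns.
#' @export
select_erp <- function(tables, mi_k = 3) {
  if (inherits(tables, "erp_features")) tables <- list(tables)
  vals <- do.call(rbind, lapply(tables, `[[`, "values"))
  labels <- unlist(lapply(tables, `[[`, "labels"))
  cols <- colnames(vals)
  if (length(cols) != 16L) stop("expected a 16-column ERP feature table", call. = FALSE)
  scores <- vapply(seq_along(cols), function(j) {
    mutual_information(vals[, j], labels, k = mi_k)
  }, numeric(1))
  fam_sum <- function(measure) sum(scores[grepl(paste0("_", measure, "$"), cols)])
  amp_winner <- if (fam_sum("peak_amplitude") >= fam_sum("mean_amplitude")) {
    "peak_amplitude"
  } else "mean_amplitude"
  lat_winner <- if (fam_sum("fractional_peak_latency_50") >= fam_sum("peak_latency")) {
    "fractional_peak_latency_50"
  } else "peak_latency"
  selected <- grepl(paste0("_", amp_winner, "$"), cols) |
    grepl(paste0("_", lat_winner, "$"), cols)
  new_feature_ranking(cols, scores, selected)
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %d features, %d selected\n",
              nrow(x), sum(x$selected)))
  NextMethod()
}
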