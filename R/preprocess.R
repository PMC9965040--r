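## Epoch-level quality control and electrode-cluster averaging.

#' Default channel-to-cluster map
#'
#' @return named list mapping each cluster to its three 10-20 channels.
#' @export
default_cluster_map <- function() {
  list(occipital = c("O1", "Oz", "O2"),
       parietal = c("P3", "Pz", "P4"),
       central = c("C3", "Cz", "C4"),
       frontal = c("F3", "Fz", "F4"))
}

#' Reject epochs by absolute peak amplitude
#'
#' An epoch is removed iff its maximum absolute voltage over all samples and
#' clusters is strictly greater than `threshold_uv`. The order of the kept
#' epochs is preserved.
#'
#' @param epochs an `epoch_set`.
#' @param threshold_uv rejection threshold in microvolts (default 100).
#' @param max_removed_fraction recording-exclusion threshold passed to
#'   [check_exclusion()] when filling the report's `excluded` flag.
#' @return list with elements `epochs` (the kept subset) and `report`
#'   (a `rejection_report`).
#' @export
reject_epochs <- function(epochs, threshold_uv = 100,
                          max_removed_fraction = 0.25) {
  stopifnot(inherits(epochs, "epoch_set"))
  stopifnot_scalar_number(threshold_uv, "threshold_uv", lower = 0,
                          strict_lower = TRUE)
  n <- dim(epochs$voltages)[1]
  if (n == 0) stop("empty epoch set", call. = FALSE)
  peak <- apply(abs(epochs$voltages), 1, max)
  removed <- which(peak > threshold_uv)
  kept <- setdiff(seq_len(n), removed)
  report <- structure(
    list(kept_indices = kept, removed_indices = removed,
         retained_fraction = length(kept) / n, excluded = NA),
    class = "rejection_report"
  )
  report$excluded <- check_exclusion(report, max_removed_fraction)
  list(epochs = subset_epochs(epochs, kept), report = report)
}

#' Should a recording be excluded?
#'
#' A recording is excluded when strictly more than `max_removed_fraction` of
#' its epochs were rejected; exactly at the boundary it is kept.
#'
#' @param report a `rejection_report` from [reject_epochs()].
#' @param max_removed_fraction maximum tolerated removed fraction (default 0.25).
#' @return logical.
#' @export
check_exclusion <- function(report, max_removed_fraction = 0.25) {
  stopifnot(inherits(report, "rejection_report"))
  (1 - report$retained_fraction) > max_removed_fraction
}

#' @export
print.rejection_report <- function(x, ...) {
  n <- length(x$kept_indices) + length(x$removed_indices)
  cat(sprintf(
    "<rejection_report> kept %d / %d epochs (%.1f%%), removed %d; excluded: %s\n",
    length(x$kept_indices), n, 100 * x$retained_fraction,
    length(x$removed_indices), x$excluded))
  invisible(x)
}

#' Average channel-level epochs into electrode clusters
#'
#' Per cluster, the arithmetic mean over its channels at each sample.
#'
#' @param channel_epochs a `channel_epochs` object (trials x samples x
#'   channels, channel names on the third dimension).
#' @param cluster_map named list mapping the four clusters to channel names;
#'   default [default_cluster_map()].
#' @return an `epoch_set` with the four cluster traces.
#' @export
cluster_average <- function(channel_epochs, cluster_map = default_cluster_map()) {
  stopifnot(inherits(channel_epochs, "channel_epochs"))
  if (!setequal(names(cluster_map), CLUSTERS)) {
    stop("`cluster_map` must name exactly the clusters: ",
         paste(CLUSTERS, collapse = ", "), call. = FALSE)
  }
  have <- dimnames(channel_epochs$voltages)[[3]]
  for (cl in CLUSTERS) {
    chans <- cluster_map[[cl]]
    if (length(chans) < 1) {
      stop(sprintf("cluster '%s' lists no channels", cl), call. = FALSE)
    }
    missing <- setdiff(chans, have)
    if (length(missing)) {
      stop(sprintf("unknown channel(s) %s for cluster '%s'; valid channels: %s",
                   paste(missing, collapse = ", "), cl,
                   paste(have, collapse = ", ")), call. = FALSE)
    }
  }
  d <- dim(channel_epochs$voltages)
  v <- array(0, dim = c(d[1], d[2], length(CLUSTERS)))
  for (ci in seq_along(CLUSTERS)) {
    chans <- cluster_map[[CLUSTERS[ci]]]
    sub <- channel_epochs$voltages[, , chans, drop = FALSE]
    v[, , ci] <- apply(sub, c(1, 2), mean)
  }
  new_epoch_set(v, channel_epochs$labels, channel_epochs$times,
                channel_epochs$participant_id, channel_epochs$group,
                channel_epochs$fs)
}
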