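## Time-independent statistical ERP features: peak amplitude, mean amplitude,
## peak latency and fractional 50% peak latency per component.

#' Component measurement window
#'
#' @param component component label (`"P1"`, `"N170"`, `"P2"`, `"P3"`).
#' @param cluster electrode cluster the component is measured on.
#' @param t_start,t_end window endpoints in ms (`t_start < t_end`), inclusive;
#'   the sample nearest each endpoint is included.
#' @param polarity +1 (positive peak) or -1 (negative peak).
#' @return object of class `component_window`.
#' @export
component_window <- function(component, cluster, t_start, t_end,
                             polarity = if (component == "N170") -1 else +1) {
  component <- match.arg(component, COMPONENTS)
  cluster <- match.arg(cluster, CLUSTERS)
  if (t_start >= t_end) stop("`t_start` must be < `t_end`", call. = FALSE)
  if (!polarity %in% c(-1, 1)) stop("`polarity` must be +1 or -1", call. = FALSE)
  structure(list(component = component, cluster = cluster, t_start = t_start,
                 t_end = t_end, polarity = polarity),
            class = "component_window")
}

#' Default component windows
#'
#' P1 50-150 ms, N170 100-200 ms and P2 200-325 ms on the occipital cluster;
#' P3 250-500 ms on the central cluster.
#'
#' @return named list of [component_window()] objects.
#' @export
default_component_windows <- function() {
  list(P1 = component_window("P1", "occipital", 50, 150),
       N170 = component_window("N170", "occipital", 100, 200),
       P2 = component_window("P2", "occipital", 200, 325),
       P3 = component_window("P3", "central", 250, 500))
}

## Indices of the in-window samples: from the sample nearest t_start to the
## sample nearest t_end (endpoints inclusive).
window_indices <- function(times, window) {
  if (window$t_end < times[1] || window$t_start > times[length(times)]) {
    stop(sprintf("window [%g, %g] ms lies outside the trace's time axis [%g, %g] ms",
                 window$t_start, window$t_end, times[1], times[length(times)]),
         call. = FALSE)
  }
  seq(nearest_sample(times, window$t_start), nearest_sample(times, window$t_end))
}

#' Peak amplitude within a component window
#'
#' Maximum voltage for positive polarity, minimum for negative; the value is
#' returned signed.
#'
#' @param trace numeric voltage vector (microvolts).
#' @param times sample times in ms, same length as `trace`.
#' @param window a [component_window()].
#' @return signed peak amplitude, microvolts.
#' @export
peak_amplitude <- function(trace, times, window) {
  idx <- window_indices(times, window)
  if (window$polarity > 0) max(trace[idx]) else min(trace[idx])
}

#' Mean amplitude within a component window
#'
#' @inheritParams peak_amplitude
#' @return arithmetic mean of the in-window samples, microvolts.
#' @export
mean_amplitude <- function(trace, times, window) {
  mean(trace[window_indices(times, window)])
}

#' Peak latency within a component window
#'
#' Time of the extremum located by [peak_amplitude()]; ties are broken toward
#' the earliest sample.
#'
#' @inheritParams peak_amplitude
#' @return latency in ms.
#' @export
peak_latency <- function(trace, times, window) {
  idx <- window_indices(times, window)
  v <- window$polarity * trace[idx]
  times[idx[which.max(v)]]      # which.max returns the first maximum
}

#' Fractional peak latency
#'
#' Onset-side fractional latency: starting at the in-window peak and walking
#' backward toward `t_start`, the first place where the polarity-aligned
#' voltage drops below `fraction` times the peak value defines a crossing;
#' the returned latency is linearly interpolated between the two straddling
#' samples. If the trace never falls below the threshold within the window,
#' `t_start` is returned.
#'
#' @inheritParams peak_amplitude
#' @param fraction threshold fraction of the peak, in (0, 1); default 0.5
#'   (the fractional 50 percent peak latency).
#' @return latency in ms.
#' @export
fractional_peak_latency <- function(trace, times, window, fraction = 0.5) {
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  idx <- window_indices(times, window)
  v <- window$polarity * trace[idx]
  p <- which.max(v)
  thr <- fraction * v[p]
  ## degenerate geometry: a non-positive aligned peak sits below its own
  ## fractional threshold, so no onset-side crossing exists before it
  if (v[p] < thr) return(times[idx[p]])
  i <- p
  while (i > 1 && v[i - 1] >= thr) i <- i - 1
  if (i == 1) {
    if (v[1] >= thr) return(window$t_start)
    ## peak at the first sample and already below threshold cannot happen
    ## (v[p] >= thr by construction), so i == 1 implies v[1] >= thr.
  }
  ## crossing between samples i-1 (below) and i (at/above)
  t0 <- times[idx[i - 1]]; t1 <- times[idx[i]]
  v0 <- v[i - 1]; v1 <- v[i]
  t0 + (thr - v0) / (v1 - v0) * (t1 - t0)
}

#' Trial-average waveforms of an epoch set
#'
#' @param epochs an `epoch_set`.
#' @param which `"all"`, `"rare"` or `"frequent"` trials.
#' @return samples x clusters matrix of mean voltages.
#' @export
erp_average <- function(epochs, which = c("all", "rare", "frequent")) {
  which <- match.arg(which)
  keep <- switch(which, all = rep(TRUE, length(epochs$labels)),
                 rare = epochs$labels == 1L, frequent = epochs$labels == 0L)
  out <- apply(epochs$voltages[keep, , , drop = FALSE], c(2, 3), mean)
  colnames(out) <- CLUSTERS
  out
}

#' Grand-average waveform over participants
#'
#' Averages each participant's trial-average (collapsed over stimulus type,
#' i.e. over all trials) and then averages across participants, optionally
#' restricted to one group.
#'
#' @param epoch_sets list of `epoch_set` objects on a common time axis.
#' @param group optional group label to restrict to.
#' @param which trial subset passed to [erp_average()].
#' @return samples x clusters matrix.
#' @export
grand_average <- function(epoch_sets, group = NULL, which = "all") {
  if (!is.null(group)) {
    epoch_sets <- Filter(function(e) e$group == group, epoch_sets)
  }
  if (!length(epoch_sets)) stop("no epoch sets to average", call. = FALSE)
  avgs <- lapply(epoch_sets, erp_average, which = which)
  Reduce(`+`, avgs) / length(avgs)
}

#' Data-driven component windows from the collapsed grand average
#'
#' Diagnostic implementation of the collapsed-localizers idea: candidate
#' windows are bounded by consecutive zero-crossings of the grand-average
#' waveform collapsed across groups and stimulus types (occipital trace for
#' P1, N170, P2; central trace for P3), intersected with the default windows
#' widened by 50 ms on each side. For each component the crossing-bounded
#' segment that overlaps its default window most is chosen (a criterion that
#' depends only on the crossing geometry, hence is invariant to a sign flip
#' of the grand average). If no crossing-bounded segment overlaps the
#' default window, the default window is returned for it with a warning. These windows are
#' diagnostics; the pipeline default remains [default_component_windows()].
#'
#' @param grand_avg samples x clusters matrix from [grand_average()].
#' @param times sample times, ms.
#' @param defaults default windows (named list of [component_window()]).
#' @param widen_ms half-width of the neighbourhood around each default window
#'   (default 50 ms).
#' @return named list of [component_window()] objects.
#' @export
collapsed_localizer_windows <- function(grand_avg, times,
                                        defaults = default_component_windows(),
                                        widen_ms = 50) {
  out <- defaults
  for (nm in names(defaults)) {
    w <- defaults[[nm]]
    trace <- grand_avg[, w$cluster]
    s <- sign(trace)
    cross <- which(s[-1] * s[-length(s)] < 0)     # crossing between i and i+1
    if (length(cross) < 1) {
      warning(sprintf("no zero-crossings for %s; keeping the default window", nm))
      next
    }
    ## zero-crossing times by linear interpolation; segment boundaries are
    ## the crossings plus the trace ends
    tc <- times[cross] + (0 - trace[cross]) /
      (trace[cross + 1] - trace[cross]) * (times[cross + 1] - times[cross])
    bounds <- c(times[1], tc, times[length(times)])
    lo <- w$t_start - widen_ms; hi <- w$t_end + widen_ms
    best <- NULL; best_val <- -Inf
    for (k in seq_len(length(bounds) - 1)) {
      a <- max(bounds[k], lo); b <- min(bounds[k + 1], hi)
      if (a >= b) next
      ## choose the crossing-bounded segment overlapping the default window
      ## most; depends only on the crossing geometry, so it is invariant to a
      ## sign flip of the grand average
      overlap <- min(bounds[k + 1], w$t_end) - max(bounds[k], w$t_start)
      if (overlap > best_val) {
        best_val <- overlap
        best <- c(a, b)
      }
    }
    if (best_val <= 0) best <- NULL
    if (is.null(best)) {
      warning(sprintf("no crossing-bounded segment near the %s window; keeping the default", nm))
      next
    }
    out[[nm]] <- component_window(w$component, w$cluster, best[1], best[2],
                                  polarity = w$polarity)
  }
  out
}

ERP_MEASURES <- c("peak_amplitude", "mean_amplitude", "peak_latency",
                  "fractional_peak_latency_50")

#' Build the 16-column single-trial ERP feature table
#'
#' Each trial is parameterised by four measures (peak amplitude, mean
#' amplitude, peak latency, fractional 50 percent peak latency) for each of
#' the four components, measured on that component's cluster trace within its
#' window. N170 measures are computed on the negated trace and the amplitude
#' sign restored, so its peak amplitude is reported negative while latencies
#' refer to the negative peak.
#'
#' @param epochs a 4-cluster `epoch_set`.
#' @param windows named list of [component_window()] objects, default
#'   [default_component_windows()].
#' @return object of class `erp_features`: list with `values` (trials x 16
#'   matrix, columns `<component>_<measure>` looping measures within
#'   component), `labels`, `participant_id`, `group`.
#' @export
build_erp_features <- function(epochs, windows = default_component_windows()) {
  stopifnot(inherits(epochs, "epoch_set"))
  cols <- unlist(lapply(names(windows),
                        function(cn) paste0(cn, "_", ERP_MEASURES)))
  n <- dim(epochs$voltages)[1]
  vals <- matrix(NA_real_, nrow = n, ncol = length(cols),
                 dimnames = list(NULL, cols))
  for (cn in names(windows)) {
    w <- windows[[cn]]
    ci <- match(w$cluster, CLUSTERS)
    for (tr in seq_len(n)) {
      trace <- epochs$voltages[tr, , ci]
      vals[tr, paste0(cn, "_peak_amplitude")] <-
        peak_amplitude(trace, epochs$times, w)
      vals[tr, paste0(cn, "_mean_amplitude")] <-
        mean_amplitude(trace, epochs$times, w)
      vals[tr, paste0(cn, "_peak_latency")] <-
        peak_latency(trace, epochs$times, w)
      vals[tr, paste0(cn, "_fractional_peak_latency_50")] <-
        fractional_peak_latency(trace, epochs$times, w)
    }
  }
  structure(
    list(values = vals, labels = epochs$labels,
         participant_id = epochs$participant_id, group = epochs$group),
    class = "erp_features"
  )
}

#' @export
print.erp_features <- function(x, ...) {
  cat(sprintf("<erp_features> participant %s: %d trials x %d columns\n",
              x$participant_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}
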