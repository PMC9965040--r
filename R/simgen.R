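## Synthetic multi-participant visual-oddball EEG generator.
##
## Epochs are built as sums of Gaussian-bump ERP components defined per
## electrode cluster, plus pink (1/f) and white noise, with rare/frequent
## stimulus labels in the oddball proportions. Age groups differ in component
## latencies and amplitudes, emulating delayed and attenuated posterior ERPs
## in older adults.

#' Specify one ERP component for the simulator
#'
#' A component is a Gaussian bump in time localised to one electrode cluster:
#' `polarity * amplitude * exp(-(t - latency)^2 / (2 * width^2))`.
#' Between-participant variability shifts the latency once per participant;
#' within-participant jitter shifts it per trial; the amplitude is drawn per
#' trial.
#'
#' @param name component label, one of `"P1"`, `"N170"`, `"P2"`, `"P3"`.
#' @param cluster electrode cluster carrying the component, one of
#'   `"occipital"`, `"parietal"`, `"central"`, `"frontal"`.
#' @param mean_latency mean peak latency in ms relative to stimulus onset.
#' @param mean_amplitude mean peak magnitude in microvolts (non-negative; the
#'   sign of the deflection is carried by `polarity`).
#' @param width Gaussian sigma in ms (> 0).
#' @param polarity +1 for positive deflections, -1 for negative ones. N170
#'   must be negative; P1, P2, P3 positive.
#' @param latency_sd_between SD (ms) of the participant-level latency offset.
#' @param latency_jitter_within SD (ms) of the trial-level latency jitter.
#' @param amplitude_sd SD (microvolts) of the trial-level amplitude draw.
#' @return an object of class `component_spec`.
#' @examples
#' component_spec("P3", "central", mean_latency = 340, mean_amplitude = 5,
#'                width = 40)
#' @export
component_spec <- function(name, cluster, mean_latency, mean_amplitude, width,
                           polarity = if (name == "N170") -1 else +1,
                           latency_sd_between = 10,
                           latency_jitter_within = 10,
                           amplitude_sd = 1) {
  name <- match.arg(name, COMPONENTS)
  cluster <- match.arg(cluster, CLUSTERS)
  stopifnot_scalar_number(mean_latency, "mean_latency")
  stopifnot_scalar_number(mean_amplitude, "mean_amplitude", lower = 0)
  stopifnot_scalar_number(width, "width", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(latency_sd_between, "latency_sd_between", lower = 0)
  stopifnot_scalar_number(latency_jitter_within, "latency_jitter_within", lower = 0)
  stopifnot_scalar_number(amplitude_sd, "amplitude_sd", lower = 0)
  if (!polarity %in% c(-1, 1)) stop("`polarity` must be +1 or -1", call. = FALSE)
  if (name == "N170" && polarity != -1) {
    stop("N170 must have polarity -1", call. = FALSE)
  }
  if (name %in% c("P1", "P2", "P3") && polarity != 1) {
    stop(sprintf("%s must have polarity +1", name), call. = FALSE)
  }
  structure(
    list(name = name, cluster = cluster, polarity = polarity,
         mean_latency = mean_latency, latency_sd_between = latency_sd_between,
         latency_jitter_within = latency_jitter_within,
         mean_amplitude = mean_amplitude, amplitude_sd = amplitude_sd,
         width = width),
    class = "component_spec"
  )
}

#' Age-group generative profile
#'
#' Bundles the component sets evoked by frequent and rare stimuli with the
#' noise levels for one age group. Rare (face) trials must carry a larger P3
#' and a larger-magnitude N170 than frequent trials, and the profile pair used
#' in [simulate_dataset()] must delay the older group's P3.
#'
#' @param group `"young"` or `"older"`.
#' @param components_frequent,components_rare lists of [component_spec()]
#'   objects for frequent and rare trials.
#' @param noise_white_sd SD (microvolts) of white noise added per sample.
#' @param noise_pink_sd SD (microvolts) of 1/f (pink) noise added per epoch.
#' @return an object of class `group_profile`.
#' @export
group_profile <- function(group, components_frequent, components_rare,
                          noise_white_sd = 2, noise_pink_sd = 4) {
  group <- match.arg(group, c("young", "older"))
  chk <- function(x, nm) {
    if (!is.list(x) || !all(vapply(x, inherits, logical(1), "component_spec"))) {
      stop(sprintf("`%s` must be a list of component_spec objects", nm),
           call. = FALSE)
    }
    stats::setNames(x, vapply(x, `[[`, character(1), "name"))
  }
  components_frequent <- chk(components_frequent, "components_frequent")
  components_rare <- chk(components_rare, "components_rare")
  stopifnot_scalar_number(noise_white_sd, "noise_white_sd", lower = 0)
  stopifnot_scalar_number(noise_pink_sd, "noise_pink_sd", lower = 0)
  amp <- function(set, comp) {
    if (comp %in% names(set)) set[[comp]]$mean_amplitude else NA_real_
  }
  p3f <- amp(components_frequent, "P3"); p3r <- amp(components_rare, "P3")
  if (!is.na(p3f) && !is.na(p3r) && p3r <= p3f) {
    stop("rare-trial P3 amplitude must exceed frequent-trial P3 amplitude",
         call. = FALSE)
  }
  n1f <- amp(components_frequent, "N170"); n1r <- amp(components_rare, "N170")
  if (!is.na(n1f) && !is.na(n1r) && n1r <= n1f) {
    stop("rare-trial N170 magnitude must exceed frequent-trial N170 magnitude",
         call. = FALSE)
  }
  structure(
    list(group = group, components_frequent = components_frequent,
         components_rare = components_rare, noise_white_sd = noise_white_sd,
         noise_pink_sd = noise_pink_sd),
    class = "group_profile"
  )
}

#' Default young and older generative profiles
#'
#' Study-condition defaults: P1/N170/P2 on the occipital cluster and P3 on the
#' central cluster; rare (face) trials evoke a stronger N170 and P3; the older
#' profile delays latencies (P2 235 -> 300 ms, P3 340 -> 400 ms) and attenuates
#' posterior amplitudes while leaving the P2 amplitude age-invariant.
#'
#' @return a list with elements `young` and `older`, each a [group_profile()].
#' @export
default_group_profiles <- function() {
  comp <- function(name, cluster, lat, amp, width, jit = 10, between = 10,
                   amp_sd = 1) {
    component_spec(name, cluster, mean_latency = lat, mean_amplitude = amp,
                   width = width, latency_sd_between = between,
                   latency_jitter_within = jit, amplitude_sd = amp_sd)
  }
  young_frequent <- list(
    comp("P1", "occipital", 100, 4.0, 15),
    comp("N170", "occipital", 170, 2.0, 18),
    comp("P2", "occipital", 235, 2.5, 25),
    comp("P3", "central", 340, 1.5, 45, jit = 20, between = 15, amp_sd = 1.5)
  )
  young_rare <- list(
    comp("P1", "occipital", 100, 4.0, 15),
    comp("N170", "occipital", 170, 6.0, 18),
    comp("P2", "occipital", 235, 4.5, 25),
    comp("P3", "central", 340, 5.0, 45, jit = 20, between = 15, amp_sd = 1.5)
  )
  older_frequent <- list(
    comp("P1", "occipital", 110, 2.4, 15),
    comp("N170", "occipital", 180, 1.2, 18),
    comp("P2", "occipital", 300, 2.5, 25),
    comp("P3", "central", 400, 1.2, 45, jit = 20, between = 15, amp_sd = 1.5)
  )
  older_rare <- list(
    comp("P1", "occipital", 110, 2.4, 15),
    comp("N170", "occipital", 180, 3.6, 18),
    comp("P2", "occipital", 300, 4.5, 25),
    comp("P3", "central", 400, 4.0, 45, jit = 20, between = 15, amp_sd = 1.5)
  )
  list(
    young = group_profile("young", young_frequent, young_rare),
    older = group_profile("older", older_frequent, older_rare)
  )
}

#' Simulation configuration
#'
#' @param n_young,n_older participants per age group (study sample: 27 young,
#'   43 older).
#' @param trials_per_participant epochs per session (default 147).
#' @param n_rare rare-stimulus trials per session (default 23, i.e. 16%).
#' @param fs sampling rate in Hz (default 256).
#' @param epoch_start epoch start relative to stimulus onset, ms (default -200).
#' @param epoch_len_samples samples per epoch (default 256, spanning -200 to
#'   about +797 ms at 256 Hz).
#' @param artifact_rate per-epoch probability of an injected artifact spike.
#' @param artifact_amplitude artifact spike magnitude in microvolts (> 100).
#' @param seed master seed; all participant seeds derive from it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_young = 27, n_older = 43,
                              trials_per_participant = 147, n_rare = 23,
                              fs = 256, epoch_start = -200,
                              epoch_len_samples = 256,
                              artifact_rate = 0, artifact_amplitude = 150,
                              seed = 1L) {
  stopifnot_scalar_number(n_young, "n_young", lower = 0)
  stopifnot_scalar_number(n_older, "n_older", lower = 0)
  stopifnot_scalar_number(trials_per_participant, "trials_per_participant", lower = 1)
  stopifnot_scalar_number(n_rare, "n_rare", lower = 1)
  if (n_rare >= trials_per_participant) {
    stop("`n_rare` must be smaller than `trials_per_participant`", call. = FALSE)
  }
  stopifnot_scalar_number(fs, "fs", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(epoch_len_samples, "epoch_len_samples", lower = 64)
  stopifnot_scalar_number(artifact_rate, "artifact_rate", lower = 0, upper = 1)
  if (artifact_rate > 0) {
    stopifnot_scalar_number(artifact_amplitude, "artifact_amplitude",
                            lower = 100, strict_lower = TRUE)
  }
  structure(
    list(n_young = as.integer(n_young), n_older = as.integer(n_older),
         trials_per_participant = as.integer(trials_per_participant),
         n_rare = as.integer(n_rare), fs = fs, epoch_start = epoch_start,
         epoch_len_samples = as.integer(epoch_len_samples),
         artifact_rate = artifact_rate, artifact_amplitude = artifact_amplitude,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

## sample times (ms) of one epoch
epoch_times <- function(config) {
  config$epoch_start + (seq_len(config$epoch_len_samples) - 1) * 1000 / config$fs
}

new_epoch_set <- function(voltages, labels, times, participant_id, group, fs) {
  dimnames(voltages) <- list(NULL, NULL, CLUSTERS)
  structure(
    list(voltages = voltages, labels = as.integer(labels), times = times,
         participant_id = participant_id, group = group, fs = fs),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> participant %s (%s): %d trials (%d rare) x %d samples x %d clusters, %g Hz, %.1f..%.1f ms\n",
    x$participant_id, x$group, dim(x$voltages)[1], sum(x$labels),
    dim(x$voltages)[2], dim(x$voltages)[3], x$fs, min(x$times), max(x$times)))
  invisible(x)
}

## Keep a subset of trials, preserving order.
subset_epochs <- function(epochs, idx) {
  new_epoch_set(epochs$voltages[idx, , , drop = FALSE], epochs$labels[idx],
                epochs$times, epochs$participant_id, epochs$group, epochs$fs)
}

## Pink noise: white noise spectrally shaped by a 1/sqrt(f) gain, rescaled to
## the requested standard deviation. DC is zeroed.
pink_noise <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  ## two-sided frequency index, bin 0 = DC
  k <- c(0, seq_len(n - 1))
  k <- pmin(k, n - k)
  gain <- c(0, 1 / sqrt(k[-1]))
  x <- Re(stats::fft(spec * gain, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * sd / s
}

#' Simulate one participant's oddball session
#'
#' Draws rare-trial positions uniformly, one latency offset per component per
#' participant, per-trial latency jitter and amplitude, and adds pink plus
#' white noise per cluster. With `config$artifact_rate > 0`, artifact spikes
#' are injected afterwards via [inject_artifacts()].
#'
#' @param profile a [group_profile()].
#' @param config a [simulation_config()].
#' @param participant_seed integer seed for this participant; the same seed
#'   reproduces the session bit-identically.
#' @param participant_id identifier stored in the result.
#' @param channels_per_cluster 1 (default) simulates cluster traces directly;
#'   3 returns a channel-level `channel_epochs` object (three channels per
#'   cluster, each the cluster trace plus independent white noise) for use with
#'   [cluster_average()].
#' @param channel_noise_sd per-channel white noise SD (microvolts) in
#'   3-channel mode.
#' @return an `epoch_set` (or `channel_epochs` in 3-channel mode).
#' @export
simulate_participant <- function(profile, config, participant_seed,
                                 participant_id = "sim",
                                 channels_per_cluster = 1,
                                 channel_noise_sd = 1) {
  stopifnot(inherits(profile, "group_profile"),
            inherits(config, "simulation_config"))
  if (!channels_per_cluster %in% c(1, 3)) {
    stop("`channels_per_cluster` must be 1 or 3", call. = FALSE)
  }
  times <- epoch_times(config)
  all_comps <- c(profile$components_frequent, profile$components_rare)
  for (cs in all_comps) {
    if (cs$mean_latency < times[1] || cs$mean_latency > times[length(times)]) {
      stop(sprintf(
        "component %s mean latency %.1f ms lies outside the epoch window [%.1f, %.1f] ms; adjust the epoch or the component",
        cs$name, cs$mean_latency, times[1], times[length(times)]), call. = FALSE)
    }
  }
  n_trials <- config$trials_per_participant
  n_samp <- config$epoch_len_samples
  comp_names <- unique(vapply(all_comps, `[[`, character(1), "name"))

  out <- with_seed(participant_seed, {
    rare_idx <- sample.int(n_trials, config$n_rare)
    labels <- integer(n_trials)
    labels[rare_idx] <- 1L
    ## one latency offset per component name, shared between stimulus types
    sd_between <- vapply(comp_names, function(nm) {
      hit <- all_comps[vapply(all_comps, function(c) c$name == nm, logical(1))]
      hit[[1]]$latency_sd_between
    }, numeric(1))
    offsets <- stats::rnorm(length(comp_names), 0, sd_between)
    names(offsets) <- comp_names

    v <- array(0, dim = c(n_trials, n_samp, length(CLUSTERS)))
    for (tr in seq_len(n_trials)) {
      comps <- if (labels[tr] == 1L) profile$components_rare else
        profile$components_frequent
      for (cs in comps) {
        lat <- cs$mean_latency + offsets[[cs$name]] +
          stats::rnorm(1, 0, cs$latency_jitter_within)
        amp <- stats::rnorm(1, cs$mean_amplitude, cs$amplitude_sd)
        ci <- match(cs$cluster, CLUSTERS)
        v[tr, , ci] <- v[tr, , ci] +
          cs$polarity * amp * exp(-(times - lat)^2 / (2 * cs$width^2))
      }
      for (ci in seq_along(CLUSTERS)) {
        v[tr, , ci] <- v[tr, , ci] +
          pink_noise(n_samp, profile$noise_pink_sd) +
          stats::rnorm(n_samp, 0, profile$noise_white_sd)
      }
    }
    new_epoch_set(v, labels, times, participant_id, profile$group, config$fs)
  })

  if (config$artifact_rate > 0) {
    out <- inject_artifacts(out, config$artifact_rate,
                            config$artifact_amplitude,
                            seed = derive_seed(participant_seed, 99L))
  }
  if (channels_per_cluster == 3) {
    out <- expand_to_channels(out, channel_noise_sd,
                              seed = derive_seed(participant_seed, 7L))
  }
  out
}

## Expand a cluster-level epoch set to 3 channels per cluster by adding
## independent white noise per channel.
expand_to_channels <- function(epochs, channel_noise_sd, seed) {
  ch_map <- default_cluster_map()
  channels <- unlist(ch_map, use.names = FALSE)
  d <- dim(epochs$voltages)
  v <- array(0, dim = c(d[1], d[2], length(channels)),
             dimnames = list(NULL, NULL, channels))
  with_seed(seed, {
    for (ci in seq_along(CLUSTERS)) {
      for (ch in ch_map[[CLUSTERS[ci]]]) {
        v[, , ch] <- epochs$voltages[, , ci] +
          array(stats::rnorm(d[1] * d[2], 0, channel_noise_sd), dim = d[1:2])
      }
    }
  })
  structure(
    list(voltages = v, labels = epochs$labels, times = epochs$times,
         participant_id = epochs$participant_id, group = epochs$group,
         fs = epochs$fs, channels = channels),
    class = "channel_epochs"
  )
}

#' Simulate a full young + older dataset
#'
#' Participant seeds are derived deterministically from `config$seed` and the
#' participant's group and index, so the data of any one participant do not
#' depend on how many others are generated or in what order.
#'
#' @param young_profile,older_profile [group_profile()] objects; the older
#'   profile must place its P3 later than the young one.
#' @param config a [simulation_config()].
#' @return list of `epoch_set` objects (young participants first).
#' @export
simulate_dataset <- function(young_profile = default_group_profiles()$young,
                             older_profile = default_group_profiles()$older,
                             config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_young + config$n_older < 1) {
    stop("at least one participant must be requested", call. = FALSE)
  }
  p3lat <- function(p) {
    cr <- p$components_rare
    if ("P3" %in% names(cr)) cr[["P3"]]$mean_latency else NA_real_
  }
  ly <- p3lat(young_profile); lo <- p3lat(older_profile)
  if (!is.na(ly) && !is.na(lo) && lo <= ly) {
    stop("older profile must have a later P3 mean latency than the young profile",
         call. = FALSE)
  }
  out <- vector("list", config$n_young + config$n_older)
  k <- 0L
  for (i in seq_len(config$n_young)) {
    k <- k + 1L
    out[[k]] <- simulate_participant(
      young_profile, config, derive_seed(config$seed, 1L, i),
      participant_id = sprintf("young_%02d", i))
  }
  for (i in seq_len(config$n_older)) {
    k <- k + 1L
    out[[k]] <- simulate_participant(
      older_profile, config, derive_seed(config$seed, 2L, i),
      participant_id = sprintf("older_%02d", i))
  }
  out
}

#' Inject high-amplitude artifact epochs
#'
#' Each epoch is independently selected with probability `rate`; selected
#' epochs receive a one-sample spike of `+amplitude` or `-amplitude` (random
#' sign) at a random sample of a random cluster.
#'
#' @param epochs an `epoch_set`.
#' @param rate per-epoch selection probability in `[0, 1]`.
#' @param amplitude spike magnitude, microvolts (> 100 so that the default
#'   rejection threshold catches it).
#' @param seed integer seed.
#' @return the modified `epoch_set`.
#' @export
inject_artifacts <- function(epochs, rate, amplitude, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  stopifnot_scalar_number(rate, "rate", lower = 0, upper = 1)
  stopifnot_scalar_number(amplitude, "amplitude", lower = 100,
                          strict_lower = TRUE)
  if (rate == 0) return(epochs)
  d <- dim(epochs$voltages)
  with_seed(seed, {
    hit <- stats::runif(d[1]) < rate
    for (tr in which(hit)) {
      s <- sample.int(d[2], 1)
      ci <- sample.int(d[3], 1)
      sgn <- sample(c(-1, 1), 1)
      epochs$voltages[tr, s, ci] <- epochs$voltages[tr, s, ci] + sgn * amplitude
    }
  })
  epochs
}
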