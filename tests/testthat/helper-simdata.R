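# Small fixtures built in code: reduced-noise profiles and desk-scale
# configurations keep the suite fast while exercising the real pipeline.

# Single-component profile with all variability switched off: the epoch is
# exactly the Gaussian bump (rare trials) or flat (frequent trials).
noise_free_p3_profile <- function(amp = 5, lat = 340, width = 40,
                                  group = "young") {
  p3 <- component_spec("P3", "central", mean_latency = lat,
                       mean_amplitude = amp, width = width,
                       latency_sd_between = 0, latency_jitter_within = 0,
                       amplitude_sd = 0)
  group_profile(group, components_frequent = list(),
                components_rare = list(p3),
                noise_white_sd = 0, noise_pink_sd = 0)
}

# Zero-signal, zero-noise profile (flat epochs) for artifact arithmetic.
silent_profile <- function(group = "young") {
  group_profile(group, components_frequent = list(),
                components_rare = list(), noise_white_sd = 0,
                noise_pink_sd = 0)
}

# Default profiles with noise scaled down, for parameter-recovery tests that
# isolate the measurement rather than noise robustness.
quiet_profiles <- function(white = 0.5, pink = 1) {
  prof <- default_group_profiles()
  for (g in names(prof)) {
    prof[[g]]$noise_white_sd <- white
    prof[[g]]$noise_pink_sd <- pink
  }
  prof
}

# Desk-scale config: 128 Hz, 96-sample epochs -> 64 trimmed time points
# covering -75..417 ms.
desk_config_sim <- function(...) {
  args <- utils::modifyList(list(fs = 128, epoch_len_samples = 96), list(...))
  do.call(simulation_config, args)
}

# Build a temporal_features object directly from an array (synthetic feature
# tensors for selection tests).
make_temporal_features <- function(values, labels,
                                   feature_names = default_feature_names(),
                                   times = seq_len(dim(values)[2])) {
  dimnames(values) <- list(NULL, NULL, feature_names)
  structure(list(values = values, feature_names = feature_names,
                 times = times, labels = as.integer(labels),
                 participant_id = "synth", group = "young"),
            class = "temporal_features")
}

default_feature_names <- function(freqs = frequency_grid()) {
  clusters <- c("occipital", "parietal", "central", "frontal")
  c(paste0("amp_", clusters),
    unlist(lapply(clusters, function(cl) paste0("pow_", freqs, "Hz_", cl))))
}

# Build an erp_features object directly from a matrix.
make_erp_features <- function(values, labels, group = "young",
                              participant_id = "synth") {
  structure(list(values = values, labels = as.integer(labels),
                 participant_id = participant_id, group = group),
            class = "erp_features")
}

# Construct a channel-level epochs object from an array with channel dimnames.
make_channel_epochs <- function(voltages, labels, times, fs = 256) {
  structure(list(voltages = voltages, labels = as.integer(labels),
                 times = times, participant_id = "chan", group = "young",
                 fs = fs, channels = dimnames(voltages)[[3]]),
            class = "channel_epochs")
}

# Flat epoch_set of given size (all zeros), for injection/rejection tests.
make_flat_epochs <- function(n_trials, n_samples = 64, fs = 256) {
  times <- -200 + (seq_len(n_samples) - 1) * 1000 / fs
  labels <- integer(n_trials)
  labels[seq_len(max(1, round(n_trials * 0.16)))] <- 1L
  erpdecode:::new_epoch_set(array(0, dim = c(n_trials, n_samples, 4)),
                            labels, times, "flat", "young", fs)
}
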