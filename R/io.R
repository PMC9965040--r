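## Delimited-text serialization with JSON metadata sidecars. Voltages and
## feature values round-trip losslessly well beyond 6 significant digits.

#' Write an epoch set to delimited text plus a JSON sidecar
#'
#' Long format, one row per (trial, cluster, sample): columns `trial`,
#' `cluster`, `time_ms`, `voltage_uv`, `label`. The sidecar
#' `<prefix>.json` stores participant id, group and sampling rate.
#'
#' @param epochs an `epoch_set`.
#' @param prefix file path prefix; `<prefix>.csv` and `<prefix>.json` are
#'   written.
#' @return invisibly, the two file paths.
#' @export
write_epoch_set <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$voltages)
  df <- data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    cluster = rep(CLUSTERS, each = d[1] * d[2]),
    time_ms = rep(rep(epochs$times, each = d[1]), times = d[3]),
    voltage_uv = as.vector(epochs$voltages),
    label = rep(epochs$labels, times = d[2] * d[3])
  )
  csv <- paste0(prefix, ".csv"); json <- paste0(prefix, ".json")
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(
    list(participant_id = epochs$participant_id, group = epochs$group,
         fs = epochs$fs, n_trials = d[1], n_samples = d[2]),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' Read an epoch set written by [write_epoch_set()]
#'
#' @param prefix the file path prefix used when writing.
#' @return an `epoch_set`.
#' @export
read_epoch_set <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, ".csv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n_trials <- meta$n_trials; n_samples <- meta$n_samples
  v <- array(NA_real_, dim = c(n_trials, n_samples, length(CLUSTERS)))
  times <- sort(unique(df$time_ms))
  for (ci in seq_along(CLUSTERS)) {
    sub <- df[df$cluster == CLUSTERS[ci], ]
    ## rows are ordered trial-fastest then time
    v[, , ci] <- matrix(sub$voltage_uv, nrow = n_trials, ncol = n_samples)
  }
  labels <- df$label[df$cluster == CLUSTERS[1]][seq_len(n_trials)]
  new_epoch_set(v, labels, times, meta$participant_id, meta$group, meta$fs)
}

#' Write an ERP feature table
#'
#' Wide delimited text with a header, one row per trial, the label column
#' last, plus a JSON sidecar with participant id and group.
#'
#' @param table an `erp_features` object.
#' @param prefix file path prefix.
#' @return invisibly, the file paths.
#' @export
write_erp_features <- function(table, prefix) {
  stopifnot(inherits(table, "erp_features"))
  df <- as.data.frame(table$values)
  df$label <- table$labels
  csv <- paste0(prefix, ".csv"); json <- paste0(prefix, ".json")
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(
    list(participant_id = table$participant_id, group = table$group),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' Read an ERP feature table written by [write_erp_features()]
#'
#' @param prefix the file path prefix used when writing.
#' @return an `erp_features` object.
#' @export
read_erp_features <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  labels <- df$label
  vals <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  structure(list(values = vals, labels = as.integer(labels),
                 participant_id = meta$participant_id, group = meta$group),
            class = "erp_features")
}

#' Write a temporal feature tensor in long format
#'
#' Columns `trial`, `time_ms`, `feature`, `value`, plus a JSON schema sidecar
#' (feature names, labels, participant id, group).
#'
#' @param tensor a `temporal_features` object.
#' @param prefix file path prefix.
#' @return invisibly, the file paths.
#' @export
write_temporal_features <- function(tensor, prefix) {
  stopifnot(inherits(tensor, "temporal_features"))
  d <- dim(tensor$values)
  df <- data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    time_ms = rep(rep(tensor$times, each = d[1]), times = d[3]),
    feature = rep(tensor$feature_names, each = d[1] * d[2]),
    value = as.vector(tensor$values)
  )
  csv <- paste0(prefix, ".csv"); json <- paste0(prefix, ".json")
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(
    list(participant_id = tensor$participant_id, group = tensor$group,
         feature_names = tensor$feature_names, labels = tensor$labels,
         times = tensor$times),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' Read a temporal feature tensor written by [write_temporal_features()]
#'
#' @param prefix the file path prefix used when writing.
#' @return a `temporal_features` object.
#' @export
read_temporal_features <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, ".csv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  nt <- length(meta$labels); ns <- length(meta$times)
  nf <- length(meta$feature_names)
  v <- array(df$value, dim = c(nt, ns, nf),
             dimnames = list(NULL, NULL, meta$feature_names))
  structure(
    list(values = v, feature_names = meta$feature_names, times = meta$times,
         labels = as.integer(meta$labels),
         participant_id = meta$participant_id, group = meta$group),
    class = "temporal_features"
  )
}

#' Write a feature ranking as delimited text
#'
#' @param ranking a `feature_ranking`.
#' @param path output file.
#' @export
write_feature_ranking <- function(ranking, path) {
  utils::write.csv(as.data.frame(ranking), path, row.names = FALSE)
  invisible(path)
}

#' Write decoding records as long-format delimited text
#'
#' @param records data.frame of decoding records (optionally with
#'   `participant` and `group` columns added by the pipeline).
#' @param path output file.
#' @export
write_decoding_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
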