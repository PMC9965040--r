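## End-to-end runner: simulate -> preprocess -> features -> select -> decode
## -> stats (-> importance), with a validated config, per-stage logging and a
## reproducible run manifest.

RUN_CONFIG_KEYS <- c(
  "n_young", "n_older", "trials_per_participant", "n_rare", "fs",
  "epoch_start", "epoch_len_samples", "artifact_rate", "artifact_amplitude",
  "seed", "dataset", "classifiers", "select_k", "cv_folds", "time_subsample",
  "reject_threshold_uv", "max_removed_fraction", "run_importance",
  "importance_classifier", "importance_repeats"
)

#' Build and validate a pipeline run configuration
#'
#' Unknown keys are rejected. Simulation keys mirror [simulation_config()];
#' `dataset` chooses which feature branch to run.
#'
#' @param ... named configuration values; see [simulation_config()] plus
#'   `dataset` (`"temporal"`, `"statistical"` or `"both"`), `classifiers`
#'   (character vector of classifier names), `select_k`, `cv_folds`,
#'   `time_subsample` (decode every n-th trimmed time point in temporal mode),
#'   `reject_threshold_uv`, `max_removed_fraction`, `run_importance`,
#'   `importance_classifier`, `importance_repeats`.
#' @return object of class `run_config` (a validated named list).
#' @export
run_config <- function(...) {
  user <- list(...)
  unknown <- setdiff(names(user), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- list(
    n_young = 10L, n_older = 10L, trials_per_participant = 147L, n_rare = 23L,
    fs = 128, epoch_start = -200, epoch_len_samples = 96L,
    artifact_rate = 0.02, artifact_amplitude = 150, seed = 1L,
    dataset = "statistical", classifiers = c("lda", "logreg", "rf"),
    select_k = 8L, cv_folds = 10L, time_subsample = 1L,
    reject_threshold_uv = 100, max_removed_fraction = 0.25,
    run_importance = FALSE, importance_classifier = "rf",
    importance_repeats = 5L
  )
  cfg[names(user)] <- user
  if (!is.character(cfg$dataset) ||
      !cfg$dataset %in% c("temporal", "statistical", "both")) {
    stop("`dataset` must be one of \"temporal\", \"statistical\", \"both\"",
         call. = FALSE)
  }
  bad <- setdiff(cfg$classifiers, CLASSIFIER_NAMES)
  if (length(bad)) {
    stop("unknown classifier(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (cfg$run_importance &&
      !cfg$importance_classifier %in% cfg$classifiers) {
    stop("`importance_classifier` must be among `classifiers`", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Desk-scale preset configuration
#'
#' Small enough to run the full pipeline in minutes: 10 + 10 participants,
#' 147 trials, 128 Hz / 96-sample epochs (64 trimmed time points, -75 to
#' +414 ms) and three classifiers.
#'
#' @param ... overrides forwarded to [run_config()].
#' @return a `run_config`.
#' @export
desk_config <- function(...) run_config(...)

#' Full-study-scale preset configuration
#'
#' Mirrors the study geometry: 27 young + 43 older participants, 147 trials,
#' 256 Hz / 256-sample epochs (224 trimmed time points) and the full
#' nine-classifier suite. Expect hours of compute in temporal mode.
#'
#' @param ... overrides forwarded to [run_config()].
#' @return a `run_config`.
#' @export
study_scale_config <- function(...) {
  defaults <- list(n_young = 27L, n_older = 43L, fs = 256,
                   epoch_len_samples = 256L, dataset = "both",
                   classifiers = CLASSIFIER_NAMES)
  user <- list(...)
  defaults[names(user)] <- user
  do.call(run_config, defaults)
}

log_line <- function(log_path, fmt, ...) {
  cat(sprintf(fmt, ...), "\n", file = log_path, append = TRUE, sep = "")
  invisible(NULL)
}

#' Run the full pipeline
#'
#' Simulates the configured dataset, rejects artifact epochs (excluding
#' recordings that lose more than the configured fraction), extracts the
#' configured feature sets, selects features by mutual information, decodes
#' per participant, runs the classifier and age-group statistics, and writes
#' every stage output plus a manifest into `out_dir`. Re-running with the
#' same config reproduces all outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results (`epoch_sets`,
#'   `reports`, `rankings`, `decoding`, `comparison`, `age`, `importance`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("pipeline run\n", file = log_path)
  manifest <- list(config = unclass(config), stages = list())
  t_all <- proc.time()[["elapsed"]]

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log_line(log_path, "stage %-12s %.2f s", name,
             proc.time()[["elapsed"]] - t0)
    res
  }

  ## -- simulate ------------------------------------------------------------
  sim_cfg <- simulation_config(
    n_young = config$n_young, n_older = config$n_older,
    trials_per_participant = config$trials_per_participant,
    n_rare = config$n_rare, fs = config$fs,
    epoch_start = config$epoch_start,
    epoch_len_samples = config$epoch_len_samples,
    artifact_rate = config$artifact_rate,
    artifact_amplitude = config$artifact_amplitude, seed = config$seed)
  epoch_sets <- stage("simulate", simulate_dataset(config = sim_cfg))
  manifest$stages$simulate <- list(n_participants = length(epoch_sets),
                                   seed = config$seed)

  ## -- preprocess ----------------------------------------------------------
  pre <- stage("preprocess", {
    lapply(epoch_sets, function(e) {
      reject_epochs(e, config$reject_threshold_uv, config$max_removed_fraction)
    })
  })
  reports <- lapply(pre, `[[`, "report")
  excluded <- vapply(reports, `[[`, logical(1), "excluded")
  kept_sets <- lapply(pre[!excluded], `[[`, "epochs")
  rej_df <- data.frame(
    participant = vapply(epoch_sets, `[[`, character(1), "participant_id"),
    group = vapply(epoch_sets, `[[`, character(1), "group"),
    retained_fraction = vapply(reports, `[[`, numeric(1), "retained_fraction"),
    excluded = excluded)
  utils::write.csv(rej_df, file.path(out_dir, "rejection.csv"),
                   row.names = FALSE)
  manifest$stages$preprocess <- list(
    excluded = sum(excluded), file = "rejection.csv")
  if (length(kept_sets) < 2) {
    stop("stage 'preprocess' failed: fewer than two recordings survived rejection",
         call. = FALSE)
  }

  groups <- vapply(kept_sets, `[[`, character(1), "group")
  ids <- vapply(kept_sets, `[[`, character(1), "participant_id")
  run_temporal <- config$dataset %in% c("temporal", "both")
  run_static <- config$dataset %in% c("statistical", "both")
  specs <- default_classifier_specs(config$classifiers)
  rankings <- list(); decoding <- list(); scores <- list()

  decode_branch <- function(branch, feature_sets, decode_fun) {
    recs <- vector("list", length(feature_sets))
    for (i in seq_along(feature_sets)) {
      r <- decode_fun(feature_sets[[i]], derive_seed(config$seed, 3L, i))
      df <- as.data.frame(r)
      df$participant <- ids[i]; df$group <- groups[i]; df$dataset <- branch
      recs[[i]] <- df
    }
    do.call(rbind, recs)
  }

  if (run_static) {
    erp <- stage("features_erp",
                 lapply(kept_sets, build_erp_features))
    rankings$statistical <- stage("select_erp", select_erp(erp))
    write_feature_ranking(rankings$statistical,
                          file.path(out_dir, "ranking_statistical.csv"))
    erp_sel <- lapply(erp, apply_selection, rankings$statistical)
    decoding$statistical <- stage("decode_static", decode_branch(
      "statistical", erp_sel,
      function(tab, s) decode_static(tab, specs, seed = s,
                                     k = config$cv_folds)))
    write_decoding_records(decoding$statistical,
                           file.path(out_dir, "decoding_statistical.csv"))
    manifest$stages$statistical <- list(
      ranking = "ranking_statistical.csv",
      decoding = "decoding_statistical.csv")
  }

  if (run_temporal) {
    tens <- stage("features_temporal",
                  lapply(kept_sets, build_temporal_features))
    rankings$temporal <- stage("select_temporal",
                               select_temporal(tens, k = config$select_k,
                                               time_subsample = 4))
    write_feature_ranking(rankings$temporal,
                          file.path(out_dir, "ranking_temporal.csv"))
    tens_sel <- lapply(tens, apply_selection, rankings$temporal)
    nt <- dim(tens_sel[[1]]$values)[2]
    tidx <- seq(1, nt, by = config$time_subsample)
    decoding$temporal <- stage("decode_time", decode_branch(
      "temporal", tens_sel,
      function(ten, s) decode_timecourse(ten, specs, seed = s,
                                         k = config$cv_folds,
                                         time_indices = tidx)))
    write_decoding_records(decoding$temporal,
                           file.path(out_dir, "decoding_temporal.csv"))
    manifest$stages$temporal <- list(
      ranking = "ranking_temporal.csv", decoding = "decoding_temporal.csv")
  }

  ## -- stats ---------------------------------------------------------------
  stats_out <- stage("stats", {
    out <- list()
    if (run_static) {
      df <- decoding$statistical
      agg <- stats::aggregate(df["auroc"],
                              by = list(participant = df$participant,
                                        classifier = df$classifier),
                              FUN = mean, na.rm = TRUE)
      m <- stats::reshape(agg, idvar = "participant", timevar = "classifier",
                          direction = "wide")
      rownames(m) <- m$participant
      m$participant <- NULL
      colnames(m) <- sub("^auroc\\.", "", colnames(m))
      if (ncol(m) >= 3) {
        out$comparison <- compare_classifiers(as.matrix(m))
        jsonlite::write_json(
          list(friedman_stat = out$comparison$friedman_stat,
               friedman_p = out$comparison$friedman_p,
               cd_value = out$comparison$cd_value,
               mean_ranks = as.list(out$comparison$mean_ranks)),
          file.path(out_dir, "comparison_statistical.json"),
          auto_unbox = TRUE, digits = NA)
      }
      scores_df <- merge(agg, unique(df[c("participant", "group")]),
                         by = "participant")
      scores_df$dataset <- "statistical"
      names(scores_df)[names(scores_df) == "auroc"] <- "score"
      out$age <- age_compare(scores_df)
    }
    out
  })

  importance <- NULL
  if (config$run_importance && run_static) {
    importance <- stage("importance", {
      importance_profile(erp_sel, classifier_spec(config$importance_classifier),
                         seed = derive_seed(config$seed, 4L),
                         k = config$cv_folds,
                         n_repeats = config$importance_repeats)
    })
    utils::write.csv(as.data.frame(importance),
                     file.path(out_dir, "importance.csv"), row.names = FALSE)
    manifest$stages$importance <- list(file = "importance.csv")
  }

  ## timings live in run.log; the manifest stays bit-identical across reruns
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(log_path, "total %.2f s", proc.time()[["elapsed"]] - t_all)
  invisible(list(epoch_sets = epoch_sets, reports = reports,
                 rankings = rankings, decoding = decoding,
                 comparison = stats_out$comparison, age = stats_out$age,
                 importance = importance, manifest = manifest))
}
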