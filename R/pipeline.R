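# End-to-end orchestration: simulate (or load) recordings, track the
# speckle displacement, lock-in filter at the drive frequency, assemble
# feature vectors, split at the video level, train, and evaluate.

#' Lock-in feature row for one recording
#'
#' Sequential-mode displacement tracking, independent lock-in filtering of
#' the x and y channels at the drive frequency, and assembly into one
#' fixed-length feature row.
#'
#' @param video A `speckle_video` or rows x cols x frames array.
#' @param fs Frame rate (Hz); taken from the video protocol when available.
#' @param center_frequency Drive frequency (Hz).
#' @param bandwidth_bins Lock-in band half-width in bins.
#' @param target_length Feature-vector length.
#' @return List with `features` (numeric row), `band_energy_x`,
#'   `band_energy_y` and `mean_peak` diagnostics.
#' @export
video_lockin_features <- function(video, fs = NULL, center_frequency = 140,
                                  bandwidth_bins = 1, target_length = 500) {
  if (inherits(video, "speckle_video") && is.null(fs)) {
    fs <- video$protocol$fps
  }
  if (is.null(fs)) stop_invalid("`fs` must be supplied for raw arrays")
  series <- track_video(video, mode = "sequential")
  lx <- lockin_filter(series$dx, fs, center_frequency, bandwidth_bins)
  ly <- lockin_filter(series$dy, fs, center_frequency, bandwidth_bins)
  list(features = build_ml_features(lx, ly, target_length),
       band_energy_x = lx$band_energy_fraction,
       band_energy_y = ly$band_energy_fraction,
       mean_peak = series$mean_peak)
}

#' Simulate a labelled dataset and assemble SVM features in memory
#'
#' Generates `videos_per_level` recordings per reference glucose level
#' under one field condition and runs the tracking + lock-in front end on
#' each, without touching disk.
#'
#' @param levels Glucose levels (mg/dl), e.g. `reference_levels()$glucose_level`.
#' @param videos_per_level Recordings per level.
#' @param protocol_template A [simulation_protocol()] (glucose level, field
#'   flag and seed are overridden per video).
#' @param motion A [motion_model()].
#' @param field_on Field condition for the whole set.
#' @param seed Master seed.
#' @param target_length Feature-vector length.
#' @return List with `features` (matrix), `labels` (numeric vector) and
#'   `band_energy` (mean in-band fraction across recordings).
#' @export
simulate_feature_set <- function(levels, videos_per_level, protocol_template,
                                 motion = motion_model(), field_on = TRUE,
                                 seed = 1, target_length = 500) {
  grid <- expand.grid(replicate = seq_len(videos_per_level),
                      glucose_level = levels)
  feats <- matrix(NA_real_, nrow(grid), target_length)
  band <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- protocol_template
    p$glucose_level <- grid$glucose_level[i]
    p$field_on <- field_on
    p$seed <- derive_seed(seed, i + if (field_on) 0 else 10000)
    video <- simulate_recording(p, motion)
    out <- video_lockin_features(video,
                                 center_frequency = p$drive_frequency,
                                 target_length = target_length)
    feats[i, ] <- out$features
    band[i] <- mean(c(out$band_energy_x, out$band_energy_y))
  }
  list(features = feats, labels = grid$glucose_level,
       band_energy = mean(band))
}

#' Run the lock-in + SVM pipeline on one simulated field condition
#'
#' Simulates the dataset, makes a stratified 70/30 video-level split,
#' trains the Bayesian-optimized SVM on the training videos and evaluates
#' on the held-out videos.
#'
#' @inheritParams simulate_feature_set
#' @param train_fraction Training fraction of videos per class.
#' @param opt_budget Hyperparameter evaluations for the Bayesian search.
#' @return List with `report` (a `classifier_report` on the held-out set),
#'   `model` (the `speckle_svm`), `cv_accuracy`, `band_energy` and `n_test`.
#' @export
run_svm_pipeline <- function(levels, videos_per_level, protocol_template,
                             motion = motion_model(), field_on = TRUE,
                             seed = 1, train_fraction = 0.7,
                             opt_budget = 20, target_length = 500) {
  set <- simulate_feature_set(levels, videos_per_level, protocol_template,
                              motion, field_on, seed, target_length)
  train <- stratified_split(set$labels, train_fraction,
                            seed = derive_seed(seed, 31))
  model <- train_svm(set$features[train, , drop = FALSE],
                     set$labels[train], opt_budget = opt_budget,
                     seed = derive_seed(seed, 32))
  pred <- predict(model, set$features[!train, , drop = FALSE])
  report <- evaluate_classifier(set$labels[!train], pred,
                                class_order = sort(unique(set$labels)))
  list(report = report, model = model, cv_accuracy = model$cv_accuracy,
       band_energy = set$band_energy, n_test = sum(!train))
}
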