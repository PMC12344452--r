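# End-to-end orchestration: simulate -> segment files -> kinematic features
# -> classification -> expert comparison, from a single config, with a run
# manifest, frozen config copy, seeds and checksums. Stages communicate
# only through the files they declare, so deleting a stage's outputs and
# rerunning reproduces them exactly.

#' Default run configuration
#'
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @return Nested configuration list.
#' @export
default_run_config <- function(out_dir = tempfile("tailkin_run_"),
                               seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(enabled = TRUE, n_dogs = 2L, sessions = 2L,
                    trials_per_session = 3L, effect_scale = 1,
                    test_phase = "test1", fps = 60,
                    duration_mean = 3.34, duration_sd = 3.45),
    noise = list(jitter_sd = 2, dropout_rate = 0.02),
    input = list(metadata = NULL, segment_dir = NULL),
    features = list(conf_threshold = 0.5, max_gap = 5L,
                    velocity_mode = "per_second", n_sectors = 18L),
    classify = list(enabled = TRUE, protocol = "lodo",
                    classifier = "ensemble", k = 5L,
                    max_depth = 9L, nrounds = 100L,
                    epochs = 30L, dropout = 0.1),
    threshold_eval = list(enabled = FALSE, train_dilution = -3L),
    survey = list(enabled = FALSE, n_videos = 32L, n_participants = 190L,
                  expert_p_correct = 0.46)
  )
}

#' Validate a run configuration
#'
#' Checks field types, ranges and cross-field constraints. Never raises on
#' user error: returns a structured error list.
#'
#' @param config Configuration list (see [default_run_config()]).
#' @return List with \code{ok} (logical) and \code{errors} (character
#'   vector naming each offending field).
#' @export
validate_config <- function(config) {
  errors <- character(0)
  add <- function(msg) errors <<- c(errors, msg)
  if (is.null(config$seed) || is.na(suppressWarnings(as.integer(config$seed))))
    add("seed: must be an integer")
  if (is.null(config$out_dir)) add("out_dir: missing")
  sim <- config$simulate
  if (isTRUE(sim$enabled)) {
    if (!is.null(sim$n_dogs) && sim$n_dogs < 1) add("simulate.n_dogs: must be >= 1")
    if (!is.null(sim$effect_scale) && sim$effect_scale < 0)
      add("simulate.effect_scale: must be >= 0")
    if (!is.null(sim$fps) && sim$fps <= 0) add("simulate.fps: must be > 0")
  } else {
    if (is.null(config$input$metadata) || !file.exists(config$input$metadata))
      add("input.metadata: file does not exist (required when simulation is disabled)")
    if (is.null(config$input$segment_dir) ||
        !dir.exists(config$input$segment_dir))
      add("input.segment_dir: directory does not exist (required when simulation is disabled)")
  }
  no <- config$noise
  if (!is.null(no$dropout_rate) && (no$dropout_rate < 0 || no$dropout_rate > 1))
    add("noise.dropout_rate: must be in [0, 1]")
  fe <- config$features
  if (!is.null(fe$conf_threshold) &&
      (fe$conf_threshold < 0 || fe$conf_threshold > 1))
    add("features.conf_threshold: must be in [0, 1]")
  cl <- config$classify
  if (isTRUE(cl$enabled)) {
    if (identical(cl$protocol, "kfold") && (is.null(cl$k) || cl$k < 2))
      add("classify.k: k-fold protocol needs k >= 2")
    if (!is.null(cl$dropout) && (cl$dropout < 0 || cl$dropout >= 1))
      add("classify.dropout: must be in [0, 1)")
  }
  if (isTRUE(config$threshold_eval$enabled) &&
      !identical(sim$test_phase, "test2") && isTRUE(sim$enabled))
    add("threshold_eval: requires simulate.test_phase = 'test2' (dilution metadata)")
  list(ok = length(errors) == 0, errors = errors)
}

.stage_files <- function(dir) {
  fs <- list.files(dir, recursive = TRUE, full.names = TRUE)
  fs[!grepl("manifest\\.json$", fs)]
}

#' Run the pipeline
#'
#' Executes the enabled stages in order (simulate, features, classify,
#' threshold-eval, survey-compare), writing each stage's outputs plus a
#' manifest with per-file MD5 checksums, per-stage timing, the seed, and a
#' frozen copy of the config. A stage failure aborts with the failing
#' stage named; partial outputs are kept.
#'
#' @param config Configuration list; invalid configs abort with the
#'   structured error list in the message.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_run_config()) {
  val <- validate_config(config)
  if (!val$ok) {
    stop("invalid config:\n  ", paste(val$errors, collapse = "\n  "))
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out, "config_frozen.yaml"))
  manifest <- list(seed = config$seed, stages = list())
  seeds <- sub_seeds(config$seed, 6L)

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      outputs = res, elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  seg_dir <- file.path(out, "segments")
  meta_path <- file.path(out, "metadata.csv")

  # -- stage 1: simulate (or point at provided inputs) ---------------------
  if (isTRUE(config$simulate$enabled)) {
    run_stage("simulate", function() {
      sim <- config$simulate
      design <- study_design(
        n_dogs = sim$n_dogs, sessions = sim$sessions,
        trials_per_session = sim$trials_per_session, fps = sim$fps,
        duration_mean = sim$duration_mean, duration_sd = sim$duration_sd,
        effect_scale = sim$effect_scale, test_phase = sim$test_phase,
        seed = seeds[1])
      noise <- do.call(noise_model, config$noise)
      profiles <- sample_dog_profiles(sim$n_dogs, seed = seeds[2])
      study <- simulate_study(profiles, design, noise)
      dir.create(seg_dir, showWarnings = FALSE)
      for (seg in study$segments) {
        write_landmark_table(
          seg$frames, file.path(seg_dir, sprintf("seg%05d.csv",
                                                 seg$segment_id)))
      }
      utils::write.csv(study$metadata, meta_path, row.names = FALSE)
      c(meta_path, file.path(seg_dir, sprintf("seg%05d.csv",
                                              study$metadata$segment_id)))
    })
  } else {
    meta_path <- config$input$metadata
    seg_dir <- config$input$segment_dir
  }

  # -- stage 2: kinematic features ----------------------------------------
  feat_path <- file.path(out, "features.csv")
  polar_path <- file.path(out, "polar_histogram.csv")
  run_stage("features", function() {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    fe <- config$features
    segs <- lapply(seq_len(nrow(meta)), function(i) {
      fr <- read_landmark_table(
        file.path(seg_dir, sprintf("seg%05d.csv", meta$segment_id[i])))
      trajectory_segment(fr, dog_id = meta$dog_id[i],
                         session = meta$session[i], trial = meta$trial[i],
                         area = meta$area[i], label = meta$label[i],
                         sub_label = meta$sub_label[i],
                         test_phase = meta$test_phase[i],
                         dilution_exponent = meta$dilution_exponent[i],
                         alerted = meta$alerted[i],
                         segment_id = meta$segment_id[i])
    })
    feats <- feature_table(segs, velocity_mode = fe$velocity_mode,
                           conf_threshold = fe$conf_threshold,
                           max_gap = fe$max_gap)
    write_feature_table(feats, feat_path)
    all_theta <- unlist(lapply(segs, function(s)
      tail_angle_series(s, conf_threshold = fe$conf_threshold,
                        max_gap = fe$max_gap)$theta))
    write_polar_histogram(polar_histogram(all_theta, fe$n_sectors),
                          polar_path)
    c(feat_path, polar_path)
  })

  # -- stage 3: classification --------------------------------------------
  eval_path <- file.path(out, "eval_report.json")
  if (isTRUE(config$classify$enabled)) {
    run_stage("classify", function() {
      feats <- utils::read.csv(feat_path, stringsAsFactors = FALSE)
      cl <- config$classify
      rep <- if (identical(cl$classifier, "recurrent")) {
        meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
        segs <- lapply(seq_len(nrow(meta)), function(i) {
          fr <- read_landmark_table(
            file.path(seg_dir, sprintf("seg%05d.csv", meta$segment_id[i])))
          trajectory_segment(fr, dog_id = meta$dog_id[i],
                             label = meta$label[i],
                             segment_id = meta$segment_id[i])
        })
        samples <- build_sequence_samples(segs)
        cfg <- recurrent_config(epochs = cl$epochs, dropout = cl$dropout,
                                seed = seeds[3])
        if (identical(cl$protocol, "kfold")) {
          kfold_eval(samples, k = cl$k, cfg, seed = seeds[3])
        } else {
          leave_one_dog_out_eval(samples, cfg, seed = seeds[3])
        }
      } else {
        cfg <- ensemble_config(max_depth = cl$max_depth,
                               nrounds = cl$nrounds, seed = seeds[3])
        leave_one_dog_out_eval(feats, cfg, classifier = "ensemble",
                               seed = seeds[3])
      }
      write_eval_report(rep, eval_path,
                        csv = file.path(out, "eval_folds.csv"))
      c(eval_path, file.path(out, "eval_folds.csv"))
    })
  }

  # -- stage 4: concentration generalization ------------------------------
  if (isTRUE(config$threshold_eval$enabled)) {
    thr_path <- file.path(out, "threshold_eval.json")
    run_stage("threshold_eval", function() {
      feats <- utils::read.csv(feat_path, stringsAsFactors = FALSE)
      cfg <- ensemble_config(max_depth = config$classify$max_depth,
                             nrounds = config$classify$nrounds,
                             seed = seeds[4])
      rep <- threshold_generalization_eval(
        feats, cfg, train_dilution = config$threshold_eval$train_dilution)
      rep$model <- NULL
      write_eval_report(rep, thr_path)
      thr_path
    })
  }

  # -- stage 5: comparison with a (simulated) expert panel ----------------
  if (isTRUE(config$survey$enabled)) {
    cmp_path <- file.path(out, "expert_comparison.json")
    run_stage("survey_compare", function() {
      feats <- utils::read.csv(feat_path, stringsAsFactors = FALSE)
      sv <- config$survey
      cmp <- compare_model_to_experts(
        feats, n_videos = sv$n_videos, n_participants = sv$n_participants,
        expert_p_correct = sv$expert_p_correct, seed = seeds[5])
      jsonlite::write_json(cmp[c("auc_model", "auc_expert", "delong_p",
                                 "model_accuracy", "expert_accuracy",
                                 "per_dog_correlation")],
                           cmp_path, auto_unbox = TRUE, digits = NA)
      cmp_path
    })
  }

  files <- .stage_files(out)
  manifest$checksums <- as.list(stats::setNames(
    unname(tools::md5sum(files)), sub(paste0("^", out, "/?"), "", files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Compare model scores with a simulated expert panel on held-out videos
#'
#' Selects a balanced video set (half target-area segments from alerted
#' trials, half non-target), trains the feature ensemble on the remaining
#' segments, scores the held-out videos, simulates an expert panel on the
#' same videos, and compares the two with AUCs, the paired DeLong test and
#' the per-dog accuracy correlation.
#'
#' @param features Kinematic feature data frame.
#' @param n_videos Held-out video count (default 32: 16 target, 16
#'   non-target).
#' @param n_participants Simulated panel size.
#' @param expert_p_correct Mean per-answer probability an expert is correct.
#' @param expert_difficulty_sd Between-video spread of that probability,
#'   see [simulate_expert_responses()].
#' @param seed Integer seed.
#' @return List with AUCs, DeLong result, accuracies and the per-dog
#'   correlation.
#' @export
compare_model_to_experts <- function(features, n_videos = 32L,
                                     n_participants = 190L,
                                     expert_p_correct = 0.46,
                                     expert_difficulty_sd = 0.25,
                                     seed = 1L) {
  stopifnot(n_videos >= 4, n_videos %% 2 == 0)
  sseed <- sub_seeds(seed, 3L)
  half <- n_videos / 2L
  idx_t <- which(features$label == "target" &
                   (is.na(features$alerted) | features$alerted))
  idx_n <- which(features$label == "non_target")
  if (length(idx_t) < half || length(idx_n) < half) {
    stop("not enough segments to hold out ", n_videos, " videos")
  }
  held <- with_seed(sseed[1], c(sample(idx_t, half), sample(idx_n, half)))
  truth <- stats::setNames(features$label[held],
                           paste0("video", sprintf("%02d", seq_len(n_videos))))
  model <- train_feature_ensemble(features[-held, , drop = FALSE],
                                  ensemble_config(seed = sseed[2]))
  score_model <- predict(model, features[held, , drop = FALSE],
                         type = "prob")
  pred_model <- predict(model, features[held, , drop = FALSE])

  panel <- simulate_expert_responses(truth, n_participants = n_participants,
                                     p_correct = expert_p_correct,
                                     difficulty_sd = expert_difficulty_sd,
                                     seed = sseed[3])
  score_expert <- expert_video_scores(panel)$score
  acc_expert <- expert_accuracy(panel, truth)

  dl <- delong_paired_test(score_model, score_expert, truth)
  dogs <- features$dog_id[held]
  model_per_dog <- .per_dog_accuracy(pred_model, truth, dogs)
  # per-video expert correctness over answered responses only
  answered <- panel$responses != "skipped"
  correct <- (panel$responses == "target_present") ==
    matrix(truth == "target", nrow(panel$responses), length(truth),
           byrow = TRUE)
  per_video_expert <- colSums(correct & answered) / pmax(colSums(answered), 1)
  expert_per_dog <- data.frame(
    dog_id = names(tapply(per_video_expert, dogs, mean)),
    accuracy = as.numeric(tapply(per_video_expert, dogs, mean)))
  per_dog_cor <- tryCatch(
    per_dog_accuracy_correlation(model_per_dog, expert_per_dog),
    error = function(e) NA_real_, warning = function(w) NA_real_)

  list(auc_model = dl$auc_a, auc_expert = dl$auc_b, delong_z = dl$z,
       delong_p = dl$p,
       model_accuracy = unname(accuracy_f1(pred_model, truth)["accuracy"]),
       expert_accuracy = acc_expert$pooled,
       per_dog_correlation = per_dog_cor,
       model_per_dog = model_per_dog, expert_per_dog = expert_per_dog,
       truth = truth, score_model = score_model,
       score_expert = score_expert)
}
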