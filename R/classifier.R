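# Target / non-target sequence classification: body-frame normalized
# sequence samples, the recurrent classifier's cross-validation protocols
# (stratified k-fold and leave-one-dog-out), the gradient-boosting + RBF
# support-vector feature ensemble with weighted majority vote, and the
# concentration-generalization protocol.

#' Build classifier input samples from labelled segments
#'
#' Per frame, the three tail landmarks (base, middle, tip) are expressed in
#' the body-centred frame and divided by the shoulders to tail-base
#' distance (\code{scale_mode = "body"}, making the series invariant to
#' camera placement and dog size), or min-max scaled per clip
#' (\code{scale_mode = "clip"}). The seventh channel is the detector
#' confidence. Frames with a degenerate body frame or missing landmarks are
#' dropped; a segment without at least 2 usable frames is an error.
#'
#' @param segments List of labelled \code{trajectory_segment}.
#' @param scale_mode \code{"body"} (default) or \code{"clip"}.
#' @param eps Body-frame degeneracy threshold (px).
#' @return List of \code{sequence_sample}: \code{series} (T x 7 matrix with
#'   columns base_x, base_y, mid_x, mid_y, tip_x, tip_y, conf),
#'   \code{label}, \code{dog_id}, \code{metadata}.
#' @export
build_sequence_samples <- function(segments, scale_mode = c("body", "clip"),
                                   eps = 1) {
  scale_mode <- match.arg(scale_mode)
  lapply(segments, function(seg) {
    fr <- seg$frames
    bx <- fr$tail_base_x - fr$shoulders_x
    by <- fr$tail_base_y - fr$shoulders_y
    D <- sqrt(bx^2 + by^2)
    ok <- is.finite(D) & D > eps &
      stats::complete.cases(fr[c("tail_base_x", "tail_base_y",
                                 "tail_middle_x", "tail_middle_y",
                                 "tail_tip_x", "tail_tip_y")])
    if (sum(ok) < 2) {
      stop("segment ", seg$segment_id %||% "?",
           ": no usable frames for sequence construction")
    }
    fr <- fr[ok, , drop = FALSE]
    if (scale_mode == "body") {
      bx <- bx[ok] / D[ok]; by <- by[ok] / D[ok]; Dv <- D[ok]
      rx <- -by; ry <- bx
      proj <- function(px, py) {
        vx <- fr[[px]] - fr$tail_base_x
        vy <- fr[[py]] - fr$tail_base_y
        cbind((vx * rx + vy * ry) / Dv, (vx * bx + vy * by) / Dv)
      }
      series <- cbind(proj("tail_base_x", "tail_base_y"),
                      proj("tail_middle_x", "tail_middle_y"),
                      proj("tail_tip_x", "tail_tip_y"),
                      fr$conf)
    } else {
      mm <- function(v) {
        rng <- range(v)
        if (diff(rng) == 0) rep(0.5, length(v))
        else (v - rng[1]) / diff(rng)
      }
      series <- cbind(mm(fr$tail_base_x), mm(fr$tail_base_y),
                      mm(fr$tail_middle_x), mm(fr$tail_middle_y),
                      mm(fr$tail_tip_x), mm(fr$tail_tip_y), fr$conf)
    }
    colnames(series) <- c("base_x", "base_y", "mid_x", "mid_y",
                          "tip_x", "tip_y", "conf")
    structure(list(series = series, label = seg$label, dog_id = seg$dog_id,
                   metadata = list(segment_id = seg$segment_id,
                                   test_phase = seg$test_phase,
                                   dilution_exponent = seg$dilution_exponent,
                                   area = seg$area)),
              class = "sequence_sample")
  })
}

#' Accuracy and F1 score
#'
#' Accuracy is the fraction of correct predictions; F1 is the harmonic mean
#' of precision and recall with \code{"target"} as the positive class,
#' defined as 0 when precision + recall is 0.
#'
#' @param predictions,labels Character vectors in
#'   \code{\{"target", "non_target"\}} of equal length.
#' @return Named numeric vector \code{c(accuracy, f1)}.
#' @export
accuracy_f1 <- function(predictions, labels) {
  if (length(predictions) != length(labels)) stop("length mismatch")
  if (length(labels) == 0) stop("empty input")
  acc <- mean(predictions == labels)
  tp <- sum(predictions == "target" & labels == "target")
  fp <- sum(predictions == "target" & labels == "non_target")
  fn <- sum(predictions == "non_target" & labels == "target")
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(accuracy = acc, f1 = f1)
}

.sample_labels <- function(samples) {
  vapply(samples, `[[`, character(1), "label")
}

.sample_dogs <- function(samples) {
  vapply(samples, `[[`, character(1), "dog_id")
}

.new_eval_report <- function(protocol, folds, per_dog = NULL,
                             per_dilution = NULL, labels, seed) {
  structure(list(protocol = protocol, folds = folds,
                 accuracy = mean(folds$accuracy), f1 = mean(folds$f1),
                 per_dog = per_dog, per_dilution = per_dilution,
                 n_per_class = table(labels), seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> protocol=%s  accuracy=%.3f  f1=%.3f  (%d folds)\n",
              x$protocol, x$accuracy, x$f1, nrow(x$folds)))
  invisible(x)
}

# Per-dog accuracy from pooled held-out predictions.
.per_dog_accuracy <- function(pred, labels, dogs) {
  agg <- tapply(pred == labels, dogs, mean)
  data.frame(dog_id = names(agg), accuracy = as.numeric(agg),
             stringsAsFactors = FALSE)
}

#' Stratified k-fold evaluation of the recurrent classifier
#'
#' Samples are divided into k pairwise-disjoint folds stratified by label;
#' each fold serves once as the 20% held-out test set while the model is
#' trained on the rest. The reported accuracy and F1 are the means across
#' folds.
#'
#' @param samples List of \code{sequence_sample}.
#' @param k Number of folds (default 5).
#' @param config A [recurrent_config()].
#' @param seed Seed for fold assignment and per-fold training.
#' @return An \code{eval_report}.
#' @export
kfold_eval <- function(samples, k = 5L, config = recurrent_config(),
                       seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  labels <- .sample_labels(samples)
  if (min(table(labels)) < k) stop("need at least k samples per class")
  fold <- integer(length(samples))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  seeds <- sub_seeds(seed, k)
  pred <- character(length(samples))
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    cfg <- config; cfg$seed <- seeds[f]
    model <- train_recurrent(samples[fold != f], cfg)
    p <- predict_recurrent(model, samples[fold == f])
    ph <- ifelse(p >= 0.5, "target", "non_target")
    pred[fold == f] <- ph
    rows[[f]] <- data.frame(fold = f, n_test = sum(fold == f),
                            t(accuracy_f1(ph, labels[fold == f])))
  }
  folds <- do.call(rbind, rows)
  rep <- .new_eval_report("kfold5", folds,
                          per_dog = .per_dog_accuracy(pred, labels,
                                                      .sample_dogs(samples)),
                          labels = labels, seed = seed)
  rep$fold_assignment <- fold
  rep
}

#' Leave-one-dog-out evaluation
#'
#' One fold per dog: the model is trained on every other dog's samples and
#' tested on the held-out dog, so performance reflects generalization to
#' unseen individuals rather than dog-specific wag styles. The final
#' accuracy/F1 are means across dogs; per-dog accuracies are retained. A
#' held-out dog whose samples are all one class is flagged (accuracy is
#' still computed).
#'
#' @param samples List of \code{sequence_sample}, or a kinematic feature
#'   data frame (with \code{label} and \code{dog_id} columns) when
#'   \code{classifier = "ensemble"}.
#' @param config A [recurrent_config()] or [ensemble_config()].
#' @param classifier \code{"recurrent"} (default) or \code{"ensemble"}.
#' @param seed Seed for per-fold training.
#' @return An \code{eval_report} with one fold per dog.
#' @export
leave_one_dog_out_eval <- function(samples,
                                   config = recurrent_config(),
                                   classifier = c("recurrent", "ensemble"),
                                   seed = 1L) {
  classifier <- match.arg(classifier)
  if (classifier == "ensemble" || is.data.frame(samples)) {
    labels <- samples$label
    dogs <- samples$dog_id
  } else {
    labels <- .sample_labels(samples)
    dogs <- .sample_dogs(samples)
  }
  dog_ids <- unique(dogs)
  if (length(dog_ids) < 2) stop("leave-one-dog-out needs >= 2 dogs")
  seeds <- sub_seeds(seed, length(dog_ids))
  rows <- vector("list", length(dog_ids))
  for (i in seq_along(dog_ids)) {
    d <- dog_ids[i]
    test <- dogs == d
    stopifnot(!any(dogs[!test] == d))  # dog-disjointness, asserted every run
    single_class <- length(unique(labels[test])) < 2
    if (single_class) {
      message("dog ", d, " has samples of only one class in its test fold")
    }
    if (classifier == "recurrent") {
      cfg <- config; cfg$seed <- seeds[i]
      model <- train_recurrent(samples[!test], cfg)
      p <- predict_recurrent(model, samples[test])
      ph <- ifelse(p >= 0.5, "target", "non_target")
    } else {
      cfg <- config; cfg$seed <- seeds[i]
      model <- train_feature_ensemble(samples[!test, , drop = FALSE], cfg)
      ph <- predict(model, samples[test, , drop = FALSE])
    }
    rows[[i]] <- data.frame(fold = i, dog_id = d, n_test = sum(test),
                            single_class = single_class,
                            t(accuracy_f1(ph, labels[test])),
                            stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, rows)
  .new_eval_report("leave_one_dog_out", folds,
                   per_dog = folds[c("dog_id", "accuracy")],
                   labels = labels, seed = seed)
}

#' Feature-ensemble configuration
#'
#' The test-2 classifier: a gradient-boosted decision-tree member with
#' maximum tree depth 9 and an RBF-kernel support-vector member, combined
#' by weighted majority vote. Member weights default to each member's own
#' validation accuracy on an internal stratified holdout; ties are broken
#' toward \code{non_target} (conservative: avoids false alerts).
#'
#' @param max_depth Tree depth of the boosted member.
#' @param nrounds Boosting rounds.
#' @param eta Boosting learning rate.
#' @param svm_cost Soft-margin cost of the SVM member.
#' @param weights Optional fixed member weights \code{c(xgb, svm)} (> 0).
#' @param val_fraction Holdout fraction used to estimate member weights.
#' @param features Feature columns used (default the six kinematic
#'   features).
#' @param seed Integer seed.
#' @return List of class \code{ensemble_config}.
#' @export
ensemble_config <- function(max_depth = 9L, nrounds = 100L, eta = 0.1,
                            svm_cost = 1, weights = NULL,
                            val_fraction = 0.2,
                            features = kinematic_feature_names(),
                            seed = 1L) {
  if (!is.null(weights)) stopifnot(length(weights) == 2, all(weights > 0))
  structure(list(max_depth = as.integer(max_depth),
                 nrounds = as.integer(nrounds), eta = eta,
                 svm_cost = svm_cost, weights = weights,
                 val_fraction = val_fraction, features = features,
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

.fit_members <- function(X, y, config) {
  xgb <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = config$max_depth, eta = config$eta,
                  nthread = 1),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = config$nrounds, verbose = 0)
  # scale only non-constant columns so degenerate features cannot poison
  # the kernel member
  scale_cols <- apply(X, 2, stats::sd) > 1e-12
  sv <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                   cost = config$svm_cost, scale = scale_cols)
  # Platt-style probability calibration of the SVM decision values, fitted
  # deterministically on the training data (avoids libsvm's internally
  # randomized probability model)
  pr <- predict(sv, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  sign_flip <- if (identical(colnames(dv), "0/1")) -1 else 1
  dec <- sign_flip * as.numeric(dv)
  platt <- suppressWarnings(
    stats::glm(y ~ dec, family = stats::binomial()))
  list(xgb = xgb, svm = sv, svm_sign = sign_flip, platt = platt)
}

.member_predict <- function(members, X) {
  p_xgb <- predict(members$xgb, xgboost::xgb.DMatrix(X, nthread = 1))
  pr <- predict(members$svm, X, decision.values = TRUE)
  dec <- members$svm_sign * as.numeric(attr(pr, "decision.values"))
  p_svm <- as.numeric(stats::predict(members$platt,
                                     newdata = data.frame(dec = dec),
                                     type = "response"))
  cls_svm <- as.integer(as.character(pr))
  list(p_xgb = p_xgb, p_svm = p_svm,
       v_xgb = as.integer(p_xgb >= 0.5), v_svm = cls_svm)
}

#' Train the boosted-trees + SVM feature ensemble
#'
#' @param features Data frame with a \code{label} column
#'   (\code{target}/\code{non_target}) and the feature columns named in
#'   \code{config$features}.
#' @param config An [ensemble_config()].
#' @return List of class \code{feature_ensemble}.
#' @export
train_feature_ensemble <- function(features, config = ensemble_config()) {
  y <- as.integer(features$label == "target")
  if (length(unique(y)) < 2) stop("training set must contain both classes")
  X <- as.matrix(features[config$features])
  storage.mode(X) <- "double"
  with_seed(config$seed, {
    w <- config$weights
    if (is.null(w)) {
      # estimate member weights as validation accuracy on a stratified
      # internal holdout, then refit members on the full training set
      val <- logical(length(y))
      for (cl in c(0, 1)) {
        idx <- which(y == cl)
        n_val <- max(1L, round(config$val_fraction * length(idx)))
        val[sample(idx, n_val)] <- TRUE
      }
      if (length(unique(y[!val])) == 2 && sum(val) >= 2) {
        m0 <- .fit_members(X[!val, , drop = FALSE], y[!val], config)
        pv <- .member_predict(m0, X[val, , drop = FALSE])
        w <- c(mean(pv$v_xgb == y[val]), mean(pv$v_svm == y[val]))
      } else {
        w <- c(1, 1)
      }
      w <- pmax(w, 1e-6)
    }
    members <- .fit_members(X, y, config)
    structure(list(members = members, weights = w, config = config),
              class = "feature_ensemble")
  })
}

#' Predict with the feature ensemble
#'
#' Class predictions are a weighted majority vote of the two members, ties
#' broken toward \code{non_target}; probabilities are the weighted mean of
#' member probabilities (for ROC/AUC use).
#'
#' @param object A \code{feature_ensemble}.
#' @param newdata Feature data frame.
#' @param type \code{"class"} or \code{"prob"}.
#' @param ... Unused.
#' @return Character vector of labels, or numeric P(target).
#' @export
predict.feature_ensemble <- function(object, newdata,
                                     type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[object$config$features])
  storage.mode(X) <- "double"
  pv <- .member_predict(object$members, X)
  w <- object$weights
  if (type == "prob") {
    return((w[1] * pv$p_xgb + w[2] * pv$p_svm) / sum(w))
  }
  vote_target <- w[1] * pv$v_xgb + w[2] * pv$v_svm
  vote_non <- w[1] * (1 - pv$v_xgb) + w[2] * (1 - pv$v_svm)
  ifelse(vote_target > vote_non, "target", "non_target")
}

#' Concentration-generalization evaluation
#'
#' Trains the feature ensemble on segments from the training dilution and
#' evaluates on each lower-concentration dilution separately, producing the
#' accuracy-versus-dilution degradation curve. No cross-validation is used;
#' train and test dilutions must be disjoint.
#'
#' @param features Kinematic feature data frame with \code{label} and
#'   \code{dilution_exponent} columns.
#' @param config An [ensemble_config()].
#' @param train_dilution Dilution exponent of the training sessions
#'   (default -3).
#' @return An \code{eval_report} with one fold per test dilution and a
#'   \code{per_dilution} table.
#' @export
threshold_generalization_eval <- function(features,
                                          config = ensemble_config(),
                                          train_dilution = -3L) {
  dil <- features$dilution_exponent
  if (anyNA(dil)) stop("all segments need dilution metadata")
  train <- dil == train_dilution
  if (!any(train)) stop("no training segments at dilution ", train_dilution)
  test_dils <- sort(unique(dil[!train]), decreasing = TRUE)
  if (length(test_dils) == 0) stop("train and test dilutions overlap: no test data")
  model <- train_feature_ensemble(features[train, , drop = FALSE], config)
  rows <- list()
  for (d in test_dils) {
    sel <- dil == d & !train
    if (!any(sel)) {
      warning("no test segments at dilution ", d, "; omitted")
      next
    }
    ph <- predict(model, features[sel, , drop = FALSE])
    rows[[length(rows) + 1L]] <-
      data.frame(fold = length(rows) + 1L, dilution_exponent = d,
                 n_test = sum(sel), t(accuracy_f1(ph, features$label[sel])))
  }
  folds <- do.call(rbind, rows)
  rep <- .new_eval_report("train_high_test_low", folds,
                          per_dilution = folds[c("dilution_exponent",
                                                 "accuracy", "f1")],
                          labels = features$label[!train],
                          seed = config$seed)
  rep$model <- model
  rep
}

#' Write an evaluation report to JSON (and optionally fold CSV)
#'
#' @param report An \code{eval_report}.
#' @param path JSON output file.
#' @param csv Optional CSV path for the fold table.
#' @return \code{path}, invisibly.
#' @export
write_eval_report <- function(report, path, csv = NULL) {
  out <- list(protocol = report$protocol, accuracy = report$accuracy,
              f1 = report$f1, folds = report$folds,
              per_dog = report$per_dog, per_dilution = report$per_dilution,
              n_per_class = as.list(report$n_per_class), seed = report$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(csv)) utils::write.csv(report$folds, csv, row.names = FALSE)
  invisible(path)
}
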