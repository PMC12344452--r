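# Landmark-detector evaluation metrics: RMSE over per-landmark Euclidean
# errors and PCK (percentage of correct keypoints) at an anatomically
# normalized threshold.

#' Paired landmark predictions and ground truth
#'
#' @param pred,truth Numeric matrices (n x 2) of predicted and true
#'   positions, or data frames with x/y columns; rows aligned by landmark.
#' @param D Per-row normalization distance (px): the true shoulders to
#'   tail-base distance of the image each landmark belongs to. Recycled if
#'   scalar.
#' @param image Optional image id per row (for per-image summaries).
#' @param landmark Optional landmark name per row.
#' @return Data frame of class \code{landmark_pairs}.
#' @export
landmark_pairs <- function(pred, truth, D, image = NULL, landmark = NULL) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  stopifnot(ncol(pred) == 2, ncol(truth) == 2, nrow(pred) == nrow(truth))
  n <- nrow(pred)
  D <- rep_len(as.numeric(D), n)
  if (any(!is.na(D) & D <= 0)) stop("normalization distance D must be > 0")
  out <- data.frame(
    image = if (is.null(image)) 1L else rep_len(image, n),
    landmark = if (is.null(landmark)) seq_len(n) else rep_len(landmark, n),
    pred_x = pred[, 1], pred_y = pred[, 2],
    true_x = truth[, 1], true_y = truth[, 2], D = D,
    stringsAsFactors = FALSE)
  class(out) <- c("landmark_pairs", class(out))
  out
}

.pair_dist <- function(pairs) {
  sqrt((pairs$pred_x - pairs$true_x)^2 + (pairs$pred_y - pairs$true_y)^2)
}

.drop_missing_pairs <- function(pairs) {
  ok <- stats::complete.cases(pairs[c("pred_x", "pred_y", "true_x",
                                      "true_y")])
  n_missing <- sum(!ok)
  if (n_missing) message(n_missing, " pair(s) with missing entries excluded")
  pairs[ok, , drop = FALSE]
}

#' Root-mean-square landmark error
#'
#' Square root of the mean, over landmarks, of the squared Euclidean
#' distance between each predicted position and its ground truth. With
#' \code{per_coordinate = TRUE} the mean is instead taken over the 2n
#' scalar coordinate errors (a reading of the scalar formula that halves
#' the squared error per landmark).
#'
#' @param pairs A \code{landmark_pairs} set.
#' @param per_coordinate Use the per-coordinate variant (default FALSE).
#' @return RMSE in pixels.
#' @export
rmse <- function(pairs, per_coordinate = FALSE) {
  pairs <- .drop_missing_pairs(pairs)
  if (nrow(pairs) == 0) stop("no landmark pairs to evaluate")
  d2 <- (pairs$pred_x - pairs$true_x)^2 + (pairs$pred_y - pairs$true_y)^2
  if (per_coordinate) sqrt(mean(d2) / 2) else sqrt(mean(d2))
}

#' Percentage of correct keypoints (PCK)
#'
#' Percentage of predicted landmarks whose Euclidean distance to the truth
#' is at most \code{threshold} times the per-image normalization distance D
#' (the true shoulders to tail-base distance); a distance exactly on the
#' boundary counts as correct. Pooled over all landmarks by default;
#' \code{per_image = TRUE} averages the per-image percentages instead.
#'
#' @param pairs A \code{landmark_pairs} set.
#' @param threshold Fraction of D (default 0.1, i.e. PCK@0.1).
#' @param per_image Average per-image percentages (default FALSE: pooled).
#' @return Percentage in [0, 100].
#' @export
pck <- function(pairs, threshold = 0.1, per_image = FALSE) {
  if (threshold <= 0) stop("threshold must be > 0")
  pairs <- .drop_missing_pairs(pairs)
  if (nrow(pairs) == 0) stop("no landmark pairs to evaluate")
  if (any(is.na(pairs$D) | pairs$D <= 0)) {
    stop("normalization distance D must be > 0 for every pair")
  }
  correct <- .pair_dist(pairs) <= threshold * pairs$D
  if (per_image) {
    100 * mean(tapply(correct, pairs$image, mean))
  } else {
    100 * mean(correct)
  }
}

#' Detector evaluation report over a threshold grid
#'
#' @param pairs A \code{landmark_pairs} set.
#' @param thresholds PCK threshold grid.
#' @return List with pooled RMSE, per-landmark RMSE, and PCK per threshold.
#' @export
pose_evaluation_report <- function(pairs, thresholds = c(0.05, 0.1, 0.2)) {
  pairs <- .drop_missing_pairs(pairs)
  d2 <- (pairs$pred_x - pairs$true_x)^2 + (pairs$pred_y - pairs$true_y)^2
  list(
    rmse = sqrt(mean(d2)),
    rmse_per_landmark = vapply(split(d2, pairs$landmark),
                               function(x) sqrt(mean(x)), numeric(1)),
    pck = stats::setNames(
      vapply(thresholds, function(th) pck(pairs, th), numeric(1)),
      paste0("pck@", thresholds)),
    n_pairs = nrow(pairs))
}
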