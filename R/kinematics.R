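# Body-centred tail kinematics: body frame, signed tail angle, angular
# velocity, polar occupancy histogram, and per-segment feature extraction.

DEG <- 180 / pi

#' Landmark column names of a landmark table
#'
#' The canonical 14-column layout: time, six landmarks as (x, y) pairs in
#' image coordinates (x right, y down), and detector confidence.
#'
#' @return Character vector of column names.
#' @export
landmark_columns <- function() {
  pts <- c("nose", "front_head", "shoulders", "tail_base", "tail_middle",
           "tail_tip")
  c("t", as.vector(t(outer(pts, c("x", "y"), paste, sep = "_"))), "conf")
}

#' Construct the body-centred coordinate frame
#'
#' The frame is anchored at the tail base B with the +y body axis pointing
#' from the shoulders S towards B, and the +x axis pointing towards the
#' dog's right. In image coordinates (x right, y down) viewed from directly
#' above a non-mirrored camera, the dog's right is \code{(-b_y, b_x)} where
#' \code{(b_x, b_y)} is the unit shoulders-to-tail-base vector; the
#' \code{handedness} switch negates it for mirrored footage.
#'
#' @param shoulders Numeric length-2 position (px) of the shoulders landmark.
#' @param tail_base Numeric length-2 position (px) of the tail-base landmark.
#' @param handedness \code{"standard"} (y-down overhead image) or
#'   \code{"mirrored"}.
#' @param eps Minimum shoulders-to-tail-base distance (px) below which the
#'   frame is degenerate and flagged invalid.
#' @return List with \code{origin}, unit vectors \code{axis_b} and
#'   \code{axis_r}, and logical \code{valid}.
#' @export
body_frame <- function(shoulders, tail_base,
                       handedness = c("standard", "mirrored"), eps = 1) {
  handedness <- match.arg(handedness)
  b <- c(tail_base[1] - shoulders[1], tail_base[2] - shoulders[2])
  n <- sqrt(sum(b^2))
  if (!is.finite(n) || n <= eps) {
    return(list(origin = tail_base, axis_b = c(NA_real_, NA_real_),
                axis_r = c(NA_real_, NA_real_), valid = FALSE))
  }
  axis_b <- b / n
  axis_r <- c(-axis_b[2], axis_b[1])
  if (handedness == "mirrored") axis_r <- -axis_r
  list(origin = tail_base, axis_b = axis_b, axis_r = axis_r, valid = TRUE)
}

#' Signed tail angle of a single frame
#'
#' Angle between the shoulders-to-tail-base body axis and the vector from
#' the tail base to the tail middle, in degrees, positive towards the dog's
#' right, zero when the tail points straight back, range (-180, 180].
#'
#' @param tail_middle Numeric length-2 position (px).
#' @param bf Body frame from [body_frame()].
#' @return Signed angle in degrees, or \code{NA} if the frame is invalid or
#'   the landmark is missing.
#' @export
tail_angle <- function(tail_middle, bf) {
  if (!isTRUE(bf$valid) || anyNA(tail_middle)) return(NA_real_)
  m <- c(tail_middle[1] - bf$origin[1], tail_middle[2] - bf$origin[2])
  atan2(sum(m * bf$axis_r), sum(m * bf$axis_b)) * DEG
}

# Vectorized tail angle over the rows of a landmark table. Returns theta in
# degrees with NA where the body frame is degenerate or a landmark missing.
.tail_angles <- function(frames, handedness = "standard", eps = 1,
                         landmark = "tail_middle") {
  bx <- frames$tail_base_x - frames$shoulders_x
  by <- frames$tail_base_y - frames$shoulders_y
  n <- sqrt(bx^2 + by^2)
  ok <- is.finite(n) & n > eps
  ub <- bx / n; vb <- by / n
  ur <- -vb; vr <- ub
  if (handedness == "mirrored") { ur <- -ur; vr <- -vr }
  mx <- frames[[paste0(landmark, "_x")]] - frames$tail_base_x
  my <- frames[[paste0(landmark, "_y")]] - frames$tail_base_y
  theta <- atan2(mx * ur + my * vr, mx * ub + my * vb) * DEG
  theta[!ok | !is.finite(mx) | !is.finite(my)] <- NA_real_
  theta
}

#' Per-frame tail-angle series of a trajectory segment
#'
#' Computes the signed tail angle for every frame, masks frames with a
#' degenerate body frame, a missing tail landmark, or detector confidence
#' below \code{conf_threshold}, and linearly interpolates the angle across
#' masked runs of at most \code{max_gap} frames (interpolation is done in
#' angle space, not on raw coordinates; longer runs stay masked).
#'
#' @param segment A \code{trajectory_segment} or a landmark-table data frame.
#' @param handedness Image handedness, see [body_frame()].
#' @param conf_threshold Confidence below which a frame is masked.
#' @param max_gap Longest masked run (frames) that is interpolated.
#' @param eps Degeneracy threshold for the body frame (px).
#' @param landmark Tail landmark defining the angle, default
#'   \code{"tail_middle"} (the tip is less stable, especially for curly
#'   tails).
#' @return List of class \code{tail_angle_series} with \code{t},
#'   \code{theta} (deg, NA where masked) and logical \code{valid}.
#' @export
tail_angle_series <- function(segment, handedness = "standard",
                              conf_threshold = 0.5, max_gap = 5, eps = 1,
                              landmark = "tail_middle") {
  frames <- if (is.data.frame(segment)) segment else segment$frames
  theta <- .tail_angles(frames, handedness = handedness, eps = eps,
                        landmark = landmark)
  theta <- confidence_filter(theta, frames$conf, frames$t,
                             threshold = conf_threshold, max_gap = max_gap)
  structure(list(t = frames$t, theta = theta, valid = !is.na(theta)),
            class = "tail_angle_series")
}

#' Mask low-confidence frames and bridge short gaps
#'
#' Frames with confidence below \code{threshold} are masked; masked runs of
#' at most \code{max_gap} frames that are flanked by valid frames are filled
#' by linear interpolation of the angle over time. Runs longer than
#' \code{max_gap}, and runs touching either end of the series, stay masked.
#'
#' @param theta Angle series (deg), may already contain NA.
#' @param conf Per-frame confidence in [0, 1] (NULL to skip thresholding).
#' @param t Frame times (s); defaults to frame index.
#' @param threshold Confidence threshold.
#' @param max_gap Longest run to interpolate, in frames.
#' @return Angle series with short gaps filled, long gaps NA.
#' @export
confidence_filter <- function(theta, conf = NULL, t = NULL, threshold = 0.5,
                              max_gap = 5) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (is.null(t)) t <- seq_along(theta)
  out <- theta
  if (!is.null(conf)) out[!is.na(conf) & conf < threshold] <- NA_real_
  bad <- is.na(out)
  if (!any(bad) || all(bad)) return(out)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fill <- which(r$values & r$lengths <= max_gap &
                  starts > 1L & ends < length(out))
  for (k in fill) {
    i0 <- starts[k] - 1L; i1 <- ends[k] + 1L
    idx <- starts[k]:ends[k]
    out[idx] <- out[i0] + (out[i1] - out[i0]) *
      (t[idx] - t[i0]) / (t[i1] - t[i0])
  }
  out
}

# Wrap angle differences into (-180, 180].
.wrap_diff <- function(d) {
  w <- ((d + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Angular velocity from a tail-angle series
#'
#' First differences of the tail angle between consecutive frames, wrapped
#' into (-180, 180] so a crossing of the +/-180 cut does not produce a
#' spurious full-circle jump. \code{per_second} divides by the frame
#' interval (frame-rate independent); \code{per_frame} reports the raw
#' wrapped difference, matching a fixed-rate per-frame convention.
#'
#' @param theta Angle series (deg), NA where masked.
#' @param t Frame times (s).
#' @param mode \code{"per_second"} (deg/s, default) or \code{"per_frame"}
#'   (deg/frame).
#' @return Numeric vector of length \code{length(theta) - 1}; element i is
#'   the velocity over (i, i+1], NA if either endpoint is masked.
#' @export
angular_velocity <- function(theta, t, mode = c("per_second", "per_frame")) {
  mode <- match.arg(mode)
  stopifnot(length(theta) == length(t), length(theta) >= 2)
  dt <- diff(t)
  if (any(dt <= 0, na.rm = TRUE)) stop("timestamps must be strictly increasing")
  w <- .wrap_diff(diff(theta))
  if (mode == "per_second") w <- w / dt
  w
}

#' Polar occupancy histogram of the tail angle
#'
#' Divides the semicircle behind the dog, [-90, +90] degrees, into
#' \code{n_sectors} equal sectors and counts the frames whose tail angle
#' falls in each; angles beyond +/-90 are clipped into the terminal sectors.
#' Masked frames are not counted.
#'
#' @param theta Angle series (deg).
#' @param n_sectors Number of sectors (>= 2), default 18 sectors of 10 deg.
#' @return List of class \code{polar_histogram} with \code{sector_edges},
#'   \code{counts} and \code{n_frames}.
#' @export
polar_histogram <- function(theta, n_sectors = 18) {
  if (n_sectors < 2) stop("n_sectors must be >= 2")
  th <- theta[!is.na(theta)]
  th <- pmin(pmax(th, -90), 90)
  edges <- seq(-90, 90, length.out = n_sectors + 1)
  idx <- findInterval(th, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_sectors)
  structure(list(sector_edges = edges, counts = counts,
                 n_frames = length(th)),
            class = "polar_histogram")
}

#' Per-segment kinematic feature profile
#'
#' The six per-segment summary features of the tail-angle series:
#' \describe{
#'   \item{mean_angle}{mean signed angle over the search (deg).}
#'   \item{amp_positive}{largest rightward excursion, \code{max} of the
#'     positive angles (deg; 0 if the tail never crosses right).}
#'   \item{amp_negative}{largest leftward excursion, \code{|min|} of the
#'     negative angles (deg; 0 if never left).}
#'   \item{mean_abs_velocity}{mean absolute angular velocity (deg/s by
#'     default).}
#'   \item{sum_positive}{fraction of valid frames with the tail right of the
#'     body axis.}
#'   \item{sum_negative}{fraction with the tail left of the axis.}
#' }
#' \code{zero_fraction} is reported as the exact complement
#' \code{1 - (sum_positive + sum_negative)} so the occupancy partition sums
#' to one; it differs from the count ratio by at most one ulp.
#'
#' @param segment A \code{trajectory_segment}, a landmark-table data frame,
#'   or a \code{tail_angle_series}.
#' @param velocity_mode Passed to [angular_velocity()].
#' @param min_valid Minimum number of valid frames required.
#' @param ... Passed to [tail_angle_series()] when \code{segment} is not
#'   already an angle series.
#' @return One-row data frame of class \code{kinematic_profile}.
#' @export
extract_features <- function(segment, velocity_mode = "per_second",
                             min_valid = 2, ...) {
  series <- if (inherits(segment, "tail_angle_series")) segment
            else tail_angle_series(segment, ...)
  th <- series$theta
  ok <- !is.na(th)
  n <- sum(ok)
  if (n < min_valid) {
    stop("too few valid frames for feature extraction (", n, " < ",
         min_valid, ")")
  }
  thv <- th[ok]
  omega <- angular_velocity(th, series$t, mode = velocity_mode)
  n_pos <- sum(thv > 0); n_neg <- sum(thv < 0)
  sp <- n_pos / n; sn <- n_neg / n
  out <- data.frame(
    mean_angle = mean(thv),
    amp_positive = if (n_pos > 0) max(thv[thv > 0]) else 0,
    amp_negative = if (n_neg > 0) abs(min(thv[thv < 0])) else 0,
    mean_abs_velocity = if (all(is.na(omega))) NA_real_
                        else mean(abs(omega), na.rm = TRUE),
    sum_positive = sp,
    sum_negative = sn,
    zero_fraction = 1 - (sp + sn),
    n_valid_frames = n
  )
  class(out) <- c("kinematic_profile", class(out))
  out
}

#' Kinematic feature table for a set of segments
#'
#' Applies [extract_features()] to every segment and binds the results to
#' the segment metadata. Segments with too few valid frames are dropped and
#' reported via a message.
#'
#' @param segments List of \code{trajectory_segment} objects.
#' @param ... Passed to [extract_features()].
#' @return Data frame with one row per usable segment: metadata columns
#'   (\code{segment_id, dog_id, session, trial, area, label, sub_label,
#'   test_phase, dilution_exponent, alerted}) plus the feature columns.
#' @export
feature_table <- function(segments, ...) {
  rows <- vector("list", length(segments))
  failed <- integer(0)
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    prof <- tryCatch(extract_features(seg, ...), error = function(e) NULL)
    if (is.null(prof)) { failed <- c(failed, i); next }
    meta <- data.frame(
      segment_id = if (!is.null(seg$segment_id)) seg$segment_id else i,
      dog_id = seg$dog_id %||% NA_character_,
      session = seg$session %||% NA_integer_,
      trial = seg$trial %||% NA_integer_,
      area = seg$area %||% NA_character_,
      label = seg$label %||% NA_character_,
      sub_label = seg$sub_label %||% NA_character_,
      test_phase = seg$test_phase %||% NA_character_,
      dilution_exponent = seg$dilution_exponent %||% NA_integer_,
      alerted = seg$alerted %||% NA,
      stringsAsFactors = FALSE
    )
    rows[[i]] <- cbind(meta, as.data.frame(prof))
  }
  if (length(failed)) {
    message(length(failed), " segment(s) dropped: too few valid frames")
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Names of the six kinematic features
#' @return Character vector.
#' @export
kinematic_feature_names <- function() {
  c("mean_angle", "amp_positive", "amp_negative", "mean_abs_velocity",
    "sum_positive", "sum_negative")
}

#' Write a kinematic feature table to CSV
#' @param features Data frame from [feature_table()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Export a polar histogram in long CSV format
#' @param ph A \code{polar_histogram}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_polar_histogram <- function(ph, path) {
  df <- data.frame(sector_lo = ph$sector_edges[-length(ph$sector_edges)],
                   sector_hi = ph$sector_edges[-1],
                   count = ph$counts)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
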