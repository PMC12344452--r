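# Landmark-table and behavioural event-log IO, trial segmentation into
# per-area search segments, alert-window excision, and labelling.

AREA_BEHAVIOURS <- c("area1", "area2", "area3")
KNOWN_BEHAVIOURS <- c(AREA_BEHAVIOURS, "alert")

#' Trajectory segment
#'
#' An ordered run of landmark frames for one dog searching one wall area,
#' with trial metadata and target/non-target labels attached as they become
#' known along the pipeline.
#'
#' @param frames Landmark-table data frame (see [landmark_columns()]) with
#'   at least 2 rows and strictly increasing \code{t}.
#' @param dog_id,session,trial,area,label,sub_label,test_phase,
#'   dilution_exponent,alerted Metadata slots (may be NA until labelled).
#' @param segment_id Optional identifier.
#' @return List of class \code{trajectory_segment}.
#' @export
trajectory_segment <- function(frames, dog_id = NA_character_,
                               session = NA_integer_, trial = NA_integer_,
                               area = NA_character_, label = NA_character_,
                               sub_label = NA_character_,
                               test_phase = NA_character_,
                               dilution_exponent = NA_integer_,
                               alerted = NA, segment_id = NA_integer_) {
  stopifnot(is.data.frame(frames), nrow(frames) >= 2)
  if (any(diff(frames$t) <= 0)) stop("frame times must be strictly increasing")
  if (!is.na(label) && !is.na(sub_label) &&
      xor(label == "target", sub_label == "target")) {
    stop("label must be 'target' exactly when sub_label is 'target'")
  }
  structure(list(frames = frames, dog_id = dog_id, session = session,
                 trial = trial, area = area, label = label,
                 sub_label = sub_label, test_phase = test_phase,
                 dilution_exponent = dilution_exponent, alerted = alerted,
                 segment_id = segment_id),
            class = "trajectory_segment")
}

#' @export
print.trajectory_segment <- function(x, ...) {
  cat(sprintf(
    "<trajectory_segment> %d frames [%.2f, %.2f] s  dog=%s area=%s label=%s\n",
    nrow(x$frames), min(x$frames$t), max(x$frames$t),
    x$dog_id, x$area, x$label))
  invisible(x)
}

#' Read a per-frame landmark table
#'
#' Comma-separated, dot-decimal, header required; the 14 columns of
#' [landmark_columns()] must be present (extra columns are ignored). Cells
#' that cannot be parsed as numbers are set missing and reported with their
#' file line numbers; empty cells become missing values, never zeros.
#'
#' @param path File path.
#' @param sort If TRUE, rows are ordered by time; if FALSE (default),
#'   non-monotone timestamps are an error.
#' @return Data frame of frames ordered by \code{t}.
#' @export
read_landmark_table <- function(path, sort = FALSE) {
  if (!file.exists(path)) stop("cannot read landmark table: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  need <- landmark_columns()
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("landmark table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- raw[need]
  bad_lines <- integer(0)
  for (cc in need) {
    v <- out[[cc]]
    num <- suppressWarnings(as.numeric(v))
    malformed <- which(is.na(num) & !is.na(v) & nzchar(v))
    if (length(malformed)) bad_lines <- union(bad_lines, malformed + 1L)
    out[[cc]] <- num
  }
  if (length(bad_lines)) {
    warning("malformed cells set to missing on line(s): ",
            paste(sort(bad_lines), collapse = ", "))
  }
  if (anyNA(out$t)) stop("missing timestamps in landmark table")
  if (is.unsorted(out$t, strictly = TRUE)) {
    if (!sort) stop("timestamps are not strictly increasing (set sort = TRUE)")
    out <- out[order(out$t), , drop = FALSE]
    if (anyDuplicated(out$t)) stop("duplicate timestamps in landmark table")
  }
  rownames(out) <- NULL
  out
}

#' Write a landmark table
#'
#' Numbers are written with 17 significant digits so a write/read round
#' trip reproduces every value bit-exactly.
#'
#' @param frames Landmark-table data frame.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_landmark_table <- function(frames, path) {
  out <- frames[landmark_columns()]
  for (cc in names(out)) {
    v <- formatC(out[[cc]], digits = 17, format = "g")
    v[is.na(out[[cc]])] <- ""
    out[[cc]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a behavioural event log
#'
#' Parses the tabular export dialect of the BORIS annotation tool: one row
#' per coded bout with behaviour, start and stop columns (column-name
#' matching is case-insensitive and tolerant of the \code{"Start (s)"}
#' style; delimiter is sniffed between comma and tab). Area bouts must be
#' mutually exclusive in time.
#'
#' @param path File path.
#' @param unknown How to treat behaviours outside the ethogram
#'   (\code{area1..area3, alert}): \code{"reject"} (error), \code{"drop"},
#'   or \code{"keep"}.
#' @param rezero If TRUE, subtract the earliest start so times are relative
#'   to trial start (BORIS media offsets).
#' @return Data frame with columns \code{behaviour, start, stop}.
#' @export
read_event_log <- function(path, unknown = c("reject", "drop", "keep"),
                           rezero = FALSE) {
  unknown <- match.arg(unknown)
  if (!file.exists(path)) stop("cannot read event log: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           strip.white = TRUE)
  lw <- tolower(trimws(names(raw)))
  pick <- function(patterns) {
    for (p in patterns) {
      hit <- grep(p, lw)
      if (length(hit)) return(hit[1])
    }
    NA_integer_
  }
  ib <- pick(c("^behaviou?r$", "behaviou?r"))
  is_ <- pick(c("^start", "start"))
  ip <- pick(c("^stop", "stop", "^end"))
  if (anyNA(c(ib, is_, ip))) {
    stop("event log must contain behaviour, start and stop columns")
  }
  ev <- data.frame(behaviour = tolower(trimws(as.character(raw[[ib]]))),
                   start = as.numeric(raw[[is_]]),
                   stop = as.numeric(raw[[ip]]),
                   stringsAsFactors = FALSE)
  ev$behaviour <- gsub("[[:space:]]+", "", ev$behaviour)
  unk <- which(!ev$behaviour %in% KNOWN_BEHAVIOURS)
  if (length(unk)) {
    if (unknown == "reject") {
      stop("unknown behaviour label(s) in row(s) ",
           paste(unk, collapse = ", "), ": ",
           paste(unique(ev$behaviour[unk]), collapse = ", "))
    }
    if (unknown == "drop") ev <- ev[-unk, , drop = FALSE]
  }
  bad <- which(!(ev$stop > ev$start))
  if (length(bad)) {
    stop("stop <= start in event row(s): ", paste(bad, collapse = ", "))
  }
  if (rezero && nrow(ev)) {
    ev$stop <- ev$stop - min(ev$start)
    ev$start <- ev$start - min(ev$start)
  }
  .check_area_overlap(ev)
  rownames(ev) <- NULL
  ev
}

# Area bouts must not overlap (half-open intervals: touching is fine).
.check_area_overlap <- function(ev) {
  a <- ev[ev$behaviour %in% AREA_BEHAVIOURS, , drop = FALSE]
  if (nrow(a) < 2) return(invisible())
  o <- order(a$start)
  rows <- as.integer(rownames(a))[o]
  a <- a[o, ]
  overlap <- which(a$start[-1] < a$stop[-nrow(a)])
  if (length(overlap)) {
    i <- overlap[1]
    stop(sprintf("overlapping area events: row %d (%s %.3f-%.3f) and row %d (%s %.3f-%.3f)",
                 rows[i], a$behaviour[i], a$start[i], a$stop[i],
                 rows[i + 1], a$behaviour[i + 1], a$start[i + 1],
                 a$stop[i + 1]))
  }
  invisible()
}

#' Split a trial's frames into per-area search segments
#'
#' One segment per maximal area bout; a frame belongs to the bout whose
#' half-open interval [start, stop) contains its timestamp, so a frame
#' exactly on a boundary belongs to the later bout. Bouts yielding fewer
#' than \code{min_frames} frames are dropped and counted.
#'
#' @param frames Landmark-table data frame.
#' @param events Event-record data frame from [read_event_log()].
#' @param min_frames Minimum frames per segment (default 2).
#' @return List of unlabelled \code{trajectory_segment}s with attribute
#'   \code{dropped_frames} (frames inside area bouts that were discarded
#'   with an under-sized segment).
#' @export
split_segments <- function(frames, events, min_frames = 2L) {
  areas <- events[events$behaviour %in% AREA_BEHAVIOURS, , drop = FALSE]
  if (nrow(areas) == 0) stop("no area events in event log")
  areas <- areas[order(areas$start), , drop = FALSE]
  segs <- list(); dropped <- 0L
  for (i in seq_len(nrow(areas))) {
    sel <- frames$t >= areas$start[i] & frames$t < areas$stop[i]
    n <- sum(sel)
    if (n < min_frames) {
      if (n > 0) message("dropping ", n, " frame(s): bout ", i, " (",
                         areas$behaviour[i], ") too short")
      dropped <- dropped + n
      next
    }
    segs[[length(segs) + 1L]] <-
      trajectory_segment(frames[sel, , drop = FALSE],
                         area = areas$behaviour[i])
  }
  attr(segs, "dropped_frames") <- dropped
  segs
}

#' Excise alert windows from search segments
#'
#' Frames from one second before an alert starts through the end of the
#' alert are removed (the alert posture is a trained response, not search
#' behaviour, and the second before it is contaminated by its onset). A
#' segment intersected by an alert keeps only its pre-alert part; whatever
#' follows a completed alert is reward/handler interaction and is
#' discarded. Segments left shorter than \code{min_duration} seconds (or
#' \code{min_frames} frames) are dropped.
#'
#' @param segments List of \code{trajectory_segment}.
#' @param events Event-record data frame (only \code{alert} rows are used).
#' @param pre_buffer Seconds excised before alert onset (default 1).
#' @param min_duration Minimum retained segment span (s), default 0.5.
#' @param min_frames Minimum retained frames, default 2.
#' @return Filtered list of segments (unchanged if there are no alerts).
#' @export
excise_alert <- function(segments, events, pre_buffer = 1.0,
                         min_duration = 0.5, min_frames = 2L) {
  alerts <- events[events$behaviour == "alert", , drop = FALSE]
  if (nrow(alerts) == 0) return(segments)
  out <- list()
  for (seg in segments) {
    fr <- seg$frames
    t0 <- min(fr$t); t1 <- max(fr$t)
    hit <- alerts[alerts$start - pre_buffer <= t1 & alerts$stop >= t0, ,
                  drop = FALSE]
    if (nrow(hit)) {
      cutoff <- min(hit$start) - pre_buffer
      fr <- fr[fr$t < cutoff, , drop = FALSE]
    }
    if (nrow(fr) < min_frames) next
    if (max(fr$t) - min(fr$t) < min_duration) next
    seg$frames <- fr
    out[[length(out) + 1L]] <- seg
  }
  out
}

#' Trial layout
#'
#' Maps each wall area to its content for one trial and records the trial
#' outcome. Test 1 has one target, one distractor and one no-odour area;
#' test 2 has one target and two distractor areas.
#'
#' @param mapping Named character vector, names are areas, values in
#'   \code{target, distractor, no_odour}; exactly one \code{target}.
#' @param alerted Did the dog alert correctly in this trial?
#' @param trial Optional trial id.
#' @return List of class \code{trial_layout}.
#' @export
trial_layout <- function(mapping, alerted = NA, trial = NA_integer_) {
  stopifnot(all(mapping %in% c("target", "distractor", "no_odour")),
            sum(mapping == "target") == 1)
  structure(list(mapping = mapping, alerted = alerted, trial = trial),
            class = "trial_layout")
}

#' Label segments from a trial layout
#'
#' Sets \code{sub_label} from the layout's area mapping, \code{label} to
#' \code{"target"} exactly for target-area segments and
#' \code{"non_target"} otherwise, and the trial's alert outcome.
#'
#' @param segments List of \code{trajectory_segment}.
#' @param layout A \code{trial_layout}.
#' @return Labelled segments; label counts are reported via a message.
#' @export
label_segments <- function(segments, layout) {
  stopifnot(inherits(layout, "trial_layout"))
  out <- lapply(segments, function(seg) {
    if (!seg$area %in% names(layout$mapping)) {
      stop("segment area '", seg$area, "' missing from trial layout")
    }
    seg$sub_label <- unname(layout$mapping[[seg$area]])
    seg$label <- if (seg$sub_label == "target") "target" else "non_target"
    seg$alerted <- layout$alerted
    if (!is.na(layout$trial)) seg$trial <- layout$trial
    seg
  })
  labs <- vapply(out, `[[`, character(1), "label")
  message(sum(labs == "target"), " target / ",
          sum(labs == "non_target"), " non-target segment(s)")
  out
}

#' Select training positives by trial outcome
#'
#' For classifier training only target-area segments from trials in which
#' the dog successfully alerted count as positives; non-target segments
#' pass through unchanged when \code{keep_non_target} is TRUE.
#'
#' @param segments Labelled segments with \code{alerted} populated.
#' @param keep_non_target Keep non-target segments (default TRUE).
#' @return Filtered segment list.
#' @export
filter_training_positives <- function(segments, keep_non_target = TRUE) {
  keep <- vapply(segments, function(seg) {
    if (is.na(seg$label)) stop("segments must be labelled")
    if (seg$label == "target") isTRUE(seg$alerted)
    else keep_non_target
  }, logical(1))
  segments[keep]
}

#' Write segment metadata to CSV
#' @param segments Labelled segments.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_segment_metadata <- function(segments, path) {
  meta <- do.call(rbind, lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    data.frame(segment_id = s$segment_id %||% i, dog = s$dog_id,
               session = s$session, trial = s$trial, area = s$area,
               label = s$label, sub_label = s$sub_label,
               test_phase = s$test_phase, dilution = s$dilution_exponent,
               alerted = s$alerted, n_frames = nrow(s$frames),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(meta, path, row.names = FALSE)
  invisible(path)
}

#' Write an event log in BORIS-style tabular form
#' @param events Data frame \code{behaviour, start, stop}.
#' @param path Output file (.tsv for tab-separated, else CSV).
#' @return \code{path}, invisibly.
#' @export
write_event_log <- function(events, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- data.frame(Behavior = events$behaviour,
                    `Start (s)` = events$start,
                    `Stop (s)` = events$stop, check.names = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
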