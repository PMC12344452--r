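# Landmark-table and event-log IO, segmentation, excision, labelling.

make_frames <- function(t) {
  n <- length(t)
  df <- data.frame(t = t)
  for (cc in setdiff(landmark_columns(), c("t", "conf"))) {
    df[[cc]] <- rnorm(n, 100, 30)
  }
  df$conf <- runif(n)
  df
}

test_that("landmark tables round-trip bit-exactly", {
  set.seed(20)
  fr <- make_frames(seq(0, 1, by = 1 / 60))
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(fr, path)
  back <- read_landmark_table(path)
  expect_identical(unname(as.matrix(back)), unname(as.matrix(fr)))
})

test_that("missing cells come back missing, malformed cells are reported", {
  fr <- make_frames(c(0, 1 / 60, 2 / 60))
  fr$tail_tip_x[2] <- NA; fr$tail_tip_y[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(fr, path)
  back <- read_landmark_table(path)
  expect_true(is.na(back$tail_tip_x[2]))
  expect_equal(nrow(back), 3)

  # corrupt one cell in the raw text: warned with the file line number
  txt <- readLines(path)
  txt[3] <- sub("^([^,]*),[^,]*", "\\1,oops", txt[3])
  writeLines(txt, path)
  expect_warning(back2 <- read_landmark_table(path), "line\\(s\\): 3")
  expect_true(is.na(back2$nose_x[2]))
})

test_that("shuffled rows are restored to time order only when asked", {
  set.seed(21)
  fr <- make_frames(seq(0, 0.5, by = 1 / 60))
  shuffled <- fr[sample(nrow(fr)), ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(shuffled, path)
  expect_error(read_landmark_table(path), "sort")
  back <- read_landmark_table(path, sort = TRUE)
  expect_identical(back$t, sort(fr$t))  # explicit sort oracle
  expect_equal(back$nose_x, fr$nose_x[order(fr$t)][seq_len(nrow(back))])
})

test_that("required columns are enforced", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("t,nose_x\n0,1\n0.1,2", path)
  expect_error(read_landmark_table(path), "tail_base_x")
})

test_that("event logs parse the BORIS-style dialect and reject overlaps", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Behavior\tStart (s)\tStop (s)",
               "area2\t0\t10"), path)
  ev <- read_event_log(path)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$behaviour, "area2")
  expect_equal(ev$stop, 10)

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("behaviour,start,stop", "area1,0,5", "area2,4,8"), path2)
  expect_error(read_event_log(path2), "overlapping area events")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("behaviour,start,stop", "area1,0,5", "grooming,5,6"), path3)
  expect_error(read_event_log(path3), "unknown behaviour")
  expect_equal(nrow(read_event_log(path3, unknown = "drop")), 1)
  expect_equal(nrow(read_event_log(path3, unknown = "keep")), 2)

  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("behaviour,start,stop", "area1,5,5"), path4)
  expect_error(read_event_log(path4), "stop <= start")
})

test_that("an interleaved ethogram fixture parses to the hand-built records", {
  # alert nested inside area2; areas touch at boundaries (no overlap)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("behaviour,start,stop",
               "area1,0,3.5",
               "area2,3.5,9",
               "alert,6,9",
               "area3,9,12"), path)
  ev <- read_event_log(path)
  expect_identical(ev$behaviour, c("area1", "area2", "alert", "area3"))
  expect_identical(ev$start, c(0, 3.5, 6, 9))
  expect_identical(ev$stop, c(3.5, 9, 9, 12))
})

test_that("segment splitting follows the half-open interval rule", {
  fr <- make_frames(seq(0, 4 - 1 / 60, by = 1 / 60))
  ev <- data.frame(behaviour = c("area1", "area2"), start = c(0, 2),
                   stop = c(2, 4))
  segs <- split_segments(fr, ev)
  expect_length(segs, 2)
  expect_equal(nrow(segs[[1]]$frames), 120)
  expect_equal(nrow(segs[[2]]$frames), 120)
  expect_equal(segs[[1]]$area, "area1")
  # frame at exactly t = 2 belongs to the later bout
  expect_equal(min(segs[[2]]$frames$t), 2)

  one <- split_segments(fr, data.frame(behaviour = "area3", start = 0,
                                       stop = 5))
  expect_length(one, 1)
  expect_equal(nrow(one[[1]]$frames), nrow(fr))
  expect_error(split_segments(fr, data.frame(behaviour = "alert",
                                             start = 0, stop = 1)),
               "no area events")
})

test_that("random segmentations equal brute-force per-frame lookup", {
  set.seed(22)
  for (rep in 1:20) {
    fr <- make_frames(sort(runif(300, 0, 30)))
    cuts <- sort(runif(5, 1, 29))
    bounds <- c(0, cuts, 30)
    keep <- sort(sample(length(bounds) - 1, 4))
    ev <- data.frame(behaviour = sample(c("area1", "area2", "area3"), 4,
                                        replace = TRUE),
                     start = bounds[keep], stop = bounds[keep + 1])
    segs <- split_segments(fr, ev, min_frames = 2)
    # brute force: assign each frame to the event interval containing it
    assign <- rep(NA_integer_, nrow(fr))
    for (i in seq_len(nrow(fr))) {
      for (j in seq_len(nrow(ev))) {
        if (fr$t[i] >= ev$start[j] && fr$t[i] < ev$stop[j]) assign[i] <- j
      }
    }
    counts <- table(factor(assign, levels = seq_len(nrow(ev))))
    got <- integer(nrow(ev))
    for (s in segs) {
      j <- which(ev$behaviour == s$area &
                   ev$start <= min(s$frames$t) & max(s$frames$t) < ev$stop)
      got[j] <- nrow(s$frames)
    }
    in_events <- sum(!is.na(assign))
    expect_equal(sum(got) + attr(segs, "dropped_frames"), in_events)
    expect_true(all(got[got > 0] == counts[got > 0]))
  }
})

test_that("alert excision keeps only the pre-alert span", {
  fr <- make_frames(seq(0, 10 - 1 / 60, by = 1 / 60))
  segs <- split_segments(fr, data.frame(behaviour = "area1", start = 0,
                                        stop = 10))
  # alert 6-10: excise [5, 10]; retained span [0, 5)
  out <- excise_alert(segs, data.frame(behaviour = "alert", start = 6,
                                       stop = 10))
  expect_length(out, 1)
  expect_lt(max(out[[1]]$frames$t), 5)
  expect_equal(nrow(out[[1]]$frames), 300)

  # no alerts: identity
  expect_identical(excise_alert(segs, data.frame(behaviour = "area1",
                                                 start = 0, stop = 10)),
                   segs)

  # early interior alert: nothing before start - 1 s survives -> dropped
  out2 <- excise_alert(segs, data.frame(behaviour = "alert", start = 0.5,
                                        stop = 4.5))
  expect_length(out2, 0)
})

test_that("random excisions equal a brute-force frame mask", {
  set.seed(23)
  for (rep in 1:20) {
    fr <- make_frames(seq(0, 12, by = 1 / 30))
    segs <- split_segments(fr, data.frame(behaviour = "area2", start = 0,
                                          stop = 12.5))
    a0 <- runif(1, 0, 11); a1 <- a0 + runif(1, 0.3, 3)
    ev <- data.frame(behaviour = "alert", start = a0, stop = a1)
    out <- excise_alert(segs, ev, min_duration = 0, min_frames = 2)
    oracle <- fr$t[fr$t < a0 - 1]
    if (length(oracle) < 2) {
      expect_length(out, 0)
    } else {
      expect_length(out, 1)
      expect_identical(out[[1]]$frames$t, oracle)
    }
    # excision never increases frame counts
    if (length(out)) {
      expect_lte(nrow(out[[1]]$frames), nrow(segs[[1]]$frames))
    }
  }
})

test_that("labelling follows the trial layout and positives filter works", {
  fr <- make_frames(seq(0, 6 - 1 / 60, by = 1 / 60))
  ev <- data.frame(behaviour = c("area1", "area2", "area3"),
                   start = c(0, 2, 4), stop = c(2, 4, 6))
  segs <- split_segments(fr, ev)
  layout <- trial_layout(c(area1 = "target", area2 = "distractor",
                           area3 = "no_odour"), alerted = TRUE)
  suppressMessages(lab <- label_segments(segs, layout))
  expect_equal(vapply(lab, `[[`, character(1), "label"),
               c("target", "non_target", "non_target"))
  expect_equal(lab[[3]]$sub_label, "no_odour")

  # unlabelled area errors
  bad <- segs; bad[[1]]$area <- "area9"
  expect_error(suppressMessages(label_segments(bad, layout)), "area9")

  # positives filter: target kept only when alerted
  lab_no <- suppressMessages(
    label_segments(segs, trial_layout(c(area1 = "target",
                                        area2 = "distractor",
                                        area3 = "no_odour"),
                                      alerted = FALSE)))
  expect_length(filter_training_positives(lab), 3)
  expect_length(filter_training_positives(lab_no), 2)
  expect_length(filter_training_positives(lab_no, keep_non_target = FALSE), 0)
})

test_that("random layouts match a brute-force label lookup", {
  set.seed(24)
  for (rep in 1:50) {
    areas <- c("area1", "area2", "area3")
    contents <- sample(c("target", "distractor", "no_odour"))
    layout <- trial_layout(setNames(contents, areas),
                           alerted = runif(1) < 0.5)
    fr <- make_frames(seq(0, 1, by = 1 / 60))
    seg <- trajectory_segment(fr, area = sample(areas, 1))
    lab <- suppressMessages(label_segments(list(seg), layout))[[1]]
    expect_equal(lab$sub_label, unname(layout$mapping[[lab$area]]))
    expect_equal(lab$label == "target", lab$sub_label == "target")
  }
})
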