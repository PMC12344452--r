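# Generator: population sampling, inverse-pair with the kinematics
# extractor, duration calibration, study structure, determinism.

test_that("zero-spread population reproduces the means exactly", {
  pop <- default_population()
  for (nm in names(pop)) pop[[nm]][2] <- 0
  prof <- sample_dog_profiles(1, pop, seed = 5)[[1]]
  expect_equal(prof$baseline$bias, pop$bias[1])
  expect_equal(prof$baseline$amp_right, pop$amp_right[1])
  expect_equal(prof$baseline$amp_left, pop$amp_left[1])
  expect_equal(prof$baseline$freq, pop$freq[1])
  expect_equal(prof$body_scale, pop$body_scale[1])
  expect_equal(prof$target_shift$amp_left, pop$shift_amp_left[1])
})

test_that("profile sampling is deterministic and validates input", {
  p1 <- sample_dog_profiles(8, seed = 6)
  p2 <- sample_dog_profiles(8, seed = 6)
  expect_identical(p1, p2)
  expect_identical(anyDuplicated(vapply(p1, `[[`, character(1), "dog_id")),
                   0L)
  expect_error(sample_dog_profiles(0), "n_dogs")
  bad <- default_population(); bad$bias[2] <- -1
  expect_error(sample_dog_profiles(2, bad), "spread")
})

test_that("sampled bias spread matches the population spread", {
  pop <- default_population()
  pop$bias <- c(0, 5)
  prof <- sample_dog_profiles(1000, pop, seed = 7)
  s <- sd(vapply(prof, function(p) p$baseline$bias, numeric(1)))
  # 3 standard errors of an SD estimate at n = 1000: 3 * 5 / sqrt(2n)
  expect_lt(abs(s - 5), 0.35)
})

test_that("noise-free segments invert through the angle extractor", {
  prof <- dog_profile("d", wag_params(bias = 12, amp_right = 35,
                                      amp_left = 55, freq = 4,
                                      phase = 0.7, noise_sd = 0))
  des <- study_design()
  seg <- simulate_segment(prof, "area2", 2.5, des, zero_noise(), seed = 8)
  t <- seg$frames$t
  s <- sin(2 * pi * 4 * t + 0.7)
  theta_true <- 12 + ifelse(s >= 0, 35, 55) * s
  got <- tail_angle_series(seg, conf_threshold = 0)$theta
  expect_lt(max(abs(got - theta_true)), 1e-6)
})

test_that("degenerate oscillation gives a constant angle equal to the bias", {
  prof <- dog_profile("d", wag_params(bias = 9, amp_right = 0, amp_left = 0,
                                      freq = 4, noise_sd = 0))
  seg <- simulate_segment(prof, "area1", 1, study_design(), zero_noise(),
                          seed = 9)
  got <- tail_angle_series(seg, conf_threshold = 0)$theta
  expect_equal(got, rep(9, length(got)), tolerance = 1e-9)
})

test_that("segment preconditions are enforced", {
  prof <- dog_profile("d")
  expect_error(simulate_segment(prof, "area1", 0.01, study_design(),
                                zero_noise()), "too short")
  expect_error(simulate_segment(prof, "hallway", 2, study_design(),
                                zero_noise()), "invalid area")
})

test_that("durations reproduce the study's printed moments", {
  des <- study_design()
  set.seed(10)
  d <- sample_durations(5055, des)
  expect_gte(min(d), des$duration_min)
  expect_lt(abs(mean(d) - 3.34), 0.15)
  expect_lt(abs(sd(d) - 3.45), 0.5)   # SD of a heavy-tailed sample at n=5055
})

test_that("a minimal study yields one labelled segment per area", {
  prof <- sample_dog_profiles(1, seed = 11)
  study <- simulate_study(prof, study_design(n_dogs = 1, sessions = 1,
                                             trials_per_session = 1,
                                             seed = 12))
  expect_length(study$segments, 3)
  labs <- vapply(study$segments, `[[`, character(1), "sub_label")
  expect_equal(sum(labs == "target"), 1)
  expect_setequal(vapply(study$segments, `[[`, character(1), "area"),
                  c("area1", "area2", "area3"))
  expect_error(simulate_study(list(), study_design()), "non-empty")
})

test_that("studies are bit-identical under the same seed", {
  prof <- sample_dog_profiles(2, seed = 13)
  des <- study_design(n_dogs = 2, sessions = 1, trials_per_session = 2,
                      seed = 14)
  s1 <- simulate_study(prof, des)
  s2 <- simulate_study(prof, des)
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(s1$segments[[5]]$frames, s2$segments[[5]]$frames)
})

test_that("test-2 mode tags dilution steps 10^-3 .. 10^-6", {
  prof <- sample_dog_profiles(1, seed = 15)
  des <- study_design(n_dogs = 1, sessions = 1, trials_per_session = 1,
                      test_phase = "test2", seed = 16)
  study <- simulate_study(prof, des)
  m <- study$metadata
  expect_setequal(unique(m$dilution_exponent), c(-3, -4, -5, -6))
  steps <- unique(m[c("dilution_exponent", "effect_scale")])
  steps <- steps[order(-steps$dilution_exponent), ]
  expect_equal(steps$effect_scale, c(1, 0.5, 0.25, 0.1))
  # test 2 layouts: one target, two distractor areas
  expect_setequal(unique(m$sub_label), c("target", "distractor"))
  expect_equal(sum(m$sub_label == "target"), 4)
})

test_that("the target left-amplitude effect grows with effect scale", {
  gap <- vapply(c(0, 0.5, 1), function(es) {
    diffs <- vapply(1:5, function(r) {
      study <- small_study(n_dogs = 2, trials = 2, effect_scale = es,
                           seed = 100 + r)
      suppressMessages(ft <- feature_table(study$segments))
      mean(ft$amp_negative[ft$label == "target"]) -
        mean(ft$amp_negative[ft$label == "non_target"])
    }, numeric(1))
    mean(diffs)
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
  expect_lt(abs(gap[1]), 6)     # no systematic gap at zero effect
  expect_gt(gap[3], 12)         # ~25 deg shift largely recovered
})

test_that("trial streams carry consistent events and reconstruct labels", {
  prof <- sample_dog_profiles(1, seed = 17)[[1]]
  tr <- simulate_trial_stream(prof, design = study_design(), seed = 18,
                              alerted = TRUE)
  expect_true("alert" %in% tr$events$behaviour)
  segs <- split_segments(tr$frames, tr$events)
  expect_length(segs, 3)
  kept <- excise_alert(segs, tr$events)
  # the alert (and its 1 s pre-buffer) is gone from the target segment
  al <- tr$events[tr$events$behaviour == "alert", ]
  for (s in kept) {
    expect_true(all(s$frames$t < al$start - 1 | s$frames$t > al$stop))
  }
  suppressMessages(lab <- label_segments(
    kept, trial_layout(tr$layout, alerted = TRUE)))
  expect_equal(sum(vapply(lab, `[[`, character(1), "label") == "target"), 1)
})
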