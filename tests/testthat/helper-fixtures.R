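# Shared fixture builders: all fixtures are constructed in code.

# Landmark frames placed by inverting the body-frame geometry: given a true
# tail angle per frame, put the tail middle where the extractor must
# recover exactly that angle. Returns the frame table and the truth.
frames_from_theta <- function(theta, fps = 60, S = c(0, 0), B = c(0, 100),
                              tail_len = 80, conf = 1) {
  n <- length(theta)
  b <- (B - S) / sqrt(sum((B - S)^2))
  r <- c(-b[2], b[1])
  th <- theta * pi / 180
  mx <- B[1] + tail_len * (cos(th) * b[1] + sin(th) * r[1])
  my <- B[2] + tail_len * (cos(th) * b[2] + sin(th) * r[2])
  data.frame(
    t = seq(0, by = 1 / fps, length.out = n),
    nose_x = S[1], nose_y = S[2] - 50,
    front_head_x = S[1], front_head_y = S[2] - 25,
    shoulders_x = S[1], shoulders_y = S[2],
    tail_base_x = B[1], tail_base_y = B[2],
    tail_middle_x = mx, tail_middle_y = my,
    tail_tip_x = mx, tail_tip_y = my,
    conf = conf)
}

# A segment with a known constant or supplied angle trace.
segment_from_theta <- function(theta, ...) {
  trajectory_segment(frames_from_theta(theta, ...), dog_id = "dogA",
                     area = "area1")
}

# Noise-free generator settings for inverse-pair tests.
zero_noise <- function() {
  noise_model(jitter_sd = 0, dropout_rate = 0,
              conf_high = c(1, 0), conf_low = c(1, 0))
}

# Rigid transform of every landmark column of a frame table.
apply_rigid <- function(frames, angle = 0, shift = c(0, 0), scale = 1) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  out <- frames
  pts <- c("nose", "front_head", "shoulders", "tail_base", "tail_middle",
           "tail_tip")
  for (p in pts) {
    xy <- scale * (as.matrix(frames[paste0(p, c("_x", "_y"))]) %*% t(R))
    out[[paste0(p, "_x")]] <- xy[, 1] + shift[1]
    out[[paste0(p, "_y")]] <- xy[, 2] + shift[2]
  }
  out
}

# Mirror the image left-right (x -> -x).
apply_mirror <- function(frames) {
  out <- frames
  for (p in c("nose", "front_head", "shoulders", "tail_base", "tail_middle",
              "tail_tip")) {
    out[[paste0(p, "_x")]] <- -frames[[paste0(p, "_x")]]
  }
  out
}

# A small labelled synthetic study for classifier tests.
small_study <- function(n_dogs = 4, sessions = 1, trials = 4,
                        shift_amp_left = 25, effect_scale = 1, seed = 1,
                        test_phase = "test1") {
  pop <- default_population()
  pop$shift_amp_left <- c(shift_amp_left, 4)
  profiles <- sample_dog_profiles(n_dogs, pop, seed = seed)
  design <- study_design(n_dogs = n_dogs, sessions = sessions,
                         trials_per_session = trials,
                         effect_scale = effect_scale,
                         test_phase = test_phase, seed = seed + 1)
  simulate_study(profiles, design, noise_model())
}

# Linearly separable kinematic feature table.
separable_features <- function(n_per_class = 30, seed = 1, gap = 6) {
  set.seed(seed)
  mk <- function(label, mu) {
    data.frame(label = label, dog_id = sample(paste0("d", 1:4), n_per_class,
                                              replace = TRUE),
               mean_angle = rnorm(n_per_class, mu, 1),
               amp_positive = rnorm(n_per_class, 40, 5),
               amp_negative = rnorm(n_per_class, 40 + mu, 5),
               mean_abs_velocity = rnorm(n_per_class, 600, 50),
               sum_positive = runif(n_per_class),
               sum_negative = runif(n_per_class),
               stringsAsFactors = FALSE)
  }
  rbind(mk("target", gap), mk("non_target", -gap))
}
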