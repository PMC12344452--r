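# Synthetic landmark-trajectory generator: oscillatory tail wagging with
# per-dog random effects, class-conditional lateral bias in the target area,
# and a detector-noise model, emitting the same landmark tables and event
# logs the tracking IO layer reads.

# Evaluate expr under a temporary RNG state so package randomness is fully
# seed-controlled and never disturbs the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# n reproducible child seeds derived from one parent seed.
sub_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Wag-style parameters
#'
#' Parameterizes one dog's tail oscillation: a mean lateral offset
#' (\code{bias}, degrees, positive towards the dog's right), separate
#' rightward and leftward oscillation reaches (\code{amp_right},
#' \code{amp_left}, degrees), wag frequency (Hz), phase (rad), and white
#' angle jitter (\code{noise_sd}, degrees).
#'
#' @param bias,amp_right,amp_left,freq,phase,noise_sd Numeric scalars.
#' @return List of class \code{wag_params}.
#' @export
wag_params <- function(bias = 0, amp_right = 40, amp_left = 40, freq = 4,
                       phase = 0, noise_sd = 3) {
  stopifnot(abs(bias) < 90, amp_right >= 0, amp_left >= 0, freq >= 0,
            noise_sd >= 0)
  structure(list(bias = bias, amp_right = amp_right, amp_left = amp_left,
                 freq = freq, phase = phase, noise_sd = noise_sd),
            class = "wag_params")
}

#' Individual dog profile
#'
#' A dog's baseline wag style, the additive shift it expresses in the
#' target area, and its body geometry in pixels.
#'
#' @param dog_id Identifier.
#' @param baseline \code{wag_params} for non-target searching.
#' @param target_shift Named list of additive deltas to \code{baseline}
#'   applied (scaled by the study's \code{effect_scale}) in the target area.
#' @param body_scale Shoulders to tail-base distance (px), > 0.
#' @param tail_scale Tail-base to tail-tip length (px), > 0.
#' @return List of class \code{dog_profile}.
#' @export
dog_profile <- function(dog_id, baseline = wag_params(),
                        target_shift = list(amp_left = 15),
                        body_scale = 120, tail_scale = 100) {
  stopifnot(body_scale > 0, tail_scale > 0)
  structure(list(dog_id = as.character(dog_id), baseline = baseline,
                 target_shift = target_shift, body_scale = body_scale,
                 tail_scale = tail_scale),
            class = "dog_profile")
}

# Apply effect_scale * target_shift to baseline, keeping invariants.
.shifted_params <- function(baseline, shift, effect_scale) {
  p <- unclass(baseline)
  for (nm in names(shift)) {
    p[[nm]] <- p[[nm]] + effect_scale * shift[[nm]]
  }
  p$amp_right <- max(0, p$amp_right)
  p$amp_left <- max(0, p$amp_left)
  p$freq <- max(0, p$freq)
  p$noise_sd <- max(0, p$noise_sd)
  p$bias <- max(-89.9, min(89.9, p$bias))
  do.call(wag_params, p)
}

#' Study design
#'
#' The trial structure and recording conditions the generator emulates:
#' overhead 60 fps video, right-skewed segment durations (lognormal,
#' truncated below at \code{duration_min} seconds, with parameters solved so
#' the truncated distribution has the requested mean and SD), three wall
#' areas per trial, and an effect-size multiplier on each dog's target
#' shift that models odour concentration.
#'
#' @param n_dogs,sessions,trials_per_session Counts.
#' @param fps Frame rate (frames/s).
#' @param duration_mean,duration_sd Segment-duration moments (s).
#' @param duration_min Lower truncation of durations (s).
#' @param effect_scale Multiplier on \code{target_shift} (>= 0); 1 is the
#'   trained concentration.
#' @param test_phase \code{"test1"} (target / distractor / no-odour areas)
#'   or \code{"test2"} (target / two distractors, one session per dilution
#'   step).
#' @param dilution_steps For test 2: named numeric vector of effect scales,
#'   names are dilution exponents. Default steps 1, 0.5, 0.25, 0.1 tagged
#'   10^-3 .. 10^-6.
#' @param waveform Oscillation shape: \code{"sine"}, \code{"square"} or
#'   \code{"triangle"}.
#' @param tip_lag Tail-tip phase lag (s) relative to the tail middle.
#' @param heading_step_sd OU heading random-walk step SD (deg/sqrt(s)).
#' @param seed Integer seed governing the whole study.
#' @return List of class \code{study_design}.
#' @export
study_design <- function(n_dogs = 8, sessions = 10, trials_per_session = 10,
                         fps = 60, duration_mean = 3.34, duration_sd = 3.45,
                         duration_min = 1.0, effect_scale = 1,
                         test_phase = c("test1", "test2"),
                         dilution_steps = c(`-3` = 1, `-4` = 0.5,
                                            `-5` = 0.25, `-6` = 0.1),
                         waveform = c("sine", "square", "triangle"),
                         tip_lag = 0.05, heading_step_sd = 20, seed = 1L) {
  test_phase <- match.arg(test_phase)
  waveform <- match.arg(waveform)
  stopifnot(fps > 0, duration_mean > 0, duration_sd > 0, effect_scale >= 0,
            n_dogs >= 1, sessions >= 1, trials_per_session >= 1)
  structure(list(n_dogs = n_dogs, sessions = sessions,
                 trials_per_session = trials_per_session, fps = fps,
                 duration_mean = duration_mean, duration_sd = duration_sd,
                 duration_min = duration_min, effect_scale = effect_scale,
                 test_phase = test_phase, dilution_steps = dilution_steps,
                 areas = c("area1", "area2", "area3"), waveform = waveform,
                 tip_lag = tip_lag, heading_step_sd = heading_step_sd,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Detector-noise model
#'
#' Emulates pose-detector degradation: isotropic pixel jitter on every
#' landmark, per-frame dropout in which detection degrades (jitter inflated
#' five-fold and confidence drawn from the low regime), and Gaussian
#' confidence scores clipped to [0, 1].
#'
#' @param jitter_sd Isotropic landmark noise SD (px).
#' @param dropout_rate Per-frame probability of a degraded detection.
#' @param conf_high,conf_low Length-2 (mean, sd) of confidence for clean and
#'   degraded frames.
#' @return List of class \code{noise_model}.
#' @export
noise_model <- function(jitter_sd = 2, dropout_rate = 0.02,
                        conf_high = c(0.95, 0.03), conf_low = c(0.3, 0.1)) {
  stopifnot(jitter_sd >= 0, dropout_rate >= 0, dropout_rate <= 1)
  structure(list(jitter_sd = jitter_sd, dropout_rate = dropout_rate,
                 conf_high = conf_high, conf_low = conf_low),
            class = "noise_model")
}

#' Population distribution for dog profiles
#'
#' Mean and spread of every wag-style and geometry field across dogs.
#' Baseline fields are drawn Normal (phase Uniform on [0, 2*pi)); the
#' target shift defaults to a leftward-amplitude increase, the group-level
#' lateralization pattern the generator emulates (its sign is configurable
#' for sensitivity studies).
#'
#' @param shift_sign +1 for a leftward-amplitude target effect, -1 to flip.
#' @return Named list of \code{c(mean, sd)} pairs plus shift entries.
#' @export
default_population <- function(shift_sign = 1) {
  list(bias = c(0, 10), amp_right = c(40, 8), amp_left = c(40, 8),
       freq = c(4, 0.8), noise_sd = c(3, 1),
       body_scale = c(120, 15), tail_scale = c(100, 12),
       shift_amp_left = c(15 * shift_sign, 4),
       shift_amp_right = c(0, 0), shift_bias = c(0, 0),
       shift_freq = c(0, 0))
}

#' Sample individual dog profiles from a population
#'
#' @param n_dogs Number of dogs (>= 1).
#' @param population Distribution spec, see [default_population()].
#' @param seed Integer seed.
#' @return List of \code{dog_profile}, dog ids \code{dog01, dog02, ...}.
#' @export
sample_dog_profiles <- function(n_dogs, population = default_population(),
                                seed = 1L) {
  if (n_dogs < 1) stop("n_dogs must be >= 1")
  spreads <- vapply(population, function(p) p[2], numeric(1))
  if (any(spreads < 0)) stop("population spread parameters must be >= 0")
  with_seed(seed, {
    draw <- function(nm) {
      p <- population[[nm]]
      if (is.null(p)) rep(0, n_dogs) else stats::rnorm(n_dogs, p[1], p[2])
    }
    bias <- pmin(89, pmax(-89, draw("bias")))
    amp_r <- pmax(0, draw("amp_right"))
    amp_l <- pmax(0, draw("amp_left"))
    freq <- pmax(0.1, draw("freq"))
    noise <- pmax(0, draw("noise_sd"))
    phase <- stats::runif(n_dogs, 0, 2 * pi)
    body <- pmax(20, draw("body_scale"))
    tail <- pmax(20, draw("tail_scale"))
    s_al <- draw("shift_amp_left")
    s_ar <- draw("shift_amp_right")
    s_b <- draw("shift_bias")
    s_f <- draw("shift_freq")
    lapply(seq_len(n_dogs), function(i) {
      dog_profile(
        dog_id = sprintf("dog%02d", i),
        baseline = wag_params(bias = bias[i], amp_right = amp_r[i],
                              amp_left = amp_l[i], freq = freq[i],
                              phase = phase[i], noise_sd = noise[i]),
        target_shift = list(amp_left = s_al[i], amp_right = s_ar[i],
                            bias = s_b[i], freq = s_f[i]),
        body_scale = body[i], tail_scale = tail[i])
    })
  })
}

# Solve lognormal (mu, sigma) such that the distribution truncated below at
# `lower` has the requested mean and SD; closed-form truncated moments.
.trunc_lnorm_params <- function(mean, sd, lower) {
  moments <- function(mu, sigma) {
    z0 <- (log(lower) - mu) / sigma
    tail_p <- stats::pnorm(-z0)
    m1 <- exp(mu + sigma^2 / 2) * stats::pnorm(sigma - z0) / tail_p
    m2 <- exp(2 * mu + 2 * sigma^2) * stats::pnorm(2 * sigma - z0) / tail_p
    c(m1, sqrt(pmax(0, m2 - m1^2)))
  }
  obj <- function(par) {
    m <- moments(par[1], exp(par[2]))
    (m[1] - mean)^2 + (m[2] - sd)^2
  }
  cv2 <- (sd / mean)^2
  start <- c(log(mean) - log(1 + cv2) / 2, log(sqrt(log(1 + cv2))))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Draw segment durations
#'
#' Lognormal truncated below at \code{design$duration_min}, with parameters
#' calibrated so the truncated distribution has mean
#' \code{design$duration_mean} and SD \code{design$duration_sd}.
#'
#' @param n Number of durations.
#' @param design A \code{study_design}.
#' @return Numeric vector of durations (s). Uses the current RNG stream.
#' @export
sample_durations <- function(n, design) {
  p <- .trunc_lnorm_params(design$duration_mean, design$duration_sd,
                           design$duration_min)
  f0 <- stats::plnorm(design$duration_min, p["mu"], p["sigma"])
  u <- stats::runif(n, f0, 1)
  stats::qlnorm(u, p["mu"], p["sigma"])
}

# Oscillation carrier in [-1, 1] for the configured waveform.
.carrier <- function(t, freq, phase, waveform) {
  s <- sin(2 * pi * freq * t + phase)
  switch(waveform,
         sine = s,
         square = sign(s),
         triangle = (2 / pi) * asin(s))
}

#' Simulate one search segment
#'
#' Generates a per-frame landmark table for one dog searching one area. The
#' underlying tail angle is \code{theta(t) = bias + A(t) * s(t) + eps} with
#' carrier \code{s} in [-1, 1] and amplitude \code{A} equal to
#' \code{amp_right} on positive half-cycles and \code{amp_left} on negative
#' ones; in the target area the wag parameters are shifted by
#' \code{effect_scale * target_shift}. The dog's heading follows an
#' Ornstein-Uhlenbeck random walk so the body frame is exercised under
#' rotation, and landmarks are placed by inverting the body-frame geometry
#' (tail middle at half tail length from the tail base at angle theta; tail
#' tip at full length with a configurable phase lag). Detector noise is
#' applied last.
#'
#' @param profile A \code{dog_profile}.
#' @param area Area label.
#' @param duration Segment duration (s), >= 2 frame intervals.
#' @param design A \code{study_design} (frame rate, waveform, effect scale).
#' @param noise A \code{noise_model}.
#' @param seed Integer seed.
#' @param is_target Whether this area holds the target odour.
#' @param effect_scale Override of \code{design$effect_scale}.
#' @return A \code{trajectory_segment} (frames plus metadata slots).
#' @export
simulate_segment <- function(profile, area, duration, design = study_design(),
                             noise = noise_model(), seed = 1L,
                             is_target = FALSE,
                             effect_scale = design$effect_scale) {
  if (duration < 2 / design$fps) stop("duration too short for two frames")
  if (!area %in% design$areas) stop("invalid area label: ", area)
  fps <- design$fps
  n <- max(2L, as.integer(round(duration * fps)))
  t <- seq(0, by = 1 / fps, length.out = n)

  params <- if (is_target) {
    .shifted_params(profile$baseline, profile$target_shift, effect_scale)
  } else {
    profile$baseline
  }

  with_seed(seed, {
    s <- .carrier(t, params$freq, params$phase, design$waveform)
    amp <- ifelse(s >= 0, params$amp_right, params$amp_left)
    theta_clean <- params$bias + amp * s
    theta <- theta_clean + stats::rnorm(n, 0, params$noise_sd)

    # tip lags the middle: tip angle = middle angle + lag * dtheta/dt,
    # derivative taken on the noise-free angle
    dth <- c(diff(theta_clean), 0) * fps
    theta_tip <- theta_clean + design$tip_lag * dth

    # Ornstein-Uhlenbeck heading (direction of the body axis, rad) and a
    # slow positional drift of the tail base
    dt <- 1 / fps
    psi <- numeric(n)
    psi[1] <- stats::runif(1, 0, 2 * pi)
    step_sd <- design$heading_step_sd * pi / 180
    innov <- stats::rnorm(n - 1, 0, step_sd * sqrt(dt))
    kappa <- 0.5
    for (i in 2:n) {
      psi[i] <- psi[i - 1] + kappa * (psi[1] - psi[i - 1]) * dt + innov[i - 1]
    }
    speed <- 10  # px/s drift while searching
    bx <- 640 + cumsum(c(0, speed * dt * cos(psi[-n] + pi)))
    by <- 360 + cumsum(c(0, speed * dt * sin(psi[-n] + pi)))

    dx <- cos(psi); dy <- sin(psi)      # axis_b: shoulders -> tail base
    rx <- -dy; ry <- dx                 # dog's right in y-down image coords
    th <- theta * pi / 180
    tt <- theta_tip * pi / 180
    half <- profile$tail_scale / 2

    frames <- data.frame(
      t = t,
      nose_x = bx - (profile$body_scale * 1.9) * dx,
      nose_y = by - (profile$body_scale * 1.9) * dy,
      front_head_x = bx - (profile$body_scale * 1.5) * dx,
      front_head_y = by - (profile$body_scale * 1.5) * dy,
      shoulders_x = bx - profile$body_scale * dx,
      shoulders_y = by - profile$body_scale * dy,
      tail_base_x = bx,
      tail_base_y = by,
      tail_middle_x = bx + half * (cos(th) * dx + sin(th) * rx),
      tail_middle_y = by + half * (cos(th) * dy + sin(th) * ry),
      tail_tip_x = bx + profile$tail_scale * (cos(tt) * dx + sin(tt) * rx),
      tail_tip_y = by + profile$tail_scale * (cos(tt) * dy + sin(tt) * ry),
      conf = NA_real_
    )

    degraded <- stats::runif(n) < noise$dropout_rate
    jit <- ifelse(degraded, 5 * noise$jitter_sd, noise$jitter_sd)
    coord_cols <- setdiff(names(frames), c("t", "conf"))
    for (cc in coord_cols) {
      frames[[cc]] <- frames[[cc]] + stats::rnorm(n, 0, jit)
    }
    conf <- ifelse(degraded,
                   stats::rnorm(n, noise$conf_low[1], noise$conf_low[2]),
                   stats::rnorm(n, noise$conf_high[1], noise$conf_high[2]))
    frames$conf <- pmin(1, pmax(0, conf))

    trajectory_segment(frames, dog_id = profile$dog_id, area = area)
  })
}

#' Simulate a full study
#'
#' Every dog runs \code{sessions x trials_per_session} trials; each trial
#' yields one segment per wall area with target placement rotating
#' pseudo-randomly across areas, labels attached, and an alert outcome
#' drawn with probability \code{0.5 + 0.5 * min(1, effect_scale)} (certain
#' at the trained concentration, chance-level as the effect vanishes). In
#' test-2 mode one session is run per dilution step and segments carry the
#' matching dilution exponent.
#'
#' @param profiles List of \code{dog_profile}.
#' @param design A \code{study_design}.
#' @param noise A \code{noise_model}.
#' @param p_in_odour Probability that a target-area segment actually has
#'   the dog in odour contact (and hence expressing its target shift).
#'   Searching the target area does not guarantee smelling the target;
#'   values below 1 inject that label noise. Default 1.
#' @return List with \code{segments} (list of labelled
#'   \code{trajectory_segment}) and \code{metadata} (one row per segment).
#' @export
simulate_study <- function(profiles, design = study_design(),
                           noise = noise_model(), p_in_odour = 1) {
  if (length(profiles) == 0) stop("profiles must be non-empty")
  steps <- if (design$test_phase == "test2") design$dilution_steps
           else stats::setNames(design$effect_scale, NA)
  sessions_per_step <- if (design$test_phase == "test2") 1L
                       else design$sessions

  n_trials <- length(profiles) * length(steps) * sessions_per_step *
    design$trials_per_session
  seeds <- sub_seeds(design$seed, n_trials * 2L)
  segs <- list()
  meta <- list()
  k <- 0L; trial_idx <- 0L
  session_no <- 0L
  for (si in seq_along(steps)) {
    es <- steps[[si]]
    dil <- if (design$test_phase == "test2")
      as.integer(names(steps)[si]) else NA_integer_
    for (sess in seq_len(sessions_per_step)) {
      session_no <- session_no + 1L
      for (p in profiles) {
        for (tr in seq_len(design$trials_per_session)) {
          trial_idx <- trial_idx + 1L
          layout <- with_seed(seeds[2L * trial_idx - 1L], {
            tgt <- sample(design$areas, 1)
            if (design$test_phase == "test2") {
              subs <- stats::setNames(rep("distractor", 3), design$areas)
            } else {
              others <- sample(setdiff(design$areas, tgt))
              subs <- stats::setNames(character(3), design$areas)
              subs[others[1]] <- "distractor"
              subs[others[2]] <- "no_odour"
            }
            subs[tgt] <- "target"
            subs
          })
          trial_seeds <- sub_seeds(seeds[2L * trial_idx], 5L)
          rest <- with_seed(trial_seeds[1], {
            durs <- sample_durations(length(design$areas), design)
            alerted <- stats::runif(1) < 0.5 + 0.5 * min(1, es)
            # conditional draw keeps the stream identical at the default
            in_odour <- if (p_in_odour >= 1) TRUE
                        else stats::runif(1) < p_in_odour
            list(durs = durs, alerted = alerted, in_odour = in_odour)
          })
          for (ai in seq_along(design$areas)) {
            a <- design$areas[ai]
            seg <- simulate_segment(
              p, a, rest$durs[ai], design, noise,
              seed = trial_seeds[1L + ai],
              is_target = layout[[a]] == "target" && rest$in_odour,
              effect_scale = es)
            k <- k + 1L
            seg$segment_id <- k
            seg$session <- session_no
            seg$trial <- tr
            seg$sub_label <- unname(layout[[a]])
            seg$label <- if (seg$sub_label == "target") "target"
                         else "non_target"
            seg$test_phase <- design$test_phase
            seg$dilution_exponent <- dil
            seg$alerted <- rest$alerted
            segs[[k]] <- seg
            meta[[k]] <- data.frame(
              segment_id = k, dog_id = p$dog_id, session = session_no,
              trial = tr, area = a, label = seg$label,
              sub_label = seg$sub_label, test_phase = design$test_phase,
              dilution_exponent = dil, effect_scale = es,
              alerted = rest$alerted, in_odour = rest$in_odour,
              duration = rest$durs[ai],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  list(segments = segs, metadata = do.call(rbind, meta))
}

#' Simulate one continuous trial stream with its event log
#'
#' Produces a single un-split landmark table covering sequential visits to
#' the three areas (with short transit gaps not covered by any area event)
#' plus the matching event log, including a terminal alert event in the
#' target area when the dog alerts. Intended to exercise the segmentation
#' and alert-excision path end to end.
#'
#' @param profile A \code{dog_profile}.
#' @param layout Named character vector mapping areas to sub-labels
#'   (exactly one \code{"target"}).
#' @param design,noise Generator settings.
#' @param seed Integer seed.
#' @param alerted Whether the dog alerts in the target area.
#' @param alert_duration Alert hold length (s), default 4.
#' @return List with \code{frames} (landmark table), \code{events}
#'   (event-record data frame) and \code{layout}.
#' @export
simulate_trial_stream <- function(profile,
                                  layout = c(area1 = "target",
                                             area2 = "distractor",
                                             area3 = "no_odour"),
                                  design = study_design(),
                                  noise = noise_model(), seed = 1L,
                                  alerted = TRUE, alert_duration = 4) {
  stopifnot(sum(layout == "target") == 1)
  seeds <- sub_seeds(seed, length(layout) + 1L)
  pieces <- list(); events <- list()
  t0 <- 0
  order_areas <- with_seed(seeds[length(layout) + 1L],
                           sample(names(layout)))
  for (i in seq_along(order_areas)) {
    a <- order_areas[i]
    is_tgt <- layout[[a]] == "target"
    dur <- with_seed(seeds[i], sample_durations(1, design))
    # guarantee enough pre-alert search that excision leaves a segment
    if (is_tgt && alerted) dur <- max(dur, 2) + alert_duration
    seg <- simulate_segment(profile, a, dur, design, noise, seed = seeds[i],
                            is_target = is_tgt)
    fr <- seg$frames
    fr$t <- fr$t + t0
    pieces[[i]] <- fr
    events[[length(events) + 1L]] <- data.frame(
      behaviour = a, start = t0, stop = t0 + dur, stringsAsFactors = FALSE)
    if (is_tgt && alerted) {
      events[[length(events) + 1L]] <- data.frame(
        behaviour = "alert", start = t0 + dur - alert_duration,
        stop = t0 + dur, stringsAsFactors = FALSE)
    }
    gap <- 0.25 + 0.05 * i  # transit between areas, uncovered by events
    t0 <- t0 + dur + gap
  }
  frames <- do.call(rbind, pieces)
  list(frames = frames, events = do.call(rbind, events), layout = layout)
}
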