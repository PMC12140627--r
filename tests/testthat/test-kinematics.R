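test_that("angular speed differentiates, smooths, and validates input", {
  fs <- 500
  expect_equal(angular_speed(rep(5, 1000), fs)$samples, rep(0, 1000))
  ## perfect 360 deg over 1 s ramp -> 360 deg/s away from the edges
  ramp <- seq(0, 360, length.out = fs + 1)
  sp <- angular_speed(ramp, fs, smoothing_window = 0)
  expect_equal(sp$samples[5:(fs - 5)], rep(360, fs - 9), tolerance = 1e-9)
  ## quantized ramp recovered within 2% after smoothing
  spq <- angular_speed(round(ramp / 0.1) * 0.1, fs, smoothing_window = 0.05)
  mid <- 50:(fs - 50)
  expect_lt(max(abs(spq$samples[mid] - 360)), 0.02 * 360)
  ## non-finite input errors with the index
  bad <- ramp; bad[17] <- NA
  expect_error(angular_speed(bad, fs), "index 17")
  expect_error(angular_speed(1, fs), "at least 2")
})

test_that("events are detected within 20 ms of ground truth on noiseless trials", {
  s <- make_small_subject(seed = 41, n_trials = 8)
  gt <- s$subject$conditions$predictable$trace$events
  det <- s$events
  m <- merge(gt[c("linked_cue_index", "time", "event_type")],
             det[c("linked_cue_index", "time")], by = "linked_cue_index")
  expect_equal(nrow(m), nrow(gt))  # full sensitivity
  expect_lt(max(abs(m$time.y - m$time.x)), 0.020)
  ## every detected event follows its linked cue
  cue_t <- s$subject$conditions$predictable$cues$time[det$linked_cue_index]
  expect_true(all(det$time > cue_t))
})

test_that("degenerate speed input yields an empty table; missing cues error", {
  fs <- 500
  cues <- generate_task_sequence(task_config("predictable", n_trials_per_block = 2,
                                             n_blocks = 1, seed = 1))
  cues$time <- cues$time + 4; cues$sample <- round(cues$time * fs) + 1L
  zero_speed <- structure(list(samples = rep(0, 30 * fs), sample_rate = fs,
                               smoothing_window = 0.05), class = "bw_speed_trace")
  det <- detect_events(zero_speed, cues)
  expect_equal(nrow(det), 0)
  expect_error(detect_events(zero_speed, NULL), "cue table")
})

test_that("two-reversal unpredictable trials yield two linked reversal rows", {
  kin <- kinematics_config()
  cfg <- task_config("unpredictable", n_trials_per_block = 30, n_blocks = 1,
                     seed = 11)
  cues <- generate_task_sequence(cfg)
  tr <- generate_wheel_trace(cues, kin, seed = 12)
  det <- detect_events(angular_speed(tr$angle, kin$sample_rate), tr$cues)
  two_rev_trials <- names(which(tapply(cues$cue_type == "reverse", cues$trial, sum) == 2))
  expect_gt(length(two_rev_trials), 0)
  for (trl in two_rev_trials) {
    rows <- det[det$trial == as.integer(trl) & det$event_type == "reversal", ]
    expect_equal(nrow(rows), 2)
    linked <- cues$cue_type[rows$linked_cue_index]
    expect_equal(linked, c("reverse", "reverse"))
  }
})

test_that("detection degrades monotonically as speed noise grows", {
  s <- make_small_subject(seed = 43, n_trials = 8)
  tr <- s$subject$conditions$predictable$trace
  gt <- tr$events
  err_at <- function(noise_sd) {
    withr::local_seed(99)
    ang <- tr$angle + rnorm(length(tr$angle), sd = noise_sd)
    det <- detect_events(angular_speed(ang, 500), tr$cues)
    m <- merge(gt[c("linked_cue_index", "time")], det[c("linked_cue_index", "time")],
               by = "linked_cue_index")
    mean(abs(m$time.y - m$time.x))
  }
  errs <- vapply(c(0, 0.5, 2), err_at, numeric(1))
  expect_true(all(diff(errs) >= -1e-6))
  expect_lt(errs[1], 0.020)
})

test_that("epoching uses half-open windows and excludes boundary trials", {
  fs <- 500
  sig <- matrix(seq_len(8000), ncol = 1)
  ev <- data.frame(trial = 1:2, event_type = "start", time = c(5000, 250) / fs,
                   sample = c(5000L, 250L), linked_cue_index = 1:2,
                   condition = "predictable", block = 1L, source = "detected")
  class(ev) <- c("bw_event_table", "data.frame")
  ep <- epoch_signals(sig, ev, fs, span = 4)
  ## event at sample 5000 covers samples 4000..5999; event at 250 excluded
  expect_equal(ep$n_excluded, 1)
  expect_equal(dim(ep$data)[2], 1)
  expect_equal(as.numeric(ep$data[, 1, 1]), as.numeric(4000:5999))
  expect_equal(ep$time[1], -2)
  expect_equal(sum(abs(ep$time) < 1e-12), 1)  # 0 is on the axis
  ## all trials out of bounds -> error
  ev2 <- ev[2, ]; class(ev2) <- class(ev)
  expect_error(epoch_signals(sig, ev2, fs, span = 4), "zero usable trials")
})

test_that("a predictable block epochs into one trial per event type", {
  s <- make_small_subject(seed = 44, n_trials = 12)
  sig <- s$subject$conditions$predictable$signals[, "STN_L", drop = FALSE]
  for (evt in c("start", "reversal", "stop")) {
    ep <- epoch_signals(sig, s$events, 500, span = 4, event_type = evt)
    expect_equal(dim(ep$data)[2], 12)
    expect_equal(ep$n_excluded, 0)
  }
})

test_that("reaction times are cue-to-event differences with negative RTs flagged", {
  cues <- data.frame(trial = 1:2, cue_type = "start", direction = 1,
                     time = c(10, 20), condition = "predictable", block = 1L,
                     sample = c(5001L, 10001L))
  ev <- data.frame(trial = 1:2, event_type = "start", time = c(10.8, 19.5),
                   sample = c(5401L, 9751L), linked_cue_index = 1:2,
                   condition = "predictable", block = 1L, source = "detected")
  rt <- reaction_times(ev, cues)
  expect_equal(rt$table$rt, c(0.8, -0.5))
  expect_equal(rt$n_flagged, 1)
  expect_equal(rt$summary$mean, 0.8)
  ev$linked_cue_index[1] <- NA
  expect_error(reaction_times(ev, cues), "linked")
})

test_that("recovered reaction-time means match the generator configuration", {
  kin <- kinematics_config()
  cues <- generate_task_sequence(task_config("unpredictable",
                                             n_trials_per_block = 150,
                                             n_blocks = 2, seed = 21))
  tr <- generate_wheel_trace(cues, kin, seed = 22)
  det <- detect_events(angular_speed(tr$angle, kin$sample_rate), tr$cues)
  rt <- reaction_times(det, tr$cues)
  m <- rt$summary[rt$summary$event_type == "start", ]
  sem <- 0.160 / sqrt(m$n)
  expect_equal(m$mean, 0.840, tolerance = 3 * sem / 0.840)
})

test_that("aligned speed averages cross the threshold at the expected times", {
  s <- make_small_subject(seed = 45, n_trials = 10)
  sp <- s$speed
  ## movement-aligned start average crosses 50 deg/s at ~0
  av <- aligned_speed_average(sp, s$events, span = 4, event_type = "start")
  cross <- av$time[which(abs(av$mean) >= 50)[1]]
  expect_lt(abs(cross), 0.06)
  ## cue-aligned average crosses at ~ mean start RT (low RT jitter so the
  ## average rise is not smeared across the distribution)
  kin_tight <- kinematics_config(rt_table = within(default_rt_table(), sd <- 0.02))
  cues <- generate_task_sequence(task_config("predictable", n_trials_per_block = 10,
                                             n_blocks = 1, seed = 51))
  trc <- generate_wheel_trace(cues, kin_tight, seed = 52)
  spc <- angular_speed(trc$angle, 500)
  detc <- detect_events(spc, trc$cues)
  avc <- aligned_speed_average(spc, detc, span = 4, alignment = "cue",
                               cues = trc$cues, event_type = "start")
  cross_c <- avc$time[which(abs(avc$mean) >= 50)[1]]
  rtsc <- reaction_times(detc, trc$cues)
  rt_mean <- rtsc$summary$mean[rtsc$summary$event_type == "start"]
  expect_lt(abs(cross_c - rt_mean), 0.08)
  ## identical trials average to any single trial
  one <- matrix(sin(seq_len(4000) / 40), ncol = 1)
  evs <- data.frame(trial = 1:2, event_type = "start", time = c(1000, 3000) / 500,
                    sample = c(1001L, 3001L), linked_cue_index = 1:2,
                    condition = "p", block = 1L, source = "detected")
  one[1001 + (-1000:999)] <- one[3001 + (-1000:999)]
  spd <- structure(list(samples = one[, 1], sample_rate = 500,
                        smoothing_window = 0), class = "bw_speed_trace")
  av2 <- aligned_speed_average(spd, evs, span = 4)
  expect_equal(av2$mean, one[1:2000 , 1], tolerance = 1e-12)
})

test_that("epoch-then-average equals average-then-window on noiseless data", {
  s <- make_small_subject(seed = 46, n_trials = 6)
  sig <- s$subject$conditions$predictable$trace$speed_true
  ep <- epoch_signals(sig, s$events, 500, span = 4, event_type = "reversal")
  m1 <- rowMeans(matrix(ep$data[, , 1], nrow = dim(ep$data)[1]))
  centers <- s$events$sample[s$events$event_type == "reversal"]
  m2 <- rowMeans(vapply(centers, function(cc) sig[(cc - 1000):(cc + 999)],
                        numeric(2000)))
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("preprocessing removes drift and halves the rate cleanly", {
  fs <- 1000
  tt <- seq_len(30 * fs) / fs
  x <- sin(2 * pi * 20 * tt) + 5 + 0.3 * tt  # 20 Hz + offset + drift
  out <- preprocess_signals(x, fs, highpass = 1, downsample_to = 500)
  expect_equal(out$fs, 500)
  expect_equal(length(out$x), length(x) / 2)
  mid <- 4000:11000  # away from filter edge transients
  expect_lt(abs(mean(out$x[mid])), 0.05)              # drift removed
  pg <- stats::spec.pgram(stats::ts(out$x[mid], frequency = 500), plot = FALSE)
  expect_lt(abs(pg$freq[which.max(pg$spec)] - 20), 1) # oscillation kept
})
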