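test_that("predictable task sequences have fixed structure and timing", {
  cfg <- task_config("predictable", n_trials_per_block = 36, n_blocks = 1, seed = 1)
  cues <- generate_task_sequence(cfg)
  expect_equal(sum(cues$cue_type == "start"), 36)
  expect_equal(sum(cues$cue_type == "reverse"), 36)
  expect_equal(sum(cues$cue_type == "stop"), 36)
  ## fixed 4 s spacing within every trial, no jitter anywhere
  for (tr in unique(cues$trial)) {
    tt <- cues$time[cues$trial == tr]
    expect_equal(diff(tt), c(4, 4))
  }
  expect_true(all(diff(cues$time) > 0))
  ## determinism: identical seed, identical table
  expect_identical(cues, generate_task_sequence(cfg))
})

test_that("unpredictable sequences draw reversals and ISIs from the stated mixture", {
  cfg <- task_config("unpredictable", n_trials_per_block = 500, n_blocks = 4, seed = 7)
  cues <- generate_task_sequence(cfg)
  n_trials <- 2000
  rev_per_trial <- tapply(cues$cue_type == "reverse", cues$trial, sum)
  ## expected reversals per trial = mean of uniform {0,1,2} = 1
  expect_equal(mean(rev_per_trial), 1, tolerance = 3 * sqrt(2 / 3 / n_trials) / 1)
  expect_setequal(unique(rev_per_trial), 0:2)
  ## within-trial ISIs: fraction at exactly 4 s inside binomial 99% CI of 0.5
  isis <- unlist(tapply(cues$time, cues$trial, diff))
  frac4 <- mean(abs(isis - 4) < 1e-9)
  n <- length(isis)
  ci <- 0.5 + c(-1, 1) * stats::qnorm(0.995) * sqrt(0.25 / n)
  expect_gt(frac4, ci[1]); expect_lt(frac4, ci[2])
  ## jittered part stays inside the configured range
  expect_true(all(isis >= 4 - 1e-9 & isis <= 7 + 1e-9))
})

test_that("invalid task configurations are rejected", {
  expect_error(task_config("unpredictable", reversal_probs = c(0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(task_config(isi_range = c(7, 4)), "low <= high")
  expect_error(task_config(pause_duration = -1), "positive")
})

test_that("wheel traces realize cue + reaction time onsets and steady speed", {
  kin <- kinematics_config(rt_table = within(default_rt_table(), {mean <- 0.8; sd <- 1e-9}))
  cues <- generate_task_sequence(task_config("predictable", n_trials_per_block = 2,
                                             n_blocks = 1, seed = 1))
  tr <- generate_wheel_trace(cues, kin, seed = 2, lead_in = 10)
  ## start cue at absolute 10 s, fixed RT 0.8 -> ground-truth start at 10.8 s
  st <- tr$events[tr$events$event_type == "start", ][1, ]
  expect_equal(st$time, 10.8, tolerance = 1e-6)
  ## steady segment speed ~ target within quantization error
  sp <- angular_speed(tr$angle, kin$sample_rate)
  seg <- sp$samples[round((10.8 + 0.5) * 500):round((10.8 + 3) * 500)]
  expect_equal(mean(seg), 400, tolerance = 0.01 * 400)
  expect_lt(max(abs(seg - 400)), 0.02 * 400)
  ## ground-truth events lie between their cue and cue + max RT + ramp margin
  cue_t <- tr$cues$time[tr$events$linked_cue_index]
  expect_true(all(tr$events$time > cue_t))
  expect_true(all(tr$events$time < cue_t + 0.8 + 2 * kin$ramp_time + kin$reversal_pause))
  ## determinism
  tr2 <- generate_wheel_trace(cues, kin, seed = 2, lead_in = 10)
  expect_identical(tr$angle, tr2$angle)
})

test_that("sampled reaction times recover their configured distribution", {
  kin <- kinematics_config()
  cues <- generate_task_sequence(task_config("predictable", n_trials_per_block = 500,
                                             n_blocks = 2, seed = 3))
  tr <- generate_wheel_trace(cues, kin, seed = 4)
  start_rts <- tr$reaction_times[cues$cue_type == "start"]
  sem <- 0.154 / sqrt(length(start_rts))
  expect_equal(mean(start_rts), 0.757, tolerance = 3 * sem / 0.757)
})

test_that("unmodulated channels are stationary with a spectral peak at band center", {
  task <- list(predictable = task_config("predictable", n_trials_per_block = 4,
                                         n_blocks = 1))
  specs <- list(oscillation_spec("STN_contra", "beta"))  # no envelope events
  subj <- simulate_subject("S1", "R", task, osc_specs = specs,
                           coupling_specs = list(), seed = 9)
  x <- subj$conditions$predictable$signals[, "STN_L"]
  ## split-half variance equality (stationarity, loose bound)
  v1 <- var(x[seq_len(length(x) %/% 2)]); v2 <- var(x[-seq_len(length(x) %/% 2)])
  expect_lt(abs(log(v1 / v2)), log(1.25))
  ## spectral peak near 20 Hz
  pg <- stats::spec.pgram(stats::ts(x, frequency = 500), spans = 25, plot = FALSE)
  expect_lt(abs(pg$freq[which.max(pg$spec)] - 20), 2)
  ## determinism of the full subject
  subj2 <- simulate_subject("S1", "R", task, osc_specs = specs,
                            coupling_specs = list(), seed = 9)
  expect_identical(subj$conditions$predictable$signals,
                   subj2$conditions$predictable$signals)
})

test_that("configured stop-rebound power ratio is realized on generator output", {
  ## isolated beta channel with a 2.0x (power) rebound after stop
  specs <- list(oscillation_spec("STN_contra", "beta",
                                 envelope = list(stop = list(gain_db = 10 * log10(2),
                                                             onset = 0, duration = 1.6))))
  task <- list(predictable = task_config("predictable", n_trials_per_block = 25,
                                         n_blocks = 2))
  ratios <- c()
  for (s in 1:3) {
    subj <- simulate_subject("S", "R", task, osc_specs = specs,
                             coupling_specs = list(), seed = 20 + s)
    cc <- subj$conditions$predictable
    ep <- epoch_signals(cc$signals[, "STN_L", drop = FALSE], cc$trace$events,
                        500, span = 4, event_type = "stop")
    m <- power_tfr(mtm_fourier(ep, tfr_spec(bands = list(low = c(5, 45)),
                                            n_tapers = c(low = 4L))), band = "low")
    fsel <- m$freqs >= 13 & m$freqs <= 30
    ## central post bins (avoid window smearing at the edges)
    post <- m$times >= 0.45 & m$times < 1.15
    pre <- m$times >= -1.15 & m$times < -0.45
    ratios <- c(ratios, mean(m$values[fsel, post]) / mean(m$values[fsel, pre]))
  }
  ## beta-band ratio diluted by the ~4% in-band 1/f background:
  ## (2 + f) / (1 + f) with f ~ 0.04/1 -> about 1.96
  expect_equal(mean(ratios), 2.0, tolerance = 0.1)
})

test_that("shared-signal coherence matches the analytic value and the no-coupling null", {
  withr::local_seed(31)
  fs <- 500; ntr <- 80; nsamp <- 2000; cstr <- 0.8
  dat0 <- array(rnorm(nsamp * ntr * 2), c(nsamp, ntr, 2))  # independent
  dat1 <- dat0
  for (tr in seq_len(ntr)) {
    x <- dat0[, tr, 1]
    dat1[, tr, 2] <- cstr * c(0, x[-nsamp]) + dat0[, tr, 2]
  }
  spec <- tfr_spec(bands = list(low = c(5, 45)), n_tapers = c(low = 4L))
  ## coupled: coherence^2 = c^2 Sx / (c^2 Sx + Sn) with white unit spectra
  coh <- coherence_tfr(mtm_fourier(make_epoch_set(dat1), spec), c(1, 2))
  expected_sq <- cstr^2 / (cstr^2 + 1)
  expect_equal(mean(coh$values^2), expected_sq, tolerance = 0.05)
  ## uncoupled: mean coherence^2 ~ 1/N (estimator bias), N = trials x tapers
  coh0 <- coherence_tfr(mtm_fourier(make_epoch_set(dat0), spec), c(1, 2))
  n_obs <- ntr * 4
  expect_lt(abs(mean(coh0$values^2) - 1 / n_obs), 0.5 / n_obs)
})

test_that("unpredictable ISI sequences carry no serial structure", {
  cfg <- task_config("unpredictable", n_trials_per_block = 300, n_blocks = 1, seed = 5)
  cues <- generate_task_sequence(cfg)
  isis <- unlist(tapply(cues$time, cues$trial, diff))
  ## permutation test on lag-1 autocorrelation
  obs <- cor(isis[-length(isis)], isis[-1])
  withr::local_seed(6)
  null <- replicate(500, {
    p <- sample(isis)
    cor(p[-length(p)], p[-1])
  })
  p_val <- mean(abs(null) >= abs(obs))
  expect_gt(p_val, 0.01)
})

test_that("coupling referencing an unknown channel role errors", {
  task <- list(predictable = task_config("predictable", n_trials_per_block = 2,
                                         n_blocks = 1))
  specs <- list(oscillation_spec("STN_contra", "beta"))
  bad <- list(coupling_spec("M1_contra", "STN_contra"))
  expect_error(simulate_subject("S1", "R", task, osc_specs = specs,
                                coupling_specs = bad, seed = 1),
               "without an oscillation spec")
})

test_that("cohorts round-trip through the plain-text container", {
  task <- list(predictable = task_config("predictable", n_trials_per_block = 2,
                                         n_blocks = 1))
  specs <- list(oscillation_spec("STN_contra", "beta"))
  coh <- simulate_cohort(2, task, osc_specs = specs, coupling_specs = list(),
                         seed = 3)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$hand, coh[[1]]$hand)
  expect_equal(as.numeric(back[[1]]$conditions$predictable$signals[, "STN_L"]),
               as.numeric(coh[[1]]$conditions$predictable$signals[, "STN_L"]),
               tolerance = 1e-6)
  expect_equal(back[[1]]$conditions$predictable$trace$events$sample,
               coh[[1]]$conditions$predictable$trace$events$sample)
})
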