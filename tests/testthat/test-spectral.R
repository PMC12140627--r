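test_that("Slepian tapers are orthonormal with the stated half-bandwidth", {
  tap4 <- slepian_tapers(400, 4)
  expect_lt(max(abs(crossprod(tap4) - diag(4))), 1e-10)
  ## half-bandwidth W = (K+1)/(2T): 3.125 Hz for 4 tapers in 0.8 s at 500 Hz
  expect_equal(attr(tap4, "half_bandwidth") * 500, 3.125)
  tap7 <- slepian_tapers(400, 7)
  expect_lt(max(abs(crossprod(tap7) - diag(7))), 1e-10)
  expect_equal(attr(tap7, "half_bandwidth") * 500, 5)
  expect_error(slepian_tapers(400, 0), "positive")
  expect_error(slepian_tapers(10, 10), "smaller")
})

test_that("multitaper coefficients match a direct tapered-DFT oracle", {
  fs <- 500
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs) - 2
  spec <- tfr_spec(bands = list(low = c(5, 45)), n_tapers = c(low = 4L))
  for (x in list(sin(2 * pi * 20 * tt),
                 withr::with_seed(1, rnorm(length(tt))))) {
    mtm <- mtm_fourier(make_epoch_set(array(x, c(length(x), 1, 1))), spec)
    oracle <- direct_mtm_oracle(x, fs)
    expect_equal(mtm$bands$low$freqs, oracle$freqs)
    expect_lt(max(Mod(mtm$bands$low$coeff[, , , 1, 1] - oracle$coeff)), 1e-10)
  }
  ## all-zero input -> all-zero coefficients
  mtm0 <- mtm_fourier(make_epoch_set(array(0, c(2000, 1, 1))), spec)
  expect_true(all(Mod(mtm0$bands$low$coeff) == 0))
})

test_that("a pure sine concentrates within the taper half-bandwidth", {
  fs <- 500
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs) - 2
  x <- sin(2 * pi * 20 * tt)
  spec <- tfr_spec(bands = list(low = c(5, 45)), n_tapers = c(low = 4L))
  p <- power_tfr(mtm_fourier(make_epoch_set(array(x, c(2000, 1, 1))), spec),
                 band = "low")
  prof <- rowMeans(p$values)
  expect_equal(p$freqs[which.max(prof)], 20)
  in_bw <- abs(p$freqs - 20) <= 3.125
  expect_gt(sum(prof[in_bw]) / sum(prof), 0.90)
})

test_that("white noise gives a flat time-averaged multitaper spectrum", {
  fs <- 500
  withr::local_seed(2)
  spec <- tfr_spec(bands = list(low = c(5, 45)), n_tapers = c(low = 4L))
  dat <- array(rnorm(2000 * 30), c(2000, 30, 1))
  p <- power_tfr(mtm_fourier(make_epoch_set(dat), spec), band = "low")
  prof <- rowMeans(p$values)
  ## relative spread around flat: sampling error with 30x4x65 obs per bin
  expect_lt(sd(prof) / mean(prof), 0.08)
})

test_that("power scales quadratically and averages tapers correctly", {
  fs <- 500
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs) - 2
  x <- sin(2 * pi * 20 * tt) + 0.3 * cos(2 * pi * 31 * tt)
  spec <- tfr_spec(bands = list(low = c(5, 45)), n_tapers = c(low = 1L))
  mtm1 <- mtm_fourier(make_epoch_set(array(x, c(2000, 1, 1))), spec)
  p1 <- power_tfr(mtm1, band = "low")
  ## single taper, single trial: exactly |coeff|^2
  expect_equal(p1$values, Mod(mtm1$bands$low$coeff[, , 1, 1, 1])^2)
  p2 <- power_tfr(mtm_fourier(make_epoch_set(array(2 * x, c(2000, 1, 1))), spec),
                  band = "low")
  expect_equal(p2$values, 4 * p1$values, tolerance = 1e-12)
})

test_that("a resonator channel peaks within a half-bandwidth of its center", {
  withr::local_seed(3)
  dat <- array(NA_real_, c(2000, 20, 1))
  for (tr in 1:20) dat[, tr, 1] <- ar2_series(2000, 20, 3, 1, 500)
  spec <- tfr_spec(bands = list(low = c(5, 45)), n_tapers = c(low = 4L))
  p <- power_tfr(mtm_fourier(make_epoch_set(dat), spec), band = "low")
  pk <- p$freqs[which.max(rowMeans(p$values))]
  expect_lt(abs(pk - 20), 3.125)
})

test_that("multitaper power satisfies Parseval per window", {
  fs <- 500
  withr::local_seed(4)
  x <- rnorm(2000)
  win_n <- 400
  tap <- slepian_tapers(win_n, 4)
  spec <- tfr_spec(bands = list(all = c(0, 250)), n_tapers = c(all = 4L))
  mtm <- mtm_fourier(make_epoch_set(array(x, c(2000, 1, 1))), spec)
  co <- mtm$bands$all$coeff   # freq x time x taper
  tt <- (seq_len(2000) - 1 - 1000) / fs
  for (ci in c(1, 30, 65)) {
    i0 <- which.min(abs(tt - mtm$bands$all$times[ci])) - win_n / 2
    seg <- x[i0:(i0 + win_n - 1)]; seg <- seg - mean(seg)
    for (k in 1:4) {
      xt <- seg * tap[, k]
      ## one-sided sum with DC/Nyquist counted once
      pw <- Mod(co[, ci, k, 1, 1])^2
      total <- (2 * sum(pw) - pw[1] - pw[length(pw)]) / win_n
      expect_equal(total, sum(xt^2), tolerance = 0.01)
    }
  }
})

test_that("coherence is bounded, exact for identical channels, and needs 2 observations", {
  fs <- 500
  withr::local_seed(5)
  x <- array(rnorm(2000 * 10), c(2000, 10, 1))
  dat <- array(c(x, x), c(2000, 10, 2))
  spec <- tfr_spec(bands = list(low = c(5, 45)), n_tapers = c(low = 4L))
  mtm <- mtm_fourier(make_epoch_set(dat), spec)
  coh <- coherence_tfr(mtm, c(1, 2))
  expect_equal(max(abs(coh$values - 1)), 0, tolerance = 1e-12)
  ## independent channels stay within [0, 1]
  dat2 <- array(rnorm(2000 * 10 * 2), c(2000, 10, 2))
  coh2 <- coherence_tfr(mtm_fourier(make_epoch_set(dat2), spec), c(1, 2))
  expect_true(all(coh2$values >= 0 & coh2$values <= 1))
  ## single trial x single taper -> degenerate
  spec1 <- tfr_spec(bands = list(low = c(5, 45)), n_tapers = c(low = 1L))
  mtm1 <- mtm_fourier(make_epoch_set(dat2[, 1, , drop = FALSE]), spec1)
  expect_error(coherence_tfr(mtm1, c(1, 2)), "at least 2 observations")
})

test_that("generator coupling produces the implied coherence at band center", {
  task <- list(predictable = task_config("predictable", n_trials_per_block = 12,
                                         n_blocks = 1))
  ests <- c()
  for (i in 1:4) {
    subj <- simulate_subject(paste0("S", i), "R", task,
                             osc_specs = default_oscillation_specs(c("STN", "M1")),
                             seed = 300 + i)
    speed <- angular_speed(subj$conditions$predictable$trace$angle, 500)
    events <- detect_events(speed, subj$conditions$predictable$cues)
    ep <- epoch_signals(subj$conditions$predictable$signals[, c("M1_L", "STN_L")],
                        events, 500, span = 4, event_type = "start")
    spec <- tfr_spec(bands = list(low = c(5, 45)), n_tapers = c(low = 4L))
    coh <- coherence_tfr(mtm_fourier(ep, spec), c("M1_L", "STN_L"))
    ests <- c(ests, mean(coh$values[abs(coh$freqs - 20) < 0.1, coh$times < 0]))
  }
  imp <- implied_coherence(subj$conditions$predictable$truth, "M1_L", "STN_L", 20)
  expect_equal(mean(ests), imp, tolerance = 0.05 / imp)
})

test_that("baseline correction implements dB and subtraction semantics", {
  freqs <- seq(5, 45, by = 1.25)
  times <- seq(-1.6, 1.6, by = 0.05)
  flat <- matrix(3, length(freqs), length(times))
  m <- betawheel:::new_tfr_map(flat, freqs, times, "power")
  mc <- baseline_correct(m, c(-1.6, 0), "db")
  expect_equal(mc$values, flat * 0)
  ## doubling power post-event -> +3.0103 dB
  v <- flat; v[, times >= 0] <- 6
  mc2 <- baseline_correct(betawheel:::new_tfr_map(v, freqs, times, "power"))
  expect_equal(mean(mc2$values[, times >= 0]), 10 * log10(2), tolerance = 1e-9)
  expect_equal(mean(mc2$values[, times < 0]), 0, tolerance = 1e-12)
  ## coherence: subtraction; equal to baseline -> all zero
  cohm <- betawheel:::new_tfr_map(flat / 10, freqs, times, "coherence")
  cc <- baseline_correct(cohm)
  expect_equal(cc$values, flat * 0)
  expect_equal(cc$kind, "coherence_change")
  ## zero baseline power errors
  v0 <- flat; v0[, times < 0] <- 0
  expect_error(baseline_correct(betawheel:::new_tfr_map(v0, freqs, times, "power")),
               "baseline power")
  ## double correction errors
  expect_error(baseline_correct(mc), "already")
})

test_that("band modulation is post minus pre with window dilution arithmetic", {
  freqs <- seq(5, 45, by = 1.25)
  times <- seq(-1.6, 1.55, by = 0.05)
  v <- matrix(0, length(freqs), length(times))
  m0 <- betawheel:::new_tfr_map(v, freqs, times, "power_dB", "corrected")
  expect_equal(band_modulation(m0, c(13, 30))$modulation, 0)
  ## +2.5 dB confined to 0.3..1.0 s -> modulation = 2.5 * 0.7 / 1.6
  v2 <- v
  v2[freqs >= 13 & freqs <= 30, times >= 0.3 & times < 1.0] <- 2.5
  m2 <- betawheel:::new_tfr_map(v2, freqs, times, "power_dB", "corrected")
  got <- band_modulation(m2, c(13, 30))
  expect_equal(got$modulation, 2.5 * 0.7 / 1.6, tolerance = 0.01)
  expect_equal(got$modulation, got$post - got$pre)
  expect_error(band_modulation(m2, c(100, 120)), "outside")
})

test_that("power maps ignore trial order; coherence is invariant to joint permutation", {
  withr::local_seed(6)
  dat <- array(rnorm(2000 * 8 * 2), c(2000, 8, 2))
  spec <- tfr_spec(bands = list(low = c(5, 45)), n_tapers = c(low = 4L))
  perm <- sample(8)
  m1 <- mtm_fourier(make_epoch_set(dat), spec)
  m2 <- mtm_fourier(make_epoch_set(dat[, perm, , drop = FALSE]), spec)
  expect_equal(power_tfr(m1, 1, "low")$values, power_tfr(m2, 1, "low")$values,
               tolerance = 1e-12)
  expect_equal(coherence_tfr(m1, c(1, 2))$values, coherence_tfr(m2, c(1, 2))$values,
               tolerance = 1e-12)
})

test_that("segment band modulation matches a constructed power step", {
  fs <- 500
  withr::local_seed(7)
  ## trials whose post-event half has twice the variance
  dat <- array(rnorm(2000 * 20), c(2000, 20, 1))
  dat[1001:2000, , ] <- dat[1001:2000, , ] * sqrt(2)
  ep <- make_epoch_set(dat)
  got <- segment_band_modulation(ep, 1, band = c(2, 249), n_tapers = 7)
  expect_equal(got$modulation, 10 * log10(2), tolerance = 0.05)
})

test_that("trial-resolved power averages to the trial-mean map", {
  withr::local_seed(8)
  dat <- array(rnorm(2000 * 6), c(2000, 6, 1))
  spec <- tfr_spec(bands = list(low = c(5, 45)), n_tapers = c(low = 4L))
  mtm <- mtm_fourier(make_epoch_set(dat), spec)
  ptr <- power_tfr(mtm, band = "low", average_trials = FALSE)
  pav <- power_tfr(mtm, band = "low")
  expect_equal(dim(ptr$values), c(6, 33, 65))
  expect_equal(apply(ptr$values, c(2, 3), mean), pav$values, tolerance = 1e-12)
})

test_that("short epochs are rejected with the required span", {
  spec <- tfr_spec()
  ep <- make_epoch_set(array(rnorm(600 * 2), c(600, 2, 1)))  # 1.2 s epochs
  expect_error(mtm_fourier(ep, spec), "epoch too short")
})
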