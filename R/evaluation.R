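## Validation suites: simulation-based checks of the statistical machinery
## (type-I error, detection power, direction recovery, parameter recovery)
## run on reduced synthetic cohorts with known ground truth.

#' Empirical type-I error of the cluster permutation test
#'
#' Repeatedly draws pure-null subject stacks (independent standard-normal
#' baseline-corrected maps, zero expectation per bin) and records how often
#' any significant cluster is reported.
#'
#' @param n_reps Number of null datasets.
#' @param n_subjects Subjects per dataset.
#' @param freqs,times Grid axes.
#' @param cfg A [cluster_test_config()].
#' @param seed Integer seed.
#' @return List: `rate` (fraction of datasets with any significant
#'   cluster), `hits`, `n_reps`.
#' @export
cluster_type1_rate <- function(n_reps = 200L, n_subjects = 20L,
                               freqs = seq(5, 45, by = 1.25),
                               times = seq(-1.6, 1.6, by = 0.05),
                               cfg = cluster_test_config(),
                               seed = 1L) {
  hits <- 0L
  nf <- length(freqs); nt <- length(times)
  for (r in seq_len(n_reps)) {
    maps <- with_seed_or_not(derive_seed(seed, paste0("null", r)),
      lapply(seq_len(n_subjects), function(i)
        new_tfr_map(matrix(stats::rnorm(nf * nt), nf, nt), freqs, times,
                    "power_dB", "corrected")))
    cfg$seed <- derive_seed(seed, paste0("perm", r))
    res <- cluster_permutation_test(baseline_contrast_maps(maps), cfg)
    hits <- hits + as.integer(any(res$clusters$significant))
  }
  list(rate = hits / n_reps, hits = hits, n_reps = n_reps)
}

## significant cluster of the requested sign overlapping a band x window box
has_cluster_in <- function(res, sign, band = c(13, 30), window = c(0, 1.6)) {
  cl <- res$clusters
  cl <- cl[cl$significant & cl$sign == sign, , drop = FALSE]
  if (nrow(cl) == 0L) return(FALSE)
  any(cl$freq_lo <= band[2] & cl$freq_hi >= band[1] &
        cl$time_lo <= window[2] & cl$time_hi >= window[1])
}

#' Detection of injected beta suppression and rebound across replicate cohorts
#'
#' For each replicate, simulates a reduced cohort (single predictable
#' block), detects events, computes contralateral STN and M1 dB maps for
#' start and stop, and runs the group cluster permutation test; a replicate
#' counts as detected when a significant negative beta cluster overlaps the
#' post-start window and a significant positive one the post-stop window,
#' in both areas.
#'
#' @param n_reps Replicate cohorts.
#' @param n_subjects,n_trials Cohort size per replicate. The subject count
#'   must keep the sign-flip permutation space large relative to the
#'   cluster alpha: with n subjects only 2^n sign patterns exist, so a
#'   cluster can never reach p <= alpha/2 unless 2^(n-1) well exceeds
#'   2/alpha; 8 subjects is the smallest comfortable choice at alpha 0.05.
#' @param cluster_cfg A [cluster_test_config()].
#' @param seed Integer seed.
#' @return List: `rate` (fraction of replicates with all four detections),
#'   `detail` (replicate x check logical matrix).
#' @export
suppression_rebound_detection_rate <- function(n_reps = 100L, n_subjects = 8L,
                                               n_trials = 8L,
                                               cluster_cfg = cluster_test_config(),
                                               seed = 1L) {
  task <- list(predictable = task_config("predictable",
                                         n_trials_per_block = n_trials,
                                         n_blocks = 1L))
  spec <- tfr_spec(bands = list(low = c(5, 45)), n_tapers = c(low = 4L))
  osc <- default_oscillation_specs(c("STN", "M1"))
  checks <- c("STN_start_neg", "STN_stop_pos", "M1_start_neg", "M1_stop_pos")
  detail <- matrix(NA, n_reps, 4L, dimnames = list(NULL, checks))
  for (r in seq_len(n_reps)) {
    maps <- list(STN_start = list(), STN_stop = list(),
                 M1_start = list(), M1_stop = list())
    for (i in seq_len(n_subjects)) {
      subj <- simulate_subject(paste0("S", i), "R", task, osc_specs = osc,
                               seed = derive_seed(seed, paste0("rep", r, "s", i)))
      cc <- subj$conditions$predictable
      speed <- angular_speed(cc$trace$angle, subj$sample_rate)
      events <- detect_events(speed, cc$cues)
      for (area in c("STN", "M1")) {
        ch <- role_to_channel(paste0(area, "_contra"), subj$hand)
        for (evt in c("start", "stop")) {
          ep <- epoch_signals(cc$signals[, ch, drop = FALSE], events,
                              subj$sample_rate, span = 4, event_type = evt)
          map <- baseline_correct(power_tfr(mtm_fourier(ep, spec), band = "low"))
          key <- paste(area, evt, sep = "_")
          maps[[key]] <- c(maps[[key]], list(map))
        }
      }
    }
    for (k in seq_along(checks)) {
      key <- sub("_(neg|pos)$", "", checks[k])
      sgn <- if (grepl("neg$", checks[k])) "negative" else "positive"
      cluster_cfg$seed <- derive_seed(seed, paste0("perm", r, key))
      res <- cluster_permutation_test(baseline_contrast_maps(maps[[key]]),
                                      cluster_cfg)
      detail[r, k] <- has_cluster_in(res, sgn)
    }
  }
  list(rate = mean(apply(detail, 1L, all)), detail = detail)
}

#' Directed-coupling epochs for connectivity validation
#'
#' Post-event-window style trials of a cortex-like source and an STN-like
#' target: both carry 1/f background and their own beta resonator; the
#' target additionally receives a lagged, scaled copy of the source's beta
#' component (strictly causal source -> target).
#'
#' @param n_trials Trials.
#' @param n_samples Samples per trial.
#' @param strength,lag Coupling coefficient and lag (samples).
#' @param fs Sampling rate, Hz.
#' @return A `bw_epoch_set` with channels `cortex`, `stn`.
#' @export
coupled_pair_epochs <- function(n_trials = 40L, n_samples = 2000L,
                                strength = 0.65, lag = 10L, fs = 500) {
  dat <- array(NA_real_, c(n_samples, n_trials, 2L))
  for (tr in seq_len(n_trials)) {
    xb <- ar2_series(n_samples + lag, 20, 3, 1, fs)
    x <- pink_noise(n_samples + lag, 1, 0.25, fs) + xb
    y <- pink_noise(n_samples + lag, 1, 0.25, fs) +
      ar2_series(n_samples + lag, 20, 3, 1, fs) +
      strength * c(rep(0, lag), xb[seq_len(n_samples)])
    dat[, tr, 1L] <- x[(lag + 1L):(lag + n_samples)]
    dat[, tr, 2L] <- y[(lag + 1L):(lag + n_samples)]
  }
  dimnames(dat) <- list(NULL, NULL, c("cortex", "stn"))
  structure(list(data = dat,
                 time = (seq_len(n_samples) - 1L - n_samples %/% 2L) / fs,
                 channels = c("cortex", "stn"), info = NULL,
                 alignment = "movement", n_excluded = 0L, sample_rate = fs),
            class = "bw_epoch_set")
}

#' Granger direction recovery rate over repeated coupled datasets
#'
#' Each run draws fresh coupled cortex->STN epochs, computes the
#' time-reversed Granger contrast in the beta band, and scores whether the
#' contrast is positive for cortex->STN and negative for STN->cortex.
#'
#' @param n_runs Number of datasets.
#' @param n_trials Trials per dataset.
#' @param seed Integer seed.
#' @return List: `rate` (fraction of runs with both signs correct),
#'   `max_residual` (worst factorization residual over all runs),
#'   `mean_delta_forward`.
#' @export
granger_direction_recovery <- function(n_runs = 100L, n_trials = 40L,
                                       seed = 1L) {
  correct <- logical(n_runs)
  max_res <- 0
  deltas <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    ep <- with_seed_or_not(derive_seed(seed, paste0("gc", r)),
                           coupled_pair_epochs(n_trials))
    gc <- time_reversal_contrast(ep, c("cortex", "stn"),
                                 bands = list(beta = c(13, 30)))
    fw <- gc$delta[gc$source == "cortex"]
    bw <- gc$delta[gc$source == "stn"]
    correct[r] <- fw > 0 && bw < 0
    deltas[r] <- fw
    max_res <- max(max_res, attr(gc, "residuals"))
  }
  list(rate = mean(correct), max_residual = max_res,
       mean_delta_forward = mean(deltas))
}

#' Kinematic recovery: detection sensitivity, timing error, reaction times
#'
#' Simulates encoder traces for both conditions, runs detection, and
#' compares detected events and reaction times against ground truth.
#'
#' @param n_trials Trials per condition.
#' @param seed Integer seed.
#' @return List: `sensitivity`, `timing_error_ms` (mean absolute),
#'   `rt_mean_predictable_start`, `rt_mean_unpredictable_start`, `rt_n`.
#' @export
kinematics_recovery <- function(n_trials = 300L, seed = 1L) {
  kin <- kinematics_config()
  n_truth <- 0L; n_match <- 0L; terr <- c()
  rt_means <- c(); rt_ns <- c()
  for (cond in c("predictable", "unpredictable")) {
    cfg <- task_config(cond, n_trials_per_block = n_trials, n_blocks = 1L,
                       seed = derive_seed(seed, paste0(cond, "task")))
    cues <- generate_task_sequence(cfg)
    tr <- generate_wheel_trace(cues, kin, seed = derive_seed(seed, paste0(cond, "wheel")))
    det <- detect_events(angular_speed(tr$angle, kin$sample_rate), tr$cues)
    gt <- tr$events
    m <- merge(gt[c("linked_cue_index", "time")], det[c("linked_cue_index", "time")],
               by = "linked_cue_index")
    n_truth <- n_truth + nrow(gt); n_match <- n_match + nrow(m)
    terr <- c(terr, abs(m$time.y - m$time.x))
    rt <- reaction_times(det, tr$cues)
    row <- rt$summary[rt$summary$event_type == "start", ]
    rt_means[cond] <- row$mean; rt_ns[cond] <- row$n
  }
  list(sensitivity = n_match / n_truth,
       timing_error_ms = 1000 * mean(terr),
       rt_mean_predictable_start = unname(rt_means["predictable"]),
       rt_mean_unpredictable_start = unname(rt_means["unpredictable"]),
       rt_n = unname(rt_ns))
}

#' Parameter recovery on a reduced synthetic cohort
#'
#' Estimates contralateral M1 start suppression and STN stop rebound (dB),
#' the M1->STN baseline coherence at the beta center, and the M1 rebound
#' lateralization index, and returns them alongside the generator's
#' implied values.
#'
#' @param n_subjects,n_trials Cohort size.
#' @param seed Integer seed.
#' @return List of estimate/implied pairs plus per-subject values.
#' @export
parameter_recovery <- function(n_subjects = 10L, n_trials = 12L, seed = 1L) {
  task <- list(predictable = task_config("predictable",
                                         n_trials_per_block = n_trials,
                                         n_blocks = 1L))
  spec <- tfr_spec(bands = list(low = c(5, 45)), n_tapers = c(low = 4L))
  osc <- default_oscillation_specs(c("STN", "M1"))
  sup <- reb <- reb_ipsi <- coh <- li <- numeric(n_subjects)
  truth <- NULL
  for (i in seq_len(n_subjects)) {
    subj <- simulate_subject(paste0("S", i), "R", task, osc_specs = osc,
                             seed = derive_seed(seed, paste0("pr", i)))
    cc <- subj$conditions$predictable
    truth <- cc$truth
    speed <- angular_speed(cc$trace$angle, subj$sample_rate)
    events <- detect_events(speed, cc$cues)
    get_map <- function(ch, evt) {
      ep <- epoch_signals(cc$signals[, ch, drop = FALSE], events,
                          subj$sample_rate, span = 4, event_type = evt)
      baseline_correct(power_tfr(mtm_fourier(ep, spec), band = "low"))
    }
    sup[i] <- band_modulation(get_map("M1_L", "start"))$modulation
    reb[i] <- band_modulation(get_map("STN_L", "stop"))$modulation
    m1_reb <- band_modulation(get_map("M1_L", "stop"))$modulation
    m1_reb_i <- band_modulation(get_map("M1_R", "stop"))$modulation
    li[i] <- suppressWarnings(lateralization_index(m1_reb, m1_reb_i))
    ep2 <- epoch_signals(cc$signals[, c("M1_L", "STN_L")], events,
                         subj$sample_rate, span = 4, event_type = "start")
    cm <- coherence_tfr(mtm_fourier(ep2, spec), c("M1_L", "STN_L"))
    coh[i] <- mean(cm$values[abs(cm$freqs - 20) < 0.1, cm$times < 0])
  }
  list(
    suppression_db = mean(sup), suppression_sem = stats::sd(sup) / sqrt(n_subjects),
    suppression_implied = implied_band_modulation(truth, "M1_L", "start", "predictable"),
    rebound_db = mean(reb), rebound_sem = stats::sd(reb) / sqrt(n_subjects),
    rebound_implied = implied_band_modulation(truth, "STN_L", "stop", "predictable"),
    coherence = mean(coh),
    coherence_implied = implied_coherence(truth, "M1_L", "STN_L", 20),
    li = mean(li), li_sem = stats::sd(li) / sqrt(n_subjects),
    li_expected = 3 / 7,
    per_subject = list(suppression = sup, rebound = reb, coherence = coh, li = li)
  )
}
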