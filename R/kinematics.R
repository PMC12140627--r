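## Encoder-trace kinematics: angular speed, semi-automated movement event
## detection, epoching, and behavioral summaries.

#' Angular speed from an encoder angle trace
#'
#' Central finite difference scaled to deg/s, then moving-average smoothed.
#' The sign of the speed encodes turning direction.
#'
#' @param angle Numeric angle trace, degrees.
#' @param sample_rate Sampling rate, Hz.
#' @param smoothing_window Moving-average window, seconds (0 disables).
#' @return A `bw_speed_trace` list: `samples` (deg/s, same length as
#'   `angle`), `sample_rate`, `smoothing_window`.
#' @export
angular_speed <- function(angle, sample_rate, smoothing_window = 0.05) {
  if (length(angle) < 2L) stopf("angle trace must have at least 2 samples")
  bad <- which(!is.finite(angle))
  if (length(bad) > 0L) stopf("non-finite angle sample at index %d", bad[1])
  n <- length(angle)
  v <- numeric(n)
  v[2:(n - 1)] <- (angle[3:n] - angle[1:(n - 2)]) * sample_rate / 2
  v[1] <- (angle[2] - angle[1]) * sample_rate
  v[n] <- (angle[n] - angle[n - 1]) * sample_rate
  if (smoothing_window > 0)
    v <- moving_average(v, round(smoothing_window * sample_rate))
  structure(list(samples = v, sample_rate = sample_rate,
                 smoothing_window = smoothing_window),
            class = "bw_speed_trace")
}

#' Event-detection configuration
#'
#' Amplitude and duration thresholds per event type, plus the noise-floor
#' fraction used to refine threshold crossings to movement onsets/offsets
#' and the flank window within which a reversal's opposite-sign
#' supra-threshold speeds must occur.
#'
#' @param amplitude_threshold deg/s; speed magnitude defining "moving".
#' @param duration_threshold s; how long the speed must stay beyond (start)
#'   or below (stop) the amplitude threshold.
#' @param flank_window s; maximal half-width of the sub-threshold interval
#'   around a reversal zero-crossing.
#' @param floor_fraction Fraction of `amplitude_threshold` treated as the
#'   noise floor when refining crossings to onset/offset times.
#' @return A `bw_detect_config` list.
#' @export
event_detection_config <- function(amplitude_threshold = 50,
                                   duration_threshold = 0.3,
                                   flank_window = 0.5,
                                   floor_fraction = 0.15) {
  assert_scalar_pos(amplitude_threshold, "amplitude_threshold")
  assert_scalar_pos(duration_threshold, "duration_threshold")
  assert_scalar_pos(flank_window, "flank_window")
  structure(list(amplitude_threshold = amplitude_threshold,
                 duration_threshold = duration_threshold,
                 flank_window = flank_window,
                 floor_fraction = floor_fraction),
            class = "bw_detect_config")
}

## first index i in [from, to] such that cond holds at i..i+len-1 (NA if none)
first_run_start <- function(flag, from, to, len) {
  if (from > to) return(NA_integer_)
  x <- flag[from:to]
  if (!any(x)) return(NA_integer_)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= len)
  if (length(ok) == 0L) return(NA_integer_)
  from + starts[ok[1]] - 1L
}

#' Detect movement events from a speed trace
#'
#' Semi-automated detection: per cue, a threshold crossing that persists for
#' the duration threshold marks the event, then the crossing is refined to
#' the movement onset (start: walk back to the noise floor), offset (stop:
#' walk forward to the noise floor), or the zero-crossing (reversal: center
#' of the sub-threshold interval between opposite-sign supra-threshold
#' flanks). Events violating temporal ordering are dropped with a logged
#' reason, standing in for manual correction.
#'
#' @param speed A [angular_speed()] result.
#' @param cues Cue table with absolute `sample` and `cue_type` columns.
#' @param cfg An [event_detection_config()].
#' @return A `bw_event_table` (`source = "detected"`); attribute `dropped`
#'   records rejected candidates with reasons.
#' @export
detect_events <- function(speed, cues, cfg = event_detection_config()) {
  if (is.null(cues) || nrow(cues) == 0L) stopf("a cue table is required")
  if (!inherits(speed, "bw_speed_trace") || length(speed$samples) == 0L)
    stopf("`speed` must be a non-empty bw_speed_trace")
  v <- speed$samples
  fs <- speed$sample_rate
  n <- length(v)
  amp <- cfg$amplitude_threshold
  dur_n <- max(1L, as.integer(round(cfg$duration_threshold * fs)))
  floor_amp <- cfg$floor_fraction * amp
  flank_n <- as.integer(round(cfg$flank_window * fs))
  above <- abs(v) >= amp
  below <- !above

  out <- list()
  dropped <- list()
  ncue <- nrow(cues)
  cue_samples <- cues$sample
  for (i in seq_len(ncue)) {
    s0 <- cue_samples[i]
    s1 <- if (i < ncue) cue_samples[i + 1L] - 1L else n
    s1 <- min(s1 + dur_n, n)  # allow persistence check to run past window end
    ct <- cues$cue_type[i]
    ev_sample <- NA_integer_
    if (ct == "start") {
      cross <- first_run_start(above, s0, s1, dur_n)
      if (!is.na(cross)) {
        j <- cross
        while (j > s0 && abs(v[j - 1L]) > floor_amp) j <- j - 1L
        ev_sample <- j
      }
    } else if (ct == "stop") {
      ## a stop requires ongoing movement first: search for the quiet run
      ## only after the last supra-threshold activity in the window
      moving <- first_run_start(above, s0, s1, 1L)
      if (!is.na(moving)) {
        cross <- first_run_start(below, moving, s1, dur_n)
        if (!is.na(cross)) {
          j <- cross
          while (j < s1 && abs(v[j]) > floor_amp) j <- j + 1L
          ev_sample <- j
        }
      }
    } else if (ct == "reverse") {
      ## sub-threshold runs flanked by opposite-sign supra-threshold speed
      idx <- s0
      while (idx <= s1 && is.na(ev_sample)) {
        run0 <- first_run_start(below, idx, s1, 1L)
        if (is.na(run0)) break
        run1 <- run0
        while (run1 < n && below[run1 + 1L]) run1 <- run1 + 1L
        pre_ok <- run0 > 1L && above[run0 - 1L]
        post_ok <- run1 < n && above[run1 + 1L]
        if (pre_ok && post_ok &&
            sign(v[run0 - 1L]) != sign(v[run1 + 1L]) &&
            (run1 - run0) <= 2L * flank_n) {
          ev_sample <- as.integer(round((run0 + run1) / 2))
        }
        idx <- run1 + 1L
      }
    }
    if (is.na(ev_sample)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        cue_index = i, reason = "no qualifying threshold pattern",
        stringsAsFactors = FALSE)
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      trial = cues$trial[i],
      event_type = cue_to_event[[ct]],
      time = (ev_sample - 1L) / fs,
      sample = ev_sample,
      linked_cue_index = i,
      condition = cues$condition[i],
      block = cues$block[i],
      source = "detected",
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    ev <- data.frame(trial = integer(), event_type = character(),
                     time = numeric(), sample = integer(),
                     linked_cue_index = integer(), condition = character(),
                     block = integer(), source = character(),
                     stringsAsFactors = FALSE)
  } else {
    ev <- do.call(rbind, out)
    ## ordering-based rejection (deterministic stand-in for manual review)
    keep <- rep(TRUE, nrow(ev))
    last <- -Inf
    for (k in seq_len(nrow(ev))) {
      if (ev$sample[k] <= last) {
        keep[k] <- FALSE
        dropped[[length(dropped) + 1L]] <- data.frame(
          cue_index = ev$linked_cue_index[k], reason = "violates event ordering",
          stringsAsFactors = FALSE)
      } else last <- ev$sample[k]
    }
    ev <- ev[keep, , drop = FALSE]
    rownames(ev) <- NULL
  }
  class(ev) <- c("bw_event_table", "data.frame")
  attr(ev, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else NULL
  ev
}

#' Epoch signals around events
#'
#' One trial per event of the requested type, `span` seconds wide, centered
#' on the event sample (movement-aligned) or on the linked cue sample
#' (cue-aligned). Windows are half-open: an event at sample s with a 4 s
#' span at 500 Hz covers samples s-1000 .. s+999. Out-of-bounds trials are
#' excluded and counted.
#'
#' @param signals Numeric vector or samples x channels matrix.
#' @param events A `bw_event_table`.
#' @param sample_rate Hz.
#' @param span Epoch width, seconds.
#' @param alignment `"movement"` or `"cue"`.
#' @param cues Cue table (required for cue alignment).
#' @param event_type,condition Optional filters.
#' @return A `bw_epoch_set`: `data` array (time x trial x channel), `time`
#'   axis (s, 0 = aligning sample), `channels`, `info` per-trial metadata,
#'   `n_excluded`, `sample_rate`.
#' @export
epoch_signals <- function(signals, events, sample_rate, span = 4,
                          alignment = c("movement", "cue"), cues = NULL,
                          event_type = NULL, condition = NULL) {
  alignment <- match.arg(alignment)
  if (is.vector(signals)) signals <- matrix(signals, ncol = 1L,
                                            dimnames = list(NULL, "signal"))
  ev <- events
  if (!is.null(event_type)) ev <- ev[ev$event_type %in% event_type, , drop = FALSE]
  if (!is.null(condition)) ev <- ev[ev$condition %in% condition, , drop = FALSE]
  if (nrow(ev) == 0L) stopf("no events of the requested type/condition")
  centers <- if (alignment == "movement") ev$sample else {
    if (is.null(cues)) stopf("cue-aligned epoching requires `cues`")
    cues$sample[ev$linked_cue_index]
  }
  half <- as.integer(round(span / 2 * sample_rate))
  n <- nrow(signals)
  ok <- centers - half >= 1L & centers + half - 1L <= n
  n_excluded <- sum(!ok)
  if (!any(ok)) stopf("zero usable trials after boundary exclusion")
  centers <- centers[ok]
  ev <- ev[ok, , drop = FALSE]
  nt <- 2L * half
  dat <- array(NA_real_, c(nt, length(centers), ncol(signals)),
               dimnames = list(NULL, NULL, colnames(signals)))
  for (k in seq_along(centers)) {
    idx <- (centers[k] - half):(centers[k] + half - 1L)
    dat[, k, ] <- signals[idx, , drop = FALSE]
  }
  structure(list(
    data = dat,
    time = (seq_len(nt) - 1L - half) / sample_rate,
    channels = colnames(signals),
    info = ev,
    alignment = alignment,
    n_excluded = n_excluded,
    sample_rate = sample_rate
  ), class = "bw_epoch_set")
}

#' Reaction times from detected events and cues
#'
#' RT = event time minus linked cue time. Negative RTs (event preceding its
#' cue) are flagged and excluded from the summaries.
#'
#' @param events A `bw_event_table` with `linked_cue_index`.
#' @param cues Cue table with absolute `time`.
#' @return List: `table` (per-event RTs), `summary` (mean, sd, n per
#'   condition x event type), `n_flagged`.
#' @export
reaction_times <- function(events, cues) {
  if (is.null(events$linked_cue_index) || anyNA(events$linked_cue_index))
    stopf("every event must be linked to a cue")
  rt <- events$time - cues$time[events$linked_cue_index]
  tab <- data.frame(condition = events$condition,
                    event_type = events$event_type,
                    trial = events$trial, rt = rt,
                    stringsAsFactors = FALSE)
  flagged <- tab$rt < 0
  tab$flagged <- flagged
  ok <- tab[!flagged, , drop = FALSE]
  summ <- stats::aggregate(rt ~ condition + event_type, data = ok,
                           FUN = function(x) c(mean = mean(x), sd = stats::sd(x), n = length(x)))
  summ <- cbind(summ[c("condition", "event_type")], as.data.frame(summ$rt))
  list(table = tab, summary = summ, n_flagged = sum(flagged))
}

#' Event- or cue-aligned trial-average speed
#'
#' @inheritParams epoch_signals
#' @param speed A `bw_speed_trace`.
#' @return List: `time`, `mean` (trial-average speed curve), `n_trials`.
#' @export
aligned_speed_average <- function(speed, events, span = 4,
                                  alignment = c("movement", "cue"),
                                  cues = NULL, event_type = NULL,
                                  condition = NULL) {
  ep <- epoch_signals(speed$samples, events, speed$sample_rate, span,
                      alignment, cues, event_type, condition)
  list(time = ep$time,
       mean = rowMeans(matrix(ep$data[, , 1L], nrow = dim(ep$data)[1L])),
       n_trials = dim(ep$data)[2L])
}
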