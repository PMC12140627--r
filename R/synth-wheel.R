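## Wheel-encoder trace generation: smooth angular-speed profiles integrated
## to an absolute angle, quantized at the encoder resolution, with ground
## truth movement events (speed onset, reversal zero-crossing, final zero).

#' Kinematics configuration for the wheel-trace generator
#'
#' Reaction-time defaults follow the condition-dependent means/SDs used
#' throughout the package: predictable start 0.757 (0.154) s, unpredictable
#' start 0.840 (0.160) s, predictable stop 0.824 (0.202) s, unpredictable
#' stop 0.889 (0.233) s. Reversal reaction times are free parameters.
#'
#' @param target_speed Steady turning speed, deg/s.
#' @param ramp_time Raised-cosine acceleration/deceleration time, s.
#' @param reversal_pause Dwell at zero speed during a reversal, s.
#' @param rt_table data.frame with columns `condition`, `event`
#'   (`start`/`reversal`/`stop`), `mean`, `sd` (seconds).
#' @param encoder_resolution Angle quantization step, degrees.
#' @param sample_rate Sampling rate, Hz (shared by encoder and neural data).
#' @return A `bw_kinematics_config` list.
#' @export
kinematics_config <- function(target_speed = 400,
                              ramp_time = 0.15,
                              reversal_pause = 0.2,
                              rt_table = default_rt_table(),
                              encoder_resolution = 0.1,
                              sample_rate = 500) {
  assert_scalar_pos(target_speed, "target_speed")
  assert_scalar_pos(ramp_time, "ramp_time")
  assert_scalar_pos(sample_rate, "sample_rate")
  if (reversal_pause < 0) stopf("`reversal_pause` must be >= 0")
  need <- c("condition", "event", "mean", "sd")
  if (!all(need %in% names(rt_table))) stopf("`rt_table` needs columns %s", paste(need, collapse = ", "))
  if (any(rt_table$mean <= 0) || any(rt_table$sd < 0)) stopf("reaction-time means must be > 0 and SDs >= 0")
  structure(list(
    target_speed = target_speed, ramp_time = ramp_time,
    reversal_pause = reversal_pause, rt_table = rt_table,
    encoder_resolution = encoder_resolution, sample_rate = sample_rate
  ), class = "bw_kinematics_config")
}

#' @rdname kinematics_config
#' @export
default_rt_table <- function() {
  data.frame(
    condition = rep(c("predictable", "unpredictable"), each = 3),
    event = rep(c("start", "reversal", "stop"), 2),
    mean = c(0.757, 0.760, 0.824, 0.840, 0.850, 0.889),
    sd   = c(0.154, 0.160, 0.202, 0.160, 0.170, 0.233),
    stringsAsFactors = FALSE
  )
}

rt_params <- function(rt_table, condition, event) {
  row <- rt_table[rt_table$condition == condition & rt_table$event == event, ]
  if (nrow(row) != 1L) stopf("no reaction-time entry for condition '%s', event '%s'", condition, event)
  list(mean = row$mean, sd = row$sd)
}

cue_to_event <- c(start = "start", reverse = "reversal", stop = "stop")

#' Generate an encoder angle trace with ground-truth events
#'
#' Integrates a piecewise speed profile (raised-cosine ramps between steady
#' segments) over the cue sequence. Movement onset for each cue is the cue
#' time plus a truncated-normal reaction time; reversals decelerate through
#' zero, dwell for `reversal_pause`, and re-accelerate in the opposite
#' direction. The returned angle is quantized at the encoder resolution.
#'
#' Ground-truth event times: `start` = speed onset, `reversal` = center of
#' the zero-speed dwell, `stop` = the sample at which speed first returns
#' to zero.
#'
#' @param cues A `bw_cue_table` from [generate_task_sequence()].
#' @param kin A [kinematics_config()].
#' @param seed Integer seed or `NULL`.
#' @param lead_in,tail Quiet recording padding before the first and after the
#'   last cue, seconds (must exceed half an epoch span).
#' @return A `bw_wheel_trace` list: `angle` (quantized, deg), `speed_true`
#'   (unquantized deg/s), `sample_rate`, `cues` (with absolute `time` and
#'   1-based `sample` columns), `events` (`bw_event_table`, ground truth),
#'   `n_resampled_rt`.
#' @export
generate_wheel_trace <- function(cues, kin, seed = NULL, lead_in = 4, tail = 6) {
  if (!inherits(cues, "bw_cue_table")) stopf("`cues` must come from generate_task_sequence()")
  fs <- kin$sample_rate
  with_seed_or_not(seed, {
    cue_abs <- cues$time + lead_in
    duration <- max(cue_abs) + tail
    n <- as.integer(round(duration * fs))
    speed <- numeric(n)
    n_resampled <- 0L

    ncue <- nrow(cues)
    next_cue_gap <- c(diff(cues$time), Inf)

    ## sample reaction times, resampling any that would collide with the
    ## next cue in the sequence
    rts <- numeric(ncue)
    for (i in seq_len(ncue)) {
      ev <- cue_to_event[[cues$cue_type[i]]]
      pr <- rt_params(kin$rt_table, cues$condition[i], ev)
      rt <- rtruncnorm_pos(1L, pr$mean, pr$sd)
      tries <- 0L
      while (rt >= next_cue_gap[i] && tries < 50L) {
        rt <- rtruncnorm_pos(1L, pr$mean, pr$sd)
        n_resampled <- n_resampled + 1L
        tries <- tries + 1L
      }
      rts[i] <- rt
    }
    if (n_resampled > 0L)
      warnf("%d reaction time(s) exceeded the next inter-stimulus interval and were resampled", n_resampled)

    ramp_n <- max(2L, as.integer(round(kin$ramp_time * fs)))
    pause_n <- as.integer(round(kin$reversal_pause * fs))
    ramp01 <- cosine_ramp(ramp_n)

    ## all assignments into `speed` stay in this frame so R modifies the
    ## vector in place (helper functions would force full copies per cue)
    cur_val <- 0
    cur_idx <- 1L
    ev_type_v <- character(ncue); ev_time_v <- numeric(ncue)
    for (i in seq_len(ncue)) {
      t_on <- cue_abs[i] + rts[i]
      i_on <- as.integer(round(t_on * fs)) + 1L
      if (i_on - 1L >= cur_idx) speed[cur_idx:min(i_on - 1L, n)] <- cur_val
      ct <- cues$cue_type[i]
      if (ct == "start") {
        target <- cues$direction[i] * kin$target_speed
        idx <- i_on + seq_len(ramp_n) - 1L
        keep <- idx >= 1L & idx <= n
        speed[idx[keep]] <- (target * ramp01)[keep]
        cur_idx <- i_on + ramp_n
        cur_val <- target
        ev_time_v[i] <- t_on
        ev_type_v[i] <- "start"
      } else if (ct == "reverse") {
        target <- -cur_val
        idx <- i_on + seq_len(ramp_n) - 1L
        keep <- idx >= 1L & idx <= n
        speed[idx[keep]] <- (cur_val * (1 - ramp01))[keep]
        p0 <- i_on + ramp_n; p1 <- i_on + ramp_n + pause_n - 1L
        if (p1 >= p0 && p0 <= n) speed[p0:min(p1, n)] <- 0
        idx <- i_on + ramp_n + pause_n + seq_len(ramp_n) - 1L
        keep <- idx >= 1L & idx <= n
        speed[idx[keep]] <- (target * ramp01)[keep]
        cur_idx <- i_on + 2L * ramp_n + pause_n
        cur_val <- target
        ev_time_v[i] <- t_on + kin$ramp_time + kin$reversal_pause / 2
        ev_type_v[i] <- "reversal"
      } else {
        idx <- i_on + seq_len(ramp_n) - 1L
        keep <- idx >= 1L & idx <= n
        speed[idx[keep]] <- (cur_val * (1 - ramp01))[keep]
        cur_idx <- i_on + ramp_n
        cur_val <- 0
        ev_time_v[i] <- t_on + kin$ramp_time
        ev_type_v[i] <- "stop"
      }
    }
    if (cur_idx <= n) speed[cur_idx:n] <- cur_val
    events <- data.frame(
      trial = cues$trial, event_type = ev_type_v, time = ev_time_v,
      sample = as.integer(round(ev_time_v * fs)) + 1L,
      linked_cue_index = seq_len(ncue), condition = cues$condition,
      block = cues$block, source = "ground_truth",
      stringsAsFactors = FALSE
    )

    angle <- cumsum(speed) / fs
    res <- kin$encoder_resolution
    angle_q <- if (res > 0) round(angle / res) * res else angle

    ev <- events
    class(ev) <- c("bw_event_table", "data.frame")

    cues_out <- cues
    cues_out$time <- cue_abs
    cues_out$sample <- as.integer(round(cue_abs * fs)) + 1L

    structure(list(
      angle = angle_q, speed_true = speed, sample_rate = fs,
      cues = cues_out, events = ev, n_resampled_rt = n_resampled,
      lead_in = lead_in, reaction_times = rts
    ), class = "bw_wheel_trace")
  })
}
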