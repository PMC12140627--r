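## Task-sequence generation: cue tables for the wheel-turning paradigm.
##
## Two block types. Predictable: every trial is start -> reverse -> stop with
## a fixed inter-cue interval, followed by a fixed pause. Unpredictable: the
## number of reversals per trial is drawn from {0, 1, 2} with configurable
## probabilities, and inter-stimulus intervals are drawn from a mixture that
## keeps a configurable fraction at the fixed interval and spreads the rest
## uniformly over a range, so cue timing carries no predictive information
## beyond the mixture itself.

#' Task configuration for one block type
#'
#' @param condition `"predictable"` or `"unpredictable"`.
#' @param n_trials_per_block Trials per block.
#' @param n_blocks Number of blocks of this condition.
#' @param isi_fixed Fixed inter-stimulus interval in seconds (the predictable
#'   inter-cue spacing, and the point mass of the unpredictable mixture).
#' @param isi_range Length-2 numeric, uniform range (s) for the jittered part
#'   of the unpredictable inter-stimulus interval mixture.
#' @param isi_fixed_fraction Fraction of unpredictable intervals held at
#'   `isi_fixed`.
#' @param reversal_counts Integer vector of allowed reversal counts per trial
#'   (unpredictable condition).
#' @param reversal_probs Probabilities for `reversal_counts`; must sum to 1.
#' @param pause_duration Pause after each trial's stop cue, seconds. In the
#'   unpredictable condition the pause is drawn from the same ISI mixture.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A `bw_task_config` list.
#' @export
task_config <- function(condition = c("predictable", "unpredictable"),
                        n_trials_per_block = 36L,
                        n_blocks = 2L,
                        isi_fixed = 4,
                        isi_range = c(4, 7),
                        isi_fixed_fraction = 0.5,
                        reversal_counts = c(0L, 1L, 2L),
                        reversal_probs = c(1, 1, 1) / 3,
                        pause_duration = 4,
                        seed = NULL) {
  condition <- match.arg(condition)
  assert_scalar_pos(n_trials_per_block, "n_trials_per_block")
  assert_scalar_pos(n_blocks, "n_blocks")
  assert_scalar_pos(isi_fixed, "isi_fixed")
  assert_scalar_pos(pause_duration, "pause_duration")
  if (length(isi_range) != 2L || isi_range[1] > isi_range[2])
    stopf("`isi_range` must be c(low, high) with low <= high")
  if (length(reversal_counts) != length(reversal_probs))
    stopf("`reversal_counts` and `reversal_probs` must have equal length")
  assert_prob_vector(reversal_probs, "reversal_probs")
  if (isi_fixed_fraction < 0 || isi_fixed_fraction > 1)
    stopf("`isi_fixed_fraction` must be in [0, 1]")
  structure(list(
    condition = condition,
    n_trials_per_block = as.integer(n_trials_per_block),
    n_blocks = as.integer(n_blocks),
    isi_fixed = isi_fixed,
    isi_range = isi_range,
    isi_fixed_fraction = isi_fixed_fraction,
    reversal_counts = as.integer(reversal_counts),
    reversal_probs = reversal_probs,
    pause_duration = pause_duration,
    seed = seed
  ), class = "bw_task_config")
}

draw_isi <- function(n, cfg) {
  fixed <- stats::runif(n) < cfg$isi_fixed_fraction
  out <- numeric(n)
  out[fixed] <- cfg$isi_fixed
  out[!fixed] <- stats::runif(sum(!fixed), cfg$isi_range[1], cfg$isi_range[2])
  out
}

#' Generate a cue table for one condition
#'
#' Cue times start at 0 (first start cue). Directions alternate at each
#' reversal; the unpredictable start direction is balanced across trials.
#'
#' @param cfg A [task_config()].
#' @return A data.frame of class `bw_cue_table` with columns `block`,
#'   `trial`, `cue_type` (`start`/`reverse`/`stop`), `direction` (+1/-1),
#'   `time` (s), `condition`.
#' @export
generate_task_sequence <- function(cfg) {
  if (!inherits(cfg, "bw_task_config")) stopf("`cfg` must come from task_config()")
  with_seed_or_not(cfg$seed, {
    rows <- list()
    t_now <- 0
    trial_id <- 0L
    for (b in seq_len(cfg$n_blocks)) {
      ## balanced start directions within a block
      dirs <- rep(c(1, -1), length.out = cfg$n_trials_per_block)
      if (cfg$condition == "unpredictable") dirs <- sample(dirs)
      for (tr in seq_len(cfg$n_trials_per_block)) {
        trial_id <- trial_id + 1L
        if (cfg$condition == "predictable") {
          n_rev <- 1L
          isis <- rep(cfg$isi_fixed, n_rev + 1L)
          pause <- cfg$pause_duration
          dir0 <- 1
        } else {
          n_rev <- sample(cfg$reversal_counts, 1L, prob = cfg$reversal_probs)
          isis <- draw_isi(n_rev + 1L, cfg)
          pause <- draw_isi(1L, cfg)
          dir0 <- dirs[tr]
        }
        cue_types <- c("start", rep("reverse", n_rev), "stop")
        times <- t_now + c(0, cumsum(isis))
        dir_seq <- dir0 * c(1, cumprod(rep(-1, n_rev)), NA)[seq_along(cue_types)]
        dir_seq[length(dir_seq)] <- 0  # stop cue has no direction
        rows[[length(rows) + 1L]] <- data.frame(
          block = b, trial = trial_id, cue_type = cue_types,
          direction = dir_seq, time = times,
          condition = cfg$condition, stringsAsFactors = FALSE
        )
        t_now <- times[length(times)] + pause
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("bw_cue_table", "data.frame")
    attr(out, "total_duration") <- t_now
    out
  })
}
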