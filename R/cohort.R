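## Synthetic cohort assembly and on-disk persistence (plain-text formats:
## CSV for arrays and tables, JSON for metadata).

#' Simulate one subject
#'
#' Generates, per condition, a cue table, a wheel-encoder trace with
#' ground-truth events, and coupled neural signals.
#'
#' @param id Subject identifier.
#' @param hand Moving hand, `"L"` or `"R"`.
#' @param task Named list of [task_config()] per condition.
#' @param kin A [kinematics_config()].
#' @param osc_specs,coupling_specs Oscillation/coupling specifications.
#' @param noise_exponent,noise_power Background noise parameters.
#' @param seed Integer seed (per-stage seeds derived deterministically).
#' @return A `bw_subject` list: `id`, `hand`, `sample_rate`, `conditions`
#'   (per condition: `cues`, `trace`, `signals`, `truth`).
#' @export
simulate_subject <- function(id, hand = "R",
                             task = list(predictable = task_config("predictable"),
                                         unpredictable = task_config("unpredictable")),
                             kin = kinematics_config(),
                             osc_specs = default_oscillation_specs(),
                             coupling_specs = default_coupling_specs(),
                             noise_exponent = 1, noise_power = 0.25,
                             seed = NULL) {
  conditions <- list()
  for (cond in names(task)) {
    cfg <- task[[cond]]
    cfg$seed <- derive_seed(seed, paste0(id, cond, "task"))
    cues <- generate_task_sequence(cfg)
    trace <- generate_wheel_trace(cues, kin,
                                  seed = derive_seed(seed, paste0(id, cond, "wheel")))
    neural <- generate_neural_data(trace, osc_specs, coupling_specs, hand,
                                   noise_exponent, noise_power,
                                   seed = derive_seed(seed, paste0(id, cond, "neural")))
    conditions[[cond]] <- list(cues = trace$cues, trace = trace,
                               signals = neural$signals, truth = neural$truth)
  }
  structure(list(id = id, hand = hand, sample_rate = kin$sample_rate,
                 conditions = conditions, kin = kin),
            class = "bw_subject")
}

#' Simulate a cohort of subjects
#'
#' Moving hand alternates across subjects; all other parameters are shared.
#' All randomness derives from the single `seed`.
#'
#' @inheritParams simulate_subject
#' @param n_subjects Cohort size.
#' @return A `bw_cohort` list of `bw_subject`s (attribute `seed`).
#' @export
simulate_cohort <- function(n_subjects = 20L,
                            task = list(predictable = task_config("predictable"),
                                        unpredictable = task_config("unpredictable")),
                            kin = kinematics_config(),
                            osc_specs = default_oscillation_specs(),
                            coupling_specs = default_coupling_specs(),
                            noise_exponent = 1, noise_power = 0.25,
                            seed = NULL) {
  hands <- rep(c("R", "L"), length.out = n_subjects)
  subjects <- lapply(seq_len(n_subjects), function(i)
    simulate_subject(paste0("S", sprintf("%02d", i)), hands[i], task, kin,
                     osc_specs, coupling_specs, noise_exponent, noise_power,
                     seed = derive_seed(seed, paste0("subject", i))))
  structure(subjects, class = "bw_cohort", seed = seed)
}

#' Write a cohort to a directory of plain-text files
#'
#' Per subject and condition: signals and encoder angle as CSV, cue and
#' ground-truth event tables as CSV, and subject metadata as JSON.
#'
#' @param cohort A `bw_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in cohort) {
    sd <- file.path(dir, subj$id)
    dir.create(sd, showWarnings = FALSE)
    meta <- list(id = subj$id, hand = subj$hand, sample_rate = subj$sample_rate,
                 conditions = names(subj$conditions))
    jsonlite::write_json(meta, file.path(sd, "meta.json"), auto_unbox = TRUE)
    for (cond in names(subj$conditions)) {
      cc <- subj$conditions[[cond]]
      utils::write.csv(as.data.frame(cc$signals),
                       file.path(sd, paste0(cond, "_signals.csv")), row.names = FALSE)
      utils::write.csv(data.frame(angle = cc$trace$angle),
                       file.path(sd, paste0(cond, "_angle.csv")), row.names = FALSE)
      utils::write.csv(as.data.frame(cc$cues),
                       file.path(sd, paste0(cond, "_cues.csv")), row.names = FALSE)
      utils::write.csv(as.data.frame(cc$trace$events),
                       file.path(sd, paste0(cond, "_events.csv")), row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' Ground-truth generator parameters are not persisted; the loaded object
#' carries signals, angle traces, cue and event tables only.
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `bw_cohort`-like list (without `truth` entries).
#' @export
read_cohort <- function(dir) {
  subj_dirs <- list.dirs(dir, recursive = FALSE)
  subjects <- lapply(subj_dirs, function(sd) {
    meta <- jsonlite::read_json(file.path(sd, "meta.json"), simplifyVector = TRUE)
    conditions <- list()
    for (cond in meta$conditions) {
      sig <- as.matrix(utils::read.csv(file.path(sd, paste0(cond, "_signals.csv"))))
      angle <- utils::read.csv(file.path(sd, paste0(cond, "_angle.csv")))$angle
      cues <- utils::read.csv(file.path(sd, paste0(cond, "_cues.csv")),
                              stringsAsFactors = FALSE)
      class(cues) <- c("bw_cue_table", "data.frame")
      events <- utils::read.csv(file.path(sd, paste0(cond, "_events.csv")),
                                stringsAsFactors = FALSE)
      class(events) <- c("bw_event_table", "data.frame")
      conditions[[cond]] <- list(cues = cues, signals = sig,
                                 trace = list(angle = angle, events = events,
                                              sample_rate = meta$sample_rate,
                                              cues = cues))
    }
    structure(list(id = meta$id, hand = meta$hand,
                   sample_rate = meta$sample_rate, conditions = conditions),
              class = "bw_subject")
  })
  structure(subjects, class = "bw_cohort")
}
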