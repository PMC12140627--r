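## End-to-end orchestration: simulate (or accept) a cohort, detect events,
## epoch, compute spectra and connectivity, run group statistics, and emit
## a structured report.

#' Pipeline run configuration
#'
#' Nests all stage configurations. Reduced problem sizes (fewer subjects,
#' trials, areas or events) are set here; the defaults describe the full
#' study layout (20 subjects, two 36-trial blocks per condition).
#'
#' @param seed Top-level seed; all stage seeds derive from it.
#' @param n_subjects Cohort size.
#' @param task Named list of [task_config()] per condition.
#' @param kin [kinematics_config()].
#' @param detection [event_detection_config()].
#' @param tfr [tfr_spec()].
#' @param cluster [cluster_test_config()].
#' @param areas Areas analyzed (channels exist for contra and ipsi sides).
#' @param events Movement event types analyzed.
#' @param granger_pair Channel roles for the Granger contrast.
#' @param granger_window,granger_tapers Post-event window (s) and taper
#'   count for the Granger cross-spectra.
#' @param stages Which stages to run.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A `bw_run_config` list.
#' @export
run_config <- function(seed = 1L,
                       n_subjects = 20L,
                       task = list(predictable = task_config("predictable"),
                                   unpredictable = task_config("unpredictable")),
                       kin = kinematics_config(),
                       detection = event_detection_config(),
                       tfr = tfr_spec(),
                       cluster = cluster_test_config(),
                       areas = c("STN", "M1"),
                       events = c("start", "reversal", "stop"),
                       granger_pair = c("M1_contra", "STN_contra"),
                       granger_window = c(0, 2),
                       granger_tapers = 15L,
                       stages = c("simulate", "kinematics", "tfr", "cluster",
                                  "granger", "stats", "validate"),
                       out_dir = NULL) {
  structure(list(seed = seed, n_subjects = n_subjects, task = task, kin = kin,
                 detection = detection, tfr = tfr, cluster = cluster,
                 areas = areas, events = events, granger_pair = granger_pair,
                 granger_window = granger_window, granger_tapers = granger_tapers,
                 stages = stages, out_dir = out_dir),
            class = "bw_run_config")
}

#' Load a run configuration from YAML
#'
#' Scalar fields override the defaults of [run_config()]; nested stage
#' configurations accept the same field names as their constructors.
#'
#' @param path YAML file.
#' @return A `bw_run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in intersect(names(y), c("seed", "n_subjects", "areas", "events",
                                   "stages", "out_dir", "granger_window",
                                   "granger_tapers", "granger_pair")))
    cfg[[nm]] <- y[[nm]]
  if (!is.null(y$task))
    cfg$task <- lapply(stats::setNames(nm = names(y$task)), function(cond)
      do.call(task_config, c(list(condition = cond), y$task[[cond]])))
  if (!is.null(y$kin)) cfg$kin <- do.call(kinematics_config, y$kin)
  if (!is.null(y$detection)) cfg$detection <- do.call(event_detection_config, y$detection)
  if (!is.null(y$cluster)) cfg$cluster <- do.call(cluster_test_config, y$cluster)
  cfg
}

## analysis-side channel name for an area/side given the moving hand
area_channel <- function(area, side, hand) role_to_channel(paste(area, side, sep = "_"), hand)

## per-subject kinematics: speed, detected events, reaction times
analyze_subject_kinematics <- function(subj, detection, smoothing = 0.05) {
  out <- list()
  for (cond in names(subj$conditions)) {
    cc <- subj$conditions[[cond]]
    speed <- angular_speed(cc$trace$angle, subj$sample_rate, smoothing)
    det <- detect_events(speed, cc$cues, detection)
    out[[cond]] <- list(speed = speed, events = det,
                        rt = reaction_times(det, cc$cues))
  }
  out
}

## corrected dB power map for one subject/channel/event (conditions pooled)
subject_power_map <- function(subj, kine, channel, event_type, spec,
                              conditions = names(subj$conditions)) {
  eps <- list()
  for (cond in conditions) {
    ep <- epoch_signals(subj$conditions[[cond]]$signals[, channel, drop = FALSE],
                        kine[[cond]]$events, subj$sample_rate, span = 4,
                        event_type = event_type)
    eps[[cond]] <- ep
  }
  ## concatenate trials across conditions
  dat <- do.call(abind3, lapply(eps, `[[`, "data"))
  ep <- eps[[1]]
  ep$data <- dat
  mtm <- mtm_fourier(ep, spec)
  baseline_correct(power_tfr(mtm, channel = 1L, band = "low"),
                   spec$baseline_window, mode = "db")
}

## bind (time x trial x channel) arrays along trials
abind3 <- function(...) {
  arrs <- list(...)
  nt <- vapply(arrs, function(a) dim(a)[2L], 0L)
  out <- array(NA_real_, c(dim(arrs[[1]])[1L], sum(nt), dim(arrs[[1]])[3L]))
  at <- 0L
  for (a in arrs) {
    out[, at + seq_len(dim(a)[2L]), ] <- a
    at <- at + dim(a)[2L]
  }
  out
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort (stage `simulate`), detects events and computes
#' reaction times (`kinematics`), computes baseline-corrected beta power
#' maps and band modulations per area/side/event/condition (`tfr`), runs
#' group cluster permutation tests against baseline (`cluster`), computes
#' the time-reversed Granger contrast for the configured pair (`granger`),
#' assembles behavioral and band statistics including the lateralization
#' index (`stats`), and compares estimates against the generator's ground
#' truth (`validate`). Artifacts are written to `cfg$out_dir` when set.
#'
#' @param cfg A [run_config()].
#' @param cohort Optional pre-simulated `bw_cohort` (skips `simulate`).
#' @return A `bw_report` list.
#' @export
run_full_analysis <- function(cfg = run_config(), cohort = NULL) {
  stages <- cfg$stages
  report <- list(seed = cfg$seed, n_subjects = cfg$n_subjects,
                 events = cfg$events, areas = cfg$areas)
  stage_guard <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  if (is.null(cohort) && "simulate" %in% stages) {
    cohort <- stage_guard("simulate",
      simulate_cohort(cfg$n_subjects, cfg$task, cfg$kin, seed = cfg$seed))
  }
  if (is.null(cohort)) stopf("no cohort: provide one or include the 'simulate' stage")
  if (!is.null(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (identical(stages, "simulate")) {
    if (!is.null(cfg$out_dir)) write_cohort(cohort, file.path(cfg$out_dir, "cohort"))
    report$cohort <- cohort
    class(report) <- "bw_report"
    return(report)
  }

  conditions <- names(cohort[[1]]$conditions)
  kine <- NULL
  if ("kinematics" %in% stages) {
    kine <- stage_guard("kinematics",
      lapply(cohort, analyze_subject_kinematics, detection = cfg$detection))
    names(kine) <- vapply(cohort, `[[`, "", "id")
    rt_rows <- list()
    for (i in seq_along(cohort)) {
      for (cond in conditions) {
        s <- kine[[i]][[cond]]$rt$summary
        rt_rows[[length(rt_rows) + 1L]] <-
          cbind(subject = cohort[[i]]$id, s, stringsAsFactors = FALSE)
      }
    }
    report$rt <- do.call(rbind, rt_rows)
  }

  maps <- NULL
  if ("tfr" %in% stages) {
    if (is.null(kine)) stopf("stage 'tfr' requires stage 'kinematics'")
    maps <- list()   # [[area_side]][[event]] = list of subject maps
    mods <- list()
    stage_guard("tfr", {
      for (i in seq_along(cohort)) {
        subj <- cohort[[i]]
        for (area in cfg$areas) for (side in c("contra", "ipsi")) {
          ch <- area_channel(area, side, subj$hand)
          if (!(ch %in% colnames(subj$conditions[[1]]$signals))) next
          for (evt in cfg$events) {
            key <- paste(area, side, sep = "_")
            map <- subject_power_map(subj, kine[[i]], ch, evt, cfg$tfr)
            maps[[key]][[evt]] <- c(maps[[key]][[evt]], list(map))
            for (cond in conditions) {
              mc <- subject_power_map(subj, kine[[i]], ch, evt, cfg$tfr, cond)
              bm <- band_modulation(mc, band = c(13, 30))
              mods[[length(mods) + 1L]] <- data.frame(
                subject = subj$id, area = area, side = side, event = evt,
                condition = cond, pre = bm$pre, post = bm$post,
                modulation = bm$modulation, stringsAsFactors = FALSE)
            }
          }
        }
      }
    })
    report$modulations <- do.call(rbind, mods)
  }

  if ("cluster" %in% stages) {
    if (is.null(maps)) stopf("stage 'cluster' requires stage 'tfr'")
    cl_rows <- list()
    cl_results <- list()
    stage_guard("cluster", {
      for (key in names(maps)) for (evt in names(maps[[key]])) {
        ccfg <- cfg$cluster
        ccfg$seed <- derive_seed(cfg$seed, paste0("cluster", key, evt))
        res <- cluster_permutation_test(baseline_contrast_maps(maps[[key]][[evt]]), ccfg)
        cl_results[[paste(key, evt, sep = ".")]] <- res
        cl_rows[[length(cl_rows) + 1L]] <-
          report_clusters(res, event = evt, area = key)
      }
    })
    report$clusters <- do.call(rbind, cl_rows)
    report$cluster_results <- cl_results
  }

  if ("granger" %in% stages) {
    if (is.null(kine)) stopf("stage 'granger' requires stage 'kinematics'")
    g_rows <- list()
    stage_guard("granger", {
      for (i in seq_along(cohort)) {
        subj <- cohort[[i]]
        pair <- vapply(cfg$granger_pair, role_to_channel, "", hand = subj$hand)
        eps <- list()
        for (cond in conditions) {
          eps[[cond]] <- epoch_signals(subj$conditions[[cond]]$signals[, pair],
                                       kine[[i]][[cond]]$events,
                                       subj$sample_rate, span = 4,
                                       event_type = "start")
        }
        ep <- eps[[1]]
        ep$data <- do.call(abind3, lapply(eps, `[[`, "data"))
        gc <- time_reversal_contrast(ep, pair, cfg$granger_window,
                                     n_tapers = cfg$granger_tapers)
        ## role labels pool subjects across hands (physical channels differ)
        gc$role_source <- rep(cfg$granger_pair[c(1, 2)], length.out = nrow(gc))
        gc$role_target <- rep(cfg$granger_pair[c(2, 1)], length.out = nrow(gc))
        g_rows[[length(g_rows) + 1L]] <-
          cbind(subject = subj$id, as.data.frame(gc), stringsAsFactors = FALSE)
      }
    })
    report$granger <- do.call(rbind, g_rows)
  }

  if ("stats" %in% stages) {
    stage_guard("stats", {
      if (!is.null(report$rt)) {
        rt_wide <- stats::aggregate(mean ~ subject + condition + event_type,
                                    data = report$rt, FUN = mean)
        tests <- list()
        for (evt in intersect(c("start", "stop"), unique(rt_wide$event_type))) {
          if (length(conditions) < 2L) break
          a <- rt_wide[rt_wide$event_type == evt & rt_wide$condition == conditions[1], ]
          b <- rt_wide[rt_wide$event_type == evt & rt_wide$condition == conditions[2], ]
          m <- merge(a, b, by = "subject")
          if (nrow(m) >= 2L) {
            pt <- paired_t(m$mean.x, m$mean.y, sided = "less")
            tests[[evt]] <- data.frame(event = evt, t = pt$t, df = pt$df,
                                       p_one_sided = pt$p_one_sided, d = pt$d,
                                       stringsAsFactors = FALSE)
          }
        }
        report$rt_tests <- if (length(tests)) do.call(rbind, tests) else NULL
        if (length(conditions) >= 2L && length(unique(rt_wide$event_type)) >= 2L) {
          rt_wide$value <- rt_wide$mean
          report$rt_anova <- tryCatch(
            rm_anova(rt_wide, dv = "value", subject = "subject",
                     within = c("condition", "event_type")),
            error = function(e) NULL)
        }
      }
      if (!is.null(report$modulations)) {
        md <- report$modulations
        li_rows <- list()
        for (area in unique(md$area)) {
          for (evt in intersect(c("start", "stop"), unique(md$event))) {
            co <- md[md$area == area & md$side == "contra" & md$event == evt, ]
            ip <- md[md$area == area & md$side == "ipsi" & md$event == evt, ]
            agg_co <- stats::aggregate(modulation ~ subject, co, mean)
            agg_ip <- stats::aggregate(modulation ~ subject, ip, mean)
            m <- merge(agg_co, agg_ip, by = "subject")
            if (nrow(m) == 0L) next
            li <- suppressWarnings(lateralization_index(m$modulation.x, m$modulation.y))
            li_rows[[length(li_rows) + 1L]] <- data.frame(
              subject = m$subject, area = area,
              modulation_type = if (evt == "start") "suppression" else "rebound",
              li = li, stringsAsFactors = FALSE)
          }
        }
        report$lateralization <- if (length(li_rows)) do.call(rbind, li_rows) else NULL
        ## predictability x movement ANOVA on contra modulations (area-mean)
        if (length(conditions) >= 2L && length(cfg$events) >= 2L) {
          mm <- md[md$side == "contra", ]
          agg <- stats::aggregate(modulation ~ subject + condition + event, mm, mean)
          agg$value <- agg$modulation
          report$modulation_anova <- tryCatch(
            rm_anova(agg, dv = "value", subject = "subject",
                     within = c("condition", "event")),
            error = function(e) NULL)
        }
      }
      if (!is.null(report$granger)) {
        g <- report$granger
        dir_key <- paste(g$role_source, "->", g$role_target)
        tests <- list()
        for (band in unique(g$band)) for (dk in unique(dir_key)) {
          sel <- g$band == band & dir_key == dk
          deltas <- g$delta[sel]
          if (length(deltas) >= 2L && stats::sd(deltas) > 0) {
            pt <- paired_t(deltas, rep(0, length(deltas)), sided = "greater")
            tests[[length(tests) + 1L]] <- data.frame(
              band = band, direction = dk, mean_delta = mean(deltas),
              t = pt$t, p_one_sided = pt$p_one_sided, stringsAsFactors = FALSE)
          }
        }
        report$granger_tests <- if (length(tests)) do.call(rbind, tests) else NULL
      }
    })
  }

  if ("validate" %in% stages && !is.null(cohort[[1]]$conditions[[1]]$truth)) {
    report$recovery <- stage_guard("validate",
      validate_against_truth(report, cohort, kine))
  }

  if (!is.null(cfg$out_dir)) {
    for (nm in c("rt", "modulations", "clusters", "granger", "lateralization",
                 "recovery")) {
      if (!is.null(report[[nm]]))
        utils::write.csv(report[[nm]],
                         file.path(cfg$out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
    }
    summary_bits <- report[setdiff(names(report),
                                   c("cluster_results", "cohort"))]
    jsonlite::write_json(summary_bits, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, dataframe = "rows",
                         pretty = TRUE)
  }
  class(report) <- "bw_report"
  report
}

#' Compare pipeline estimates against generator ground truth
#'
#' @param report A `bw_report` (with kinematics/tfr/granger outputs).
#' @param cohort The synthetic `bw_cohort` the report was computed from.
#' @param kine Per-subject kinematics results (detected events); recomputed
#'   if missing.
#' @return data.frame: quantity, truth, estimate, error.
#' @export
validate_against_truth <- function(report, cohort, kine = NULL) {
  if (is.null(cohort[[1]]$conditions[[1]]$truth))
    stopf("cohort carries no ground truth")
  if (is.null(kine))
    kine <- lapply(cohort, analyze_subject_kinematics,
                   detection = event_detection_config())
  rows <- list()
  add <- function(quantity, truth, estimate)
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, truth = truth, estimate = estimate,
      error = estimate - truth, stringsAsFactors = FALSE)

  ## event detection: sensitivity and absolute timing error vs ground truth
  n_truth <- 0L; n_match <- 0L; terr <- numeric(0)
  for (i in seq_along(cohort)) {
    for (cond in names(cohort[[i]]$conditions)) {
      gt <- cohort[[i]]$conditions[[cond]]$trace$events
      det <- kine[[i]][[cond]]$events
      n_truth <- n_truth + nrow(gt)
      m <- merge(gt[c("linked_cue_index", "time")],
                 det[c("linked_cue_index", "time")], by = "linked_cue_index")
      n_match <- n_match + nrow(m)
      terr <- c(terr, abs(m$time.y - m$time.x))
    }
  }
  add("event_detection_sensitivity", 1, n_match / n_truth)
  add("event_timing_error_ms", 0, 1000 * mean(terr))

  ## reaction-time recovery per condition x event
  kin_cfg <- cohort[[1]]$kin
  if (!is.null(report$rt) && !is.null(kin_cfg)) {
    for (cond in unique(report$rt$condition)) for (evt in unique(report$rt$event_type)) {
      sel <- report$rt$condition == cond & report$rt$event_type == evt
      if (!any(sel)) next
      est <- mean(report$rt$mean[sel])
      ## ground-truth events for reversal/stop lie at the zero-crossing /
      ## final zero, i.e. ramp time (plus half the reversal dwell) after
      ## the sampled response onset
      offset <- switch(evt, start = 0,
                       reversal = kin_cfg$ramp_time + kin_cfg$reversal_pause / 2,
                       stop = kin_cfg$ramp_time)
      tr <- rt_params(kin_cfg$rt_table, cond, evt)$mean + offset
      add(paste("rt_mean", cond, evt, sep = "_"), tr, est)
    }
  }

  ## band-modulation recovery vs implied analytic truth (contra side)
  if (!is.null(report$modulations)) {
    md <- report$modulations
    truth0 <- cohort[[1]]$conditions[[1]]$truth
    for (area in unique(md$area)) for (evt in unique(md$event)) {
      for (cond in unique(md$condition)) {
        sel <- md$area == area & md$side == "contra" & md$event == evt &
          md$condition == cond
        if (!any(sel)) next
        est <- mean(md$modulation[sel])
        subj1 <- cohort[[1]]
        ch <- area_channel(area, "contra", subj1$hand)
        tr <- implied_band_modulation(subj1$conditions[[cond]]$truth, ch,
                                      evt, cond)
        add(paste("beta_mod_db", area, evt, cond, sep = "_"), tr, est)
      }
    }
  }

  ## Granger direction: fraction of subjects with the configured
  ## cortex->STN direction recovered (positive delta for source->target)
  if (!is.null(report$granger)) {
    g <- report$granger[report$granger$band == "beta", ]
    fwd <- g[seq(1, nrow(g), by = 2), ]  # odd rows = configured source->target
    add("granger_direction_recovery", 1, mean(fwd$delta > 0))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
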