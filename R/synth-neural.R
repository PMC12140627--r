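## Coupled oscillatory signal generation. Each channel is a 1/f^alpha
## background plus band-limited stochastic oscillations (white-noise-driven
## damped resonators, AR(2)) whose amplitude envelopes follow event-locked
## gains. Directed coupling adds a lagged, scaled copy of a source channel's
## band-limited component to a target channel, so influence is strictly
## causal source -> target.

## ---- primitives -----------------------------------------------------------

ar2_coefficients <- function(center, bandwidth, fs) {
  r <- 1 - pi * bandwidth / fs
  if (r <= 0 || r >= 1) stopf("AR(2) pole radius out of (0,1); check bandwidth/sample rate")
  theta <- 2 * pi * center / fs
  list(a1 = 2 * r * cos(theta), a2 = -r^2, r = r, theta = theta)
}

ar2_variance <- function(a1, a2, sigma2 = 1) {
  sigma2 * (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
}

## Unnormalized AR(2) spectral shape |1/A(e^{-iw})|^2
ar2_shape <- function(f, a1, a2, fs) {
  z <- exp(-2i * pi * f / fs)
  1 / Mod(1 - a1 * z - a2 * z^2)^2
}

#' Band-limited stochastic oscillation (damped resonator)
#'
#' White-noise-driven AR(2) process with poles at `center` Hz and an
#' approximate -3 dB bandwidth `bandwidth` Hz, scaled to the requested
#' stationary variance.
#'
#' @param n Number of samples.
#' @param center,bandwidth Resonance center and bandwidth, Hz.
#' @param power Stationary variance of the series.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of length `n`.
#' @export
ar2_series <- function(n, center, bandwidth, power, fs) {
  cf <- ar2_coefficients(center, bandwidth, fs)
  sigma2 <- power / ar2_variance(cf$a1, cf$a2, 1)
  burn <- min(2000L, n)
  eps <- stats::rnorm(n + burn, sd = sqrt(sigma2))
  x <- stats::filter(eps, c(cf$a1, cf$a2), method = "recursive")
  as.numeric(x)[(burn + 1L):(burn + n)]
}

#' 1/f^alpha background noise
#'
#' Spectral-synthesis pink-ish noise with power spectral density
#' proportional to `max(f, 1)^-alpha` (flattened below 1 Hz so the process
#' has no drift), normalized to the requested total variance.
#'
#' @param n Number of samples.
#' @param exponent Spectral slope alpha.
#' @param power Total variance.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, exponent = 1, power = 1, fs = 500) {
  nfft <- n
  f <- seq(0, fs, length.out = nfft + 1L)[1:nfft]
  f[f > fs / 2] <- fs - f[f > fs / 2]  # fold to physical frequency
  scale <- pmax(f, 1)^(-exponent / 2)
  scale[1] <- 0
  w <- stats::rnorm(nfft)
  x <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / nfft
  x <- x - mean(x)
  x * sqrt(power) / stats::sd(x)
}

pink_shape <- function(f, exponent) pmax(f, 1)^(-exponent)

## Normalize an unnormalized PSD shape on a grid to integrate to `power`.
normalize_psd <- function(shape_vals, f_grid, power) {
  shape_vals * power / sum(shape_vals * c(diff(f_grid)[1]))
}

## ---- specifications -------------------------------------------------------

#' Oscillation specification for one channel role
#'
#' @param role Channel role, e.g. `"STN_contra"`, `"M1_ipsi"`; the generator
#'   resolves contra/ipsi to a physical hemisphere from the subject's moving
#'   hand.
#' @param band Band label, `"beta"` or `"gamma"`.
#' @param center,bandwidth Resonator center frequency and bandwidth, Hz.
#' @param power Baseline stationary variance of the oscillation.
#' @param envelope Named list keyed by event type (`start`, `reverse`,
#'   `stop`); each entry a list with `gain_db` (scalar, or named by
#'   condition), `onset` and `duration` in seconds relative to the
#'   ground-truth movement event. Gains are power ratios in dB applied to
#'   the oscillation's variance over the window (0.1 s cosine edges).
#' @return A `bw_osc_spec` list.
#' @export
oscillation_spec <- function(role, band = c("beta", "gamma"),
                             center = if (match.arg(band) == "beta") 20 else 70,
                             bandwidth = if (match.arg(band) == "beta") 3 else 10,
                             power = 1,
                             envelope = list()) {
  band <- match.arg(band)
  assert_scalar_pos(center, "center"); assert_scalar_pos(power, "power")
  for (ev in envelope) {
    if (is.null(ev$gain_db) || is.null(ev$onset) || is.null(ev$duration))
      stopf("each envelope entry needs gain_db, onset, duration")
    if (ev$duration <= 0) stopf("envelope durations must be > 0")
  }
  structure(list(role = role, band = band, center = center,
                 bandwidth = bandwidth, power = power, envelope = envelope),
            class = "bw_osc_spec")
}

#' Directed coupling specification
#'
#' @param source_role,target_role Channel roles (contra/ipsi terms).
#' @param band Which band-limited component of the source is transmitted.
#' @param lag Transmission lag in samples (>= 1, strictly causal).
#' @param strength Mixing coefficient applied to the source component.
#' @param event_modulation Named list keyed by event type; each entry a list
#'   with `gain` (amplitude factor on `strength`, scalar or named by
#'   condition), `onset`, `duration` (s).
#' @return A `bw_coupling_spec` list.
#' @export
coupling_spec <- function(source_role, target_role, band = "beta",
                          lag = 10L, strength = 0.65,
                          event_modulation = list()) {
  if (lag < 1L) stopf("`lag` must be >= 1 sample (strictly causal)")
  if (strength < 0) stopf("`strength` must be >= 0")
  structure(list(source_role = source_role, target_role = target_role,
                 band = band, lag = as.integer(lag), strength = strength,
                 event_modulation = event_modulation),
            class = "bw_coupling_spec")
}

#' Default oscillation specifications emulating event-locked beta/gamma
#' phenomenology
#'
#' Beta (20 Hz) on bilateral STN, M1, and MSMC with movement-start
#' suppression (stronger contralaterally and in the predictable condition),
#' a post-stop rebound (contra +2.5 dB vs ipsi +1.0 dB), and brief
#' reversal-related modulations (cortical decrease, subthalamic increase);
#' gamma (70 Hz) on the contralateral STN with a brief increase at movement
#' start. The numeric depths are free generator parameters with known
#' ground truth, not empirical values.
#'
#' @param areas Character vector of area names.
#' @return List of [oscillation_spec()] objects.
#' @export
default_oscillation_specs <- function(areas = c("STN", "M1", "MSMC")) {
  specs <- list()
  for (a in areas) {
    for (side in c("contra", "ipsi")) {
      contra <- side == "contra"
      start_gain <- if (contra) c(predictable = -3, unpredictable = -2.4)
                    else c(predictable = -1.5, unpredictable = -1.2)
      stop_gain <- if (contra) 2.5 else 1.0
      rev_gain <- if (a == "STN") 1.0 else -1.0
      specs[[paste(a, side, sep = "_")]] <- oscillation_spec(
        role = paste(a, side, sep = "_"), band = "beta",
        envelope = list(
          start = list(gain_db = start_gain, onset = 0, duration = 1.6),
          stop = list(gain_db = stop_gain, onset = 0, duration = 1.6),
          reverse = list(gain_db = rev_gain, onset = 0, duration = 0.8)
        )
      )
    }
  }
  if ("STN" %in% areas) {
    specs[["STN_contra_gamma"]] <- oscillation_spec(
      role = "STN_contra", band = "gamma", power = 0.5,
      envelope = list(start = list(gain_db = 2, onset = 0, duration = 0.8))
    )
  }
  specs
}

#' Default coupling: cortical beta drives the subthalamic nucleus
#'
#' M1 -> STN beta coupling in each hemisphere, with the post-stop coupling
#' gain raised in the unpredictable condition (coherence increases after
#' stops are stronger when cues are unpredictable).
#'
#' @return List of [coupling_spec()] objects.
#' @export
default_coupling_specs <- function() {
  list(
    coupling_spec("M1_contra", "STN_contra", band = "beta", lag = 10L, strength = 0.65,
                  event_modulation = list(
                    stop = list(gain = c(predictable = 1.0, unpredictable = 1.3),
                                onset = 0, duration = 1.6))),
    coupling_spec("M1_ipsi", "STN_ipsi", band = "beta", lag = 10L, strength = 0.65,
                  event_modulation = list(
                    stop = list(gain = c(predictable = 1.0, unpredictable = 1.3),
                                onset = 0, duration = 1.6)))
  )
}

## Resolve contra/ipsi role to a physical channel name given the moving hand.
#' @export
#' @rdname generate_neural_data
role_to_channel <- function(role, hand) {
  if (!grepl("_(contra|ipsi)$", role)) return(role)
  area <- sub("_(contra|ipsi)$", "", role)
  side <- sub("^.*_", "", role)
  hemi <- if (hand == "R") { if (side == "contra") "L" else "R" }
          else { if (side == "contra") "R" else "L" }
  paste(area, hemi, sep = "_")
}

pick_gain <- function(gain, condition) {
  if (length(gain) == 1L && is.null(names(gain))) return(unname(gain))
  if (!is.null(names(gain))) {
    if (condition %in% names(gain)) return(unname(gain[[condition]]))
    stopf("no gain entry for condition '%s'", condition)
  }
  unname(gain)
}

## Amplitude envelope from event-locked power gains. `events` must carry
## absolute `time` and `condition`; event types in the envelope list use cue
## nomenclature (start/reverse/stop), events use movement nomenclature.
event_name_map <- c(start = "start", reverse = "reversal", stop = "stop")

build_envelope <- function(n, fs, events, envelope, edge = 0.1, square = FALSE) {
  env <- rep(1, n)
  if (length(envelope) == 0L) return(env)
  edge_n <- max(1L, as.integer(round(edge * fs)))
  for (ev_key in names(envelope)) {
    spec <- envelope[[ev_key]]
    ev_type <- event_name_map[[ev_key]]
    rows <- events[events$event_type == ev_type, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      g <- pick_gain(if (!is.null(spec$gain_db)) inv_db(spec$gain_db) else spec$gain,
                     rows$condition[k])
      amp <- if (square) g else sqrt(g)
      t0 <- rows$time[k] + spec$onset
      i0 <- as.integer(round(t0 * fs)) + 1L
      i1 <- i0 + as.integer(round(spec$duration * fs)) - 1L
      if (i1 < 1L || i0 > n) next
      seg_lo <- max(i0, 1L); seg_hi <- min(i1, n)
      prof <- rep(amp, i1 - i0 + 1L)
      ne <- min(edge_n, floor(length(prof) / 2))
      if (ne > 1L) {
        up <- 1 + (amp - 1) * cosine_ramp(ne)
        prof[1:ne] <- up
        prof[(length(prof) - ne + 1L):length(prof)] <- rev(up)
      }
      env[seg_lo:seg_hi] <- env[seg_lo:seg_hi] * prof[(seg_lo - i0 + 1L):(seg_hi - i0 + 1L)]
    }
  }
  env
}

## ---- generation -----------------------------------------------------------

#' Generate coupled multi-channel neural signals for one recording
#'
#' @param trace A `bw_wheel_trace` (supplies duration, sample rate, and the
#'   ground-truth events that drive the envelopes).
#' @param osc_specs List of [oscillation_spec()]; channel roles with no spec
#'   get background noise only.
#' @param coupling_specs List of [coupling_spec()].
#' @param hand Moving hand, `"L"` or `"R"`; resolves contra/ipsi roles.
#' @param noise_exponent,noise_power Background 1/f^alpha slope and total
#'   variance (shared by all channels).
#' @param seed Integer seed or `NULL`.
#' @return List with `signals` (samples x channels matrix, physical channel
#'   names), `truth` (resolved per-channel component parameters, couplings,
#'   hand, noise).
#' @export
generate_neural_data <- function(trace, osc_specs = default_oscillation_specs(),
                                 coupling_specs = default_coupling_specs(),
                                 hand = "R", noise_exponent = 1,
                                 noise_power = 0.25, seed = NULL) {
  fs <- trace$sample_rate
  n <- length(trace$angle)
  events <- trace$events
  channels <- unique(vapply(osc_specs, function(s) role_to_channel(s$role, hand), ""))
  for (cs in coupling_specs) {
    src <- role_to_channel(cs$source_role, hand)
    tgt <- role_to_channel(cs$target_role, hand)
    if (!(src %in% channels) || !(tgt %in% channels))
      stopf("coupling references channel role without an oscillation spec: %s -> %s",
            cs$source_role, cs$target_role)
  }
  with_seed_or_not(seed, {
    sig <- matrix(0, n, length(channels), dimnames = list(NULL, channels))
    components <- list()  # [[channel]][[band]] = modulated oscillation series
    truth_channels <- list()
    for (ch in channels) {
      bg <- pink_noise(n, noise_exponent, noise_power, fs)
      sig[, ch] <- bg
      truth_channels[[ch]] <- list(oscillations = list())
      for (sp in osc_specs) {
        if (role_to_channel(sp$role, hand) != ch) next
        x <- ar2_series(n, sp$center, sp$bandwidth, sp$power, fs)
        env <- build_envelope(n, fs, events, sp$envelope)
        comp <- x * env
        if (is.null(components[[ch]])) components[[ch]] <- list()
        components[[ch]][[sp$band]] <- comp
        sig[, ch] <- sig[, ch] + comp
        truth_channels[[ch]]$oscillations[[sp$band]] <- sp
      }
    }
    resolved_couplings <- list()
    for (cs in coupling_specs) {
      src <- role_to_channel(cs$source_role, hand)
      tgt <- role_to_channel(cs$target_role, hand)
      comp <- components[[src]][[cs$band]]
      if (is.null(comp)) stopf("source channel %s has no %s component", src, cs$band)
      lagged <- c(rep(0, cs$lag), comp[1:(n - cs$lag)])
      gain_env <- build_envelope(n, fs, events,
                                 lapply(cs$event_modulation, function(e)
                                   list(gain = e$gain, onset = e$onset, duration = e$duration)),
                                 square = TRUE)
      sig[, tgt] <- sig[, tgt] + cs$strength * gain_env * lagged
      resolved_couplings[[length(resolved_couplings) + 1L]] <-
        c(cs, list(source_channel = src, target_channel = tgt))
    }
    list(signals = sig,
         truth = list(channels = truth_channels, couplings = resolved_couplings,
                      hand = hand, noise_exponent = noise_exponent,
                      noise_power = noise_power, sample_rate = fs))
  })
}

## ---- implied (analytic) ground truth --------------------------------------

## Per-Hz PSDs of a channel's components on a frequency grid, normalized so
## each integrates to its component's total power.
channel_psd <- function(truth, channel, f_grid) {
  out <- list(background = normalize_psd(pink_shape(f_grid, truth$noise_exponent),
                                         f_grid, truth$noise_power))
  for (band in names(truth$channels[[channel]]$oscillations)) {
    sp <- truth$channels[[channel]]$oscillations[[band]]
    cf <- ar2_coefficients(sp$center, sp$bandwidth, truth$sample_rate)
    out[[band]] <- normalize_psd(ar2_shape(f_grid, cf$a1, cf$a2, truth$sample_rate),
                                 f_grid, sp$power)
  }
  out
}

band_power_from_psd <- function(psd, f_grid, band) {
  df <- diff(f_grid)[1]
  sum(psd[f_grid >= band[1] & f_grid <= band[2]]) * df
}

## Power-gain time profile (envelope squared) for one envelope entry on a
## time grid relative to the event.
power_gain_profile <- function(env_entry, condition, t_grid, fs) {
  if (is.null(env_entry)) return(rep(1, length(t_grid)))
  span <- c(min(t_grid) - 1, max(t_grid) + 1)
  n <- as.integer(round((span[2] - span[1]) * fs))
  ev <- data.frame(event_type = "start", time = -span[1], condition = condition,
                   stringsAsFactors = FALSE)
  env <- build_envelope(n, fs, ev, list(start = env_entry))
  tt <- (seq_len(n) - 1) / fs + span[1]
  env[vapply(t_grid, function(t0) which.min(abs(tt - t0)), 0L)]^2
}

#' Implied (analytic) band-power modulation of the generator
#'
#' The post-minus-pre beta modulation in dB that the multitaper estimator
#' is expected to report for a generator configuration. Emulates the
#' estimator: per-frequency power (oscillation + 1/f background + coupled
#' in-band contributions) smoothed over the multitaper frequency
#' half-bandwidth, the event-locked power gain smeared by the sliding
#' window's taper energy profile, dB taken per time-frequency bin against
#' the per-frequency baseline mean, then averaged over band and window.
#'
#' @param truth `truth` list from [generate_neural_data()].
#' @param channel Physical channel name.
#' @param event_type `"start"`, `"reversal"`, or `"stop"`.
#' @param condition Condition label used by per-condition gains.
#' @param band Frequency band, Hz (length 2).
#' @param pre_window,post_window Analysis windows, s relative to the event.
#' @param window,n_tapers Sliding-window length (s) and taper count of the
#'   estimator being emulated.
#' @param step TFR step size, s.
#' @return Implied modulation, dB.
#' @export
implied_band_modulation <- function(truth, channel, event_type, condition,
                                    band = c(13, 30),
                                    pre_window = c(-1.6, 0),
                                    post_window = c(0, 1.6),
                                    window = 0.8, n_tapers = 4L,
                                    step = 0.05) {
  fs <- truth$sample_rate
  df <- 0.25
  f_grid <- seq(df, fs / 2, by = df)
  psd <- channel_psd(truth, channel, f_grid)
  cue_key <- names(event_name_map)[match(event_type, event_name_map)]

  ## frequency smoothing over the multitaper half-bandwidth
  w_hz <- (n_tapers + 1) / (2 * window)
  smooth_f <- function(p) moving_average(p, max(1L, round(2 * w_hz / df)))
  fsel <- f_grid >= band[1] & f_grid <= band[2]

  ## temporal smearing kernel: mean taper energy profile of the window
  win_n <- as.integer(round(window * fs))
  tap <- slepian_tapers(win_n, n_tapers)
  kern <- rowMeans(tap^2)
  kern <- kern / sum(kern)

  t_centers <- seq(min(pre_window[1], post_window[1]),
                   max(pre_window[2], post_window[2]), by = step)
  tfine <- seq(min(t_centers) - window, max(t_centers) + window, by = 1 / fs)
  smear <- function(gain_profile) {
    sm <- stats::filter(gain_profile, rev(kern), sides = 2)
    sm[is.na(sm)] <- gain_profile[is.na(sm)]
    as.numeric(sm)[vapply(t_centers, function(t0) which.min(abs(tfine - t0)), 0L)]
  }

  ## accumulate smeared per-frequency power over components
  nb <- sum(fsel); nt <- length(t_centers)
  P <- matrix(0, nb, nt)
  P <- P + smooth_f(psd$background)[fsel] %o% rep(1, nt)
  for (bn in setdiff(names(psd), "background")) {
    sp <- truth$channels[[channel]]$oscillations[[bn]]
    gain <- smear(power_gain_profile(sp$envelope[[cue_key]], condition, tfine, fs))
    P <- P + smooth_f(psd[[bn]])[fsel] %o% gain
  }
  for (cs in truth$couplings) {
    if (cs$target_channel != channel) next
    src_sp <- truth$channels[[cs$source_channel]]$oscillations[[cs$band]]
    src_psd <- channel_psd(truth, cs$source_channel, f_grid)[[cs$band]]
    src_gain <- power_gain_profile(src_sp$envelope[[cue_key]], condition, tfine, fs)
    cpl_entry <- cs$event_modulation[[cue_key]]
    cpl_gain <- if (is.null(cpl_entry)) rep(1, length(tfine)) else
      power_gain_profile(list(gain_db = NULL,
                              gain = pick_gain(cpl_entry$gain, condition)^2,
                              onset = cpl_entry$onset,
                              duration = cpl_entry$duration),
                         condition, tfine, fs)
    gain <- smear(src_gain * cpl_gain)
    P <- P + cs$strength^2 * smooth_f(src_psd)[fsel] %o% gain
  }

  in_win <- function(w) t_centers >= w[1] - 1e-9 & t_centers < w[2] - 1e-9
  base <- rowMeans(P[, in_win(pre_window), drop = FALSE])
  dbmap <- 10 * log10(sweep(P, 1L, base, `/`))
  mean(dbmap[, in_win(post_window)]) - mean(dbmap[, in_win(pre_window)])
}

#' Implied baseline coherence between a coupled channel pair
#'
#' The magnitude coherence at frequency `f` that the multitaper estimator
#' is expected to report for the shared-signal model target = own +
#' strength * lagged(source band component), away from any event
#' modulation. Auto- and cross-spectra (the latter carrying the lag's
#' phase rotation) are smoothed over the estimator's spectral
#' half-bandwidth before forming the ratio.
#'
#' @inheritParams implied_band_modulation
#' @param source_channel,target_channel Physical channel names.
#' @param f Frequency, Hz.
#' @param window,n_tapers Window length (s) and taper count of the
#'   estimator being emulated.
#' @return Coherence magnitude in [0, 1].
#' @export
implied_coherence <- function(truth, source_channel, target_channel, f,
                              window = 0.8, n_tapers = 4L) {
  fs <- truth$sample_rate
  df <- 0.25
  f_grid <- seq(df, fs / 2, by = df)
  i <- which.min(abs(f_grid - f))
  src_psd <- channel_psd(truth, source_channel, f_grid)
  tgt_psd <- channel_psd(truth, target_channel, f_grid)
  cpl <- NULL
  for (cs in truth$couplings)
    if (cs$source_channel == source_channel && cs$target_channel == target_channel) cpl <- cs
  if (is.null(cpl)) return(0)
  s_band <- src_psd[[cpl$band]]
  s_xy <- cpl$strength * s_band * exp(-2i * pi * f_grid * cpl$lag / fs)
  s_xx <- Reduce(`+`, src_psd)
  s_yy <- Reduce(`+`, tgt_psd) + cpl$strength^2 * s_band
  w_hz <- (n_tapers + 1) / (2 * window)
  nk <- max(1L, round(2 * w_hz / df))
  sm <- function(x) {
    re <- moving_average(Re(x), nk)
    if (is.complex(x)) complex(real = re, imaginary = moving_average(Im(x), nk)) else re
  }
  Mod(sm(s_xy)[i]) / sqrt(sm(s_xx)[i] * sm(s_yy)[i])
}
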