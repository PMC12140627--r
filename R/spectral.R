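## Multitaper time-frequency analysis: Slepian tapers, sliding-window
## tapered Fourier transforms, power and across-trial coherence maps,
## baseline correction, and band-window modulation summaries.

.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed as eigenvectors of the symmetric tridiagonal matrix of the
#' spheroidal eigenvalue problem, unit-energy and mutually orthogonal.
#' The time-bandwidth product is set from the taper count by
#' NW = (K + 1) / 2, i.e. the half-bandwidth in Hz is (K + 1) / (2 T) for a
#' window of T seconds.
#'
#' @param window_samples Window length N in samples.
#' @param n_tapers Number of tapers K (>= 1, < N).
#' @return N x K matrix, attributes `nw` and `half_bandwidth` (cycles per
#'   sample).
#' @export
slepian_tapers <- function(window_samples, n_tapers) {
  if (n_tapers <= 0) stopf("`n_tapers` must be positive")
  n <- as.integer(window_samples)
  k <- as.integer(n_tapers)
  if (k >= n) stopf("`n_tapers` must be smaller than `window_samples`")
  key <- paste(n, k, sep = "_")
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  w <- (k + 1) / (2 * n)  # half-bandwidth, cycles/sample
  i <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  M <- diag(diag_main)
  M[cbind(1:(n - 1), 2:n)] <- off
  M[cbind(2:n, 1:(n - 1))] <- off
  eg <- eigen(M, symmetric = TRUE)
  tap <- eg$vectors[, seq_len(k), drop = FALSE]
  ## deterministic sign: first element of appreciable magnitude positive
  for (j in seq_len(k)) {
    v <- tap[, j]
    ref <- which(abs(v) > max(abs(v)) / 2)[1]
    if (v[ref] < 0) tap[, j] <- -v
  }
  attr(tap, "nw") <- (k + 1) / 2
  attr(tap, "half_bandwidth") <- w
  .taper_cache[[key]] <- tap
  tap
}

#' Time-frequency analysis specification
#'
#' Defaults: 0.8 s windows stepped by 50 ms over -1.6..1.6 s, a low band
#' 5-45 Hz with 4 tapers and a high band 55-90 Hz with 7 tapers (skipping
#' line noise at 50 Hz), Rayleigh-spaced frequency grid (1/window = 1.25
#' Hz), and a pre-event baseline window -1.6..0 s.
#'
#' @param bands Named list of frequency ranges (Hz).
#' @param n_tapers Named integer vector matching `bands`.
#' @param window Sliding window length, s.
#' @param step Window step, s.
#' @param analysis_span Time range of window centers, s relative to event.
#' @param baseline_window Baseline time range, s.
#' @return A `bw_tfr_spec` list.
#' @export
tfr_spec <- function(bands = list(low = c(5, 45), high = c(55, 90)),
                     n_tapers = c(low = 4L, high = 7L),
                     window = 0.8, step = 0.05,
                     analysis_span = c(-1.6, 1.6),
                     baseline_window = c(-1.6, 0)) {
  assert_scalar_pos(window, "window")
  if (step > window) stopf("`step` must be <= `window`")
  if (!all(names(bands) %in% names(n_tapers)))
    stopf("`n_tapers` must be named like `bands`")
  structure(list(bands = bands, n_tapers = n_tapers, window = window,
                 step = step, analysis_span = analysis_span,
                 baseline_window = baseline_window),
            class = "bw_tfr_spec")
}

#' Sliding-window multitaper Fourier coefficients
#'
#' Tapered Fourier transforms on a regular time/frequency grid; each band
#' uses its own taper count. Frequencies are the DFT bins of the window
#' (multiples of 1/window) within the band; window positions whose samples
#' fall outside the epoch are not computed (no padding). Each window is
#' demeaned before tapering.
#'
#' @param epochs A `bw_epoch_set`.
#' @param spec A [tfr_spec()].
#' @return A `bw_mtm` list: per band, a complex array with dimensions
#'   (freq, time, taper, trial, channel) plus axis vectors.
#' @export
mtm_fourier <- function(epochs, spec = tfr_spec()) {
  fs <- epochs$sample_rate
  win_n <- as.integer(round(spec$window * fs))
  half_w <- win_n %/% 2L
  tt <- epochs$time
  centers <- seq(spec$analysis_span[1], spec$analysis_span[2] + 1e-9, by = spec$step)
  need <- c(min(centers) - spec$window / 2, max(centers) + spec$window / 2)
  if (need[1] < min(tt) - 1e-9 || need[2] > max(tt) + 1 / fs + 1e-9)
    stopf("epoch too short for the analysis span: need %.2f..%.2f s", need[1], need[2])
  center_idx <- vapply(centers, function(ct) which.min(abs(tt - ct)), 0L)
  lo <- center_idx - half_w
  hi <- lo + win_n - 1L
  keep <- lo >= 1L & hi <= length(tt)
  centers <- centers[keep]; lo <- lo[keep]
  n_time <- length(centers)
  if (n_time == 0L) stopf("no window fits inside the epoch")
  idx_mat <- outer(seq_len(win_n) - 1L, lo, `+`)  # win_n x n_time

  freqs_all <- (0:(win_n %/% 2L)) * fs / win_n
  ntr <- dim(epochs$data)[2L]
  nch <- dim(epochs$data)[3L]
  out <- list()
  for (bn in names(spec$bands)) {
    band <- spec$bands[[bn]]
    fsel <- which(freqs_all >= band[1] - 1e-9 & freqs_all <= band[2] + 1e-9)
    if (length(fsel) == 0L) stopf("band '%s' contains no frequency bins", bn)
    k <- spec$n_tapers[[bn]]
    tap <- slepian_tapers(win_n, k)
    coeff <- array(complex(real = 0), c(length(fsel), n_time, k, ntr, nch))
    for (ch in seq_len(nch)) {
      for (tr in seq_len(ntr)) {
        xw <- matrix(epochs$data[, tr, ch][idx_mat], win_n, n_time)
        xw <- sweep(xw, 2L, colMeans(xw))
        for (j in seq_len(k)) {
          ft <- stats::mvfft(xw * tap[, j])
          coeff[, , j, tr, ch] <- ft[fsel, , drop = FALSE]
        }
      }
    }
    out[[bn]] <- list(coeff = coeff, freqs = freqs_all[fsel], times = centers,
                      n_tapers = k)
  }
  structure(list(bands = out, channels = epochs$channels,
                 sample_rate = fs, window = spec$window,
                 info = epochs$info),
            class = "bw_mtm")
}

new_tfr_map <- function(values, freqs, times, kind, baseline_state = "raw",
                        band = NULL) {
  structure(list(values = values, freqs = freqs, times = times, kind = kind,
                 baseline_state = baseline_state, band = band),
            class = "bw_tfr_map")
}

#' Time-frequency power from multitaper coefficients
#'
#' Squared coefficient magnitudes averaged over tapers, and over trials
#' unless `average_trials = FALSE`.
#'
#' @param mtm A [mtm_fourier()] result.
#' @param channel Channel name or index.
#' @param band Band name (`NULL` = all bands, row-bound over frequency).
#' @param average_trials Average over trials?
#' @return A `bw_tfr_map` (`kind = "power"`), values (freq x time) or
#'   (trial x freq x time).
#' @export
power_tfr <- function(mtm, channel = 1L, band = NULL, average_trials = TRUE) {
  bands <- if (is.null(band)) names(mtm$bands) else band
  ch <- if (is.character(channel)) match(channel, mtm$channels) else channel
  if (is.na(ch)) stopf("unknown channel")
  vals <- list(); freqs <- numeric()
  for (bn in bands) {
    b <- mtm$bands[[bn]]
    d <- dim(b$coeff)
    p <- Mod(b$coeff[, , , , ch, drop = FALSE])^2
    if (average_trials) {
      dim(p) <- c(d[1] * d[2], d[3] * d[4])
      vals[[bn]] <- matrix(rowMeans(p), d[1], d[2])
    } else {
      p <- apply(p, c(1, 2, 4), mean)  # average tapers
      vals[[bn]] <- aperm(p, c(3, 1, 2))
    }
    freqs <- c(freqs, b$freqs)
  }
  v <- if (average_trials) do.call(rbind, vals) else {
    ar <- array(NA_real_, c(dim(vals[[1]])[1], length(freqs), length(mtm$bands[[bands[1]]]$times)))
    at <- 0L
    for (bn in bands) {
      nf <- dim(vals[[bn]])[2]
      ar[, at + seq_len(nf), ] <- vals[[bn]]
      at <- at + nf
    }
    ar
  }
  new_tfr_map(v, freqs, mtm$bands[[bands[1]]]$times, "power")
}

#' Across-trial multitaper coherence between two channels
#'
#' Magnitude coherence per time-frequency bin, pooling trials and tapers as
#' observations: |sum X conj(Y)| / sqrt(sum |X|^2 sum |Y|^2).
#'
#' @param mtm A [mtm_fourier()] result.
#' @param pair Length-2 channel names or indices.
#' @param band Band name (`NULL` = all).
#' @return A `bw_tfr_map` (`kind = "coherence"`), values freq x time in
#'   [0, 1].
#' @export
coherence_tfr <- function(mtm, pair, band = NULL) {
  bands <- if (is.null(band)) names(mtm$bands) else band
  ij <- if (is.character(pair)) match(pair, mtm$channels) else pair
  if (anyNA(ij) || length(ij) != 2L) stopf("`pair` must name two channels")
  vals <- list(); freqs <- numeric()
  for (bn in bands) {
    b <- mtm$bands[[bn]]
    n_obs <- dim(b$coeff)[3L] * dim(b$coeff)[4L]
    if (n_obs < 2L) stopf("coherence needs at least 2 observations (trials x tapers)")
    d <- dim(b$coeff)
    X <- b$coeff[, , , , ij[1], drop = FALSE]
    Y <- b$coeff[, , , , ij[2], drop = FALSE]
    flat_sum <- function(z) {
      dim(z) <- c(d[1] * d[2], d[3] * d[4])
      matrix(rowSums(z), d[1], d[2])
    }
    cross <- flat_sum(X * Conj(Y))
    px <- flat_sum(Mod(X)^2)
    py <- flat_sum(Mod(Y)^2)
    vals[[bn]] <- Mod(cross) / sqrt(px * py)
    freqs <- c(freqs, b$freqs)
  }
  new_tfr_map(do.call(rbind, vals), freqs, mtm$bands[[bands[1]]]$times,
              "coherence")
}

#' Baseline-correct a time-frequency map
#'
#' Power maps are expressed in dB relative to the per-frequency mean over
#' the baseline window; coherence maps have the per-frequency baseline mean
#' subtracted.
#'
#' @param map A raw `bw_tfr_map`.
#' @param baseline_window Time range (s), half-open.
#' @param mode `"db"` (power), `"subtract"` (coherence), or `"auto"`.
#' @return Corrected `bw_tfr_map`.
#' @export
baseline_correct <- function(map, baseline_window = c(-1.6, 0),
                             mode = c("auto", "db", "subtract")) {
  mode <- match.arg(mode)
  if (map$baseline_state != "raw") stopf("map is already baseline-corrected")
  if (mode == "auto") mode <- if (map$kind == "power") "db" else "subtract"
  sel <- map$times >= baseline_window[1] - 1e-9 & map$times < baseline_window[2] - 1e-9
  if (!any(sel)) stopf("no time bins inside the baseline window")
  v <- map$values
  trialwise <- length(dim(v)) == 3L
  base <- if (trialwise) apply(v[, , sel, drop = FALSE], c(1, 2), mean)
          else rowMeans(v[, sel, drop = FALSE])
  if (mode == "db") {
    if (any(base <= 0)) stopf("zero or negative baseline power")
    v <- if (trialwise) 10 * log10(sweep(v, c(1, 2), base, `/`))
         else 10 * log10(sweep(v, 1L, base, `/`))
    kind <- "power_dB"
  } else {
    v <- if (trialwise) sweep(v, c(1, 2), base, `-`)
         else sweep(v, 1L, base, `-`)
    kind <- if (map$kind == "coherence") "coherence_change" else map$kind
  }
  out <- new_tfr_map(v, map$freqs, map$times, kind, baseline_state = "corrected")
  out$baseline_window <- baseline_window
  out
}

#' Band- and window-averaged modulation from a corrected map
#'
#' Pre value, post value, and their difference (post - pre), averaged over
#' the band's frequency bins and each window's time bins.
#'
#' @param map A baseline-corrected `bw_tfr_map` (freq x time).
#' @param band Frequency range, Hz.
#' @param pre_window,post_window Time ranges, s (half-open).
#' @return List: `pre`, `post`, `modulation` (= post - pre).
#' @export
band_modulation <- function(map, band = c(13, 30),
                            pre_window = c(-1.6, 0), post_window = c(0, 1.6)) {
  fsel <- map$freqs >= band[1] - 1e-9 & map$freqs <= band[2] + 1e-9
  if (!any(fsel)) stopf("band outside the computed frequency grid")
  win_mean <- function(w) {
    tsel <- map$times >= w[1] - 1e-9 & map$times < w[2] - 1e-9
    if (!any(tsel)) stopf("window %.2f..%.2f s outside the map", w[1], w[2])
    mean(map$values[fsel, tsel])
  }
  pre <- win_mean(pre_window); post <- win_mean(post_window)
  list(pre = pre, post = post, modulation = post - pre)
}

#' Whole-segment band modulation (no sliding window)
#'
#' Multitaper band power (or coherence) computed over whole pre- and
#' post-event segments, as used for channel/ROI selection and the Granger
#' windows: one window per segment rather than a sliding TFR.
#'
#' @param epochs A `bw_epoch_set`.
#' @param channel Channel (power) or length-2 pair (coherence).
#' @param band Frequency range, Hz.
#' @param pre_window,post_window Segment windows, s (half-open).
#' @param n_tapers Taper count for the segment window.
#' @param measure `"power"` or `"coherence"`.
#' @return List: `pre`, `post`, `modulation` (dB post/pre for power,
#'   difference for coherence).
#' @export
segment_band_modulation <- function(epochs, channel, band = c(13, 30),
                                    pre_window = c(-2, 0), post_window = c(0, 2),
                                    n_tapers = 7L,
                                    measure = c("power", "coherence")) {
  measure <- match.arg(measure)
  fs <- epochs$sample_rate
  seg_value <- function(w) {
    sel <- epochs$time >= w[1] - 1e-9 & epochs$time < w[2] - 1e-9
    n <- sum(sel)
    tap <- slepian_tapers(n, n_tapers)
    freqs <- (0:(n %/% 2L)) * fs / n
    fsel <- which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9)
    get_coef <- function(ch) {
      chi <- if (is.character(ch)) match(ch, epochs$channels) else ch
      x <- matrix(epochs$data[sel, , chi], n)
      x <- sweep(x, 2L, colMeans(x))
      co <- array(complex(real = 0), c(length(fsel), ncol(x), n_tapers))
      for (j in seq_len(n_tapers))
        co[, , j] <- stats::mvfft(x * tap[, j])[fsel, , drop = FALSE]
      co
    }
    if (measure == "power") {
      mean(Mod(get_coef(channel[1]))^2)
    } else {
      X <- get_coef(channel[1]); Y <- get_coef(channel[2])
      cross <- apply(X * Conj(Y), 1L, sum)
      mean(Mod(cross) / sqrt(apply(Mod(X)^2, 1L, sum) * apply(Mod(Y)^2, 1L, sum)))
    }
  }
  pre <- seg_value(pre_window); post <- seg_value(post_window)
  mod <- if (measure == "power") db(post / pre) else post - pre
  list(pre = pre, post = post, modulation = mod)
}

#' Preprocess continuous signals (high-pass and downsample)
#'
#' Zero-phase FIR high-pass (for drift removal on real recordings) and
#' integer-factor downsampling. Synthetic data generated at the analysis
#' rate bypass this step.
#'
#' @param x Numeric vector or samples x channels matrix.
#' @param fs Sampling rate, Hz.
#' @param highpass High-pass cutoff, Hz (`NULL` to skip).
#' @param downsample_to Target rate, Hz (must divide `fs`; `NULL` to skip).
#' @param order FIR filter order; `NULL` sizes it from the cutoff
#'   (3.3 cycles of the cutoff frequency) so the transition band stays
#'   near the cutoff.
#' @return List: `x` (filtered/decimated), `fs` (new rate).
#' @export
preprocess_signals <- function(x, fs, highpass = 1, downsample_to = NULL,
                               order = NULL) {
  vec <- is.vector(x)
  if (vec) x <- matrix(x, ncol = 1L)
  ## symmetric FIR kernels applied by centered convolution with reflection
  ## padding: zero phase without the edge artifacts of recursive filtering
  apply_fir <- function(xj, h) {
    half <- (length(h) - 1L) %/% 2L
    xp <- c(rev(xj[seq_len(half)]), xj, rev(xj[(length(xj) - half + 1L):length(xj)]))
    y <- stats::filter(xp, h, sides = 2L)
    as.numeric(y)[(half + 1L):(half + length(xj))]
  }
  if (!is.null(highpass)) {
    ord <- order %||% 2L * (round(3.3 * fs / highpass) %/% 2L)
    h <- signal::fir1(ord, highpass / (fs / 2), type = "high")
    h <- h - mean(h)  # exact null at DC
    for (j in seq_len(ncol(x))) x[, j] <- apply_fir(x[, j], h)
  }
  if (!is.null(downsample_to)) {
    dec <- fs / downsample_to
    if (abs(dec - round(dec)) > 1e-9) stopf("`downsample_to` must divide `fs`")
    dec <- as.integer(round(dec))
    if (dec > 1L) {
      ## anti-alias low-pass at 80% of the new Nyquist
      lp <- signal::fir1(order %||% 256L, 0.8 * (downsample_to / 2) / (fs / 2))
      for (j in seq_len(ncol(x))) x[, j] <- apply_fir(x[, j], lp)
      x <- x[seq(1L, nrow(x), by = dec), , drop = FALSE]
      fs <- downsample_to
    }
  }
  list(x = if (vec) x[, 1L] else x, fs = fs)
}
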