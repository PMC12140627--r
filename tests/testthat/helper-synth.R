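# Shared fixture builders (all fixtures are generated in code).

fs_default <- 500

# Wrap a samples x trials x channels array (or samples x trials matrix)
# as an epoch set centered at 0.
make_epoch_set <- function(dat, fs = fs_default, channels = NULL) {
  if (length(dim(dat)) == 2L) dat <- array(dat, c(dim(dat), 1L))
  n <- dim(dat)[1L]
  channels <- channels %||% paste0("ch", seq_len(dim(dat)[3L]))
  dimnames(dat) <- list(NULL, NULL, channels)
  structure(list(data = dat,
                 time = (seq_len(n) - 1L - n %/% 2L) / fs,
                 channels = channels, info = NULL, alignment = "movement",
                 n_excluded = 0L, sample_rate = fs),
            class = "bw_epoch_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct (naive) tapered-DFT oracle: per window center, per taper,
# explicitly computed DFT at the band bins. Independent of mtm_fourier's
# vectorized path.
direct_mtm_oracle <- function(x, fs, window = 0.8, step = 0.05,
                              span = c(-1.6, 1.6), band = c(5, 45),
                              n_tapers = 4L) {
  n <- length(x)
  tt <- (seq_len(n) - 1L - n %/% 2L) / fs
  win_n <- round(window * fs)
  tap <- slepian_tapers(win_n, n_tapers)
  centers <- seq(span[1], span[2] + 1e-9, by = step)
  freqs_all <- (0:(win_n %/% 2)) * fs / win_n
  fsel <- which(freqs_all >= band[1] - 1e-9 & freqs_all <= band[2] + 1e-9)
  out <- array(complex(real = 0), c(length(fsel), length(centers), n_tapers))
  for (ci in seq_along(centers)) {
    i0 <- which.min(abs(tt - centers[ci])) - win_n %/% 2L
    seg <- x[i0:(i0 + win_n - 1L)]
    seg <- seg - mean(seg)
    for (k in seq_len(n_tapers)) {
      xt <- seg * tap[, k]
      for (fi in seq_along(fsel)) {
        f <- freqs_all[fsel[fi]]
        out[fi, ci, k] <- sum(xt * exp(-2i * pi * f * (0:(win_n - 1L)) / fs))
      }
    }
  }
  list(coeff = out, freqs = freqs_all[fsel], times = centers)
}

# Analytic csd of a bivariate VAR(1) process on a uniform one-sided grid.
var1_csd <- function(A, Sigma, nf = 257, fs = fs_default) {
  freqs <- seq(0, fs / 2, length.out = nf)
  S <- array(complex(real = 0), c(nf, 2, 2))
  H <- array(complex(real = 0), c(nf, 2, 2))
  for (k in seq_len(nf)) {
    z <- exp(-2i * pi * freqs[k] / fs)
    Hk <- solve(diag(2) - A * z)
    H[k, , ] <- Hk
    S[k, , ] <- Hk %*% Sigma %*% t(Conj(Hk))
  }
  S[1, , ] <- Re(S[1, , ]); S[nf, , ] <- Re(S[nf, , ])
  list(csd = structure(list(values = S, freqs = freqs, channels = c("x", "y"),
                            n_obs = Inf, sample_rate = fs), class = "bw_csd"),
       H = H, freqs = freqs)
}

# Parametric Geweke spectrum from true VAR transfer function and noise cov.
parametric_granger <- function(H, Sigma, src, tgt) {
  nf <- dim(H)[1]
  syy <- vapply(seq_len(nf), function(k)
    Re((H[k, , ] %*% Sigma %*% t(Conj(H[k, , ])))[tgt, tgt]), numeric(1))
  hyx2 <- vapply(seq_len(nf), function(k) Mod(H[k, tgt, src])^2, numeric(1))
  partial <- Sigma[src, src] - Sigma[src, tgt]^2 / Sigma[tgt, tgt]
  log(syy / (syy - partial * hyx2))
}

# Coupled two-channel epochs: y receives a lagged scaled copy of x's
# band-limited component (ground-truth direction x -> y).
make_coupled_epochs <- function(ntr = 40, nsamp = 2000, strength = 0.65,
                                lag = 10L, fs = fs_default, y_own_beta = TRUE) {
  dat <- array(NA_real_, c(nsamp, ntr, 2))
  for (tr in seq_len(ntr)) {
    xb <- ar2_series(nsamp + lag, 20, 3, 1, fs)
    x <- pink_noise(nsamp + lag, 1, 0.25, fs) + xb
    y <- pink_noise(nsamp + lag, 1, 0.25, fs) +
      (if (y_own_beta) ar2_series(nsamp + lag, 20, 3, 1, fs) else 0) +
      strength * c(rep(0, lag), xb[seq_len(nsamp)])
    dat[, tr, 1] <- x[(lag + 1):(lag + nsamp)]
    dat[, tr, 2] <- y[(lag + 1):(lag + nsamp)]
  }
  make_epoch_set(dat, fs, c("x", "y"))
}

# One reduced synthetic subject (single predictable block) plus its
# detected kinematics.
make_small_subject <- function(seed, n_trials = 10, hand = "R",
                               osc_specs = default_oscillation_specs(c("STN", "M1")),
                               coupling_specs = default_coupling_specs()) {
  task <- list(predictable = task_config("predictable",
                                         n_trials_per_block = n_trials,
                                         n_blocks = 1L))
  subj <- simulate_subject(paste0("S", seed), hand, task,
                           osc_specs = osc_specs,
                           coupling_specs = coupling_specs, seed = seed)
  speed <- angular_speed(subj$conditions$predictable$trace$angle, fs_default)
  events <- detect_events(speed, subj$conditions$predictable$cues)
  list(subject = subj, speed = speed, events = events)
}

# Subject-level baseline-corrected dB map for one channel/event.
subject_db_map <- function(subj, events, channel, event_type,
                           spec = tfr_spec(bands = list(low = c(5, 45)),
                                           n_tapers = c(low = 4L))) {
  ep <- epoch_signals(subj$conditions$predictable$signals[, channel, drop = FALSE],
                      events, fs_default, span = 4, event_type = event_type)
  baseline_correct(power_tfr(mtm_fourier(ep, spec), band = "low"))
}
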