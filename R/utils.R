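#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules. Time convention: seconds relative
## to the aligning event, event at 0; sample indices 1-based (R) but windows
## half-open [t0, t1) in time; sample_rate in Hz.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stopf("`%s` must be a single positive finite number", name)
  invisible(x)
}

assert_prob_vector <- function(p, name) {
  if (!is.numeric(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stopf("`%s` must be non-negative and sum to 1", name)
  invisible(p)
}

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream; seed = NULL leaves the RNG alone.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

## Deterministically derive a child seed from a parent seed and a tag, so
## that all stage randomness flows from one top-level seed. Kept < 2^31.
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

## Raised-cosine ease from 0 to 1 over n samples (n >= 1).
cosine_ramp <- function(n) {
  if (n <= 1L) return(rep(1, max(n, 0L)))
  0.5 * (1 - cos(pi * seq(0, 1, length.out = n)))
}

db <- function(ratio) 10 * log10(ratio)

inv_db <- function(x) 10^(x / 10)

## Truncated-at-zero normal sampling (rejection; truncation mass negligible
## for the reaction-time defaults used here).
rtruncnorm_pos <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  guard <- 0L
  while (length(bad) > 0L && guard < 100L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
    guard <- guard + 1L
  }
  if (length(bad) > 0L) out[bad] <- mean
  out
}

## Moving-average smoothing with edge-shrinking window (centered).
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L) return(x)
  k <- rep(1 / n, n)
  sm <- stats::filter(x, k, sides = 2)
  sm <- as.numeric(sm)
  ## fill edges with partial means so length and alignment are preserved
  half <- floor(n / 2)
  nx <- length(x)
  for (i in which(is.na(sm))) {
    lo <- max(1L, i - half); hi <- min(nx, i + half)
    sm[i] <- mean(x[lo:hi])
  }
  sm
}
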