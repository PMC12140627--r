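## Behavioral and band-summary inference: paired t-tests with effect sizes,
## repeated-measures ANOVA with partial eta squared, and the hemispheric
## lateralization index.

#' Paired t-test with Cohen's d
#'
#' Standard paired t on the differences, with one- and two-sided p values
#' from the t distribution and the paired-sample effect size
#' d = mean(diff) / SD(diff), which equals t / sqrt(n).
#'
#' @param x,y Equal-length paired samples.
#' @param sided `"two"`, `"less"` (one-sided, mean diff < 0), or
#'   `"greater"`.
#' @return A `bw_paired_t` list: `t`, `df`, `p_one_sided`, `p_two_sided`,
#'   `d`, `n`, per-sample means/SDs.
#' @export
paired_t <- function(x, y, sided = c("two", "less", "greater")) {
  sided <- match.arg(sided)
  if (length(x) != length(y)) stopf("`x` and `y` must be paired (equal length)")
  n <- length(x)
  if (n < 2L) stopf("need at least 2 pairs")
  d_i <- x - y
  sd_d <- stats::sd(d_i)
  if (sd_d == 0) stopf("zero variance of paired differences; t undefined")
  t_stat <- mean(d_i) / (sd_d / sqrt(n))
  df <- n - 1L
  p_lower <- stats::pt(t_stat, df)
  p_one <- switch(sided, two = min(p_lower, 1 - p_lower),
                  less = p_lower, greater = 1 - p_lower)
  structure(list(t = t_stat, df = df,
                 p_one_sided = p_one,
                 p_two_sided = 2 * min(p_lower, 1 - p_lower),
                 d = t_stat / sqrt(n), n = n,
                 mean_x = mean(x), mean_y = mean(y),
                 sd_x = stats::sd(x), sd_y = stats::sd(y)),
            class = "bw_paired_t")
}

#' Cohen's d from a paired t statistic
#'
#' @param t Paired t statistic.
#' @param n Number of pairs (>= 2).
#' @return d = t / sqrt(n).
#' @export
cohen_d_from_t <- function(t, n) {
  if (any(n < 2)) stopf("`n` must be >= 2")
  t / sqrt(n)
}

#' Partial eta squared from F and degrees of freedom
#'
#' @param f F statistic (>= 0).
#' @param df_effect,df_error Degrees of freedom (>= 1).
#' @return Partial eta squared = F df1 / (F df1 + df2).
#' @export
partial_eta_squared <- function(f, df_effect, df_error) {
  if (any(f < 0)) stopf("`f` must be >= 0")
  if (any(df_effect < 1) || any(df_error < 1)) stopf("degrees of freedom must be >= 1")
  f * df_effect / (f * df_effect + df_error)
}

#' Two-way repeated-measures ANOVA
#'
#' Univariate within-subject decomposition (each effect tested against its
#' effect-by-subject error stratum) for a complete balanced design, with
#' partial eta squared per effect.
#'
#' @param data Long data.frame.
#' @param dv,subject Column names of the response and subject id.
#' @param within Character vector of (two) within-subject factor columns.
#' @return A data.frame: effect, df_effect, df_error, F, p, pes.
#' @export
rm_anova <- function(data, dv = "value", subject = "subject",
                     within = c("predictability", "movement")) {
  for (col in c(dv, subject, within))
    if (!col %in% names(data)) stopf("column '%s' not found", col)
  d <- data.frame(y = data[[dv]],
                  subject = factor(data[[subject]]),
                  A = factor(data[[within[1]]]),
                  B = factor(data[[within[2]]]))
  counts <- table(d$subject, d$A, d$B)
  if (any(counts != 1L)) stopf("design must be complete and balanced (one value per cell)")
  fit <- stats::aov(y ~ A * B + Error(subject / (A * B)), data = d)
  sm <- summary(fit)
  grab <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    row <- trimws(rownames(tab)) == term
    if (!any(row)) return(NULL)
    err <- trimws(rownames(tab)) == "Residuals"
    list(df1 = tab[row, "Df"], df2 = tab[err, "Df"],
         F = tab[row, "F value"], p = tab[row, "Pr(>F)"])
  }
  effects <- list(c("Error: subject:A", "A"),
                  c("Error: subject:B", "B"),
                  c("Error: subject:A:B", "A:B"))
  labels <- c(within[1], within[2], paste(within, collapse = ":"))
  rows <- list()
  for (i in seq_along(effects)) {
    g <- grab(effects[[i]][1], effects[[i]][2])
    if (is.null(g)) next
    rows[[i]] <- data.frame(effect = labels[i], df_effect = g$df1,
                            df_error = g$df2, F = g$F, p = g$p,
                            pes = partial_eta_squared(g$F, g$df1, g$df2),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hemispheric lateralization index
#'
#' LI = (|contra| - |ipsi|) / (|contra| + |ipsi|) of baseline-corrected
#' band modulations; 0 means bilateral, positive means
#' contralateral-dominant, in [-1, 1]. Both modulations are expected to
#' share a sign (suppressions both negative, rebounds both positive); a
#' sign mismatch is flagged with a warning. Both magnitudes zero returns
#' `NA` (undefined).
#'
#' @param contra,ipsi Modulation values (same units), vectorized.
#' @return LI values in [-1, 1] (or NA).
#' @export
lateralization_index <- function(contra, ipsi) {
  if (length(contra) != length(ipsi)) stopf("inputs must have equal length")
  mismatch <- sign(contra) * sign(ipsi) < 0
  if (any(mismatch, na.rm = TRUE))
    warnf("%d contra/ipsi pair(s) have opposite-sign modulations", sum(mismatch))
  num <- abs(contra) - abs(ipsi)
  den <- abs(contra) + abs(ipsi)
  out <- ifelse(den == 0, NA_real_, num / den)
  out
}
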