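## Data-driven selection of the analyzed LFP channel and cortical grid
## point by strength of event-related beta modulation.

#' Bipolar montage from contact signals
#'
#' Differences of contact pairs (adjacent contacts by default), removing
#' common-mode activity.
#'
#' @param contacts samples x contacts matrix with column names.
#' @param pairs Optional list of length-2 contact-name vectors; default:
#'   adjacent columns.
#' @return samples x pairs matrix, columns named "a-b".
#' @export
bipolar_montage <- function(contacts, pairs = NULL) {
  if (ncol(contacts) < 2L) stopf("need at least 2 contacts")
  nm <- colnames(contacts) %||% paste0("c", seq_len(ncol(contacts)))
  colnames(contacts) <- nm
  if (is.null(pairs))
    pairs <- lapply(seq_len(ncol(contacts) - 1L), function(i) nm[c(i, i + 1L)])
  out <- matrix(NA_real_, nrow(contacts), length(pairs))
  lab <- character(length(pairs))
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    if (!all(p %in% nm)) stopf("unknown contact in pair: %s", paste(p, collapse = "-"))
    out[, k] <- contacts[, p[1]] - contacts[, p[2]]
    lab[k] <- paste(p, collapse = "-")
  }
  colnames(out) <- lab
  out
}

#' Select the LFP channel with the strongest beta suppression and rebound
#'
#' Per candidate channel, computes whole-segment beta modulations for
#' start epochs (suppression, expected negative) and stop epochs (rebound,
#' expected positive); the winner maximizes |suppression| + |rebound|.
#' Ties break deterministically by channel label order.
#'
#' @param start_epochs,stop_epochs `bw_epoch_set`s sharing the candidate
#'   channels.
#' @param band Beta band, Hz.
#' @param pre_window,post_window Contrast windows, s.
#' @param n_tapers Taper count for the segment spectra.
#' @return List: `selected` (channel name), `scores` data.frame (channel,
#'   suppression, rebound, combined).
#' @export
select_lfp_channel <- function(start_epochs, stop_epochs, band = c(13, 30),
                               pre_window = c(-2, 0), post_window = c(0, 2),
                               n_tapers = 7L) {
  cand <- start_epochs$channels
  if (length(cand) < 1L) stopf("no candidate channels")
  if (!identical(cand, stop_epochs$channels))
    stopf("start and stop epochs must share candidate channels")
  rows <- lapply(cand, function(ch) {
    sup <- segment_band_modulation(start_epochs, ch, band, pre_window,
                                   post_window, n_tapers)$modulation
    reb <- segment_band_modulation(stop_epochs, ch, band, pre_window,
                                   post_window, n_tapers)$modulation
    data.frame(channel = ch, suppression = sup, rebound = reb,
               combined = abs(sup) + abs(reb), stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, rows)
  best <- scores$channel[which.max(scores$combined)]  # first max = label order
  list(selected = best, scores = scores)
}

#' Select the grid point with the strongest absolute beta contrast
#'
#' Argmax over candidates of |post - pre| beta modulation averaged over
#' subjects and event types, as used to place cortical regions of
#' interest; sign of the modulation is ignored.
#'
#' @param modulations Array candidate x subject x event of modulation
#'   values (power dB or coherence difference), or candidate x subject
#'   matrix.
#' @return List: `selected` (candidate index/name), `scores` (mean
#'   absolute modulation per candidate).
#' @export
select_roi <- function(modulations) {
  if (is.matrix(modulations)) dim(modulations) <- c(dim(modulations), 1L)
  if (length(dim(modulations)) != 3L)
    stopf("`modulations` must be candidate x subject x event")
  scores <- apply(abs(modulations), 1L, mean)
  nm <- dimnames(modulations)[[1]] %||% seq_along(scores)
  list(selected = nm[which.max(scores)], scores = stats::setNames(scores, nm))
}

#' Grid neighborhood of a selected peak
#'
#' The peak plus its k nearest grid neighbors (Euclidean distance), the
#' neighborhood used to represent a cortical region of interest.
#'
#' @param coords candidates x dims coordinate matrix.
#' @param peak Row index of the peak.
#' @param k Number of neighbors.
#' @return Integer vector of candidate indices (peak first).
#' @export
roi_neighborhood <- function(coords, peak, k = 6L) {
  if (peak < 1L || peak > nrow(coords)) stopf("`peak` out of range")
  d <- sqrt(rowSums((coords - matrix(coords[peak, ], nrow(coords),
                                     ncol(coords), byrow = TRUE))^2))
  ord <- order(d)
  ord[seq_len(min(k + 1L, nrow(coords)))]
}
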