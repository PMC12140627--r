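## Cluster-based permutation inference on time-frequency grids across
## subjects: one-sample t per bin, supra-threshold bins grouped by grid
## adjacency separately per sign, observed cluster t-sums ranked against the
## permutation distribution of the per-sign maximum |t-sum| under random
## subject sign flips.

#' Cluster-test configuration
#'
#' @param cluster_forming_alpha Two-sided bin-level alpha defining
#'   supra-threshold bins (|t| > t critical at df = N-1).
#' @param cluster_alpha Two-sided cluster-level alpha; split across tails
#'   (alpha/2 per sign).
#' @param n_permutations Number of sign-flip draws (observed included).
#' @param adjacency `"4-neighbor"` or `"8-neighbor"` on the freq x time
#'   grid.
#' @param seed Integer seed or `NULL`.
#' @return A `bw_cluster_config` list.
#' @export
cluster_test_config <- function(cluster_forming_alpha = 0.05,
                                cluster_alpha = 0.05,
                                n_permutations = 1000L,
                                adjacency = c("4-neighbor", "8-neighbor"),
                                seed = NULL) {
  adjacency <- match.arg(adjacency)
  if (cluster_forming_alpha <= 0 || cluster_forming_alpha >= 1 ||
      cluster_alpha <= 0 || cluster_alpha >= 1)
    stopf("alphas must lie in (0, 1)")
  if (n_permutations < 100L) stopf("`n_permutations` must be >= 100")
  structure(list(cluster_forming_alpha = cluster_forming_alpha,
                 cluster_alpha = cluster_alpha,
                 n_permutations = as.integer(n_permutations),
                 adjacency = adjacency, seed = seed),
            class = "bw_cluster_config")
}

#' Stack per-subject baseline-corrected maps
#'
#' @param maps List of `bw_tfr_map` (corrected, freq x time), one per
#'   subject, on identical grids.
#' @return A `bw_map_stack`: `values` (subject x freq x time), `freqs`,
#'   `times`.
#' @export
baseline_contrast_maps <- function(maps) {
  if (length(maps) < 2L) stopf("at least 2 subjects are required (t undefined otherwise)")
  f0 <- maps[[1]]$freqs; t0 <- maps[[1]]$times
  for (m in maps) {
    if (!isTRUE(all.equal(m$freqs, f0)) || !isTRUE(all.equal(m$times, t0)))
      stopf("subject maps are on mismatched time-frequency grids")
  }
  arr <- array(NA_real_, c(length(maps), length(f0), length(t0)))
  for (i in seq_along(maps)) arr[i, , ] <- maps[[i]]$values
  structure(list(values = arr, freqs = f0, times = t0),
            class = "bw_map_stack")
}

## Connected-component labeling of a logical freq x time mask.
## Union-find over the (sparse) supra-threshold bins; returns the linear
## grid indices of supra bins and an integer component label per bin.
label_clusters <- function(mask, adjacency = "4-neighbor") {
  nf <- nrow(mask); nt <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(list(idx = integer(0), labels = integer(0)))
  pos <- match(seq_len(nf * nt), idx)  # linear index -> compact id (NA if not supra)
  ## edge list between adjacent supra bins; sub-matrix which() indices are
  ## mapped back to full-grid linear indices
  sub_to_full <- function(sub_idx, sub_nf, row_off = 0L) {
    r <- (sub_idx - 1L) %% sub_nf + 1L + row_off
    cc <- (sub_idx - 1L) %/% sub_nf + 1L
    (cc - 1L) * nf + r
  }
  ## horizontal: (f, t) with (f, t+1); submatrix keeps nf rows
  h <- which(mask[, -nt, drop = FALSE] & mask[, -1, drop = FALSE])
  efrom <- h; eto <- h + nf
  ## vertical: (f, t) with (f+1, t); submatrix has nf-1 rows
  v <- sub_to_full(which(mask[-nf, , drop = FALSE] & mask[-1, , drop = FALSE]),
                   nf - 1L)
  efrom <- c(efrom, v); eto <- c(eto, v + 1L)
  if (adjacency == "8-neighbor") {
    d1 <- sub_to_full(which(mask[-nf, -nt, drop = FALSE] & mask[-1, -1, drop = FALSE]),
                      nf - 1L)
    efrom <- c(efrom, d1); eto <- c(eto, d1 + nf + 1L)
    d2 <- sub_to_full(which(mask[-1, -nt, drop = FALSE] & mask[-nf, -1, drop = FALSE]),
                      nf - 1L, row_off = 1L)
    efrom <- c(efrom, d2); eto <- c(eto, d2 + nf - 1L)
  }
  efrom <- pos[efrom]; eto <- pos[eto]
  parent <- seq_along(idx)
  for (e in seq_along(efrom)) {
    a <- efrom[e]
    while (parent[a] != a) { parent[a] <- parent[parent[a]]; a <- parent[a] }
    b <- eto[e]
    while (parent[b] != b) { parent[b] <- parent[parent[b]]; b <- parent[b] }
    if (a != b) parent[a] <- b
  }
  roots <- integer(length(idx))
  for (i in seq_along(idx)) {
    a <- i
    while (parent[a] != a) { parent[a] <- parent[parent[a]]; a <- parent[a] }
    roots[i] <- a
  }
  list(idx = idx, labels = match(roots, unique(roots)))
}

cluster_sums <- function(tmap_vec, lab) {
  if (length(lab$idx) == 0L) return(numeric(0))
  as.numeric(rowsum(tmap_vec[lab$idx], lab$labels))
}

#' Cluster-based permutation test of subject maps against zero
#'
#' One-sample t across subjects per bin; supra-threshold bins grouped by
#' adjacency separately per sign; cluster statistic = sum of t values;
#' inference by random per-subject sign flips against the per-sign maximum
#' |t-sum| distribution (observed draw included, so p >= 1/n_permutations).
#' A cluster is significant when its rank-based p is at most
#' `cluster_alpha / 2` for its tail.
#'
#' @param stack A [baseline_contrast_maps()] stack.
#' @param cfg A [cluster_test_config()].
#' @return A `bw_cluster_result`: `clusters` data.frame (sign, t_sum,
#'   n_bins, p, significant, freq/time extents), `t_map`, `sig_mask`,
#'   `crit`, axes.
#' @export
cluster_permutation_test <- function(stack, cfg = cluster_test_config()) {
  X <- stack$values
  n <- dim(X)[1]
  if (n < 2L) stopf("need >= 2 subjects")
  nf <- dim(X)[2]; nt <- dim(X)[3]
  Xm <- matrix(X, n)  # n x (nf*nt)
  SS <- colSums(Xm^2)
  crit <- stats::qt(1 - cfg$cluster_forming_alpha / 2, df = n - 1)

  t_from_signs <- function(s) {
    m <- as.numeric(s %*% Xm) / n
    v <- (SS - n * m^2) / (n - 1)
    v[v < .Machine$double.eps] <- .Machine$double.eps
    m / sqrt(v / n)
  }
  max_sums <- function(tvec) {
    tm <- matrix(tvec, nf, nt)
    pos_lab <- label_clusters(tm > crit, cfg$adjacency)
    neg_lab <- label_clusters(tm < -crit, cfg$adjacency)
    ps <- cluster_sums(tvec, pos_lab)
    ns <- cluster_sums(tvec, neg_lab)
    c(pos = if (length(ps)) max(ps) else 0,
      neg = if (length(ns)) max(abs(ns)) else 0)
  }

  t_obs <- t_from_signs(rep(1, n))
  tm_obs <- matrix(t_obs, nf, nt)
  pos_lab <- label_clusters(tm_obs > crit, cfg$adjacency)
  neg_lab <- label_clusters(tm_obs < -crit, cfg$adjacency)

  null_pos <- numeric(cfg$n_permutations)
  null_neg <- numeric(cfg$n_permutations)
  obs_max <- max_sums(t_obs)
  null_pos[1] <- obs_max["pos"]; null_neg[1] <- obs_max["neg"]
  ## all permutation t maps in one matrix product
  signs <- with_seed_or_not(cfg$seed,
    matrix(sample(c(-1, 1), (cfg$n_permutations - 1L) * n, replace = TRUE),
           cfg$n_permutations - 1L, n))
  Mall <- (signs %*% Xm) / n
  Vall <- sweep(-n * Mall^2, 2L, SS, `+`) / (n - 1)
  Vall[Vall < .Machine$double.eps] <- .Machine$double.eps
  Tall <- Mall / sqrt(Vall / n)
  for (p in 2:cfg$n_permutations) {
    mx <- max_sums(Tall[p - 1L, ])
    null_pos[p] <- mx["pos"]; null_neg[p] <- mx["neg"]
  }

  clusters <- list()
  sig_mask <- matrix(FALSE, nf, nt)
  collect <- function(lab, sign_chr, null_dist) {
    if (length(lab$idx) == 0L) return()
    idx <- lab$idx; labels <- lab$labels
    for (lb in unique(labels)) {
      bins <- idx[labels == lb]
      ts <- sum(t_obs[bins])
      ## small tolerance so the observed draw always counts itself
      ## (rowsum vs sum can differ in the last float bit)
      p <- mean(null_dist >= abs(ts) * (1 - 1e-12))
      sig <- p <= cfg$cluster_alpha / 2
      if (sig) sig_mask[bins] <<- TRUE
      fr <- ((bins - 1L) %% nf) + 1L
      ti <- ((bins - 1L) %/% nf) + 1L
      clusters[[length(clusters) + 1L]] <<- data.frame(
        sign = sign_chr, t_sum = ts, n_bins = length(bins), p = p,
        significant = sig,
        freq_lo = min(stack$freqs[fr]), freq_hi = max(stack$freqs[fr]),
        time_lo = min(stack$times[ti]), time_hi = max(stack$times[ti]),
        stringsAsFactors = FALSE)
    }
  }
  collect(pos_lab, "positive", null_pos)
  collect(neg_lab, "negative", null_neg)
  cl <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(sign = character(), t_sum = numeric(), n_bins = integer(),
               p = numeric(), significant = logical(), freq_lo = numeric(),
               freq_hi = numeric(), time_lo = numeric(), time_hi = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(cl)) cl <- cl[order(-abs(cl$t_sum)), , drop = FALSE]
  rownames(cl) <- NULL
  structure(list(clusters = cl, t_map = tm_obs, sig_mask = sig_mask,
                 crit = crit, freqs = stack$freqs, times = stack$times,
                 n_subjects = n, config = cfg),
            class = "bw_cluster_result")
}

#' Tabulate clusters for reporting
#'
#' @param result A `bw_cluster_result`.
#' @param event,condition,area Optional labels added to every row.
#' @param file Optional CSV path; an empty result writes a header-only
#'   file.
#' @return The report data.frame, invisibly if written to file.
#' @export
report_clusters <- function(result, event = NA, condition = NA, area = NA,
                            file = NULL) {
  df <- result$clusters
  out <- cbind(data.frame(event = rep(event, nrow(df)),
                          condition = rep(condition, nrow(df)),
                          area = rep(area, nrow(df)),
                          stringsAsFactors = FALSE), df)
  if (nrow(df) == 0L)
    out <- data.frame(event = character(), condition = character(),
                      area = character(), sign = character(),
                      t_sum = numeric(), n_bins = integer(), p = numeric(),
                      significant = logical(), freq_lo = numeric(),
                      freq_hi = numeric(), time_lo = numeric(),
                      time_hi = numeric(), stringsAsFactors = FALSE)
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
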