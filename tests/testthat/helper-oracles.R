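# Independent brute-force oracles and small fixture builders used across the
# test files.  These deliberately avoid the package's own implementations.

# all-pairs shortest paths by Floyd-Warshall
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

# characteristic path length, connected-pairs convention
bf_lp <- function(adj) {
  d <- fw_distances(adj)
  off <- d[row(d) != col(d)]
  if (!any(is.finite(off))) return(NA_real_)
  mean(off[is.finite(off)])
}

bf_eg <- function(adj) {
  d <- fw_distances(adj)
  mean(1 / d[row(d) != col(d)])
}

# clustering coefficient by exhaustive triple enumeration
bf_cp <- function(adj) {
  n <- nrow(adj)
  terms <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      tri <- tri + (adj[nb[a], nb[b]] > 0)
    tri / (k * (k - 1) / 2)
  }, numeric(1))
  mean(terms)
}

# local efficiency: global efficiency of each induced neighborhood
bf_eloc <- function(adj) {
  n <- nrow(adj)
  terms <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    bf_eg(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(terms)
}

random_graph <- function(n, p) {
  a <- matrix(0L, n, n)
  ut <- upper.tri(a)
  a[ut] <- stats::rbinom(sum(ut), 1L, p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  diag(a) <- 0L
  a
}

# brute-force KNN by exhaustive distance sort
bf_knn <- function(train, labels, test, k) {
  d <- sqrt(colSums((t(train) - test)^2))
  nb <- order(d)[seq_len(k)]
  tab <- table(labels[nb])
  names(tab)[which.max(tab)]
}

# symmetric matrix with given upper-triangle values (row-major by pair)
sym_from_upper <- function(n, values, diag_value = 1) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- NA
  idx <- which(is.na(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  m[idx] <- values
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- diag_value
  m
}

# hemo recording wrapping a channels x samples HbT matrix (HbO = 0.6 HbT,
# HbR = 0.4 HbT)
hemo_from_hbt <- function(hbt, fs = 11) {
  nch <- nrow(hbt)
  conc <- array(NA_real_, c(nch, 3, ncol(hbt)))
  conc[, 1, ] <- 0.6 * hbt
  conc[, 2, ] <- 0.4 * hbt
  conc[, 3, ] <- hbt
  montage <- if (nch == 48) default_montage() else generic_montage(nch)
  hemo_recording(conc, fs = fs, montage = montage)
}

# small clean synthetic config used by statistics/classification tests:
# confound-free acquisition so correlation structure is resolvable in 300 s
clean_config <- function(seed, n_group_a = 8L, n_group_b = 10L,
                         n_channels = 48L, duration = 300, ...) {
  synth_config(n_group_a = n_group_a, n_group_b = n_group_b,
               n_channels = n_channels, duration = duration, seed = seed,
               noise_amplitudes = list(cardiac = 0, respiration = 0,
                                       mayer = 0, systemic = 0, drift = 0,
                                       white = 0.3),
               motion_spike_rate = 0, ...)
}

# confound-free per-subject network/ROI features (no band-pass or PCA:
# the latent structure is planted directly in band)
clean_features <- function(cohort, metrics = c("Eg", "Lp"),
                           rois = "L_OC") {
  rows <- lapply(cohort$recordings, function(r) {
    fc <- fc_matrix(mbll_convert(r))
    auc <- network_metrics(fc, metrics = metrics)$auc
    roi <- roi_mean(fc, r$montage)
    c(auc, stats::setNames(roi$mean_r[match(rois, roi$region)], rois))
  })
  as.data.frame(do.call(rbind, rows))
}
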