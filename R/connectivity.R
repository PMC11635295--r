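#' Whole-head functional connectivity matrix
#'
#' Pearson correlations between the HbT series of every pair of active
#' channels, typically computed on the 5-min stable segment after filtering
#' and motion correction.  Channels masked by quality control (or listed in
#' the recording's `active` vector) become `NA` rows/columns; zero-variance
#' channels are flagged missing with a warning.
#'
#' @param hemo A `hemo_recording`.
#' @param qc Optional `qc_report`; bad channels are masked.
#' @param chromophore Chromophore to correlate (default `"HbT"`).
#' @return A `fc_matrix`: `n x n` symmetric correlation matrix with
#'   attributes `active` (logical) and `subject`.
#' @export
fc_matrix <- function(hemo, qc = NULL, chromophore = "HbT") {
  stopifnot(inherits(hemo, "hemo_recording"))
  x <- chromophore_matrix(hemo, chromophore)
  n <- nrow(x)
  ns <- ncol(x)
  if (ns < 2L) stop("need at least 2 samples to correlate")
  active <- rep(TRUE, n)
  if (!is.null(hemo$active)) active <- active & hemo$active
  if (!is.null(qc)) {
    stopifnot(inherits(qc, "qc_report"), nrow(qc) == n)
    active <- active & !qc$bad
  }
  if (sum(active) < 2L) stop("fewer than 2 active channels")
  zero_var <- active & apply(x, 1L, stats::sd) == 0
  if (any(zero_var)) {
    warning("zero-variance channel(s) ",
            paste(which(zero_var), collapse = ", "),
            ": correlations undefined, marked missing")
    active <- active & !zero_var
    if (sum(active) < 2L) stop("fewer than 2 active channels after dropping zero-variance channels")
  }
  r <- matrix(NA_real_, n, n, dimnames = list(seq_len(n), seq_len(n)))
  r[active, active] <- stats::cor(t(x[active, , drop = FALSE]))
  structure(r, class = "fc_matrix", active = active,
            subject = hemo$subject)
}

#' Active submatrix of a connectivity matrix
#'
#' @param fc A `fc_matrix` or plain symmetric matrix; rows that are all-`NA`
#'   off the diagonal count as inactive.
#' @return The correlation matrix restricted to active channels, dimnames =
#'   channel ids.
#' @export
fc_active_matrix <- function(fc) {
  r <- unclass(fc)
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  if (is.null(dimnames(r)))
    dimnames(r) <- list(seq_len(nrow(r)), seq_len(ncol(r)))
  active <- attr(fc, "active")
  if (is.null(active)) {
    off <- r
    diag(off) <- NA
    active <- rowSums(!is.na(off)) > 0
  }
  r[active, active, drop = FALSE]
}

#' @export
print.fc_matrix <- function(x, ...) {
  act <- attr(x, "active")
  cat(sprintf("Functional connectivity matrix%s: %d channels (%d active)\n",
              if (is.na(attr(x, "subject"))) ""
              else paste0(" [", attr(x, "subject"), "]"),
              nrow(x), sum(act)))
  off <- x[row(x) != col(x)]
  cat(sprintf("  mean off-diagonal r = %.3f\n", mean(off, na.rm = TRUE)))
  invisible(x)
}

#' Mean off-diagonal connectivity strength
#'
#' @param fc A `fc_matrix`.
#' @return Mean of the active upper-triangle correlations.
#' @export
mean_fc_strength <- function(fc) {
  r <- fc_active_matrix(fc)
  mean(r[upper.tri(r)])
}

#' Region-of-interest mean connectivity
#'
#' Averages the within-region off-diagonal correlations over the unordered
#' channel pairs whose both members are active.  Regions with fewer than two
#' active channels get `NA` (missing, not zero).
#'
#' @param fc A `fc_matrix`.
#' @param montage A `fnirs_montage` defining the regions.
#' @return Data frame with `region`, `mean_r` and `n_pairs`.
#' @export
roi_mean <- function(fc, montage) {
  stopifnot(inherits(montage, "fnirs_montage"))
  r <- unclass(fc)
  active <- attr(fc, "active")
  if (is.null(active)) active <- rowSums(!is.na(r)) > 0
  out <- data.frame(region = names(montage$regions),
                    mean_r = NA_real_, n_pairs = 0L)
  for (i in seq_along(montage$regions)) {
    ch <- intersect(montage$regions[[i]], which(active))
    if (length(ch) < 2L) next
    sub <- r[ch, ch]
    vals <- sub[upper.tri(sub)]
    out$mean_r[i] <- mean(vals)
    out$n_pairs[i] <- length(vals)
  }
  out
}

#' Pooled distribution of connectivity values
#'
#' Histogram counts of the upper-triangle correlations pooled over
#' subjects, per group.  Bins are right-closed intervals `(lo, hi]`; the
#' default edges step by 0.1 so that 0.1 itself is a bin boundary.
#'
#' @param fcs List of `fc_matrix` objects.
#' @param edges Strictly increasing bin edges (default `seq(-1, 1, 0.1)`).
#' @param groups Optional group label per matrix (default one pooled group).
#' @return Data frame with `group`, `bin_lo`, `bin_hi`, `count`.
#' @export
fc_distribution <- function(fcs, edges = seq(-1, 1, by = 0.1),
                            groups = NULL) {
  if (length(fcs) == 0L) stop("empty list of connectivity matrices")
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  if (is.null(groups)) groups <- rep("all", length(fcs))
  stopifnot(length(groups) == length(fcs))
  out <- list()
  for (g in unique(groups)) {
    vals <- unlist(lapply(fcs[groups == g], function(fc) {
      r <- unclass(fc)
      r[upper.tri(r)]
    }))
    vals <- vals[!is.na(vals)]
    h <- hist(vals, breaks = edges, plot = FALSE, right = TRUE,
              include.lowest = TRUE)
    out[[g]] <- data.frame(group = g, bin_lo = head(edges, -1),
                           bin_hi = tail(edges, -1), count = h$counts)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Group-mean connectivity matrix
#'
#' Entry-wise mean over subjects, using for each channel pair only the
#' subjects where both channels are active; pairs observed in fewer than
#' `min_subjects` subjects become `NA` rather than being zero-filled.
#'
#' @param fcs List of `fc_matrix` objects with a common channel count.
#' @param min_subjects Minimum subjects per pair (default 1).
#' @return A `fc_matrix` of the group mean.
#' @export
group_mean_fc <- function(fcs, min_subjects = 1L) {
  if (length(fcs) == 0L) stop("empty list of connectivity matrices")
  n <- nrow(fcs[[1]])
  acc <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (fc in fcs) {
    r <- unclass(fc)
    stopifnot(nrow(r) == n)
    ok <- !is.na(r)
    acc[ok] <- acc[ok] + r[ok]
    cnt <- cnt + ok
  }
  m <- acc / cnt
  m[cnt < min_subjects] <- NA_real_
  active <- rowSums(cnt > 0) > 0
  structure(m, class = "fc_matrix", active = active,
            subject = "group-mean", dimnames = list(1:n, 1:n))
}

#' Suprathreshold edges of a group-mean connectivity matrix
#'
#' @param fc A `fc_matrix` (typically a group mean).
#' @param threshold Correlation threshold (default 0.35); strictly greater
#'   values are kept.
#' @return Data frame `i`, `j` (`i < j`), `r`, sorted by `(i, j)`.
#' @export
suprathreshold_edges <- function(fc, threshold = 0.35) {
  r <- unclass(fc)
  ut <- which(upper.tri(r) & !is.na(r) & r > threshold, arr.ind = TRUE)
  ord <- order(ut[, 1L], ut[, 2L])
  data.frame(i = ut[ord, 1L], j = ut[ord, 2L], r = r[ut[ord, , drop = FALSE]],
             row.names = NULL)
}

# schematic per-channel coordinates: six region centroids on a circle,
# member channels fanned around their centroid (channels in two regions sit
# at the mean of their two fan positions)
montage_layout <- function(montage) {
  nreg <- length(montage$regions)
  centers <- cbind(cos(2 * pi * (seq_len(nreg) - 1) / nreg),
                   sin(2 * pi * (seq_len(nreg) - 1) / nreg)) * 10
  xy <- matrix(0, montage$n_channels, 2)
  hits <- integer(montage$n_channels)
  for (i in seq_len(nreg)) {
    ch <- montage$regions[[i]]
    ang <- 2 * pi * seq_along(ch) / length(ch)
    pos <- cbind(centers[i, 1] + 3 * cos(ang), centers[i, 2] + 3 * sin(ang))
    xy[ch, ] <- xy[ch, ] + pos
    hits[ch] <- hits[ch] + 1L
  }
  xy / pmax(hits, 1L)
}

#' Export a connectivity graph as .node / .edge text files
#'
#' Writes the plain-text node and edge files used by surface-rendering
#' viewers: one row per channel with schematic coordinates, a region color
#' index and the channel degree, and a square edge matrix keeping only
#' suprathreshold connections.
#'
#' @param fc A `fc_matrix` (typically a group mean).
#' @param montage A `fnirs_montage`.
#' @param prefix Output path prefix; writes `<prefix>.node` and
#'   `<prefix>.edge`.
#' @param threshold Connection threshold (default 0.35).
#' @return Invisibly, the two file paths.
#' @export
write_node_edge <- function(fc, montage, prefix, threshold = 0.35) {
  r <- unclass(fc)
  n <- nrow(r)
  stopifnot(montage$n_channels == n)
  e <- r
  e[is.na(e) | e <= threshold] <- 0
  diag(e) <- 0
  xy <- montage_layout(montage)
  color <- integer(n)
  for (i in seq_along(montage$regions))
    color[montage$regions[[i]]] <- i
  nodes <- data.frame(x = round(xy[, 1], 3), y = round(xy[, 2], 3), z = 0,
                      color = color, size = colSums(e > 0),
                      label = paste0("ch", seq_len(n)))
  node_path <- paste0(prefix, ".node")
  edge_path <- paste0(prefix, ".edge")
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(round(e, 6), edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(node_path, edge_path))
}
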