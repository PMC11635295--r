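#' Raw dual-wavelength recording
#'
#' Container for one subject's raw optical-intensity time series.
#'
#' @param intensity Numeric array `channels x wavelengths x samples`,
#'   strictly positive (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param montage A `fnirs_montage` matching the channel count.
#' @param wavelengths Wavelength pair in nm.
#' @param subject Optional subject identifier.
#' @return A `raw_recording` object.
#' @export
raw_recording <- function(intensity, fs, montage = default_montage(dim(intensity)[1]),
                          wavelengths = c(730, 850), subject = NA_character_) {
  if (length(dim(intensity)) != 3L)
    stop("intensity must be a channels x wavelengths x samples array")
  if (dim(intensity)[2] != length(wavelengths))
    stop("second dimension must match the number of wavelengths")
  bad <- which(intensity <= 0 | !is.finite(intensity), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "nonpositive intensity at channel %d, wavelength %g nm, sample %d",
      bad[1, 1], wavelengths[bad[1, 2]], bad[1, 3]))
  }
  stopifnot(fs > 0, inherits(montage, "fnirs_montage"),
            montage$n_channels == dim(intensity)[1])
  structure(list(intensity = intensity, fs = fs, montage = montage,
                 wavelengths = wavelengths, subject = subject),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("Raw fNIRS recording%s: %d channels x %d wavelengths x %d samples (%.1f s at %g Hz)\n",
              if (is.na(x$subject)) "" else paste0(" [", x$subject, "]"),
              d[1], d[2], d[3], d[3] / x$fs, x$fs))
  invisible(x)
}

#' Hemoglobin concentration recording
#'
#' @param conc Numeric array `channels x 3 x samples` with chromophores
#'   `HbO`, `HbR`, `HbT` in relative uM; `HbT` must equal `HbO + HbR`.
#' @param fs Sampling rate in Hz.
#' @param montage A `fnirs_montage`.
#' @param subject Optional subject id.
#' @param provenance List of processing flags (`filtered`, `pca_corrected`,
#'   `segment`).
#' @return A `hemo_recording` object.
#' @export
hemo_recording <- function(conc, fs, montage = default_montage(dim(conc)[1]),
                           subject = NA_character_,
                           provenance = list(filtered = FALSE,
                                             pca_corrected = FALSE,
                                             segment = NULL)) {
  if (length(dim(conc)) != 3L || dim(conc)[2] != 3L)
    stop("conc must be a channels x 3 (HbO, HbR, HbT) x samples array")
  dimnames(conc)[[2]] <- c("HbO", "HbR", "HbT")
  err <- max(abs(conc[, 3, ] - conc[, 1, ] - conc[, 2, ]))
  if (!is.finite(err) || err > 1e-8 * max(1, max(abs(conc))))
    stop("HbT must equal HbO + HbR elementwise")
  stopifnot(fs > 0, inherits(montage, "fnirs_montage"),
            montage$n_channels == dim(conc)[1])
  structure(list(conc = conc, fs = fs, montage = montage, subject = subject,
                 provenance = provenance),
            class = "hemo_recording")
}

#' @export
print.hemo_recording <- function(x, ...) {
  d <- dim(x$conc)
  cat(sprintf("Hemoglobin recording%s: %d channels x %d samples (%.1f s at %g Hz)\n",
              if (is.na(x$subject)) "" else paste0(" [", x$subject, "]"),
              d[1], d[3], d[3] / x$fs, x$fs))
  cat("  filtered:", isTRUE(x$provenance$filtered),
      " pca_corrected:", isTRUE(x$provenance$pca_corrected), "\n")
  invisible(x)
}

#' Extract one chromophore as a channels x samples matrix
#'
#' @param hemo A `hemo_recording`.
#' @param chromophore One of `"HbO"`, `"HbR"`, `"HbT"`.
#' @return Numeric matrix, channels in rows.
#' @export
chromophore_matrix <- function(hemo, chromophore = "HbT") {
  stopifnot(inherits(hemo, "hemo_recording"))
  ch <- match.arg(chromophore, c("HbO", "HbR", "HbT"))
  hemo$conc[, ch, , drop = TRUE]
}

#' Optical density change
#'
#' `dOD(t) = -log10(I(t) / I0)` per channel and wavelength, with the
#' baseline `I0` taken as the geometric temporal mean of that
#' channel/wavelength series.  Equivalently, `dOD` is the negative
#' log10-intensity minus its temporal mean, so each dOD series is exactly
#' zero-mean (the zero-mean-log contract), dOD is invariant to a constant
#' rescaling of a channel's intensity, and the forward intensity model is
#' exactly invertible for zero-mean concentration changes.
#'
#' @param raw A `raw_recording`.
#' @return Array `channels x wavelengths x samples` of optical-density
#'   changes.
#' @export
optical_density <- function(raw) {
  stopifnot(inherits(raw, "raw_recording"))
  lod <- -log10(raw$intensity)
  sweep(lod, c(1, 2), apply(lod, c(1, 2), mean))
}

#' Modified Beer-Lambert conversion
#'
#' Converts raw intensities to hemoglobin concentration changes: the
#' optical-density change at each wavelength is modeled as
#' `dOD(lambda) = [eps(lambda,HbO) dHbO + eps(lambda,HbR) dHbR] * DPF(lambda) * L`
#' and the 2x2 linear system is solved per channel and sample;
#' `HbT = HbO + HbR`.
#'
#' @param raw A `raw_recording`.
#' @param optics An `optical_model`.
#' @return A `hemo_recording` in relative uM.
#' @export
mbll_convert <- function(raw, optics = optical_model()) {
  stopifnot(inherits(raw, "raw_recording"), inherits(optics, "optical_model"))
  if (!isTRUE(all.equal(raw$wavelengths, optics$wavelengths)))
    stop("recording and optical model wavelengths differ")
  od <- optical_density(raw)
  nch <- dim(od)[1]; ns <- dim(od)[3]
  minv <- solve(optics$forward)
  # solve the 2x2 system for all channels and samples at once
  od2 <- rbind(as.vector(od[, 1, ]), as.vector(od[, 2, ]))
  hb <- minv %*% od2
  conc <- array(NA_real_, c(nch, 3, ns),
                dimnames = list(NULL, c("HbO", "HbR", "HbT"), NULL))
  conc[, 1, ] <- hb[1, ]
  conc[, 2, ] <- hb[2, ]
  conc[, 3, ] <- hb[1, ] + hb[2, ]
  hemo_recording(conc, fs = raw$fs, montage = raw$montage,
                 subject = raw$subject)
}

# Zero-phase Butterworth filtering of one series with odd-reflection padding
# to suppress end transients at very low cutoffs.
filtfilt_padded <- function(flt, x, pad) {
  n <- length(x)
  p <- min(n - 1L, pad)
  xp <- c(2 * x[1] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  y <- signal::filtfilt(flt, xp)
  y[(p + 1L):(p + n)]
}

#' Band-pass filter a hemoglobin recording
#'
#' Zero-phase (forward-backward) Butterworth band-pass, default 0.01 to
#' 0.1 Hz, the band retaining spontaneous hemodynamic fluctuations while
#' rejecting cardiac (0.8 to 1.6 Hz), respiratory (0.2 to 0.6 Hz) and
#' Mayer-wave (around 0.1 Hz) oscillations.  HbO and HbR are filtered and
#' HbT is recomputed as their sum, so the additivity invariant is preserved
#' exactly; because the filter is linear this equals filtering HbT directly.
#'
#' @param hemo A `hemo_recording`.
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth order (default 3).
#' @return Filtered `hemo_recording` with `provenance$filtered = TRUE`.
#' @export
bandpass <- function(hemo, low = 0.01, high = 0.1, order = 3) {
  stopifnot(inherits(hemo, "hemo_recording"))
  nyq <- hemo$fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < fs/2 = ", nyq)
  flt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  pad <- as.integer(round(3 * hemo$fs / low))
  conc <- hemo$conc
  for (ch in seq_len(dim(conc)[1])) {
    hbo <- filtfilt_padded(flt, conc[ch, 1, ], pad)
    hbr <- filtfilt_padded(flt, conc[ch, 2, ], pad)
    conc[ch, 1, ] <- hbo
    conc[ch, 2, ] <- hbr
    conc[ch, 3, ] <- hbo + hbr
  }
  prov <- hemo$provenance
  prov$filtered <- TRUE
  prov$band <- c(low, high)
  hemo_recording(conc, hemo$fs, hemo$montage, hemo$subject, prov)
}

#' PCA-based motion / common-mode artifact correction
#'
#' Removes the projection onto the leading principal components of the
#' channels x time matrix, separately for HbO and HbR (HbT is recomputed as
#' the sum).  Motion artifacts and superficial systemic contamination load
#' on a small number of spatially global components; removing them leaves
#' the distributed cortical covariance structure intact.
#'
#' @param hemo A `hemo_recording`.
#' @param n_components Number of leading components to remove (default 1).
#'   Must be less than the channel count.
#' @param variance_fraction Alternatively, remove the smallest number of
#'   leading components whose cumulative variance share reaches this
#'   fraction; overrides `n_components` when given.
#' @return Corrected `hemo_recording`; `provenance$pca` records the number
#'   of removed components and removed-variance fraction per chromophore.
#' @export
pca_motion_correct <- function(hemo, n_components = 1L,
                               variance_fraction = NULL) {
  stopifnot(inherits(hemo, "hemo_recording"))
  nch <- dim(hemo$conc)[1]; ns <- dim(hemo$conc)[3]
  if (nch < 2L || ns < 2L) stop("PCA correction needs >= 2 channels and samples")
  conc <- hemo$conc
  removed <- list()
  for (ci in 1:2) {
    x <- t(conc[, ci, ])                       # samples x channels
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    sv <- svd(xc)
    var_share <- sv$d^2 / sum(sv$d^2)
    k <- if (!is.null(variance_fraction)) {
      min(which(cumsum(var_share) >= variance_fraction))
    } else as.integer(n_components)
    if (k >= nch) stop("cannot remove ", k, " components from ", nch, " channels")
    if (k > 0L) {
      v <- sv$v[, seq_len(k), drop = FALSE]
      xc <- xc - (xc %*% v) %*% t(v)
    }
    conc[, ci, ] <- t(sweep(xc, 2, mu, "+"))
    removed[[c("HbO", "HbR")[ci]]] <-
      list(n_components = k,
           removed_variance = if (k > 0L) sum(var_share[seq_len(k)]) else 0)
  }
  conc[, 3, ] <- conc[, 1, ] + conc[, 2, ]
  prov <- hemo$provenance
  prov$pca_corrected <- TRUE
  prov$pca <- removed
  hemo_recording(conc, hemo$fs, hemo$montage, hemo$subject, prov)
}

#' Select the most stable contiguous segment
#'
#' Finds the contiguous window of the requested length minimizing an
#' instability score: the total across-channel energy of the first
#' difference of HbT.  Windows containing large or sudden motion transients
#' score high and are avoided.  Ties are broken by the earliest offset.
#'
#' @param hemo A `hemo_recording`.
#' @param length_s Window length in seconds (default 300, i.e. 5 min).
#' @param offset Optional fixed start sample (1-based) overriding the search,
#'   for reproducing a previous selection.
#' @return `hemo_recording` restricted to the window;
#'   `provenance$segment` records `offset` (1-based first sample), length
#'   and score.
#' @export
select_stable_segment <- function(hemo, length_s = 300, offset = NULL) {
  stopifnot(inherits(hemo, "hemo_recording"))
  ns <- dim(hemo$conc)[3]
  w <- as.integer(round(length_s * hemo$fs))
  if (w < 2L) stop("segment length too short")
  if (w > ns)
    stop("recording (", ns, " samples) is shorter than the requested segment (",
         w, " samples)")
  hbt <- hemo$conc[, 3, , drop = TRUE]
  if (is.null(dim(hbt))) hbt <- matrix(hbt, nrow = 1L)
  d2 <- rowSums(diff(t(hbt))^2)               # energy per step, length ns-1
  if (is.null(offset)) {
    csum <- c(0, cumsum(d2))
    # windows of w samples contain w-1 first differences
    scores <- csum[(w):(ns)] - csum[1:(ns - w + 1L)]
    offset <- which.min(scores)               # which.min takes the earliest tie
    score <- scores[offset]
  } else {
    offset <- as.integer(offset)
    if (offset < 1L || offset + w - 1L > ns) stop("offset out of range")
    score <- sum(d2[offset:(offset + w - 2L)])
  }
  prov <- hemo$provenance
  prov$segment <- list(offset = offset, length = w, score = score)
  hemo_recording(hemo$conc[, , offset:(offset + w - 1L), drop = FALSE],
                 hemo$fs, hemo$montage, hemo$subject, prov)
}
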