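#' Welch power spectral density
#'
#' Averaged modified periodogram (Hann window, 50% overlap) used by the
#' cardiac-component check.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param n_segments Target number of half-overlapping segments.
#' @return List with `freq` (Hz) and `power` (arbitrary density units).
#' @export
welch_psd <- function(x, fs, n_segments = 8L) {
  n <- length(x)
  seg <- max(16L, 2L^floor(log2(2 * n / (n_segments + 1L))))
  seg <- min(seg, n)
  step <- max(1L, seg %/% 2L)
  starts <- seq(1L, n - seg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1L))  # Hann
  nf <- seg %/% 2L
  acc <- numeric(nf)
  for (s in starts) {
    segx <- x[s:(s + seg - 1L)]
    segx <- (segx - mean(segx)) * win
    sp <- abs(stats::fft(segx))^2
    acc <- acc + sp[2:(nf + 1L)]
  }
  list(freq = (1:nf) * fs / seg,
       power = acc / (length(starts) * sum(win^2) * fs))
}

#' Three-rule channel quality control
#'
#' Screens every channel of a raw recording before band-pass filtering and
#' flags it as bad if it fails any of three rules:
#' \enumerate{
#'   \item \strong{corr}: its maximum Pearson correlation with every other
#'     channel (computed on unfiltered HbT) is 0 or less — the channel does
#'     not share the common physiology all coupled optodes see;
#'   \item \strong{snr}: the raw-intensity signal-to-noise ratio (temporal
#'     mean / temporal SD, minimum over the two wavelengths) is below 2;
#'   \item \strong{cardiac}: the cardiac component is absent — the spectral
#'     power fraction in the 0.8 to 1.6 Hz band of the longer-wavelength
#'     intensity is below `cardiac_ratio_min` \emph{and} no local spectral
#'     peak stands out in that band.
#' }
#'
#' @param raw A `raw_recording` (not yet band-passed; the cardiac band must
#'   be intact).
#' @param hemo_unfiltered The matching unfiltered `hemo_recording`
#'   (recomputed via [mbll_convert()] when omitted).
#' @param snr_min SNR threshold (default 2).
#' @param cardiac_band Cardiac frequency band in Hz.
#' @param cardiac_ratio_min Minimum in-band power fraction (default 0.05).
#' @param peak_factor A channel "has a cardiac peak" when its maximum
#'   in-band Welch power exceeds `peak_factor` times the median power above
#'   0.5 Hz (default 5).
#' @return A `qc_report`: data.frame with one row per channel
#'   (`channel`, `snr`, `max_corr`, `cardiac_ratio`, `cardiac_peak`, `bad`,
#'   `reasons`).  `bad` is `TRUE` iff `reasons` is nonempty.
#' @export
prune_channels <- function(raw, hemo_unfiltered = NULL, snr_min = 2,
                           cardiac_band = c(0.8, 1.6),
                           cardiac_ratio_min = 0.05, peak_factor = 5) {
  stopifnot(inherits(raw, "raw_recording"))
  nch <- dim(raw$intensity)[1]
  if (nch < 2L) stop("channel pruning needs at least 2 channels (the correlation rule is undefined)")
  if (is.null(hemo_unfiltered)) hemo_unfiltered <- mbll_convert(raw)
  stopifnot(inherits(hemo_unfiltered, "hemo_recording"))
  if (isTRUE(hemo_unfiltered$provenance$filtered))
    warning("quality control expects unfiltered hemoglobin series; the cardiac band may already be attenuated")

  # rule 2: intensity SNR, min over wavelengths
  mu <- apply(raw$intensity, c(1, 2), mean)
  sdv <- apply(raw$intensity, c(1, 2), stats::sd)
  snr <- apply(mu / sdv, 1L, min)

  # rule 1: between-channel correlation on unfiltered HbT
  hbt <- chromophore_matrix(hemo_unfiltered, "HbT")
  sds <- apply(hbt, 1L, stats::sd)
  cm <- suppressWarnings(stats::cor(t(hbt)))
  diag(cm) <- NA
  max_corr <- apply(cm, 1L, function(z) if (all(is.na(z))) NA_real_
                                        else max(z, na.rm = TRUE))

  # rule 3: cardiac spectral content of the longer-wavelength intensity
  wl_idx <- which.max(raw$wavelengths)
  cardiac_ratio <- numeric(nch)
  cardiac_peak <- logical(nch)
  for (ch in seq_len(nch)) {
    psd <- welch_psd(raw$intensity[ch, wl_idx, ], raw$fs)
    inband <- psd$freq >= cardiac_band[1] & psd$freq <= cardiac_band[2]
    tot <- sum(psd$power)
    cardiac_ratio[ch] <- if (tot > 0) sum(psd$power[inband]) / tot else 0
    ref <- stats::median(psd$power[psd$freq >= 0.5])
    cardiac_peak[ch] <- any(inband) && ref > 0 &&
      max(psd$power[inband]) > peak_factor * ref
  }

  reasons <- vapply(seq_len(nch), function(ch) {
    r <- character()
    if (is.na(max_corr[ch]) || max_corr[ch] <= 0) r <- c(r, "corr")
    if (snr[ch] < snr_min) r <- c(r, "snr")
    if (cardiac_ratio[ch] < cardiac_ratio_min && !cardiac_peak[ch])
      r <- c(r, "cardiac")
    paste(r, collapse = ",")
  }, character(1))

  structure(data.frame(channel = seq_len(nch), snr = snr,
                       max_corr = max_corr, cardiac_ratio = cardiac_ratio,
                       cardiac_peak = cardiac_peak,
                       bad = nzchar(reasons), reasons = reasons,
                       row.names = NULL),
            class = c("qc_report", "data.frame"))
}

#' Good channels of a QC report
#'
#' @param qc A `qc_report`.
#' @return Integer vector of channels not flagged bad.
#' @export
good_channels <- function(qc) {
  stopifnot(inherits(qc, "qc_report"))
  qc$channel[!qc$bad]
}

#' Mask pruned channels out of a downstream object
#'
#' Marks bad channels as missing so that connectivity matrices, region
#' averages and networks use only surviving channels (renormalizing by the
#' surviving count); pruned channels are dropped, never interpolated.
#'
#' @param x A `fc_matrix` or `hemo_recording`.
#' @param qc A `qc_report` whose channel ids match `x`.
#' @return The masked object: for a `fc_matrix`, bad rows/columns become
#'   `NA`; for a `hemo_recording`, an `active` logical vector is attached.
#' @export
apply_mask <- function(x, qc) UseMethod("apply_mask")

#' @export
apply_mask.fc_matrix <- function(x, qc) {
  stopifnot(inherits(qc, "qc_report"), nrow(qc) == nrow(x))
  if (all(qc$bad)) stop("all channels failed quality control")
  bad <- qc$channel[qc$bad]
  x[bad, ] <- NA_real_
  x[, bad] <- NA_real_
  attr(x, "active") <- attr(x, "active") & !qc$bad
  x
}

#' @export
apply_mask.hemo_recording <- function(x, qc) {
  stopifnot(inherits(qc, "qc_report"), nrow(qc) == dim(x$conc)[1])
  if (all(qc$bad)) stop("all channels failed quality control")
  x$active <- !qc$bad
  x
}

#' Serialize a QC report
#'
#' @param qc A `qc_report`.
#' @param path Output path; `.json` gets a JSON array, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  stopifnot(inherits(qc, "qc_report"))
  if (grepl("\\.json$", path))
    jsonlite::write_json(qc, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  else utils::write.csv(qc, path, row.names = FALSE)
  invisible(path)
}
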